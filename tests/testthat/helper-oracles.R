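# Independent brute-force oracles and tiny fixture builders shared by the
# suite. Oracles deliberately use different algorithms from the package.

# ring graph of n spots (each spot has neighbours i-1, i+1 modulo n)
make_ring_graph <- function(n) {
  nbr <- lapply(seq_len(n), function(i)
    sort(c((i - 2) %% n + 1, i %% n + 1)))
  edges <- cbind(i = seq_len(n),
                 j = as.integer(seq_len(n) %% n + 1L))
  sw <- edges[, 1] > edges[, 2]
  edges[sw, ] <- edges[sw, c(2, 1)]
  structure(list(spot_id = sprintf("r%03d", seq_len(n)), n = n, nbr = nbr,
                 degree = lengths(nbr), edges = edges,
                 lattice_index = seq_len(n), tolerance_um = 0),
            class = "spot_graph")
}

# path graph of n spots
make_path_graph <- function(n) {
  nbr <- lapply(seq_len(n), function(i)
    Filter(function(j) j >= 1 && j <= n, c(i - 1, i + 1)))
  edges <- cbind(i = seq_len(n - 1), j = 2:n)
  structure(list(spot_id = sprintf("p%03d", seq_len(n)), n = n,
                 nbr = nbr, degree = lengths(nbr), edges = edges,
                 lattice_index = seq_len(n), tolerance_um = 0),
            class = "spot_graph")
}

# Moran's I by the literal double sum over the dense weight matrix
moran_bruteforce <- function(values, graph) {
  n <- graph$n
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
    w[i, j] <- 1; w[j, i] <- 1
  }
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# DBSCAN by explicit density-reachability over the dense distance matrix;
# numbering and border tie-break mirror the documented contract (clusters
# in order of first core point, borders to the lowest cluster id)
dbscan_oracle <- function(points, eps, min_samples) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(cbind(points$x_um, points$y_um)))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neigh, length, 0L) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i]) next
    cl <- cl + 1L
    todo <- i
    while (length(todo)) {
      cur <- todo[1]; todo <- todo[-1]
      if (labels[cur]) next
      labels[cur] <- cl
      todo <- c(todo, Filter(function(j) core[j] && !labels[j],
                             neigh[[cur]]))
    }
  }
  for (i in which(!core)) {
    cn <- neigh[[i]][core[neigh[[i]]]]
    if (length(cn)) labels[i] <- min(labels[cn])
  }
  labels
}

# connected components of positive spots by iterative min-label propagation
flood_fill_oracle <- function(states, graph) {
  labels <- ifelse(states, seq_len(graph$n), NA_integer_)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
      if (!is.na(labels[i]) && !is.na(labels[j]) &&
          labels[i] != labels[j]) {
        m <- min(labels[i], labels[j])
        labels[i] <- m; labels[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(which(!is.na(labels)), labels[!is.na(labels)])
  unname(lapply(comps, sort))
}

# all-pairs BFS distances through repeated boolean adjacency products
bfs_oracle <- function(graph, source) {
  n <- graph$n
  A <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    A[graph$edges[r, 1], graph$edges[r, 2]] <- TRUE
    A[graph$edges[r, 2], graph$edges[r, 1]] <- TRUE
  }
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  reach <- seq_len(n) == source
  for (k in seq_len(n)) {
    nxt <- (A %*% reach) > 0
    new <- nxt & is.na(dist)
    if (!any(new)) break
    dist[new] <- k
    reach <- reach | nxt
  }
  dist
}

jaccard_sets <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

# minimal lognorm counts_matrix from a dense matrix
lognorm_matrix <- function(m) {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("u%04d", seq_len(ncol(m)))
  counts_matrix(m, layer = "lognorm")
}

raw_matrix <- function(m) {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("u%04d", seq_len(ncol(m)))
  counts_matrix(m, layer = "raw")
}

isg_gene_set <- function(cfg)
  gene_set("ISG_score", cfg$panel$gene[cfg$panel$role == "ISG"], "ISG")

# pooled-replicate control calibration used throughout (threshold at the
# 1 - 1/N quantile of three pooled matched control samples)
calibrate_on_controls <- function(cfg, n_rep = 3) {
  isg <- isg_gene_set(cfg)
  pooled <- do.call(pool_scores, lapply(seq_len(n_rep), function(r)
    score_gene_set(make_control_sample(cfg, r)$counts, isg,
                   "summed_counts")))
  calibrate_threshold(pooled, quantile = 1 - 1 / length(pooled))
}

segment_sample <- function(sample, thr) {
  isg <- isg_gene_set(sample$truth$config)
  sc <- score_gene_set(sample$counts, isg, "summed_counts")
  st <- binarize_score(sc, thr)
  list(colonies = segment_colonies(unname(st), sample$graph),
       scores = sc, states = unname(st))
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(lattice_rows = 24, lattice_cols = 24, iz_radius_um = 350,
             bz_width_um = 200, seed = seed, ...)
}
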