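#' Assign centroid and neighbour rings around colonies
#'
#' Breadth-first shells of lattice graph distance 1..`max_ring` around each
#' colony centroid: distance 1 spots are primary neighbours, 2 secondary, 3
#' tertiary (one ring corresponds to 100 um at the default pitch). A spot
#' that belongs to a colony keeps the assignment relative to its own
#' colony's centroid; any other spot is assigned to its nearest centroid,
#' ties resolved toward the lower colony id.
#'
#' @param colonies a `colony_set` annotated by [colony_stats()] (provides
#'   centroids).
#' @param graph a `spot_graph`.
#' @param max_ring outermost ring (default 3).
#' @return data.frame (`spot_id`, `ring` factor with levels `centroid`,
#'   `primary`, `secondary`, `tertiary`[, ...], `none`; `colony` id or NA;
#'   `ring_k` integer graph distance or NA).
#' @export
assign_rings <- function(colonies, graph, max_ring = 3) {
  stopifnot(inherits(colonies, "colony_set"), inherits(graph, "spot_graph"))
  if (is.null(colonies$stats))
    stop("colonies lack centroid annotation; run colony_stats() first")
  n <- graph$n
  ring_k <- rep(NA_integer_, n)
  colony_id <- rep(NA_integer_, n)
  member_of <- rep(NA_integer_, n)
  for (k in seq_along(colonies$colonies))
    member_of[colonies$colonies[[k]]] <- k
  for (k in seq_along(colonies$colonies)) {
    d <- bfs_distance(graph, colonies$stats$centroid[k],
                      max_depth = max_ring)
    upd <- which(!is.na(d) &
                   (is.na(member_of) | member_of == k))
    for (i in upd) {
      own <- !is.na(member_of[i]) && member_of[i] == k
      better <- is.na(ring_k[i]) || d[i] < ring_k[i] ||
        (d[i] == ring_k[i] && k < colony_id[i])
      if (own || (is.na(member_of[i]) && better)) {
        ring_k[i] <- d[i]
        colony_id[i] <- k
      }
    }
  }
  ring_names <- c("centroid", "primary", "secondary", "tertiary")
  if (max_ring > 3)
    ring_names <- c(ring_names, paste0("ring", 4:max_ring))
  lab <- ifelse(is.na(ring_k), "none", ring_names[ring_k + 1L])
  data.frame(spot_id = graph$spot_id,
             ring = factor(lab, levels = c(ring_names[seq_len(max_ring + 1)],
                                           "none")),
             colony = colony_id, ring_k = ring_k,
             stringsAsFactors = FALSE)
}

#' Ring-wise differential expression against colony centroids
#'
#' For every ring k = 1..max assigned, compares ring-k spots against the
#' pooled centroid spots gene-by-gene with Wilcoxon rank-sum tests (BH
#' adjusted over genes within the ring); the effect is the natural-log fold
#' change of ring over centroid. Rings with fewer than `min_group` spots
#' are skipped with a warning.
#'
#' @param x `counts_matrix`, lognorm layer, units in graph order.
#' @param rings output of [assign_rings()].
#' @param min_group minimal group size per comparison (default 3).
#' @return data.frame (`ring`, `gene`, `lnfc`, `p`, `p_adj`).
#' @export
ring_de <- function(x, rings, min_group = 3) {
  stopifnot(inherits(x, "counts_matrix"))
  if (x$layer != "lognorm") stop("ring_de expects the lognorm layer")
  m <- as.matrix(x$counts)
  stopifnot(ncol(m) == nrow(rings))
  cent <- which(rings$ring == "centroid")
  if (length(cent) < min_group)
    stop("fewer centroid spots than min_group")
  ring_levels <- setdiff(levels(rings$ring), c("centroid", "none"))
  out <- list()
  for (rl in ring_levels) {
    sel <- which(rings$ring == rl)
    if (length(sel) < min_group) {
      warning(sprintf("ring '%s' has %d spots (< %d); skipped",
                      rl, length(sel), min_group))
      next
    }
    lnfc <- vapply(seq_len(nrow(m)),
                   function(g) lnfc_of(m[g, sel], m[g, cent]), 0)
    p <- vapply(seq_len(nrow(m)), function(g) {
      a <- m[g, sel]; b <- m[g, cent]
      if (stats::var(c(a, b)) == 0) return(1)
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                          correct = TRUE)$p.value)
    }, 0)
    out[[rl]] <- data.frame(ring = rl, gene = rownames(m), lnfc = lnfc,
                            p = p, p_adj = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Line scan of a gene score along a reference vector
#'
#' Projects spots within a perpendicular band around the segment
#' `p0 -> p1` onto it and reports the mean and standard error of the score
#' per distance bin, emulating a scan from the infarct zone toward the
#' borderzone.
#'
#' @param scores per-spot `score_vector` (or numeric), lattice order.
#' @param lattice a `spot_lattice`.
#' @param p0,p1 segment endpoints in micrometres (distinct).
#' @param bin_um bin width along the vector (default 100).
#' @param band_halfwidth_um maximal perpendicular distance (default 200).
#' @return data.frame (`bin_start_um`, `bin_end_um`, `mean`, `se`, `n`).
#' @export
line_scan <- function(scores, lattice, p0, p1, bin_um = 100,
                      band_halfwidth_um = 200) {
  stopifnot(length(p0) == 2, length(p1) == 2)
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  L <- sqrt(sum(v^2))
  if (L == 0) stop("p0 and p1 must be distinct")
  u <- v / L
  s <- as.numeric(scores)
  stopifnot(length(s) == nrow(lattice))
  rx <- lattice$x_um - p0[1]; ry <- lattice$y_um - p0[2]
  t_along <- rx * u[1] + ry * u[2]
  d_perp <- abs(rx * (-u[2]) + ry * u[1])
  keep <- lattice$in_tissue & t_along >= 0 & t_along <= L &
    d_perp <= band_halfwidth_um
  if (!any(keep)) stop("no spot falls inside the scan band")
  edges <- seq(0, L + bin_um, by = bin_um)
  bin <- cut(t_along[keep], breaks = edges, include.lowest = TRUE,
             right = FALSE)
  agg <- tapply(s[keep], bin, function(z)
    c(mean = mean(z), se = stats::sd(z) / sqrt(length(z)), n = length(z)))
  used <- !vapply(agg, is.null, TRUE)
  res <- do.call(rbind, agg[used])
  idx <- which(used)
  data.frame(bin_start_um = edges[idx], bin_end_um = edges[idx + 1],
             mean = res[, "mean"], se = res[, "se"],
             n = as.integer(res[, "n"]), row.names = NULL)
}

#' Fraction of query-positive spots per distance shell around a reference
#'
#' For each lattice-distance shell around the reference spot set (one shell
#' per ring, 100 um per ring at the default pitch, out to
#' `max_distance_um`), reports the fraction of shell spots that are
#' query-positive — the second-order neighbour fraction profile.
#'
#' @param reference_states logical per-spot reference indicator (non-empty).
#' @param query_states logical per-spot query indicator.
#' @param graph a `spot_graph`.
#' @param spacing_um lattice pitch used to convert rings to distance.
#' @param max_distance_um outermost shell distance (default 400).
#' @return data.frame (`ring`, `distance_um`, `fraction`, `n_shell`).
#' @export
neighbor_fraction_profile <- function(reference_states, query_states, graph,
                                      spacing_um = 100,
                                      max_distance_um = 400) {
  stopifnot(inherits(graph, "spot_graph"),
            length(reference_states) == graph$n,
            length(query_states) == graph$n)
  reference_states <- as.logical(reference_states)
  query_states <- as.logical(query_states)
  if (!any(reference_states)) stop("reference set is empty")
  max_ring <- floor(max_distance_um / spacing_um)
  d <- bfs_distance(graph, which(reference_states), max_depth = max_ring)
  do.call(rbind, lapply(seq_len(max_ring), function(k) {
    shell <- which(!is.na(d) & d == k)
    data.frame(ring = k, distance_um = k * spacing_um,
               fraction = if (length(shell)) mean(query_states[shell])
               else NA_real_,
               n_shell = length(shell))
  }))
}
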