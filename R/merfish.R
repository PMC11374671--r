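# fixed-radius neighbour counts / lists via grid binning (2D, um)
radius_neighbors <- function(x, y, radius, return_lists = FALSE) {
  n <- length(x)
  cell <- radius
  cx <- floor(x / cell); cy <- floor(y / cell)
  key <- paste(cx, cy)
  bins <- split(seq_len(n), key)
  counts <- integer(n)
  lists <- if (return_lists) vector("list", n) else NULL
  env <- list2env(bins, hash = TRUE)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- env[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    hit <- cand[d2 <= radius^2]
    counts[i] <- length(hit)           # includes the point itself
    if (return_lists) lists[[i]] <- hit
  }
  list(counts = counts, lists = lists)
}

#' Select a DBSCAN radius from the k-nearest-neighbour curve
#'
#' Sorts the distance of each point to its k-th nearest neighbour and
#' returns the radius at the knee of the curve, found kneedle-style: the
#' top 5% of the curve (extreme outliers) is trimmed, both axes are
#' normalized to [0, 1] on a coarse grid, and the knee is the point of
#' maximal deviation from the chord joining the curve ends. The full
#' sorted curve is attached for inspection.
#'
#' @param points data.frame with `x_um`, `y_um`.
#' @param k neighbour order (needs at least k+1 points).
#' @return selected radius (um) with the sorted curve as attribute
#'   `knn_curve`.
#' @export
select_eps <- function(points, k = 10) {
  n <- nrow(points)
  if (n < k + 1)
    stop(sprintf("need at least k+1 = %d points (have %d)", k + 1, n))
  x <- points$x_um; y <- points$y_um
  d <- as.matrix(stats::dist(cbind(x, y)))
  kdist <- apply(d, 1, function(r) sort(r)[k + 1])  # row includes self at 0
  curve <- sort(kdist)
  nt <- max(floor(n * 0.95), 3)
  m <- min(50, nt)
  grid <- stats::approx(seq_len(nt), curve[seq_len(nt)],
                        xout = seq(1, nt, length.out = m))$y
  gx <- seq(0, 1, length.out = m)
  gy <- (grid - grid[1]) / max(grid[m] - grid[1], .Machine$double.eps)
  knee <- which.max(abs(gx - gy))
  eps <- grid[knee]
  attr(eps, "knn_curve") <- curve
  eps
}

#' Density-based clustering of decoded transcript points (DBSCAN)
#'
#' Classical DBSCAN semantics: a point is a core point when at least
#' `min_samples` points (itself included) lie within `eps`; clusters are
#' the connected components of core points at distance <= eps, with
#' non-core points within `eps` of a core attached as border points
#' (deterministically, to the lowest eligible cluster id); remaining points
#' are noise. Cluster ids are numbered by order of the first member point.
#'
#' @param points data.frame with `x_um`, `y_um`.
#' @param eps radius in micrometres (default 70).
#' @param min_samples density threshold including the point itself
#'   (default 10).
#' @return integer vector of cluster ids, 0 for noise.
#' @export
dbscan_cluster <- function(points, eps = 70, min_samples = 10) {
  stopifnot(eps > 0, min_samples >= 2)
  n <- nrow(points)
  if (!n) return(integer(0))
  nb <- radius_neighbors(points$x_um, points$y_um, eps,
                         return_lists = TRUE)
  core <- nb$counts >= min_samples
  labels <- integer(n)  # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      reach <- unique(unlist(nb$lists[frontier], use.names = FALSE))
      reach <- reach[core[reach] & labels[reach] == 0L]
      labels[reach] <- cl
      frontier <- reach
    }
  }
  # border points: lowest cluster id among core neighbours
  for (i in which(!core)) {
    cn <- nb$lists[[i]]
    cn <- cn[core[cn]]
    if (length(cn)) labels[i] <- min(labels[cn])
  }
  labels
}

#' Classify ISG transcript points into colonies and scattered expression
#'
#' DBSCAN clusters of ISG transcript points are IFNIC colonies; noise
#' points are scattered ISG expression.
#'
#' @param isg_points data.frame of points already filtered to ISG species.
#' @param eps,min_samples DBSCAN parameters (defaults 70 um, 10).
#' @return list with `labels` (per-point cluster id, 0 = scattered),
#'   `n_clusters`, `cluster_sizes`, `scattered` (row indices).
#' @export
classify_isg_clusters <- function(isg_points, eps = 70, min_samples = 10) {
  labels <- dbscan_cluster(isg_points, eps = eps,
                           min_samples = min_samples)
  list(labels = labels,
       n_clusters = length(setdiff(unique(labels), 0L)),
       cluster_sizes = if (any(labels > 0))
         as.integer(table(labels[labels > 0])) else integer(0),
       scattered = which(labels == 0L))
}

#' Cell-type composition of point-cloud colonies
#'
#' A cell is positive for the scored species when at least
#' `positive_min_transcripts` of its assigned points are that species.
#' Composition is reported over positive cells whose centroids fall within
#' each cluster's spatial extent (the convex hull of its points).
#'
#' @param labels per-point cluster ids from [classify_isg_clusters()]
#'   (aligned to `rna_points` rows).
#' @param rna_points data.frame with `x_um`, `y_um`, `species`, `cell_id`.
#' @param cell_table data.frame with `cell_id`, `x_um`, `y_um`,
#'   `cell_type`.
#' @param positive_min_transcripts minimal assigned transcripts (default 1).
#' @return list per cluster: data.frame of cell-type proportions and the
#'   positive-cell ids; cells lacking a type label are excluded (count
#'   logged as attribute `n_untyped`).
#' @export
colony_composition <- function(labels, rna_points, cell_table,
                               positive_min_transcripts = 1) {
  stopifnot(length(labels) == nrow(rna_points),
            all(c("cell_id", "cell_type") %in% names(cell_table)))
  per_cell <- table(rna_points$cell_id)
  positive_cells <- names(per_cell)[per_cell >= positive_min_transcripts]
  type_of <- stats::setNames(cell_table$cell_type, cell_table$cell_id)
  untyped <- positive_cells[!positive_cells %in% names(type_of) |
                              is.na(type_of[positive_cells])]
  positive_cells <- setdiff(positive_cells, untyped)
  clusters <- sort(setdiff(unique(labels), 0L))
  out <- lapply(clusters, function(cl) {
    pts <- rna_points[labels == cl, , drop = FALSE]
    hull <- grDevices::chull(pts$x_um, pts$y_um)
    hx <- pts$x_um[hull]; hy <- pts$y_um[hull]
    cells <- cell_table[cell_table$cell_id %in% positive_cells, ,
                        drop = FALSE]
    inside <- point_in_polygon(cells$x_um, cells$y_um, hx, hy)
    members <- cells$cell_id[inside]
    tt <- table(factor(type_of[members]))
    list(cluster = cl,
         n_cells = length(members),
         proportions = if (length(members)) as.data.frame(tt / sum(tt),
                                                          responseName = "proportion")
         else data.frame(Var1 = character(0), proportion = numeric(0)),
         positive_cells = members)
  })
  names(out) <- paste0("cluster_", clusters)
  attr(out, "n_untyped") <- length(untyped)
  out
}

# even-odd ray-casting point-in-polygon (boundary-inclusive within eps)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cond <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cond & !is.na(cond))
    j <- i
  }
  inside
}

#' Classify decoded DNA loci as nuclear or extranuclear
#'
#' Nuclear loci are those in dense neighbourhoods: at least `min_neighbors`
#' decoded loci (the point itself included) within `radius_um`. Sparse loci
#' outside such neighbourhoods are extranuclear DNA. When a z coordinate is
#' present, loci within `z_edge_um` of either section face are excluded
#' first (cryosectioning shearing artefacts).
#'
#' @param loci data.frame with `x_um`, `y_um`, optional `z_um`.
#' @param radius_um neighbourhood radius (default 5).
#' @param min_neighbors neighbourhood total including the locus itself
#'   (default 10).
#' @param z_edge_um excluded depth at each section face (default 5).
#' @param section_thickness_um section thickness; required for the upper
#'   face exclusion when `z_um` is present (defaults to `max(z_um)`).
#' @return factor per locus: `nuclear`, `extranuclear`, `edge_excluded`.
#' @export
classify_extranuclear <- function(loci, radius_um = 5, min_neighbors = 10,
                                  z_edge_um = 5,
                                  section_thickness_um = NULL) {
  stopifnot(radius_um > 0, min_neighbors >= 2)
  n <- nrow(loci)
  lab <- rep("nuclear", n)
  keep <- rep(TRUE, n)
  if ("z_um" %in% names(loci)) {
    thickness <- if (is.null(section_thickness_um)) max(loci$z_um) else
      section_thickness_um
    keep <- loci$z_um >= z_edge_um & loci$z_um <= thickness - z_edge_um
    lab[!keep] <- "edge_excluded"
  }
  if (any(keep)) {
    counts <- radius_neighbors(loci$x_um[keep], loci$y_um[keep],
                               radius_um)$counts
    lab[keep][counts < min_neighbors] <- "extranuclear"
  }
  factor(lab, levels = c("nuclear", "extranuclear", "edge_excluded"))
}

#' Nuclear solidity from label masks
#'
#' Solidity of each nucleus mask is its pixel area divided by the area of
#' the convex hull of its pixel centres (shoelace formula), both in square
#' micrometres; values well below 1 indicate an irregular, deformed
#' nuclear contour. Each mask must be a single 8-connected region.
#'
#' @param masks a `nucleus_masks` object (integer label matrix +
#'   `um_per_px`).
#' @return data.frame (`nucleus`, `area_um2`, `hull_area_um2`, `solidity`).
#' @export
nuclear_solidity <- function(masks) {
  stopifnot(inherits(masks, "nucleus_masks"))
  lab <- masks$labels
  upp <- masks$um_per_px
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  out <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    if (n_components_8(w) != 1)
      stop(sprintf("mask %d has %d connected components; expected one",
                   id, n_components_8(w)))
    x <- w[, "col"] * upp; y <- w[, "row"] * upp
    hull <- grDevices::chull(x, y)
    hull_area <- polygon_area(x[hull], y[hull])
    data.frame(nucleus = id, area_um2 = nrow(w) * upp^2,
               hull_area_um2 = hull_area,
               solidity = nrow(w) * upp^2 / hull_area)
  })
  do.call(rbind, out)
}

# number of 8-connected components among pixel coordinates (vectorized
# flood fill by morphological dilation on the bounding-box submatrix)
n_components_8 <- function(w) {
  n <- nrow(w)
  if (!n) return(0L)
  r0 <- min(w[, 1]); c0 <- min(w[, 2])
  nr <- max(w[, 1]) - r0 + 3L; nc <- max(w[, 2]) - c0 + 3L
  region <- matrix(FALSE, nr, nc)
  region[cbind(w[, 1] - r0 + 2L, w[, 2] - c0 + 2L)] <- TRUE
  dilate8 <- function(m) {
    d <- m
    d[-1, ] <- d[-1, ] | m[-nr, ]
    d[-nr, ] <- d[-nr, ] | m[-1, ]
    e <- d
    e[, -1] <- e[, -1] | d[, -nc]
    e[, -nc] <- e[, -nc] | d[, -1]
    e
  }
  comps <- 0L
  while (any(region)) {
    comps <- comps + 1L
    comp <- matrix(FALSE, nr, nc)
    comp[which(region)[1]] <- TRUE
    repeat {
      grown <- dilate8(comp) & region
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    region <- region & !comp
  }
  comps
}
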