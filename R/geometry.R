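#' Construct a hexagonal spot lattice
#'
#' Builds a Visium-style hexagonal lattice of capture spots. Array indices
#' follow the Visium dialect: within array row `r`, array columns share the
#' parity of `r` and step by 2, so that the six first-order neighbours of an
#' interior spot sit at array offsets (0, +/-2) and (+/-1, +/-1). Physical
#' coordinates are micrometres with the origin at the top-left spot centre and
#' y increasing downward (image convention):
#' `x = col * spacing / 2`, `y = row * spacing * sqrt(3) / 2`, which puts
#' adjacent spot centres exactly `spacing_um` apart.
#'
#' @param rows,cols number of array rows and of spots per row.
#' @param spacing_um centre-to-centre distance of adjacent spots (default
#'   100, the Visium pitch).
#' @param diameter_um capture-spot diameter (default 55).
#' @return A `data.frame` of class `spot_lattice` with columns `spot_id`,
#'   `array_row`, `array_col`, `x_um`, `y_um`, `in_tissue`, and attributes
#'   `spacing_um`, `diameter_um`.
#' @export
hex_lattice <- function(rows, cols, spacing_um = 100, diameter_um = 55) {
  stopifnot(rows >= 1, cols >= 1, spacing_um > diameter_um, diameter_um > 0)
  array_row <- rep(seq_len(rows) - 1L, each = cols)
  array_col <- as.integer(array_row %% 2L) + 2L * rep(seq_len(cols) - 1L, rows)
  lat <- data.frame(
    spot_id   = sprintf("spot_%05d", seq_len(rows * cols)),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    x_um      = array_col * spacing_um / 2,
    y_um      = array_row * spacing_um * sqrt(3) / 2,
    in_tissue = TRUE,
    stringsAsFactors = FALSE
  )
  attr(lat, "spacing_um") <- spacing_um
  attr(lat, "diameter_um") <- diameter_um
  class(lat) <- c("spot_lattice", "data.frame")
  lat
}

lattice_spacing <- function(lattice) {
  s <- attr(lattice, "spacing_um")
  if (is.null(s)) stop("lattice lacks a spacing_um attribute")
  s
}

lattice_diameter <- function(lattice) {
  d <- attr(lattice, "diameter_um")
  if (is.null(d)) stop("lattice lacks a diameter_um attribute")
  d
}

#' Assign concentric infarct zones to lattice spots
#'
#' Zones follow a concentric-disk geometry around the infarct centre: spots
#' within `iz_radius_um` are infarct zone (IZ), spots in the annulus of width
#' `bz_width_um` beyond it are borderzone (BZ), and all remaining tissue is
#' remote zone (RZ).
#'
#' @param lattice a `spot_lattice`.
#' @param center numeric length-2, infarct centre in micrometres.
#' @param iz_radius_um radius of the infarct zone disk.
#' @param bz_width_um width of the borderzone annulus.
#' @return factor of levels `RZ`, `BZ`, `IZ` aligned to lattice rows.
#' @export
assign_zones <- function(lattice, center, iz_radius_um, bz_width_um) {
  stopifnot(length(center) == 2, iz_radius_um > 0, bz_width_um > 0)
  d <- sqrt((lattice$x_um - center[1])^2 + (lattice$y_um - center[2])^2)
  zone <- ifelse(d <= iz_radius_um, "IZ",
                 ifelse(d <= iz_radius_um + bz_width_um, "BZ", "RZ"))
  factor(zone, levels = c("RZ", "BZ", "IZ"))
}

#' Build the first-order spot adjacency graph
#'
#' Connects tissue spots whose centre-to-centre distance lies within
#' `tolerance_um` of the lattice spacing. Interior spots of a full hexagonal
#' lattice have exactly six neighbours; isolated spots are allowed.
#'
#' @param lattice a `spot_lattice`; only `in_tissue` spots enter the graph.
#' @param tolerance_um absolute distance tolerance in micrometres.
#' @return A `spot_graph`: list with `spot_id`, `n`, neighbour index lists
#'   `nbr` (indices into the tissue spots), `degree`, an `edges` matrix of
#'   index pairs (i < j), and the row indices `lattice_index` mapping back
#'   into the lattice.
#' @export
build_adjacency <- function(lattice, tolerance_um = 1.0) {
  keep <- which(lattice$in_tissue)
  x <- lattice$x_um[keep]; y <- lattice$y_um[keep]
  sp <- lattice_spacing(lattice)
  n <- length(keep)
  # snap spots to a half-spacing grid: on a physical lattice (diameter <
  # spacing) every grid cell holds at most one spot, so neighbour search
  # reduces to vectorized key matching over the 5x3 surrounding cells
  gx <- round(2 * x / sp); gy <- round(2 * y / (sp * sqrt(3)))
  koff <- 2 * max(abs(gy)) + 4
  key <- gx * koff + gy
  pairs_i <- integer(0); pairs_j <- integer(0)
  if (!anyDuplicated(key)) {
    for (dx in -2:2) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      j <- match((gx + dx) * koff + gy + dy, key)
      ok <- which(!is.na(j) & j > seq_len(n))
      if (!length(ok)) next
      d <- sqrt((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
      hit <- abs(d - sp) <= tolerance_um
      pairs_i <- c(pairs_i, ok[hit])
      pairs_j <- c(pairs_j, j[ok][hit])
    }
  } else {
    # irregular coordinates: generic binned all-pairs search
    cell <- sp * 1.5
    bkey <- paste(floor(x / cell), floor(y / cell))
    bins <- split(seq_len(n), bkey)
    for (k in names(bins)) {
      ab <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
      neighbours <- integer(0)
      for (dx in -1:1) for (dy in -1:1)
        neighbours <- c(neighbours, bins[[paste(ab[1] + dx, ab[2] + dy)]])
      for (i in bins[[k]]) {
        cand <- neighbours[neighbours > i]
        if (!length(cand)) next
        d <- sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2)
        hit <- cand[abs(d - sp) <= tolerance_um]
        pairs_i <- c(pairs_i, rep.int(i, length(hit)))
        pairs_j <- c(pairs_j, hit)
      }
    }
  }
  nbr <- vector("list", n)
  if (length(pairs_i)) {
    all_i <- c(pairs_i, pairs_j); all_j <- c(pairs_j, pairs_i)
    o <- order(all_i)
    nbr <- unname(split(all_j[o], factor(all_i[o], levels = seq_len(n))))
  } else {
    nbr <- replicate(n, integer(0), simplify = FALSE)
  }
  structure(list(
    spot_id = lattice$spot_id[keep],
    n = n,
    nbr = nbr,
    degree = lengths(nbr),
    edges = cbind(i = pairs_i, j = pairs_j),
    lattice_index = keep,
    tolerance_um = tolerance_um
  ), class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("spot_graph: %d spots, %d edges, mean degree %.2f\n",
              x$n, nrow(x$edges), mean(x$degree)))
  invisible(x)
}

# sparse symmetric binary adjacency matrix of a spot_graph
adjacency_matrix <- function(graph) {
  e <- graph$edges
  if (!nrow(e)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(graph$n, graph$n)))
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(graph$n, graph$n))
}

#' Breadth-first lattice distances from a set of source spots
#'
#' @param graph a `spot_graph`.
#' @param sources integer indices of the source spots.
#' @param max_depth stop after this many shells (`Inf` for all).
#' @return integer vector of graph distances (`NA` where unreachable or
#'   beyond `max_depth`); sources are at distance 0.
#' @export
bfs_distance <- function(graph, sources, max_depth = Inf) {
  dist <- rep(NA_integer_, graph$n)
  sources <- unique(as.integer(sources))
  stopifnot(all(sources >= 1 & sources <= graph$n))
  dist[sources] <- 0L
  frontier <- sources
  depth <- 0L
  while (length(frontier) && depth < max_depth) {
    depth <- depth + 1L
    nxt <- unique(unlist(graph$nbr[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- depth
    frontier <- nxt
  }
  dist
}

# connected components of an induced subgraph over `which_spots` (logical or
# integer); returns list of integer index vectors
graph_components <- function(graph, which_spots) {
  if (is.logical(which_spots)) which_spots <- which(which_spots)
  inset <- logical(graph$n); inset[which_spots] <- TRUE
  seen <- logical(graph$n)
  comps <- list()
  for (s in which_spots) {
    if (seen[s]) next
    comp <- integer(0)
    frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nxt <- unique(unlist(graph$nbr[frontier], use.names = FALSE))
      nxt <- nxt[inset[nxt] & !seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
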