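#' Moran's I spatial autocorrelation on a spot graph
#'
#' Classical Moran's I with binary contiguity weights over the first-order
#' lattice graph:
#' `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `w_ij` in {0, 1} and `W` the number of ordered neighbour pairs.
#' Values near 0 indicate spatial homogeneity; positive values indicate
#' clustering.
#'
#' @param values numeric per-spot vector aligned to the graph.
#' @param graph a `spot_graph`.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "spot_graph"), length(values) == graph$n)
  n <- graph$n
  if (n < 3) stop("need at least 3 spots")
  z <- values - mean(values)
  css <- sum(z^2)
  if (css == 0) stop("values have zero variance; Moran's I undefined")
  e <- graph$edges
  W <- 2 * nrow(e)
  if (W == 0) stop("graph has no edges")
  cross <- 2 * sum(z[e[, 1]] * z[e[, 2]])
  (n / W) * cross / css
}

# moments of I under the randomization (permutation) null
moran_moments <- function(values, graph) {
  n <- graph$n
  e <- graph$edges
  W <- 2 * nrow(e)
  S1 <- 2 * W                       # binary symmetric weights
  S2 <- 4 * sum(graph$degree^2)
  z <- values - mean(values)
  css <- sum(z^2)
  b2 <- n * sum(z^4) / css^2
  EI <- -1 / (n - 1)
  EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
    ((n - 1) * (n - 2) * (n - 3) * W^2)
  list(expected = EI, variance = EI2 - EI^2)
}

# Moran's I of many permuted columns at once: Z is an n x B matrix of
# centered values; returns length-B vector
moran_i_columns <- function(Z, graph, A = adjacency_matrix(graph)) {
  n <- graph$n
  W <- 2 * nrow(graph$edges)
  cross <- Matrix::colSums(Z * (A %*% Z))
  css <- Matrix::colSums(Z^2)
  (n / W) * cross / css
}

#' Genome-wide one-sided Moran's I testing
#'
#' Ranks genes by variance of their log-normalized values, tests the top
#' `n_top_variable` for positive spatial autocorrelation, and reports for
#' each a one-sided p-value taken as the maximum (conservative) of the
#' analytic randomization-normality approximation and a seeded permutation
#' null, with Benjamini-Hochberg adjustment across tested genes.
#'
#' @param x `counts_matrix` with the lognorm layer.
#' @param graph `spot_graph` aligned to the matrix units.
#' @param n_top_variable number of most variable genes to test.
#' @param n_permutations permutation-null size (error below 19, warning
#'   below 99).
#' @param seed integer seed for the permutation null.
#' @return data.frame (`gene`, `I`, `expected_I`, `z`, `p_analytic`,
#'   `p_perm`, `p`, `p_adj`, `n_spots`), sorted by decreasing I.
#' @export
morans_test_genomewide <- function(x, graph, n_top_variable = 2000,
                                   n_permutations = 999, seed = 1L) {
  stopifnot(inherits(x, "counts_matrix"), inherits(graph, "spot_graph"))
  if (x$layer != "lognorm")
    stop("morans_test_genomewide expects the lognorm layer")
  if (n_permutations < 19) stop("n_permutations must be at least 19")
  if (n_permutations < 99)
    warning("fewer than 99 permutations gives a coarse p-value grid")
  if (ncol(x$counts) != graph$n)
    stop("matrix units and graph spots do not match")
  m <- x$counts
  v <- apply(m, 1, stats::var)
  keep <- names(sort(v[v > 0], decreasing = TRUE))
  keep <- utils::head(keep, n_top_variable)
  if (!length(keep)) stop("no gene with non-zero variance")
  A <- adjacency_matrix(graph)
  n <- graph$n
  set.seed(seed)
  res <- lapply(keep, function(g) {
    vals <- as.numeric(m[g, ])
    I_obs <- morans_i(vals, graph)
    mom <- moran_moments(vals, graph)
    zstat <- (I_obs - mom$expected) / sqrt(mom$variance)
    p_analytic <- stats::pnorm(zstat, lower.tail = FALSE)
    zc <- vals - mean(vals)
    P <- matrix(0, n, n_permutations)
    for (b in seq_len(n_permutations)) P[, b] <- zc[sample.int(n)]
    I_perm <- moran_i_columns(P, graph, A)
    p_perm <- (1 + sum(I_perm >= I_obs)) / (n_permutations + 1)
    data.frame(gene = g, I = I_obs, expected_I = mom$expected, z = zstat,
               p_analytic = p_analytic, p_perm = p_perm,
               p = max(p_analytic, p_perm), n_spots = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$I), ]
  rownames(out) <- NULL
  out
}

#' Diffusion-time (sepal-style) spatial clustering score
#'
#' Normalizes a non-negative expression pattern to total mass 1 and runs an
#' explicit Euler diffusion `x <- x + dt * (A x / deg - x)` with the
#' degree-normalized lattice Laplacian until the pattern is spatially
#' homogeneous (`max |x_i - mean(x)| < tolerance`). Spatially clustered
#' patterns take longer to homogenize, so a larger diffusion time indicates
#' stronger spatial structure. The scheme is stable for `dt <= 1`.
#'
#' @param values non-negative per-spot values, not all zero.
#' @param graph a `spot_graph`.
#' @param dt Euler step (default 0.1).
#' @param tolerance homogeneity tolerance on the mass-1 scale.
#' @param max_iter iteration cap.
#' @return list (`diffusion_time`, `iterations`, `converged`, `tolerance`).
#' @export
sepal_score <- function(values, graph, dt = 0.1, tolerance = 1e-4,
                        max_iter = 1e5) {
  stopifnot(inherits(graph, "spot_graph"), length(values) == graph$n,
            all(values >= 0), dt > 0, dt <= 1)
  tot <- sum(values)
  if (tot == 0) stop("values are all zero")
  x <- values / tot
  deg <- pmax(graph$degree, 1)
  A <- adjacency_matrix(graph)
  it <- 0L
  repeat {
    if (max(abs(x - mean(x))) < tolerance || it >= max_iter) break
    x <- x + dt * (as.numeric(A %*% x) / deg - x)
    it <- it + 1L
  }
  list(diffusion_time = it * dt, iterations = it,
       converged = max(abs(x - mean(x))) < tolerance,
       tolerance = tolerance)
}
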