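#' Score a gene set per unit
#'
#' Sums the values of the set's genes in each unit, on raw counts
#' (`summed_counts`) or log-normalized values (`summed_lognorm`). Genes
#' absent from the matrix are skipped with a warning; an empty intersection
#' is an error.
#'
#' @param x `counts_matrix`; layer must match the requested basis.
#' @param set a `gene_set` (or character vector of gene names).
#' @param basis `"summed_counts"` or `"summed_lognorm"`.
#' @return object of class `score_vector`: named numeric per-unit scores
#'   with attributes `basis` and `gene_set`.
#' @export
score_gene_set <- function(x, set,
                           basis = c("summed_counts", "summed_lognorm")) {
  basis <- match.arg(basis)
  stopifnot(inherits(x, "counts_matrix"))
  expected_layer <- if (basis == "summed_counts") "raw" else "lognorm"
  if (x$layer != expected_layer)
    stop(sprintf("basis %s requires the %s layer (matrix is %s)",
                 basis, expected_layer, x$layer))
  gs <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  present <- intersect(gs, rownames(x$counts))
  if (!length(present))
    stop("no gene of the set is present in the matrix")
  if (length(present) < length(gs))
    warning(sprintf("%d of %d set genes absent from matrix; skipped",
                    length(gs) - length(present), length(gs)))
  s <- Matrix::colSums(x$counts[present, , drop = FALSE])
  structure(s, basis = basis,
            gene_set = if (inherits(set, "gene_set")) set$name else "custom",
            class = "score_vector")
}

#' Published default ISG thresholds
#'
#' Threshold expression values used in the original study: 0.70 for Ifit1
#' and 0.45 for Rsad2 (log-normalized), 3.0 for the ISG score on
#' log-normalized spatial data, and 10.0 for the ISG score on counts.
#'
#' @return named list of `threshold` objects with provenance
#'   `paper_default`.
#' @export
default_thresholds <- function() {
  mk <- function(value, basis) structure(
    list(value = value, basis = basis, provenance = "paper_default",
         control_sample_id = NA_character_), class = "threshold")
  list(
    ifit1_lognorm = mk(0.70, "summed_lognorm"),
    rsad2_lognorm = mk(0.45, "summed_lognorm"),
    isg_score_lognorm = mk(3.0, "summed_lognorm"),
    isg_score_counts = mk(10.0, "summed_counts")
  )
}

#' Pool score vectors from replicate samples
#'
#' Concatenates per-unit scores from biological replicates (same gene set
#' and basis), e.g. to calibrate one threshold on all negative-control
#' replicates jointly.
#'
#' @param ... `score_vector`s with identical basis.
#' @return a pooled `score_vector`.
#' @export
pool_scores <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "score_vector")))
  bases <- unique(vapply(parts, attr, "", "basis"))
  if (length(bases) != 1) stop("score bases differ between replicates")
  structure(unlist(lapply(parts, as.numeric)), basis = bases,
            gene_set = attr(parts[[1]], "gene_set"),
            class = "score_vector")
}

#' Calibrate an ISG threshold against a negative control
#'
#' Sets the threshold at the stated quantile of the score distribution in a
#' declared negative-control sample (a genotype unable to mount the
#' interferon response, hence with no expected colonies). The default
#' quantile 0.99 bounds the per-spot false-positive rate at 1%; for colony
#' segmentation on thousands of spots a stricter per-sample quantile such as
#' `1 - 1/n` is recommended (see the package vignette).
#'
#' @param control_scores `score_vector` from the control sample.
#' @param quantile proportion in (0, 1).
#' @param control_sample_id identifier recorded as provenance.
#' @return a `threshold` with provenance `calibrated`.
#' @export
calibrate_threshold <- function(control_scores, quantile = 0.99,
                                control_sample_id = NA_character_) {
  stopifnot(inherits(control_scores, "score_vector"),
            quantile > 0, quantile < 1)
  if (length(control_scores) < 100)
    stop(sprintf("need >= 100 control units to calibrate (have %d)",
                 length(control_scores)))
  v <- unname(stats::quantile(as.numeric(control_scores), quantile,
                              type = 1))
  structure(list(value = v, basis = attr(control_scores, "basis"),
                 provenance = "calibrated",
                 control_sample_id = control_sample_id),
            class = "threshold")
}

#' Binarize a score vector into ISG-/ISG+ states
#'
#' A unit is positive iff its score is greater than or equal to the
#' threshold (removing spots *below* the cutoff retains those at it).
#'
#' @param scores `score_vector`.
#' @param t a `threshold` with matching basis.
#' @return named logical vector.
#' @export
binarize_score <- function(scores, t) {
  stopifnot(inherits(scores, "score_vector"), inherits(t, "threshold"))
  if (!identical(attr(scores, "basis"), t$basis))
    stop(sprintf("score basis (%s) does not match threshold basis (%s)",
                 attr(scores, "basis"), t$basis))
  stats::setNames(as.numeric(scores) >= t$value, names(scores))
}

# Seurat-style natural-log fold change on log-normalized values
lnfc_of <- function(a_vals, b_vals) {
  log(mean(expm1(a_vals)) + 1) - log(mean(expm1(b_vals)) + 1)
}

#' Two-group marker detection
#'
#' Wilcoxon rank-sum marker testing between two unit groups on the
#' log-normalized layer, mirroring the conventional single-cell recipe:
#' genes enter testing only if the absolute natural-log fold change is at
#' least `min_lnfc` and the expressing fraction reaches `min_fraction` in
#' either group; BH adjustment runs over the tested genes; the table is
#' sorted by lnFC and truncated to `top_n` (ties broken by gene name). The
#' exact test is used when both groups have 25 or fewer units and no ties.
#'
#' @param x `counts_matrix`, lognorm layer.
#' @param group_a,group_b disjoint character vectors of unit ids (>= 3
#'   each).
#' @param min_lnfc,min_fraction,max_adj_p,top_n filter parameters
#'   (defaults 0.50, 0.25, 1e-4, 10).
#' @return data.frame (`gene`, `lnfc`, `pct_a`, `pct_b`, `p`, `p_adj`).
#' @export
find_markers <- function(x, group_a, group_b, min_lnfc = 0.50,
                         min_fraction = 0.25, max_adj_p = 1e-4,
                         top_n = 10) {
  stopifnot(inherits(x, "counts_matrix"))
  if (x$layer != "lognorm") stop("find_markers expects the lognorm layer")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 units")
  ma <- as.matrix(x$counts[, group_a, drop = FALSE])
  mb <- as.matrix(x$counts[, group_b, drop = FALSE])
  lnfc <- vapply(seq_len(nrow(ma)),
                 function(g) lnfc_of(ma[g, ], mb[g, ]), 0)
  pct_a <- rowMeans(ma > 0); pct_b <- rowMeans(mb > 0)
  testable <- abs(lnfc) >= min_lnfc & pmax(pct_a, pct_b) >= min_fraction
  if (!any(testable))
    return(data.frame(gene = character(0), lnfc = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  idx <- which(testable)
  p <- vapply(idx, function(g) {
    av <- ma[g, ]; bv <- mb[g, ]
    use_exact <- length(av) <= 25 && length(bv) <= 25 &&
      !anyDuplicated(c(av, bv))
    suppressWarnings(stats::wilcox.test(av, bv, exact = use_exact,
                                        correct = TRUE)$p.value)
  }, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(ma)[idx], lnfc = lnfc[idx],
                    pct_a = pct_a[idx], pct_b = pct_b[idx],
                    p = p, p_adj = p_adj, stringsAsFactors = FALSE)
  out <- out[out$p_adj <= max_adj_p, , drop = FALSE]
  out <- out[order(-out$lnfc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Area under the ROC curve via the rank-sum identity
#'
#' AUROC of `score` for discriminating `positive` units, computed as
#' `U / (n1 * n2)` from midranks (tie-aware).
#'
#' @param score numeric vector.
#' @param positive logical vector of the same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Map a gene-set score onto clusters by AUROC
#'
#' For each cluster, computes the one-vs-rest AUROC of the score and flags
#' the cluster as positively classified when AUROC strictly exceeds the
#' cutoff (default 0.7).
#'
#' @param score `score_vector` (or numeric vector).
#' @param cluster_labels per-unit labels (>= 2 clusters, each >= 2 units).
#' @param threshold classification cutoff; strict inequality.
#' @return data.frame (`cluster`, `auroc`, `classified`, `n`).
#' @export
auroc_map <- function(score, cluster_labels, threshold = 0.7) {
  s <- as.numeric(score)
  stopifnot(length(s) == length(cluster_labels))
  if (stats::var(s) == 0)
    stop("score is constant; AUROC undefined")
  tab <- table(cluster_labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (any(tab < 2)) stop("every cluster needs at least 2 units")
  clusters <- names(tab)
  a <- vapply(clusters, function(cl) auroc(s, cluster_labels == cl), 0)
  data.frame(cluster = clusters, auroc = unname(a),
             classified = unname(a > threshold),
             n = as.integer(tab[clusters]),
             stringsAsFactors = FALSE, row.names = NULL)
}
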