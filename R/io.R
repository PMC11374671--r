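#' Sparse gene-by-unit counts container
#'
#' Thin wrapper around a `Matrix::dgCMatrix` with genes as rows and units
#' (spots or cells) as columns, plus a layer tag distinguishing raw integer
#' counts from log-normalized values.
#'
#' @param counts sparse or dense numeric matrix, genes x units, with
#'   rownames (genes) and colnames (unit identifiers).
#' @param layer `"raw"` (integral, non-negative) or `"lognorm"`.
#' @return object of class `counts_matrix`.
#' @export
counts_matrix <- function(counts, layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and unit colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene names")
  if (anyDuplicated(colnames(counts))) stop("duplicate unit identifiers")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (layer == "raw" && any(counts@x != round(counts@x)))
    stop("raw layer must hold integer counts")
  structure(list(counts = counts, layer = layer), class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix [%s]: %d genes x %d units, %d stored entries\n",
              x$layer, nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' @rdname counts_matrix
#' @param x a `counts_matrix`.
#' @export
genes <- function(x) rownames(x$counts)

#' @rdname counts_matrix
#' @export
units_of <- function(x) colnames(x$counts)

#' Read a MatrixMarket counts triplet
#'
#' Reads the 10x-style trio of a MatrixMarket coordinate file plus feature
#' and barcode TSVs (first column used; uncompressed).
#'
#' @param matrix_path path to the `.mtx` file (genes x units).
#' @param features_path,barcodes_path TSVs whose first column holds gene and
#'   unit identifiers in matrix order.
#' @return `counts_matrix` with the raw layer.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats))
    stop(sprintf("feature count (%d) does not match matrix rows (%d)",
                 length(feats), nrow(m)))
  if (ncol(m) != length(bcs))
    stop(sprintf("barcode count (%d) does not match matrix columns (%d)",
                 length(bcs), ncol(m)))
  if (anyDuplicated(bcs)) stop("duplicate barcodes in barcode file")
  dimnames(m) <- list(feats, bcs)
  counts_matrix(m, layer = "raw")
}

#' Write a counts matrix as MatrixMarket triplet
#'
#' @param x `counts_matrix`.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "counts_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a Visium-dialect tissue-positions table
#'
#' Accepts both the headerless 6-column dialect and the headered dialect
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`).
#' Micrometre coordinates are derived from the array indices:
#' `x = col * spacing / 2`, `y = row * spacing * sqrt(3) / 2`.
#'
#' @param path CSV path.
#' @param spacing_um,diameter_um lattice geometry constants.
#' @return a `spot_lattice`.
#' @export
read_spot_positions <- function(path, spacing_um = 100, diameter_um = 55) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) != 6)
    stop(sprintf("expected 6 columns in positions file, found %d", ncol(df)))
  names(df) <- c("spot_id", "in_tissue", "array_row", "array_col",
                 "pxl_row", "pxl_col")
  if (anyDuplicated(df$spot_id)) stop("duplicate barcodes in positions file")
  if (!is.numeric(df$array_row) || !is.numeric(df$array_col))
    stop("array indices must be numeric")
  bad <- which(df$array_row %% 2 != df$array_col %% 2)
  if (length(bad))
    stop(sprintf("row/col parity violation at rows: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  lat <- data.frame(
    spot_id   = as.character(df$spot_id),
    array_row = as.integer(df$array_row),
    array_col = as.integer(df$array_col),
    x_um      = df$array_col * spacing_um / 2,
    y_um      = df$array_row * spacing_um * sqrt(3) / 2,
    in_tissue = as.logical(df$in_tissue > 0),
    stringsAsFactors = FALSE
  )
  attr(lat, "spacing_um") <- spacing_um
  attr(lat, "diameter_um") <- diameter_um
  class(lat) <- c("spot_lattice", "data.frame")
  lat
}

#' Write a lattice as a headered tissue-positions CSV
#' @param lattice a `spot_lattice`.
#' @param path output CSV path.
#' @export
write_spot_positions <- function(lattice, path) {
  df <- data.frame(
    barcode = lattice$spot_id,
    in_tissue = as.integer(lattice$in_tissue),
    array_row = lattice$array_row,
    array_col = lattice$array_col,
    pxl_row_in_fullres = round(lattice$y_um, 6),
    pxl_col_in_fullres = round(lattice$x_um, 6)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-control filter for raw counts
#'
#' Removes units detecting fewer than `min_genes` genes or exceeding the
#' mitochondrial-content ceiling, then removes genes detected in fewer than
#' `min_units_per_gene` of the remaining units. Mitochondrial genes are
#' recognized by name prefix.
#'
#' @param x `counts_matrix`, raw layer.
#' @param min_genes minimum number of detected genes per unit (default 200).
#' @param min_units_per_gene minimum units a gene must appear in (default 3).
#' @param max_mito_fraction maximum tolerated mitochondrial count fraction
#'   (default 0.05; units strictly above are removed).
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return filtered `counts_matrix`; removal counts attached as attribute
#'   `qc_report`.
#' @export
qc_filter <- function(x, min_genes = 200, min_units_per_gene = 3,
                      max_mito_fraction = 0.05, mito_prefix = "mt-") {
  stopifnot(inherits(x, "counts_matrix"))
  if (x$layer != "raw") stop("qc_filter expects the raw layer")
  m <- x$counts
  detected <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  tot <- Matrix::colSums(m)
  mito_frac <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) /
    pmax(tot, 1) else rep(0, ncol(m))
  keep_units <- detected >= min_genes & mito_frac <= max_mito_fraction
  m2 <- m[, keep_units, drop = FALSE]
  keep_genes <- Matrix::rowSums(m2 > 0) >= min_units_per_gene
  m3 <- m2[keep_genes, , drop = FALSE]
  if (ncol(m3) == 0 || nrow(m3) == 0)
    stop("qc_filter removed all units or all genes; relax the thresholds")
  out <- counts_matrix(m3, layer = "raw")
  attr(out, "qc_report") <- list(
    units_removed = sum(!keep_units),
    genes_removed = sum(!keep_genes),
    units_kept = ncol(m3), genes_kept = nrow(m3)
  )
  out
}

#' Log-normalize counts to 10,000 molecules
#'
#' Each unit is scaled to a 10,000-molecule library and natural-log
#' transformed: `v = ln(1 + 10000 * c / total)`. Zeros are preserved exactly
#' and ordering is untouched.
#'
#' @param x `counts_matrix`, raw layer, all unit totals positive.
#' @return `counts_matrix` with layer `"lognorm"`.
#' @export
normalize_log10k <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  if (x$layer != "raw") stop("normalize_log10k expects the raw layer")
  tot <- Matrix::colSums(x$counts)
  if (any(tot == 0))
    stop("units with zero total counts present; run qc_filter first")
  m <- x$counts
  # scale columns in sparse form: x@x indexed by column pointer
  scale_fac <- 1e4 / tot
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scale_fac[j])
  out <- counts_matrix(m, layer = "lognorm")
  out
}

#' Gene set container and readers
#'
#' A gene set is a named, non-empty list of unique gene names with a role tag
#' (`ISG`, `BZ`, `IZ`, `matricellular` or `custom`).
#'
#' @param name set label.
#' @param genes character vector of unique gene names.
#' @param role one of `ISG`, `BZ`, `IZ`, `matricellular`, `custom`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, role = "custom") {
  stopifnot(is.character(genes), length(genes) > 0)
  if (anyDuplicated(genes)) stop("genes must be unique within a set")
  role <- match.arg(role, c("ISG", "BZ", "IZ", "matricellular", "custom"))
  structure(list(name = name, genes = genes, role = role),
            class = "gene_set")
}

#' Read gene sets from TSV (`set<TAB>gene`, optional third role column) or
#' JSON (list of `{name, genes, role}`)
#' @param path file path; format chosen by extension (.json vs anything else).
#' @return named list of `gene_set`s.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    sets <- lapply(seq_len(nrow(raw)), function(i)
      gene_set(raw$name[i], unlist(raw$genes[i]),
               if ("role" %in% names(raw)) raw$role[i] else "custom"))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("gene-set TSV needs at least set and gene columns")
    sets <- lapply(split(df, df[[1]]), function(d)
      gene_set(d[[1]][1], unique(d[[2]]),
               if (ncol(d) >= 3) d[[3]][1] else "custom"))
  }
  names(sets) <- vapply(sets, function(s) s$name, "")
  sets
}

#' Read a decoded single-molecule point table
#'
#' CSV with mandatory columns `x_um`, `y_um`, `species`, optional `z_um` and
#' `cell_id`; unknown columns are preserved.
#'
#' @param path CSV path.
#' @return validated `data.frame`.
#' @export
read_point_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x_um", "y_um", "species"))
    if (!col %in% names(df))
      stop(sprintf("point table lacks mandatory column '%s'", col))
  for (col in intersect(c("x_um", "y_um", "z_um"), names(df)))
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
  df
}

#' Write a point table (micrometre coordinates at 6 decimals)
#' @param points data.frame with `x_um`, `y_um`, `species`, ...
#' @param path CSV path.
#' @export
write_point_table <- function(points, path) {
  out <- points
  for (col in intersect(c("x_um", "y_um", "z_um"), names(out)))
    out[[col]] <- round(out[[col]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as TSV (data.frame) or JSON (list)
#'
#' TSV reports carry `#`-prefixed header lines declaring the package version
#' and the normalization substitution so downstream readers see provenance.
#'
#' @param obj data.frame or list.
#' @param path output path; `.json` selects JSON.
#' @param header extra header comment lines for TSV output.
#' @export
write_report <- function(obj, path, header = character(0)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# ifnic %s", as.character(utils::packageVersion("ifnic"))),
      "# normalization: log-10k (ln(1 + 1e4*c/total)); substituted for variance-stabilizing normalization/integration",
      paste0("# ", header)[seq_along(header)]), con)
    utils::write.table(obj, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
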