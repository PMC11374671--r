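#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()]: a
#' simulation block (see [sim_config()]), QC and scoring parameters,
#' thresholding mode and stage toggles. Supplying `input` paths (a
#' MatrixMarket trio plus a tissue-positions CSV) instead of a `simulation`
#' block switches the pipeline to real data; exactly one of the two must be
#' present.
#'
#' @param seed master seed recycled into every randomized stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(),          # arguments passed to sim_config()
    input = NULL,                 # or list(matrix=, features=, barcodes=, positions=)
    qc = list(min_genes = 5, min_units_per_gene = 3,
              max_mito_fraction = 0.05, mito_prefix = "mt-"),
    threshold = list(mode = "calibrate", quantile = NULL,  # NULL: 1 - 1/N
                     n_control_replicates = 3),
    score_basis = "summed_counts",
    spatial = list(n_top_variable = 33, n_permutations = 199,
                   run_sepal = TRUE),
    localize = list(trials_per_size = 500, max_size = 12,
                    bz_quantile = 0.90),
    niche = list(max_ring = 3),
    stages = list(qc = TRUE, score = TRUE, colonies = TRUE,
                  spatial_stats = TRUE, localize = TRUE, niche = TRUE,
                  merfish = FALSE, dna = FALSE, nuclei = FALSE)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[k] <- override[k]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  merged <- merge_config(default_pipeline_config(), config)
  # an input block without an explicit simulation block disables simulation
  if (!is.null(merged$input) && !"simulation" %in% names(config))
    merged$simulation <- NULL
  merged
}

#' Run the full IFNIC analysis pipeline
#'
#' Composes the stages end to end: simulate (or read) a spatial sample, QC
#' and log-10k normalization, ISG scoring and thresholding, colony
#' segmentation and quantification, Moran's I / diffusion-time spatial
#' statistics, Monte Carlo borderzone localization, and niche ring
#' analysis; optional MERFISH point-cloud, DNA-locus and nuclear-morphology
#' stages run on matched synthetic samples. Every randomized stage consumes
#' a substream of the master seed, so a fixed configuration and seed yield
#' an identical report bundle.
#'
#' @param config configuration list, or path to a YAML/JSON file; unset
#'   keys fall back to [default_pipeline_config()].
#' @param outdir output directory for the report bundle.
#' @return the manifest (list), invisibly; files are written under
#'   `outdir`, including `manifest.json` with content hashes.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("ifnic_run_")) {
  cfg <- read_pipeline_config(config)
  has_sim <- !is.null(cfg$simulation)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    stop("stage 'validate' failed: exactly one of 'simulation' or 'input' must be present")
  if (is.null(cfg$seed) && has_sim)
    stop("stage 'validate' failed: a seed is required for simulation")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_files <- character(0)
  completed <- character(0)
  emit <- function(obj, name, header = character(0)) {
    path <- file.path(outdir, name)
    write_report(obj, path, header)
    stage_files <<- c(stage_files, path)
    path
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      # retain partial outputs with a .partial marker and halt
      writeLines(c(name, conditionMessage(e)),
                 file.path(outdir, "manifest.partial"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  # --- acquire data -------------------------------------------------------
  env <- new.env()
  run_stage(if (has_sim) "simulate" else "read_input", function() {
    if (has_sim) {
      sc <- do.call(sim_config, c(cfg$simulation,
                                  list(seed = cfg$seed)))
      env$sample <- make_lattice_sample(sc)
      env$control <- make_control_sample(sc)
      env$sim_config <- sc
    } else {
      cm <- read_counts_mtx(cfg$input$matrix, cfg$input$features,
                            cfg$input$barcodes)
      lat <- read_spot_positions(cfg$input$positions)
      keep <- lat$spot_id[lat$in_tissue]
      missing <- setdiff(keep, units_of(cm))
      if (length(missing))
        stop(sprintf("%d tissue spots missing from counts", length(missing)))
      cm$counts <- cm$counts[, keep, drop = FALSE]
      env$sample <- list(counts = cm, lattice = lat,
                         graph = build_adjacency(lat))
      env$control <- NULL
    }
  })
  graph <- env$sample$graph
  panel <- if (has_sim) env$sim_config$panel else default_gene_panel()
  isg_set <- gene_set("ISG_score",
                      intersect(panel$gene[panel$role == "ISG"],
                                genes(env$sample$counts)), "ISG")
  bz_set <- gene_set("BZ_score",
                     intersect(panel$gene[panel$role == "BZ"],
                               genes(env$sample$counts)), "BZ")

  # --- qc + normalization -------------------------------------------------
  if (isTRUE(cfg$stages$qc)) run_stage("qc", function() {
    env$sample$counts <- qc_filter(env$sample$counts,
                                   min_genes = cfg$qc$min_genes,
                                   min_units_per_gene = cfg$qc$min_units_per_gene,
                                   max_mito_fraction = cfg$qc$max_mito_fraction,
                                   mito_prefix = cfg$qc$mito_prefix)
    qr <- attr(env$sample$counts, "qc_report")
    if (qr$units_removed > 0) {
      # spots failing QC leave the lattice; adjacency is rebuilt
      kept <- units_of(env$sample$counts)
      env$sample$lattice$in_tissue <-
        env$sample$lattice$in_tissue &
        env$sample$lattice$spot_id %in% kept
      env$sample$graph <- build_adjacency(env$sample$lattice)
    }
    emit(as.data.frame(qr), "qc_report.tsv")
  })
  graph <- env$sample$graph
  env$lognorm <- normalize_log10k(env$sample$counts)

  # --- scoring + threshold ------------------------------------------------
  scores <- NULL; thr <- NULL
  if (isTRUE(cfg$stages$score)) run_stage("score", function() {
    basis <- cfg$score_basis
    mat <- if (basis == "summed_counts") env$sample$counts else env$lognorm
    env$scores <- score_gene_set(mat, isg_set, basis)
    if (identical(cfg$threshold$mode, "paper_default")) {
      env$thr <- if (basis == "summed_counts")
        default_thresholds()$isg_score_counts
      else default_thresholds()$isg_score_lognorm
    } else {
      if (!has_sim)
        stop("threshold calibration requires matched negative-control samples")
      nrep <- cfg$threshold$n_control_replicates
      cscore <- do.call(pool_scores, lapply(seq_len(nrep), function(r) {
        ctl <- if (r == 1) env$control else
          make_control_sample(env$sim_config, replicate = r)
        cmat <- if (basis == "summed_counts") ctl$counts else
          normalize_log10k(ctl$counts)
        score_gene_set(cmat, isg_set, basis)
      }))
      q <- cfg$threshold$quantile
      if (is.null(q)) q <- 1 - 1 / length(cscore)
      env$thr <- calibrate_threshold(cscore, quantile = q,
                                     control_sample_id = "matched_controls")
    }
    emit(data.frame(spot_id = names(env$scores),
                    isg_score = as.numeric(env$scores)),
         "isg_scores.tsv")
    emit(unclass(env$thr), "threshold.json")
  })

  # --- colonies -----------------------------------------------------------
  if (isTRUE(cfg$stages$colonies)) run_stage("colonies", function() {
    states <- binarize_score(env$scores, env$thr)
    env$states <- unname(states)
    cs <- segment_colonies(env$states, graph)
    cs <- colony_stats(cs, env$sample$lattice, graph,
                       scores = as.numeric(env$scores))
    env$colonies <- cs
    nd <- neighbourhood_counts(env$states, graph)
    emit(nd, "neighbourhood_matrix.tsv")
    if (length(cs$colonies)) {
      emit(data.frame(
        colony = rep(seq_along(cs$colonies), lengths(cs$colonies)),
        spot_id = cs$spot_id[unlist(cs$colonies)]), "colony_members.tsv")
      emit(cs$stats, "colony_stats.tsv")
    }
    emit(list(n_colonies = length(cs$colonies),
              colony_sizes = cs$n_spots,
              n_scattered = length(cs$scattered),
              area_convention = cs$area_convention),
         "colony_summary.json")
  })

  # --- spatial statistics -------------------------------------------------
  if (isTRUE(cfg$stages$spatial_stats)) run_stage("spatial_stats", function() {
    mt <- morans_test_genomewide(env$lognorm, graph,
                                 n_top_variable = cfg$spatial$n_top_variable,
                                 n_permutations = cfg$spatial$n_permutations,
                                 seed = substream(cfg$seed, "moran"))
    env$moran <- mt
    emit(mt, "spatial_stats.tsv")
    if (isTRUE(cfg$spatial$run_sepal)) {
      sp <- sepal_score(as.numeric(env$scores), graph)
      emit(list(score = "ISG_score",
                diffusion_time = sp$diffusion_time,
                converged = sp$converged), "sepal_isg.json")
    }
  })

  # --- localization -------------------------------------------------------
  if (isTRUE(cfg$stages$localize)) run_stage("localize", function() {
    if (!length(env$colonies$colonies)) {
      emit(list(skipped = "no observed colonies"), "localization.json")
      return(invisible(NULL))
    }
    bz_scores <- score_gene_set(env$lognorm, bz_set, "summed_lognorm")
    target <- as.numeric(bz_scores) >=
      stats::quantile(as.numeric(bz_scores), cfg$localize$bz_quantile)
    lt <- localization_test(env$colonies, target, graph,
                            trials_per_size = cfg$localize$trials_per_size,
                            max_size = cfg$localize$max_size,
                            seed = substream(cfg$seed, "localize"))
    env$localization <- lt
    emit(lt$per_size, "localization_per_size.tsv")
    emit(lt$pooled, "localization_pooled.json")
  })

  # --- niche --------------------------------------------------------------
  if (isTRUE(cfg$stages$niche)) run_stage("niche", function() {
    if (!length(env$colonies$colonies)) return(invisible(NULL))
    rings <- assign_rings(env$colonies, graph,
                          max_ring = cfg$niche$max_ring)
    emit(rings, "rings.tsv")
    de <- tryCatch(ring_de(env$lognorm, rings),
                   error = function(e) NULL)
    if (!is.null(de)) emit(de, "ring_de.tsv")
    prof <- neighbor_fraction_profile(
      reference_states = !is.na(rings$ring_k) & rings$ring_k == 0,
      query_states = env$states, graph,
      spacing_um = lattice_spacing(env$sample$lattice))
    emit(prof, "neighbor_fractions.tsv")
  })

  # --- optional point-cloud stages ---------------------------------------
  if (isTRUE(cfg$stages$merfish)) run_stage("merfish", function() {
    ms <- make_merfish_sample(env$sim_config)
    isg_genes <- panel$gene[panel$role == "ISG"]
    isg_pts <- ms$points[ms$points$species %in% isg_genes, ]
    cl <- classify_isg_clusters(isg_pts)
    comp <- colony_composition(cl$labels, isg_pts, ms$cells)
    emit(list(n_clusters = cl$n_clusters,
              cluster_sizes = cl$cluster_sizes,
              n_scattered = length(cl$scattered),
              composition = lapply(comp, function(co)
                list(cluster = co$cluster, n_cells = co$n_cells,
                     proportions = co$proportions))),
         "merfish_clusters.json")
  })
  if (isTRUE(cfg$stages$dna)) run_stage("dna", function() {
    ds <- make_dna_sample(seed = substream(cfg$seed, "dna_stage"))
    lab <- classify_extranuclear(ds$points)
    emit(list(fraction_extranuclear =
                mean(lab[lab != "edge_excluded"] == "extranuclear"),
              counts = as.list(table(lab))), "dna_classification.json")
  })
  if (isTRUE(cfg$stages$nuclei)) run_stage("nuclei", function() {
    ns <- make_nucleus_set(9, deformation = 0.8,
                           seed = substream(cfg$seed, "nuclei_stage"))
    emit(nuclear_solidity(ns$masks), "nuclear_solidity.tsv")
  })

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "ifnic",
    version = as.character(utils::packageVersion("ifnic")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "input")],
    substitutions = paste("normalization: log-10k substituted for",
                          "variance-stabilizing normalization/integration"),
    stages_completed = completed,
    files = lapply(stage_files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
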