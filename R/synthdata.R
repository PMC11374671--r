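# Deterministic substream seeds: one master seed expands to independent
# per-component seeds so counts, placement and point clouds can be
# regenerated independently.
substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) * 131)) %% 1048576
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Default 33-gene panel with zone roles
#'
#' Mirrors a MERFISH-style cardiac panel: interferon-stimulated genes (ISG),
#' borderzone cardiomyocyte genes (BZ), infarct-zone innate-immune genes
#' (IZ), matricellular/activated-fibroblast genes and cell-type markers.
#'
#' @return data.frame with columns `gene`, `role`.
#' @seealso [spatial_gene_panel()] for the whole-transcriptome emulation.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("Ifit1", "Ifit2", "Ifit3", "Cxcl10", "Rsad2", "Isg15", "Irf7",
             "Oasl1",
             "Nppa", "Nppb", "Ankrd1", "Xirp2", "Flnc",
             "Cd68", "Adgre1", "Ccr2", "Ly6c2", "S100a8",
             "Postn", "Acta2", "Sparc", "Col1a1", "Bgn",
             "Tnnt2", "Ttn", "Pecam1", "Flt1", "Col6a3", "Cxcr2", "Csf3r",
             "Lyve1", "Timd4", "Chil3"),
    role = c(rep("ISG", 8), rep("BZ", 5), rep("IZ", 5),
             rep("matricellular", 5), rep("other", 10)),
    stringsAsFactors = FALSE
  )
}

#' Spatial panel with an abundant structural background
#'
#' The 33-gene panel plus a block of highly expressed housekeeping and
#' structural transcripts. In whole-transcriptome spot data the library
#' total is dominated by such genes, so an ISG colony barely moves the
#' per-spot total; without this block, library normalization would cancel
#' the planted ISG signal (a pure composition artifact of a small panel).
#'
#' @return data.frame with columns `gene`, `role`.
#' @export
spatial_gene_panel <- function() {
  rbind(default_gene_panel(),
        data.frame(
          gene = c("Actb", "Gapdh", "Myh6", "Actc1", "Tpm1", "Des",
                   "Mb", "Eef1a1", "Rpl13a", "Rps18", "Polr2a", "Hprt"),
          role = "housekeeping",
          stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defines a synthetic infarcted-tissue sample: a hexagonal spot lattice
#' with concentric infarct (IZ) and borderzone (BZ) geometry, negative
#' binomial per-gene counts with zone-dependent programs, and contiguous
#' ISG-positive colonies planted at the borderzone.
#'
#' The defaults encode the study conditions the generator emulates:
#' Visium geometry (55 um spots at 100 um pitch), a ~3,000-spot capture
#' area, 3 borderzone colonies of 4-8 spots, and an 8-fold ISG induction
#' inside colonies over an NB(mean 3, size 4) baseline.
#'
#' @param lattice_rows,lattice_cols lattice dimensions (spots per row).
#' @param spot_spacing_um,spot_diameter_um geometry constants.
#' @param infarct_center infarct centre in um (default: lattice centre).
#' @param iz_radius_um,bz_width_um concentric zone geometry.
#' @param n_colonies number of planted ISG colonies.
#' @param colony_size_range inclusive spot-count range, within [1, 12].
#' @param colony_placement `"bz"` (colonies confined to the BZ annulus) or
#'   `"uniform"` (anywhere in tissue).
#' @param isg_effect fold-change multiplier (> 1) applied to ISG genes
#'   inside colony spots.
#' @param zone_effect fold change of BZ genes in the BZ, IZ genes in the IZ,
#'   and matricellular genes in the BZ.
#' @param matricellular_suppression multiplier (< 1) applied to
#'   matricellular genes inside colony spots, planting the inverse
#'   ISG/matricellular spatial pattern.
#' @param nb_mean baseline negative-binomial mean per gene (scalar or named
#'   per-gene vector).
#' @param nb_dispersion NB size parameter (variance = mu + mu^2/size).
#' @param panel data.frame with `gene` and `role` columns.
#' @param housekeeping_scale baseline multiplier for `housekeeping` genes,
#'   emulating the dominant structural transcriptome in the spot totals.
#' @param seed master integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(lattice_rows = 55, lattice_cols = 55,
                       spot_spacing_um = 100, spot_diameter_um = 55,
                       infarct_center = NULL,
                       iz_radius_um = 800, bz_width_um = 300,
                       n_colonies = 3, colony_size_range = c(4, 8),
                       colony_placement = c("bz", "uniform"),
                       isg_effect = 8, zone_effect = 4,
                       matricellular_suppression = 0.25,
                       nb_mean = 3, nb_dispersion = 4,
                       panel = spatial_gene_panel(),
                       housekeeping_scale = 30, seed = 1L) {
  colony_placement <- match.arg(colony_placement)
  stopifnot(spot_spacing_um > spot_diameter_um, spot_diameter_um > 0,
            nb_dispersion > 0, isg_effect > 1, n_colonies >= 0,
            length(colony_size_range) == 2,
            colony_size_range[1] >= 1, colony_size_range[2] <= 12,
            colony_size_range[1] <= colony_size_range[2],
            all(c("gene", "role") %in% names(panel)))
  if (is.null(infarct_center))
    infarct_center <- c((2 * (lattice_cols - 1) + 1) * spot_spacing_um / 4,
                        (lattice_rows - 1) * spot_spacing_um * sqrt(3) / 4)
  half_extent <- min((lattice_cols - 1) * spot_spacing_um / 2,
                     (lattice_rows - 1) * spot_spacing_um * sqrt(3) / 4)
  if (iz_radius_um + bz_width_um > 2 * half_extent)
    stop("iz_radius_um + bz_width_um does not fit in the lattice")
  structure(list(
    lattice_rows = lattice_rows, lattice_cols = lattice_cols,
    spot_spacing_um = spot_spacing_um, spot_diameter_um = spot_diameter_um,
    infarct_center = infarct_center, iz_radius_um = iz_radius_um,
    bz_width_um = bz_width_um, n_colonies = n_colonies,
    colony_size_range = colony_size_range,
    colony_placement = colony_placement, isg_effect = isg_effect,
    zone_effect = zone_effect,
    matricellular_suppression = matricellular_suppression,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    panel = panel, housekeeping_scale = housekeeping_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# grow one connected colony by uniform first-order accretion over eligible
# spots; returns integer spot indices or NULL when stuck
grow_connected_set <- function(graph, size, eligible, blocked) {
  open <- which(eligible & !blocked)
  if (!length(open)) return(NULL)
  start <- open[sample.int(length(open), 1)]
  members <- start
  while (length(members) < size) {
    cand <- unique(unlist(graph$nbr[members], use.names = FALSE))
    cand <- cand[eligible[cand] & !blocked[cand] &
                   !(cand %in% members)]
    if (!length(cand)) return(NULL)
    members <- c(members, cand[sample.int(length(cand), 1)])
  }
  sort(members)
}

#' Generate a synthetic infarcted spatial sample
#'
#' Draws gene-wise negative-binomial counts over a zoned hexagonal lattice
#' and plants `n_colonies` contiguous ISG colonies grown by uniform
#' first-order accretion (mirroring the N+1 accretion of the localization
#' null). ISG genes are multiplied by `isg_effect` inside colony spots; BZ,
#' IZ and matricellular programs follow the truth zones. Deterministic for a
#' fixed seed.
#'
#' @param config a `sim_config`.
#' @param max_retries bounded placement retries per colony before erroring.
#' @return list with `lattice` (`spot_lattice`), `graph` (`spot_graph`),
#'   `counts` (`counts_matrix`, raw), and `truth` (zones, colony membership,
#'   config echo).
#' @export
make_lattice_sample <- function(config, max_retries = 100) {
  stopifnot(inherits(config, "sim_config"))
  lattice <- hex_lattice(config$lattice_rows, config$lattice_cols,
                         config$spot_spacing_um, config$spot_diameter_um)
  graph <- build_adjacency(lattice)
  zones <- assign_zones(lattice, config$infarct_center,
                        config$iz_radius_um, config$bz_width_um)
  n <- graph$n

  # --- colony placement substream ---
  set.seed(substream(config$seed, "placement"))
  eligible <- if (config$colony_placement == "bz") {
    as.character(zones[graph$lattice_index]) == "BZ"
  } else rep(TRUE, n)
  colony_of <- rep(NA_integer_, n)
  blocked <- rep(FALSE, n)
  if (config$n_colonies > 0) {
    sizes <- sample(seq(config$colony_size_range[1],
                        config$colony_size_range[2]),
                    config$n_colonies, replace = TRUE)
    for (k in seq_len(config$n_colonies)) {
      placed <- NULL
      for (try in seq_len(max_retries)) {
        placed <- grow_connected_set(graph, sizes[k], eligible, blocked)
        if (!is.null(placed)) break
      }
      if (is.null(placed))
        stop(sprintf("could not place colony %d (size %d) after %d retries",
                     k, sizes[k], max_retries))
      colony_of[placed] <- k
      # block members and their first-order neighbours so planted colonies
      # stay non-adjacent (distinct connected components by construction)
      blocked[placed] <- TRUE
      blocked[unique(unlist(graph$nbr[placed], use.names = FALSE))] <- TRUE
    }
  }

  # --- counts substream ---
  set.seed(substream(config$seed, "counts"))
  genes <- config$panel$gene
  role <- config$panel$role
  mu_gene <- if (length(config$nb_mean) == 1) {
    rep(config$nb_mean, length(genes))
  } else {
    as.numeric(config$nb_mean[genes])
  }
  zone_spot <- as.character(zones[graph$lattice_index])
  mu_gene[role == "housekeeping"] <-
    mu_gene[role == "housekeeping"] * config$housekeeping_scale
  mu <- matrix(mu_gene, nrow = length(genes), ncol = n)
  in_bz <- zone_spot == "BZ"; in_iz <- zone_spot == "IZ"
  in_colony <- !is.na(colony_of)
  mu[role == "BZ", in_bz] <- mu[role == "BZ", in_bz] * config$zone_effect
  mu[role == "IZ", in_iz] <- mu[role == "IZ", in_iz] * config$zone_effect
  mu[role == "matricellular", in_bz] <-
    mu[role == "matricellular", in_bz] * config$zone_effect
  mu[role == "ISG", in_colony] <-
    mu[role == "ISG", in_colony] * config$isg_effect
  mu[role == "matricellular", in_colony] <-
    mu[role == "matricellular", in_colony] * config$matricellular_suppression
  cnt <- matrix(stats::rnbinom(length(mu), size = config$nb_dispersion,
                               mu = mu),
                nrow = length(genes),
                dimnames = list(genes, lattice$spot_id[graph$lattice_index]))
  membership <- stats::setNames(colony_of[!is.na(colony_of)],
                                graph$spot_id[!is.na(colony_of)])
  list(
    lattice = lattice,
    graph = graph,
    counts = counts_matrix(cnt, layer = "raw"),
    truth = list(
      zone_of_spot = stats::setNames(zone_spot, graph$spot_id),
      zone_provenance = "truth",
      colony_membership = membership,
      config = config
    )
  )
}

#' Generate a matched negative-control sample
#'
#' Identical generative process with `n_colonies` forced to zero and the ISG
#' baseline mean unchanged — the synthetic analogue of an Irf3-deficient
#' heart that cannot mount a type I interferon response.
#'
#' @param config a `sim_config`; its seed is offset internally so a control
#'   never shares draws with the matched stimulated sample.
#' @param replicate control replicate index; biological replicate controls
#'   (distinct seeds) can be pooled for threshold calibration.
#' @return as [make_lattice_sample()].
#' @export
make_control_sample <- function(config, replicate = 1) {
  stopifnot(inherits(config, "sim_config"))
  ctl <- config
  ctl$n_colonies <- 0L
  ctl$seed <- substream(config$seed, sprintf("control%d", replicate))
  make_lattice_sample(ctl)
}

# marker genes used to build per-type expression profiles
merfish_type_markers <- function() {
  list(
    "BZ CM" = c("Nppa", "Flnc", "Ankrd1"),
    "RZ CM" = c("Tnnt2", "Ttn"),
    "FB"    = c("Col1a1", "Col6a3"),
    "Mac"   = c("Cd68", "Adgre1"),
    "Neut"  = c("Cxcr2", "Csf3r"),
    "EC"    = c("Pecam1", "Flt1")
  )
}

#' Generate a MERFISH-like labelled point cloud
#'
#' Cells are placed as non-overlapping disks in a square domain; each
#' carries a cell type and emits Poisson transcript counts from a
#' type-specific profile over the 33-gene panel, scattered uniformly within
#' its disk. Cells falling inside planted circular colony regions have their
#' ISG genes multiplied by `config$isg_effect`. Every point carries its true
#' cell id.
#'
#' @param config a `sim_config` (seed, panel, `n_colonies`, `isg_effect`).
#' @param cells_per_type named integer vector over the six cardiac types.
#' @param transcripts_per_cell named per-type mean transcript budget
#'   (scalar recycled).
#' @param domain_um square domain side length.
#' @param cell_radius_um cell disk radius.
#' @param colony_region_radius_um radius of planted ISG-enriched regions.
#' @param isg_baseline_per_cell mean total baseline ISG transcripts per cell
#'   (split over the ISG genes).
#' @param isg_enrichment fold enrichment of ISG transcripts in cells inside
#'   colony regions (default 80, i.e. ~8 ISG transcripts per colony cell
#'   over the 0.1 baseline).
#' @return list with `points` (x_um, y_um, species, cell_id), `cells`
#'   (cell_id, x_um, y_um, radius_um, cell_type, in_colony) and `truth`
#'   (colony region geometry, per-cell types).
#' @export
make_merfish_sample <- function(config,
                                cells_per_type = c("BZ CM" = 600,
                                                   "RZ CM" = 500, "FB" = 500,
                                                   "Mac" = 400, "Neut" = 200,
                                                   "EC" = 200),
                                transcripts_per_cell = 60,
                                domain_um = 2000, cell_radius_um = 8,
                                colony_region_radius_um = 150,
                                isg_baseline_per_cell = 0.1,
                                isg_enrichment = 80) {
  stopifnot(inherits(config, "sim_config"))
  types <- names(cells_per_type)
  stopifnot(all(types %in% names(merfish_type_markers())))
  n_cells <- sum(cells_per_type)
  if (n_cells * pi * cell_radius_um^2 > 0.4 * domain_um^2)
    stop("requested cell density exceeds packing feasibility")
  set.seed(substream(config$seed, "merfish"))

  # colony regions: non-overlapping disks, well separated
  centers <- matrix(numeric(0), ncol = 2)
  r_reg <- colony_region_radius_um
  guard <- 0
  while (nrow(centers) < config$n_colonies) {
    p <- stats::runif(2, r_reg, domain_um - r_reg)
    if (!nrow(centers) ||
        min(sqrt(colSums((t(centers) - p)^2))) > 2 * r_reg + 250) {
      centers <- rbind(centers, p)
    }
    guard <- guard + 1
    if (guard > 10000) stop("could not place colony regions")
  }

  # dart-throw non-overlapping cell disks (grid-accelerated)
  cell_xy <- matrix(NA_real_, n_cells, 2)
  cell_size <- 2 * cell_radius_um
  grid <- new.env(hash = TRUE)
  placed <- 0; guard <- 0
  while (placed < n_cells) {
    guard <- guard + 1
    if (guard > 60 * n_cells)
      stop("requested cell density exceeds packing feasibility")
    p <- stats::runif(2, cell_radius_um, domain_um - cell_radius_um)
    gx <- floor(p[1] / cell_size); gy <- floor(p[2] / cell_size)
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(gx + dx, gy + dy)
      ids <- grid[[key]]
      if (!is.null(ids)) {
        d2 <- (cell_xy[ids, 1] - p[1])^2 + (cell_xy[ids, 2] - p[2])^2
        if (any(d2 < (2 * cell_radius_um)^2)) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    placed <- placed + 1
    cell_xy[placed, ] <- p
    key <- paste(gx, gy)
    grid[[key]] <- c(grid[[key]], placed)
  }
  type_of <- sample(rep(types, cells_per_type))
  in_colony <- rep(FALSE, n_cells)
  if (nrow(centers)) {
    for (k in seq_len(nrow(centers))) {
      d2 <- (cell_xy[, 1] - centers[k, 1])^2 + (cell_xy[, 2] - centers[k, 2])^2
      in_colony <- in_colony | d2 <= r_reg^2
    }
  }

  # per-type gene profiles over the probe library (the imaging panel does
  # not carry the whole-transcriptome housekeeping background)
  probe <- config$panel$role != "housekeeping"
  panel_genes <- config$panel$gene[probe]
  isg_genes <- config$panel$gene[config$panel$role == "ISG"]
  markers <- merfish_type_markers()
  budget <- if (length(transcripts_per_cell) == 1) {
    stats::setNames(rep(transcripts_per_cell, length(types)), types)
  } else transcripts_per_cell[types]
  profile <- sapply(types, function(ty) {
    mu <- stats::setNames(rep(0.2, length(panel_genes)), panel_genes)
    mu[markers[[ty]]] <- 0.7 * budget[ty] / length(markers[[ty]])
    mu[isg_genes] <- isg_baseline_per_cell / length(isg_genes)
    mu
  })

  pts <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    mu <- profile[, type_of[i]]
    if (in_colony[i]) mu[isg_genes] <- mu[isg_genes] * isg_enrichment
    k <- stats::rpois(length(mu), mu)
    m <- sum(k)
    if (!m) next
    rad <- cell_radius_um * sqrt(stats::runif(m))
    ang <- stats::runif(m, 0, 2 * pi)
    pts[[i]] <- data.frame(
      x_um = cell_xy[i, 1] + rad * cos(ang),
      y_um = cell_xy[i, 2] + rad * sin(ang),
      species = rep(panel_genes, k),
      cell_id = sprintf("cell_%05d", i),
      stringsAsFactors = FALSE
    )
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  rownames(points) <- NULL
  cells <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    x_um = cell_xy[, 1], y_um = cell_xy[, 2],
    radius_um = cell_radius_um,
    cell_type = type_of, in_colony = in_colony,
    stringsAsFactors = FALSE
  )
  list(points = points, cells = cells,
       truth = list(colony_centers = centers,
                    colony_radius_um = r_reg,
                    merfish_cell_types = stats::setNames(type_of,
                                                         cells$cell_id),
                    config = config))
}

#' Generate a DNA-locus point pattern with a known escape fraction
#'
#' Nuclear loci are drawn densely inside nucleus disks; a Bernoulli fraction
#' of loci is relocated outside all nuclei, at least 5 um from any nucleus
#' boundary, emulating extranuclear DNA after nuclear envelope rupture. Each
#' point carries a truth compartment flag. Locus identities are drawn from a
#' genome-scale panel of 260 loci.
#'
#' @param n_nuclei number of nuclei (placed on a jittered grid, radius 4 um).
#' @param loci_per_nucleus decoded loci per nucleus (>= 10).
#' @param extranuclear_fraction escape probability in [0, 1).
#' @param section_thickness_um optional; when given, a z coordinate uniform
#'   in [0, thickness] is attached to every point.
#' @param seed integer seed.
#' @return list with `points` (x_um, y_um[, z_um], species) and `truth`
#'   (per-point compartment, nucleus centres/radius, planted fraction).
#' @export
make_dna_sample <- function(n_nuclei = 20, loci_per_nucleus = 50,
                            extranuclear_fraction = 0.1,
                            section_thickness_um = NULL, seed = 1L) {
  stopifnot(extranuclear_fraction >= 0, loci_per_nucleus >= 10)
  if (extranuclear_fraction >= 1)
    stop("extranuclear_fraction must be < 1")
  set.seed(substream(seed, "dna"))
  r_nuc <- 4; pitch <- 30
  side <- ceiling(sqrt(n_nuclei))
  gx <- ((seq_len(n_nuclei) - 1) %% side) * pitch + pitch / 2
  gy <- ((seq_len(n_nuclei) - 1) %/% side) * pitch + pitch / 2
  centers <- cbind(gx + stats::runif(n_nuclei, -3, 3),
                   gy + stats::runif(n_nuclei, -3, 3))
  extent <- side * pitch
  total <- n_nuclei * loci_per_nucleus
  escape <- stats::runif(total) < extranuclear_fraction
  nucleus_of <- rep(seq_len(n_nuclei), each = loci_per_nucleus)
  x <- numeric(total); y <- numeric(total)
  inside <- which(!escape)
  rad <- r_nuc * sqrt(stats::runif(length(inside)))
  ang <- stats::runif(length(inside), 0, 2 * pi)
  x[inside] <- centers[nucleus_of[inside], 1] + rad * cos(ang)
  y[inside] <- centers[nucleus_of[inside], 2] + rad * sin(ang)
  for (i in which(escape)) {
    repeat {
      p <- stats::runif(2, 0, extent)
      d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
      if (min(d) >= r_nuc + 5) { x[i] <- p[1]; y[i] <- p[2]; break }
    }
  }
  points <- data.frame(
    x_um = x, y_um = y,
    species = sprintf("locus_%03d", sample.int(260, total, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  if (!is.null(section_thickness_um)) {
    stopifnot(section_thickness_um > 0)
    points$z_um <- stats::runif(total, 0, section_thickness_um)
  }
  list(points = points,
       truth = list(compartment = ifelse(escape, "extranuclear", "nuclear"),
                    nucleus_centers = centers, nucleus_radius_um = r_nuc,
                    extranuclear_fraction = extranuclear_fraction,
                    section_thickness_um = section_thickness_um))
}

# star-shaped nucleus boundary radius at angles theta
nucleus_template_radius <- function(theta, radius_um, deformation, phase) {
  a <- 0.65 * deformation
  radius_um * (1 + a * cos(5 * theta + phase))
}

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Generate rasterized nucleus masks of controlled deformation
#'
#' A family of star-shaped templates interpolating from a circle
#' (`deformation = 0`, convex, solidity 1) to a five-lobed concave shape
#' (`deformation = 1`). Truth solidity is computed exactly from the
#' generating polygon (shoelace area over convex-hull area); masks are
#' rasterized on a label image at the stated resolution.
#'
#' @param n number of nuclei.
#' @param deformation real in [0, 1].
#' @param seed integer seed (randomizes lobe phase per nucleus).
#' @param um_per_px raster resolution (default 0.1 um/pixel).
#' @param radius_um mean nucleus radius.
#' @return list with `masks` (class `nucleus_masks`: integer label matrix +
#'   `um_per_px`) and `truth` (per-nucleus solidity from the polygon).
#' @export
make_nucleus_set <- function(n, deformation, seed = 1L, um_per_px = 0.1,
                             radius_um = 6) {
  stopifnot(deformation >= 0, deformation <= 1, n >= 1)
  set.seed(substream(seed, "nuclei"))
  pitch_um <- 2 * radius_um * 1.7 + 4
  side <- ceiling(sqrt(n))
  px_pitch <- ceiling(pitch_um / um_per_px)
  labels <- matrix(0L, nrow = side * px_pitch, ncol = side * px_pitch)
  truth <- numeric(n)
  theta_fine <- seq(0, 2 * pi, length.out = 1441)[-1441]
  for (i in seq_len(n)) {
    phase <- stats::runif(1, 0, 2 * pi)
    # exact solidity from the generating polygon
    r_fine <- nucleus_template_radius(theta_fine, radius_um, deformation,
                                      phase)
    vx <- r_fine * cos(theta_fine); vy <- r_fine * sin(theta_fine)
    hull <- grDevices::chull(vx, vy)
    truth[i] <- polygon_area(vx, vy) / polygon_area(vx[hull], vy[hull])
    # rasterize (star-shaped: pixel center inside iff dist < r(theta))
    cx_um <- (((i - 1) %% side) + 0.5) * pitch_um
    cy_um <- (((i - 1) %/% side) + 0.5) * pitch_um
    half_px <- ceiling(radius_um * 1.7 / um_per_px)
    c_col <- round(cx_um / um_per_px); c_row <- round(cy_um / um_per_px)
    cols <- (c_col - half_px):(c_col + half_px)
    rows <- (c_row - half_px):(c_row + half_px)
    px <- outer(rep(1, length(rows)), (cols - 0.5) * um_per_px - cx_um)
    py <- outer((rows - 0.5) * um_per_px - cy_um, rep(1, length(cols)))
    th <- atan2(py, px)
    rr <- sqrt(px^2 + py^2)
    inside <- rr < nucleus_template_radius(th, radius_um, deformation, phase)
    block <- labels[rows, cols]
    block[inside] <- i
    labels[rows, cols] <- block
  }
  masks <- structure(list(labels = labels, um_per_px = um_per_px),
                     class = "nucleus_masks")
  list(masks = masks,
       truth = list(nucleus_solidity = stats::setNames(truth,
                                                       seq_len(n)),
                    deformation = deformation))
}

#' Write a simulated spatial sample in on-disk exchange formats
#'
#' Emits the same formats the readers consume: MatrixMarket trio, a headered
#' tissue-positions CSV, a truth TSV (spot, zone, colony id) and a JSON
#' sidecar with the generating configuration.
#'
#' @param sample result of [make_lattice_sample()].
#' @param dir output directory.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(sample$counts, dir)
  write_spot_positions(sample$lattice, file.path(dir, "tissue_positions.csv"))
  truth_df <- data.frame(
    spot_id = names(sample$truth$zone_of_spot),
    zone = unname(sample$truth$zone_of_spot),
    colony = unname(sample$truth$colony_membership[
      names(sample$truth$zone_of_spot)])
  )
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- unclass(sample$truth$config)
  cfg$panel <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
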