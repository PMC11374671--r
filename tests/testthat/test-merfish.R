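test_that("eps selection finds the intra-blob scale of separated blobs", {
  set.seed(41)
  blob <- function(cx, cy, n, r)
    data.frame(x_um = cx + runif(n, -r, r), y_um = cy + runif(n, -r, r))
  pts <- rbind(blob(0, 0, 100, 20), blob(300, 0, 100, 20))
  e <- as.numeric(select_eps(pts, k = 10))
  expect_gt(e, 3)            # above the intra-blob point spacing
  expect_lt(e, 100)          # far below the 300 um blob separation
  expect_error(select_eps(pts[1:5, ], k = 10), "k\\+1")
})

test_that("eps selection tracks the Poisson k-NN distance scale", {
  lam <- 200 / 500^2
  theo <- gamma(10.5) / gamma(10) / sqrt(lam * pi)
  ratios <- vapply(1:5, function(s) {
    set.seed(s)
    pts <- data.frame(x_um = runif(200, 0, 500),
                      y_um = runif(200, 0, 500))
    as.numeric(select_eps(pts, k = 10)) / theo
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("dbscan reproduces textbook cases", {
  set.seed(42)
  dense <- data.frame(x_um = runif(20, 0, 10), y_um = runif(20, 0, 10))
  out <- dbscan_cluster(dense, eps = 70, min_samples = 10)
  expect_equal(unique(out), 1L)                 # one cluster, no noise
  lone <- rbind(dense, data.frame(x_um = 500, y_um = 500))
  out2 <- dbscan_cluster(lone, eps = 70, min_samples = 10)
  expect_equal(out2[21], 0L)                    # isolated point is noise
})

test_that("dbscan labels equal the density-reachability oracle", {
  set.seed(43)
  for (rep in 1:60) {
    n <- sample(20:200, 1)
    k <- sample(2:4, 1)
    centers <- matrix(runif(2 * k, 0, 400), ncol = 2)
    pts <- data.frame(
      x_um = rnorm(n, centers[sample(k, n, TRUE), 1], 25),
      y_um = rnorm(n, centers[sample(k, n, TRUE), 2], 25))
    eps <- runif(1, 20, 80)
    ms <- sample(3:12, 1)
    expect_identical(dbscan_cluster(pts, eps, ms),
                     dbscan_oracle(pts, eps, ms))
  }
})

test_that("dbscan is invariant to reordering and rigid motion", {
  set.seed(44)
  pts <- data.frame(x_um = c(rnorm(40, 0, 10), rnorm(40, 300, 10)),
                    y_um = rnorm(80, 0, 10))
  ref <- dbscan_cluster(pts, eps = 50, min_samples = 5)
  perm <- sample(80)
  out_perm <- dbscan_cluster(pts[perm, ], eps = 50, min_samples = 5)
  # same partition after inverting the permutation (ids may be renamed)
  canon <- function(l) ifelse(l == 0, 0L,
                              match(l, unique(l[l > 0])))
  expect_identical(canon(out_perm[order(perm)]), canon(ref))
  th <- 0.7
  rot <- data.frame(
    x_um = cos(th) * pts$x_um - sin(th) * pts$y_um + 123,
    y_um = sin(th) * pts$x_um + cos(th) * pts$y_um - 77)
  expect_identical(dbscan_cluster(rot, eps = 50, min_samples = 5), ref)
})

test_that("planted point colonies are recovered with matching membership", {
  for (s in 1:3) {
    cfg <- sim_config(n_colonies = 8, seed = s)
    ms <- make_merfish_sample(cfg)
    isg <- cfg$panel$gene[cfg$panel$role == "ISG"]
    ip <- ms$points[ms$points$species %in% isg, ]
    cl <- classify_isg_clusters(ip)
    expect_equal(cl$n_clusters, 8)
    # per-cluster Jaccard against the planted region membership
    ctr <- ms$truth$colony_centers
    r <- ms$truth$colony_radius_um
    for (k in seq_len(8)) {
      in_k <- which(cl$labels == k)
      region <- which.min(sqrt((ctr[, 1] - mean(ip$x_um[in_k]))^2 +
                                 (ctr[, 2] - mean(ip$y_um[in_k]))^2))
      truth_pts <- which(sqrt((ip$x_um - ctr[region, 1])^2 +
                                (ip$y_um - ctr[region, 2])^2) <= r + 8)
      expect_gte(jaccard_sets(in_k, truth_pts), 0.9)
    }
  }
  # background-only sample yields no clusters
  cfg0 <- sim_config(n_colonies = 0, isg_effect = 8, seed = 4)
  ms0 <- make_merfish_sample(cfg0)
  isg <- cfg0$panel$gene[cfg0$panel$role == "ISG"]
  ip0 <- ms0$points[ms0$points$species %in% isg, ]
  expect_equal(classify_isg_clusters(ip0)$n_clusters, 0)
})

test_that("colony composition recovers a planted cell-type mixture", {
  cfg <- sim_config(n_colonies = 4, seed = 45)
  ms <- make_merfish_sample(cfg, cells_per_type = c("BZ CM" = 960,
                                                    "FB" = 240))
  isg <- cfg$panel$gene[cfg$panel$role == "ISG"]
  ip <- ms$points[ms$points$species %in% isg, ]
  cl <- classify_isg_clusters(ip)
  comp <- colony_composition(cl$labels, ip, ms$cells)
  pooled <- unlist(lapply(comp, function(co) co$positive_cells))
  types <- ms$cells$cell_type[match(pooled, ms$cells$cell_id)]
  p_bzcm <- mean(types == "BZ CM")
  se <- sqrt(0.8 * 0.2 / length(pooled))
  expect_lt(abs(p_bzcm - 0.8), 4 * se)
})

test_that("positive-cell calling honours the transcript minimum", {
  pts <- data.frame(x_um = c(0, 8, 0, 8, 50), y_um = c(0, 0, 8, 8, 50),
                    species = "Ifit1",
                    cell_id = c("c1", "c1", "c2", "c1", "c3"))
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      x_um = c(2, 3, 50), y_um = c(2, 3, 50),
                      cell_type = c("FB", "FB", "Mac"))
  labels <- c(1L, 1L, 1L, 1L, 0L)
  one <- colony_composition(labels, pts, cells,
                            positive_min_transcripts = 1)
  expect_setequal(one$cluster_1$positive_cells, c("c1", "c2"))
  expect_equal(one$cluster_1$proportions$proportion, 1)  # all fibroblast
  two <- colony_composition(labels, pts, cells,
                            positive_min_transcripts = 2)
  expect_equal(two$cluster_1$positive_cells, "c1")       # c2 has 1 point
})

test_that("extranuclear classification separates dense and sparse loci", {
  set.seed(46)
  # 50 loci inside a 4-um nucleus: all nuclear
  nuc <- data.frame(x_um = rnorm(50, 0, 1.5), y_um = rnorm(50, 0, 1.5),
                    species = "locus_001")
  expect_true(all(classify_extranuclear(nuc) == "nuclear"))
  # one point 20+ um from everything: extranuclear
  both <- rbind(nuc, data.frame(x_um = 40, y_um = 40,
                                species = "locus_002"))
  lab <- classify_extranuclear(both)
  expect_equal(as.character(lab[51]), "extranuclear")
  # labels partition the input
  expect_equal(sum(table(lab)), nrow(both))
})

test_that("adding nearby loci never flips a point to extranuclear", {
  set.seed(47)
  pts <- data.frame(x_um = runif(30, 0, 40), y_um = runif(30, 0, 40),
                    species = "l")
  before <- classify_extranuclear(pts)
  extra <- data.frame(x_um = rep(pts$x_um[1:5], each = 4) + runif(20, -1, 1),
                      y_um = rep(pts$y_um[1:5], each = 4) + runif(20, -1, 1),
                      species = "l")
  after <- classify_extranuclear(rbind(pts, extra))
  flipped <- before == "nuclear" & after[1:30] == "extranuclear"
  expect_false(any(flipped))
})

test_that("z-edge loci are excluded before density classification", {
  d <- make_dna_sample(12, 40, extranuclear_fraction = 0.1,
                       section_thickness_um = 16, seed = 48)
  lab <- classify_extranuclear(d$points, section_thickness_um = 16)
  z <- d$points$z_um
  expect_true(all(lab[z < 5 | z > 11] == "edge_excluded"))
  expect_true(all(lab[z >= 5 & z <= 11] != "edge_excluded"))
  # 2D tables pass through without edge exclusion
  d2 <- make_dna_sample(12, 40, extranuclear_fraction = 0, seed = 48)
  expect_false(any(classify_extranuclear(d2$points) == "edge_excluded"))
})

polygon_area_test <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

test_that("solidity matches the polygon oracle for convex and cross shapes", {
  # rasterized ellipse: solidity 1 within raster tolerance
  upp <- 0.1
  xs <- seq(-8, 8, by = upp); ys <- seq(-6, 6, by = upp)
  lab <- outer(ys, xs, function(y, x) as.integer((x / 7)^2 + (y / 5)^2 < 1))
  masks <- structure(list(labels = lab, um_per_px = upp),
                     class = "nucleus_masks")
  sol <- nuclear_solidity(masks)
  expect_equal(sol$solidity, 1, tolerance = 0.02)
  # cross of 3x9 arms: area 45 units^2; hull area from the exact polygon
  cross <- matrix(0L, 30, 30)
  cross[14:16, 11:19] <- 1L   # horizontal arm 3 x 9
  cross[11:19, 14:16] <- 1L   # vertical arm 9 x 3
  cm <- structure(list(labels = cross, um_per_px = 1), class = "nucleus_masks")
  got <- nuclear_solidity(cm)
  expect_equal(got$area_um2, 45)
  # oracle: shoelace on the convex hull of the pixel centres
  w <- which(cross == 1L, arr.ind = TRUE)
  h <- chull(w[, 2], w[, 1])
  oracle_hull <- polygon_area_test(w[h, 2], w[h, 1])
  expect_equal(got$hull_area_um2, oracle_hull)
  expect_equal(got$solidity, 45 / oracle_hull, tolerance = 1e-12)
  # two components rejected
  two <- cross; two[2, 2] <- 1L
  expect_error(nuclear_solidity(structure(list(labels = two, um_per_px = 1),
                                          class = "nucleus_masks")),
               "components")
})

test_that("measured solidity tracks generator truth and its ordering", {
  defs <- c(0.2, 0.5, 0.8)
  meas <- truth <- numeric(3)
  for (i in seq_along(defs)) {
    ns <- make_nucleus_set(4, defs[i], seed = 49)
    sol <- nuclear_solidity(ns$masks)
    meas[i] <- mean(sol$solidity)
    truth[i] <- mean(ns$truth$nucleus_solidity)
    expect_lt(max(abs(sol$solidity - ns$truth$nucleus_solidity)), 0.03)
  }
  expect_equal(order(meas), order(truth))
})
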