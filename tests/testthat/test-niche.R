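# colony_set with a single one-spot "colony" so ring geometry can be
# exercised around an arbitrary centroid
centroid_colony_set <- function(g, centroid) {
  st <- rep(FALSE, g$n)
  st[c(centroid, g$nbr[[centroid]][1])] <- TRUE
  cs <- segment_colonies(st, g)
  sc <- rep(0, g$n); sc[centroid] <- 1
  colony_stats(cs, hex_lattice(1, 1), g, scores = sc)
}

test_that("rings around an interior centroid hold 6, 12 and 18 spots", {
  lat <- hex_lattice(11, 11)
  g <- build_adjacency(lat)
  centroid <- which(lat$array_row == 5 & lat$array_col == 11)
  cs <- centroid_colony_set(g, centroid)
  rings <- assign_rings(cs, g)
  expect_equal(sum(rings$ring == "primary"), 6)
  expect_equal(sum(rings$ring == "secondary"), 12)
  expect_equal(sum(rings$ring == "tertiary"), 18)
  expect_equal(which(rings$ring == "centroid"), centroid)
})

test_that("edge centroids have truncated rings", {
  lat <- hex_lattice(11, 11)
  g <- build_adjacency(lat)
  corner <- which(lat$array_row == 0 & lat$array_col == 0)
  rings <- assign_rings(centroid_colony_set(g, corner), g)
  expect_lt(sum(rings$ring == "primary"), 6)
  expect_lt(sum(rings$ring == "secondary"), 12)
})

test_that("ring labels equal true BFS distances to the assigned centroid", {
  lat <- hex_lattice(9, 9)
  g <- build_adjacency(lat)
  set.seed(31)
  cs <- centroid_colony_set(g, 40)
  rings <- assign_rings(cs, g)
  d <- bfs_oracle(g, cs$stats$centroid[1])
  for (i in which(!is.na(rings$ring_k)))
    if (is.na(rings$colony[i]) || rings$colony[i] == 1)
      expect_equal(rings$ring_k[i], d[i])
})

test_that("equidistant spots go to the lower colony id", {
  lat <- hex_lattice(9, 13)
  g <- build_adjacency(lat)
  # two colonies whose centroids are 2 apart on the same row
  c1 <- which(lat$array_row == 4 & lat$array_col == 10)
  c2 <- which(lat$array_row == 4 & lat$array_col == 14)
  st <- rep(FALSE, g$n)
  st[c(c1, c1 - 1L, c2, c2 + 1L)] <- TRUE
  sc <- rep(0, g$n); sc[c1] <- 2; sc[c2] <- 2; sc[c(c1 - 1L, c2 + 1L)] <- 1
  cs <- colony_stats(segment_colonies(st, g), lat, g, scores = sc)
  expect_equal(cs$stats$centroid, sort(c(c1, c2)))
  rings <- assign_rings(cs, g)
  mid <- which(lat$array_row == 4 & lat$array_col == 12)
  expect_equal(rings$ring_k[mid], 1)
  expect_equal(rings$colony[mid], 1)   # tie resolved to colony 1
})

test_that("ring DE recovers the planted decay and inverse patterns", {
  cfg <- sim_config(seed = 17, n_colonies = 3, colony_size_range = c(7, 9))
  sm <- make_lattice_sample(cfg)
  seg <- segment_sample(sm, calibrate_on_controls(cfg))
  cs <- colony_stats(seg$colonies, sm$lattice, sm$graph,
                     scores = as.numeric(seg$scores))
  rings <- assign_rings(cs, sm$graph)
  de <- ring_de(normalize_log10k(sm$counts), rings)
  ifit <- de[de$gene == "Ifit1", ]
  expect_equal(nrow(ifit), 3)
  expect_true(all(ifit$lnfc < 0))                      # ISG decays outward
  expect_lt(ifit$lnfc[ifit$ring == "tertiary"],
            ifit$lnfc[ifit$ring == "primary"])
  postn <- de[de$gene == "Postn", ]
  expect_gt(postn$lnfc[postn$ring == "tertiary"], 0)   # matricellular rises
  # a spatially flat gene shows no marker-grade ring effect (the centroid
  # group holds only a few spots, so its fold change is noisy but small
  # next to the planted ISG decay)
  flat <- de[de$gene == "Tnnt2", ]
  expect_true(all(flat$p_adj > 1e-4))
  expect_lt(max(abs(flat$lnfc)),
            max(abs(ifit$lnfc)) / 2)
})

test_that("line scans are flat for uniform fields and step where planted", {
  lat <- hex_lattice(15, 25)
  prof <- line_scan(rep(3, nrow(lat)), lat, c(0, 600), c(2400, 600),
                    bin_um = 200)
  expect_true(all(abs(prof$mean - 3) < 1e-12))
  # step at x = 1200 um lands in the bin containing that distance
  sc <- ifelse(lat$x_um < 1200, 1, 9)
  prof2 <- line_scan(sc, lat, c(0, 600), c(2400, 600), bin_um = 200,
                     band_halfwidth_um = 300)
  lo <- prof2$mean[prof2$bin_end_um <= 1200]
  hi <- prof2$mean[prof2$bin_start_um >= 1200]
  expect_true(all(lo == 1))
  expect_true(all(hi == 9))
  # spots beyond the band never count
  n_in_band <- sum(prof2$n)
  expect_equal(n_in_band, sum(lat$x_um >= 0 & lat$x_um <= 2400 &
                                abs(lat$y_um - 600) <= 300))
  expect_error(line_scan(sc, lat, c(0, 0), c(0, 0)), "distinct")
})

test_that("line scans are invariant under joint rigid rotation", {
  lat <- hex_lattice(12, 12)
  set.seed(32)
  sc <- runif(nrow(lat))
  p0 <- c(100, 200); p1 <- c(900, 700)
  ref <- line_scan(sc, lat, p0, p1)
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- lat
  xy <- cbind(lat$x_um, lat$y_um) %*% t(R)
  rot$x_um <- xy[, 1]; rot$y_um <- xy[, 2]
  got <- line_scan(sc, rot, as.numeric(R %*% p0), as.numeric(R %*% p1))
  expect_equal(got$mean, ref$mean, tolerance = 1e-9)
  expect_equal(got$n, ref$n)
})

test_that("neighbour fraction profiles match exact shell enumeration", {
  lat <- hex_lattice(13, 13)
  g <- build_adjacency(lat)
  set.seed(33)
  ref <- runif(g$n) < 0.1
  if (!any(ref)) ref[1] <- TRUE
  query <- !ref
  prof <- neighbor_fraction_profile(ref, query, g)
  d <- bfs_distance(g, which(ref))
  for (k in 1:4) {
    shell <- which(!is.na(d) & d == k)
    expect_equal(prof$fraction[prof$ring == k], mean(query[shell]))
    expect_equal(prof$n_shell[prof$ring == k], length(shell))
  }
  # degenerate queries
  all_neg <- neighbor_fraction_profile(ref, rep(FALSE, g$n), g)
  expect_true(all(all_neg$fraction == 0, na.rm = TRUE))
  all_pos <- neighbor_fraction_profile(ref, rep(TRUE, g$n), g)
  expect_true(all(all_pos$fraction == 1, na.rm = TRUE))
  expect_error(neighbor_fraction_profile(rep(FALSE, g$n), query, g),
               "empty")
})
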