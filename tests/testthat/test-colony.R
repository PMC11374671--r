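test_that("neighbourhood counts reproduce the 0-6 N matrix", {
  lat <- hex_lattice(7, 7)
  g <- build_adjacency(lat)
  interior <- which(lat$array_row == 3 & lat$array_col == 7)
  # isolated positive spot: N = 0 everywhere except its neighbours
  st <- rep(FALSE, g$n); st[interior] <- TRUE
  nd <- neighbourhood_counts(st, g)
  expect_equal(nd$n_pos_neighbours[interior], 0)
  expect_true(all(nd$n_pos_neighbours[g$nbr[[interior]]] == 1))
  # fully positive neighbourhood: interior spot reaches N = 6
  st2 <- rep(FALSE, g$n); st2[c(interior, g$nbr[[interior]])] <- TRUE
  nd2 <- neighbourhood_counts(st2, g)
  expect_equal(nd2$n_pos_neighbours[interior], 6)
  # boundary spot with two positive neighbours
  corner <- which(lat$array_row == 0 & lat$array_col == 0)
  st3 <- rep(FALSE, g$n)
  st3[g$nbr[[corner]]] <- TRUE
  expect_equal(neighbourhood_counts(st3, g)$n_pos_neighbours[corner],
               g$degree[corner])
  expect_error(neighbourhood_counts(st[-1], g), "length")
})

test_that("segmentation equals the flood-fill oracle on random fields", {
  set.seed(21)
  for (rep in 1:60) {
    lat <- hex_lattice(sample(4:8, 1), sample(4:8, 1))
    g <- build_adjacency(lat)
    st <- runif(g$n) < runif(1, 0.1, 0.6)
    cs <- segment_colonies(st, g)
    oracle <- flood_fill_oracle(st, g)
    sizes <- lengths(oracle)
    ocol <- oracle[sizes >= 2]
    ocol <- ocol[order(vapply(ocol, min, 0L))]
    ccol <- cs$colonies[order(vapply(cs$colonies, min, 0L))]
    expect_identical(unname(ccol), unname(ocol))
    expect_equal(sort(unlist(oracle[sizes == 1])), cs$scattered)
    # partition exactness: colonies + scattered = positive spots
    expect_equal(sort(c(unlist(cs$colonies), cs$scattered)), which(st))
  }
})

test_that("no positive spot adjacent to a colony is left outside it", {
  set.seed(22)
  g <- build_adjacency(hex_lattice(8, 8))
  st <- runif(g$n) < 0.4
  cs <- segment_colonies(st, g)
  for (col in cs$colonies) {
    halo <- setdiff(unique(unlist(g$nbr[col])), col)
    expect_false(any(st[halo]))
  }
})

test_that("colony areas follow the 55-um spot conventions linearly", {
  lat <- hex_lattice(6, 6)
  g <- build_adjacency(lat)
  st <- rep(FALSE, g$n)
  st[c(8, 9, g$nbr[[8]][1])] <- TRUE
  st[20] <- TRUE  # scattered
  cs <- segment_colonies(st, g)
  ann <- colony_stats(cs, lat, g)
  per_circle <- pi * 27.5^2
  expect_equal(per_circle, 2375.83, tolerance = 1e-4)
  expect_equal(ann$stats$area_um2, ann$stats$n_spots * per_circle)
  hexed <- colony_stats(cs, lat, g, area_convention = "hex")
  expect_equal(hexed$stats$area_um2,
               hexed$stats$n_spots * sqrt(3) / 2 * 100^2)
  expect_error(colony_stats(cs, lat, g, area_convention = "square"))
})

test_that("colony centroid is the highest-scoring member spot", {
  g <- build_adjacency(hex_lattice(5, 5))
  members <- c(7, g$nbr[[7]][1:2])
  st <- rep(FALSE, g$n); st[members] <- TRUE
  sc <- rep(0, g$n); sc[members] <- c(5, 9, 2)
  cs <- colony_stats(segment_colonies(st, g), hex_lattice(5, 5), g,
                     scores = sc)
  expect_equal(cs$stats$centroid, members[2])
  # tie broken toward the lowest spot index
  sc[members] <- c(9, 9, 2)
  cs2 <- colony_stats(segment_colonies(st, g), hex_lattice(5, 5), g,
                      scores = sc)
  expect_equal(cs2$stats$centroid, min(members[1:2]))
})

test_that("saturated targets drive the localization test to p = 1", {
  cfg <- small_sim_config(seed = 5)
  sm <- make_lattice_sample(cfg)
  seg <- segment_sample(sm, calibrate_on_controls(cfg))
  lt <- localization_test(seg$colonies, rep(TRUE, sm$graph$n), sm$graph,
                          trials_per_size = 100, seed = 1)
  expect_equal(lt$pooled$p_fisher, 1)
  expect_equal(lt$size1_analytic, 1)
  expect_true(all(lt$per_size$sim_success == 100))
})

test_that("size-1 success probability matches the analytic fraction", {
  cfg <- small_sim_config(seed = 6)
  sm <- make_lattice_sample(cfg)
  g <- sm$graph
  target <- unname(sm$truth$zone_of_spot == "BZ")
  seg <- segment_sample(sm, calibrate_on_controls(cfg))
  lt <- localization_test(seg$colonies, target, g,
                          trials_per_size = 500, seed = 2)
  targetplus <- target
  targetplus[unique(unlist(g$nbr[which(target)]))] <- TRUE
  p_hat <- lt$per_size$sim_success[1] / 500
  p_true <- mean(targetplus)
  expect_equal(lt$size1_analytic, p_true)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 500))
})

test_that("localization input contracts are enforced", {
  cfg <- small_sim_config(seed = 7)
  sm <- make_lattice_sample(cfg)
  seg <- segment_sample(sm, calibrate_on_controls(cfg))
  expect_error(localization_test(seg$colonies, rep(FALSE, sm$graph$n),
                                 sm$graph), "empty")
  empty <- segment_colonies(rep(FALSE, sm$graph$n), sm$graph)
  expect_error(localization_test(empty,
                                 unname(sm$truth$zone_of_spot == "BZ"),
                                 sm$graph), "colonies")
})

test_that("simulated success counts are monotone in colony size", {
  cfg <- small_sim_config(seed = 8)
  sm <- make_lattice_sample(cfg)
  seg <- segment_sample(sm, calibrate_on_controls(cfg))
  lt <- localization_test(seg$colonies,
                          unname(sm$truth$zone_of_spot == "BZ"),
                          sm$graph, trials_per_size = 300, seed = 3)
  expect_true(all(diff(lt$per_size$sim_success) >= 0))
})
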