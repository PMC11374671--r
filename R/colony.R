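#' Neighbourhood matrix of ISG-positive first-order neighbours
#'
#' For every spot, counts its first-order neighbours in the positive state
#' (the paper-style 0-6 value N), i.e. the column sums of the intersection
#' of the binary adjacency structure with the binary ISG classification.
#'
#' @param states logical per-spot vector aligned to the graph.
#' @param graph a `spot_graph`.
#' @return data.frame (`spot_id`, `isg_pos`, `n_pos_neighbours`).
#' @export
neighbourhood_counts <- function(states, graph) {
  stopifnot(inherits(graph, "spot_graph"))
  if (length(states) != graph$n)
    stop("states length does not match graph size")
  states <- as.logical(states)
  N <- vapply(graph$nbr, function(nb) sum(states[nb]), 0L)
  data.frame(spot_id = graph$spot_id, isg_pos = states,
             n_pos_neighbours = N, stringsAsFactors = FALSE)
}

#' Segment IFNIC colonies from binary ISG states
#'
#' Colonies are the connected components of ISG-positive spots under the
#' first-order lattice graph. Contiguity is a requisite: components of size
#' one are not colonies and are reported separately as scattered spots.
#'
#' @param states logical per-spot vector aligned to the graph.
#' @param graph a `spot_graph`.
#' @return object of class `colony_set`: list with `colonies` (list of
#'   sorted spot-index vectors), `scattered` (indices of isolated positive
#'   spots), `n_spots` per colony, and the graph's `spot_id` vector.
#' @export
segment_colonies <- function(states, graph) {
  stopifnot(inherits(graph, "spot_graph"))
  if (length(states) != graph$n)
    stop("states length does not match graph size")
  comps <- graph_components(graph, as.logical(states))
  sizes <- lengths(comps)
  structure(list(
    colonies = comps[sizes >= 2],
    scattered = sort(unlist(comps[sizes == 1], use.names = FALSE)),
    n_spots = sizes[sizes >= 2],
    spot_id = graph$spot_id
  ), class = "colony_set")
}

#' @export
print.colony_set <- function(x, ...) {
  cat(sprintf("colony_set: %d colonies (sizes %s), %d scattered spots\n",
              length(x$colonies),
              if (length(x$n_spots)) paste(x$n_spots, collapse = ",")
              else "-",
              length(x$scattered)))
  invisible(x)
}

#' Annotate colonies with size, area and centroid
#'
#' Colony area is the number of member spots times a per-spot area: the
#' circular capture area `pi * (diameter/2)^2` (55 um diameter by default)
#' or the full hexagonal lattice cell `(sqrt(3)/2) * spacing^2`. The colony
#' centroid is the member spot with maximal ISG score (ties broken by
#' lowest spot id).
#'
#' @param colonies a `colony_set`.
#' @param lattice the `spot_lattice` the graph was built from.
#' @param graph the `spot_graph` matching `colonies`.
#' @param scores optional per-spot ISG `score_vector` (graph order) used to
#'   pick centroids.
#' @param area_convention `"circle"` or `"hex"`.
#' @return the `colony_set` with an added data.frame `stats` (`colony`,
#'   `n_spots`, `area_um2`, `centroid` index, `centroid_spot`).
#' @export
colony_stats <- function(colonies, lattice, graph, scores = NULL,
                         area_convention = c("circle", "hex")) {
  area_convention <- match.arg(area_convention)
  stopifnot(inherits(colonies, "colony_set"))
  sp <- lattice_spacing(lattice); dm <- lattice_diameter(lattice)
  per_spot <- switch(area_convention,
                     circle = pi * (dm / 2)^2,
                     hex = sqrt(3) / 2 * sp^2)
  if (!is.null(scores)) scores <- as.numeric(scores)
  stats_df <- do.call(rbind, lapply(seq_along(colonies$colonies),
                                    function(k) {
    mem <- colonies$colonies[[k]]
    centroid <- if (is.null(scores)) min(mem) else {
      s <- scores[mem]
      mem[which(s == max(s))][1]   # members sorted, so lowest id wins ties
    }
    data.frame(colony = k, n_spots = length(mem),
               area_um2 = length(mem) * per_spot,
               centroid = centroid,
               centroid_spot = colonies$spot_id[centroid])
  }))
  colonies$stats <- stats_df
  colonies$area_convention <- area_convention
  colonies$per_spot_area_um2 <- per_spot
  colonies
}

# grow a nested random connected set by uniform accretion; returns the
# member indices in accretion order (restarts on stall)
grow_null_set <- function(graph, size) {
  repeat {
    start <- sample.int(graph$n, 1)
    members <- integer(size)
    members[1] <- start
    inset <- logical(graph$n); inset[start] <- TRUE
    pool <- graph$nbr[[start]]
    ok <- TRUE
    if (size > 1) for (s in 2:size) {
      pool <- pool[!inset[pool]]
      pool <- unique(pool)
      if (!length(pool)) { ok <- FALSE; break }
      nxt <- pool[sample.int(length(pool), 1)]
      members[s] <- nxt
      inset[nxt] <- TRUE
      pool <- c(pool, graph$nbr[[nxt]])
    }
    if (ok) return(members)
  }
}

#' Monte Carlo borderzone-localization test
#'
#' Asks whether observed colonies overlap or neighbour a target spot set
#' (for example BZ-high spots) more often than random connected spot sets
#' of the same sizes. For each size `s = 1..max_size`, `trials_per_size`
#' random connected sets are grown by uniform neighbour accretion from a
#' uniform random tissue seed (the N+1 accretion null); a trial succeeds
#' when any member lies in, or is first-order adjacent to, the target set.
#' Observed colonies are binned by size (clipped at `max_size`) and each
#' size's 2x2 simulated-vs-observed table is tested two-sided with Fisher's
#' exact test (primary) and Yates-corrected chi-squared; a pooled test over
#' the observed sizes is also reported.
#'
#' @param colonies a `colony_set` with at least one colony.
#' @param target_states logical per-spot target indicator (non-empty, not
#'   all spots).
#' @param graph a `spot_graph`.
#' @param trials_per_size Monte Carlo trials per size (default 500).
#' @param max_size largest grown set (default 12).
#' @param seed integer seed.
#' @return object of class `localization_result`: `per_size` data.frame
#'   (`size`, `sim_success`, `sim_trials`, `obs_success`, `obs_total`,
#'   `odds_ratio`, `p_fisher`, `p_chisq`), `pooled` list, and the analytic
#'   size-1 success probability `size1_analytic`.
#' @export
localization_test <- function(colonies, target_states, graph,
                              trials_per_size = 500, max_size = 12,
                              seed = 1L) {
  stopifnot(inherits(colonies, "colony_set"), inherits(graph, "spot_graph"))
  target_states <- as.logical(target_states)
  if (length(target_states) != graph$n)
    stop("target length does not match graph size")
  if (!any(target_states)) stop("target set is empty")
  if (!length(colonies$colonies)) stop("no observed colonies")
  # overlap-or-adjacency: target plus its first-order neighbourhood
  targetplus <- target_states
  targetplus[unique(unlist(graph$nbr[which(target_states)],
                           use.names = FALSE))] <- TRUE

  set.seed(seed)
  # nested growth: one set of size max_size yields success at every size
  first_hit <- integer(trials_per_size)
  for (t in seq_len(trials_per_size)) {
    mem <- grow_null_set(graph, max_size)
    hits <- which(targetplus[mem])
    first_hit[t] <- if (length(hits)) hits[1] else max_size + 1L
  }
  sim_success <- vapply(seq_len(max_size),
                        function(s) sum(first_hit <= s), 0L)

  obs_sizes <- pmin(colonies$n_spots, max_size)
  obs_hit <- vapply(colonies$colonies,
                    function(mem) any(targetplus[mem]), TRUE)
  test_2x2 <- function(sim_s, sim_n, obs_s, obs_n) {
    tab <- matrix(c(sim_s, sim_n - sim_s, obs_s, obs_n - obs_s), 2,
                  byrow = TRUE)
    ft <- stats::fisher.test(tab)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    list(or = unname(ft$estimate), p_fisher = ft$p.value,
         p_chisq = ct$p.value)
  }
  per_size <- do.call(rbind, lapply(seq_len(max_size), function(s) {
    sel <- obs_sizes == s
    row <- data.frame(size = s, sim_success = sim_success[s],
                      sim_trials = trials_per_size,
                      obs_success = sum(obs_hit[sel]),
                      obs_total = sum(sel),
                      odds_ratio = NA_real_, p_fisher = NA_real_,
                      p_chisq = NA_real_)
    if (row$obs_total > 0) {
      tt <- test_2x2(row$sim_success, trials_per_size,
                     row$obs_success, row$obs_total)
      row$odds_ratio <- tt$or
      row$p_fisher <- tt$p_fisher
      row$p_chisq <- tt$p_chisq
    }
    row
  }))
  pooled_sim_s <- sum(sim_success[obs_sizes])
  pooled_sim_n <- trials_per_size * length(obs_sizes)
  pooled <- test_2x2(pooled_sim_s, pooled_sim_n, sum(obs_hit),
                     length(obs_hit))
  structure(list(
    per_size = per_size,
    pooled = c(pooled, list(sim_success = pooled_sim_s,
                            sim_trials = pooled_sim_n,
                            obs_success = sum(obs_hit),
                            obs_total = length(obs_hit))),
    size1_analytic = mean(targetplus),
    trials_per_size = trials_per_size, max_size = max_size, seed = seed
  ), class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat("localization_result (Fisher primary, Yates chi-squared secondary)\n")
  cat(sprintf("pooled: obs %d/%d vs sim %d/%d, p_fisher = %.4g\n",
              x$pooled$obs_success, x$pooled$obs_total,
              x$pooled$sim_success, x$pooled$sim_trials,
              x$pooled$p_fisher))
  invisible(x)
}
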