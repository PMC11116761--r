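#' Constant Potts Model quality of a partition
#'
#' Weighted CPM objective: sum over communities of
#' `internal edge weight - gamma * n_c (n_c - 1) / 2`. Larger is better;
#' gamma sets the internal-density threshold a community must exceed.
#'
#' @param am an [compute_sri()] result (weights = SRI, zero dyads are
#'   non-edges).
#' @param membership named vector (individual id -> unit label) or a
#'   `unit_partition`.
#' @param gamma resolution parameter.
#' @return CPM objective value.
#' @export
cpm_quality <- function(am, membership, gamma) {
  if (inherits(membership, "unit_partition")) membership <- membership$membership
  membership <- membership[am$ids]
  w <- am$sri
  q <- 0
  for (u in unique(membership)) {
    idx <- which(membership == u)
    nc <- length(idx)
    internal <- if (nc > 1) sum(w[idx, idx][upper.tri(w[idx, idx])]) else 0
    q <- q + internal - gamma * nc * (nc - 1) / 2
  }
  q
}

sri_graph <- function(am) {
  g <- igraph::graph_from_adjacency_matrix(
    replace(am$sri, is.na(am$sri), 0), mode = "undirected", weighted = TRUE)
  if (igraph::vcount(g) == 0) stopf("empty association graph")
  g
}

leiden_once <- function(g, gamma, n_iterations) {
  cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                               weights = igraph::E(g)$weight,
                               resolution = gamma,
                               n_iterations = n_iterations)
  igraph::membership(cl)
}

canonical_units <- function(membership) {
  # label each unit by its lexicographically smallest member id
  ids <- names(membership)
  lab <- vapply(split(ids, membership), min, "")
  setNames(lab[as.character(membership)], ids)
}

#' Detect social units by Leiden optimisation of the CPM
#'
#' Builds a weighted undirected graph from the SRI matrix (every dyad with
#' SRI > 0 is an edge) and partitions it with the Leiden algorithm under
#' the Constant Potts Model at resolution `gamma`. The optimiser is
#' restarted `n_restarts` times from different random states; the
#' best-quality partition is returned, with stability measured as the mean
#' pairwise adjusted Rand index across restarts. Each restart iterates the
#' Leiden moves until the partition is stable, within an `n_iterations`
#' budget. Unit labels are canonicalised to the smallest member id.
#'
#' @param am an [compute_sri()] result.
#' @param gamma CPM resolution (gamma = 0 merges any connected structure).
#' @param n_iterations iteration budget per restart.
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @return Object of class `unit_partition`: `membership` (named vector),
#'   `units` (list of member ids), `gamma`, `quality` (CPM objective,
#'   recomputable with [cpm_quality()]), `stability`, `n_restarts`, `seed`.
#' @export
detect_units <- function(am, gamma, n_iterations = 20000, n_restarts = 20,
                         seed = 1) {
  g <- sri_graph(am)
  # run-to-stability per restart; the budget caps pathological cases
  iters <- min(n_iterations, 1000L)
  runs <- with_seed(seed, lapply(seq_len(n_restarts), function(i)
    leiden_once(g, gamma, iters)))
  quals <- vapply(runs, function(m) cpm_quality(am, setNames(
    as.character(m), am$ids), gamma), 0)
  best <- which.max(quals)
  stability <- partition_stability(runs)
  membership <- canonical_units(setNames(as.character(runs[[best]]), am$ids))
  structure(list(membership = membership,
                 units = split(names(membership), membership),
                 gamma = gamma, quality = quals[best],
                 stability = stability,
                 n_restarts = n_restarts, n_iterations = n_iterations,
                 seed = seed),
            class = "unit_partition")
}

partition_stability <- function(runs) {
  if (length(runs) < 2) return(NA_real_)
  pairs <- combn(length(runs), 2)
  mean(apply(pairs, 2, function(p)
    mclust::adjustedRandIndex(runs[[p[1]]], runs[[p[2]]])))
}

#' @export
print.unit_partition <- function(x, ...) {
  sizes <- lengths(x$units)
  cat(sprintf("unit_partition: %d units (sizes %s) at gamma = %.3g\n",
              length(x$units), paste(sort(sizes, TRUE), collapse = ","),
              x$gamma))
  cat(sprintf("  CPM quality %.3f, stability %.3f over %d restarts\n",
              x$quality, x$stability, x$n_restarts))
  invisible(x)
}

#' Scan the CPM resolution parameter
#'
#' Runs [detect_units()] over a grid of gamma values and records, for
#' each, the number of units, the CPM quality and the stability across
#' restarts. The selected resolution `gamma_star` is the midpoint of the
#' widest contiguous plateau of constant unit count whose stability stays
#' at or above `stability_threshold`; if no such plateau exists the most
#' stable grid point is returned with a flag.
#'
#' @param am an [compute_sri()] result.
#' @param gamma_grid numeric vector of resolutions to evaluate.
#' @param n_restarts restarts per grid point.
#' @param seed integer seed.
#' @param stability_threshold minimum mean pairwise adjusted Rand index
#'   for a grid point to join a plateau.
#' @return list with `gamma_star`, `profile` (data.frame: gamma, n_units,
#'   quality, stability), `plateau` (index range) and `flagged`.
#' @export
scan_gamma <- function(am, gamma_grid, n_restarts = 20, seed = 1,
                       stability_threshold = 0.95) {
  if (!length(gamma_grid)) stopf("empty gamma grid")
  gamma_grid <- sort(gamma_grid)
  fits <- lapply(seq_along(gamma_grid), function(i)
    detect_units(am, gamma_grid[i], n_restarts = n_restarts,
                 seed = seed + i - 1))
  profile <- data.frame(gamma = gamma_grid,
                        n_units = vapply(fits, function(f) length(f$units), 1L),
                        quality = vapply(fits, function(f) f$quality, 1),
                        stability = vapply(fits, function(f)
                          if (is.na(f$stability)) 1 else f$stability, 1))
  ok <- profile$stability >= stability_threshold
  # contiguous runs of identical unit count, all stable
  run_id <- cumsum(c(TRUE, diff(profile$n_units) != 0 | diff(ok) != 0))
  widths <- tapply(seq_along(run_id), run_id, length)
  stable_runs <- tapply(ok, run_id, all)
  spans <- tapply(profile$gamma, run_id, function(g) diff(range(g)))
  cand <- which(stable_runs)
  if (length(cand)) {
    best <- cand[order(-spans[cand], -widths[cand])][1]
    idx <- which(run_id == as.integer(names(stable_runs)[best]))
    gamma_star <- mean(range(profile$gamma[idx]))
    flagged <- FALSE
  } else {
    idx <- which.max(profile$stability)
    gamma_star <- profile$gamma[idx]
    flagged <- TRUE
  }
  list(gamma_star = gamma_star, profile = profile,
       plateau = range(idx), flagged = flagged)
}

#' Summarise social units
#'
#' Per-unit size, mean within-unit SRI, and depredation involvement under
#' the convention that a unit was present at a depredation event whenever
#' at least one of its members was photographed during the vessel
#' sighting: number of distinct calendar years with at least one such
#' sighting, number of such sightings, and their percentage of all vessel
#' sightings in the dataset.
#'
#' @param p a [detect_units()] partition.
#' @param am an [compute_sri()] result (for within-unit SRI).
#' @param ds a [kw_dataset()].
#' @return data.frame with one row per unit: `unit`, `size`,
#'   `mean_within_sri` (NA for singletons), `years_sighted`,
#'   `n_depredation_sightings`, `proportion_of_sightings` (percent).
#' @export
summarise_units <- function(p, am, ds) {
  stopifnot(inherits(p, "unit_partition"), inherits(ds, "kw_dataset"))
  vs <- ds$sightings[ds$sightings$platform == "vessel", , drop = FALSE]
  total <- nrow(vs)
  yr <- utc_year(vs$start_time)
  out <- lapply(names(p$units), function(u) {
    members <- p$units[[u]]
    hit <- vapply(vs$individual_ids, function(g) any(members %in% g), TRUE)
    wsri <- if (length(members) > 1) {
      sub <- am$sri[members, members]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    data.frame(unit = u, size = length(members), mean_within_sri = wsri,
               years_sighted = length(unique(yr[hit])),
               n_depredation_sightings = sum(hit),
               proportion_of_sightings =
                 if (total > 0) 100 * sum(hit) / total else 0)
  })
  out <- do.call(rbind, out)
  out[order(out$unit), , drop = FALSE]
}
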