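#' Configuration for the synthetic photo-identification generator
#'
#' Defaults emulate the scale of the study system: 79 individuals in 17
#' social units of 1-10 members, 18 years (2005-2022) of observation from
#' two platforms (~1475 vessel sightings at depredation events, ~168
#' shore sightings), per-unit marginal occurrence probabilities spanning
#' roughly 0.04-0.225, modest year and month log-odds effects, isotropic
#' bivariate per-unit spatial ranges inside the 44-48 S / 45-55 E
#' exclusive economic zone box, a long-tailed photographs-per-sighting
#' distribution (median near 42), and saturating effort-driven detection
#' `P(identified) = 1 - exp(-lambda_detect x n_photos)`.
#'
#' @param n_individuals total individuals.
#' @param unit_sizes integer vector of unit sizes (must sum to
#'   `n_individuals`).
#' @param years calendar years covered.
#' @param n_vessel_sightings depredation events generated.
#' @param n_shore_sightings shore sightings generated.
#' @param n_vessels number of fishing vessels.
#' @param unit_prob_range range of per-unit occurrence probabilities at
#'   depredation events (assigned on a logit-spaced ladder).
#' @param shore_prob_range range of per-unit attendance probabilities at
#'   shore sightings.
#' @param year_sd,month_sd standard deviations of the year and month
#'   log-odds effects.
#' @param effort_meanlog,effort_sdlog log-normal photographs-per-sighting
#'   parameters (counts are clipped to `[1, 3299]`).
#' @param lambda_detect per-photo identification rate.
#' @param dispersion_km per-unit range dispersion (bivariate normal SD).
#' @param bbox spatial bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)`.
#' @param unit_affinity optional symmetric matrix of pairwise log-odds
#'   boosts inducing correlated unit co-attendance (default: units attend
#'   independently).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 79,
                       unit_sizes = c(1, 2, 2, 3, 3, 4, 4, 4, 5, 5, 5,
                                      6, 6, 6, 7, 8, 8),
                       years = 2005:2022,
                       n_vessel_sightings = 1475,
                       n_shore_sightings = 168,
                       n_vessels = 8,
                       unit_prob_range = c(0.04, 0.225),
                       shore_prob_range = c(0.03, 0.25),
                       year_sd = 0.15, month_sd = 0.10,
                       effort_meanlog = log(42), effort_sdlog = 1.1,
                       lambda_detect = 0.06,
                       dispersion_km = 80,
                       bbox = c(45, 55, -48, -44),
                       unit_affinity = NULL) {
  if (sum(unit_sizes) != n_individuals) {
    stopf("unit sizes sum to %d but n_individuals is %d",
          sum(unit_sizes), n_individuals)
  }
  if (any(unit_sizes < 1)) stopf("unit sizes must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic photo-identification dataset with known truth
#'
#' Simulates depredation events (vessel sightings) and shore sightings
#' under a known generative model: each social unit attends a depredation
#' event with probability `plogis(qlogis(p_unit) + year effect + month
#' effect)`; the event location is drawn from the bivariate range of one
#' attending unit; each member of an attending unit is identified with
#' the effort-dependent detection probability. Events where no individual
#' is identified are not observable and are excluded from the dataset
#' (the truth table keeps every generated event). Fixing `seed`
#' reproduces the dataset bit for bit.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `dataset` (a [kw_dataset()]) and `truth`: unit
#'   membership, per-unit probabilities (`plogis` of unit intercepts),
#'   year/month effects, unit centres, the per-event attendance matrix
#'   and the generator parameters.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_units <- length(config$unit_sizes)
    ids <- sprintf("CR%03d", seq_len(config$n_individuals))
    membership <- setNames(rep(sprintf("U%02d", seq_len(n_units)),
                               config$unit_sizes), ids)
    units <- split(ids, membership)

    # logit-spaced occurrence ladder, shuffled over units
    p_unit <- plogis(seq(qlogis(config$unit_prob_range[1]),
                         qlogis(config$unit_prob_range[2]),
                         length.out = n_units))
    p_unit <- setNames(sample(p_unit), names(units))
    p_shore <- plogis(seq(qlogis(config$shore_prob_range[1]),
                          qlogis(config$shore_prob_range[2]),
                          length.out = n_units))
    p_shore <- setNames(sample(p_shore), names(units))

    year_eff <- setNames(rnorm(length(config$years), 0, config$year_sd),
                         config$years)
    month_eff <- setNames(rnorm(12, 0, config$month_sd), 1:12)
    centres <- cbind(lon = runif(n_units, config$bbox[1] + 1,
                                 config$bbox[2] - 1),
                     lat = runif(n_units, config$bbox[3] + 0.5,
                                 config$bbox[4] - 0.5))
    rownames(centres) <- names(units)

    vess <- simulate_events(config, units, p_unit, year_eff, month_eff,
                            centres, platform = "vessel")
    shore <- simulate_events(config, units, p_shore, year_eff, month_eff,
                             centres, platform = "shore")

    s <- rbind(vess$sightings, shore$sightings)
    s <- s[lengths(s$individual_ids) > 0, , drop = FALSE]
    rownames(s) <- NULL
    truth <- list(membership = membership, units = units,
                  p_unit = p_unit, p_shore = p_shore,
                  year_effects = year_eff, month_effects = month_eff,
                  centres = centres,
                  dispersion_km = config$dispersion_km,
                  lambda_detect = config$lambda_detect,
                  attendance = vess$attendance,
                  seed = seed, config = config)
    list(dataset = kw_dataset(s), truth = truth)
  })
}

simulate_events <- function(config, units, p_unit, year_eff, month_eff,
                            centres, platform) {
  n_events <- if (platform == "vessel") config$n_vessel_sightings else
    config$n_shore_sightings
  n_units <- length(units)
  if (n_events == 0) {
    empty <- data.frame(sighting_id = character(), platform = character(),
                        start_time = as.POSIXct(character(), tz = "UTC"),
                        end_time = as.POSIXct(character(), tz = "UTC"),
                        vessel_id = character(), lon = numeric(),
                        lat = numeric(), n_photos = integer())
    empty$individual_ids <- list()
    return(list(sightings = empty,
                attendance = matrix(0L, n_units, 0,
                                    dimnames = list(names(units), NULL))))
  }
  yrs <- config$years[sample.int(length(config$years), n_events,
                                 replace = TRUE)]
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yrs), tz = "UTC") +
    runif(n_events, 0, 364 * 86400) # uniform over the year
  t0 <- t0[order(t0)]
  yrs <- utc_year(t0)
  mon <- as.integer(format(t0, "%m", tz = "UTC"))
  eta <- outer(qlogis(p_unit), rep(0, n_events), "+") +
    matrix(year_eff[as.character(yrs)], n_units, n_events, byrow = TRUE) +
    matrix(month_eff[mon], n_units, n_events, byrow = TRUE)
  if (!is.null(config$unit_affinity) && platform == "vessel") {
    # two-pass attendance: seed units attend independently, then affinity
    # boosts the attendance odds of their partners
    seed_att <- matrix(rbinom(length(eta), 1, plogis(eta)), n_units)
    boost <- config$unit_affinity %*% seed_att
    att <- matrix(rbinom(length(eta), 1, plogis(eta + boost)), n_units)
  } else {
    att <- matrix(rbinom(length(eta), 1, plogis(eta)), n_units)
  }
  rownames(att) <- names(units)

  n_photos <- pmin(pmax(round(rlnorm(n_events, config$effort_meanlog,
                                     config$effort_sdlog)), 1), 3299)
  p_detect <- 1 - exp(-config$lambda_detect * n_photos)

  lonlat <- matrix(NA_real_, n_events, 2)
  idlist <- vector("list", n_events)
  km_per_deg_lat <- 111.195
  for (k in seq_len(n_events)) {
    present <- which(att[, k] == 1)
    if (!length(present)) { idlist[[k]] <- character(); next }
    anchor <- if (length(present) == 1) present else sample(present, 1)
    lat0 <- centres[anchor, "lat"]
    sd_deg_lat <- config$dispersion_km / km_per_deg_lat
    sd_deg_lon <- sd_deg_lat / cos(lat0 * pi / 180)
    lonlat[k, ] <- c(
      min(max(centres[anchor, "lon"] + rnorm(1, 0, sd_deg_lon),
              config$bbox[1]), config$bbox[2]),
      min(max(lat0 + rnorm(1, 0, sd_deg_lat),
              config$bbox[3]), config$bbox[4]))
    members <- unlist(units[present], use.names = FALSE)
    idlist[[k]] <- members[runif(length(members)) < p_detect[k]]
  }
  if (platform == "shore") {
    # a handful of bays on the island coastline
    bays <- cbind(lon = c(51.6, 51.7, 51.8, 51.9), lat = rep(-46.4, 4))
    bi <- sample(nrow(bays), n_events, replace = TRUE)
    lonlat <- bays[bi, , drop = FALSE] +
      matrix(rnorm(2 * n_events, 0, 0.01), n_events, 2)
  }
  dur <- pmax(round(rnorm(n_events, 39, 15)), 5) * 60
  sightings <- data.frame(
    sighting_id = sprintf("%s%05d", toupper(substr(platform, 1, 1)),
                          seq_len(n_events)),
    platform = platform,
    start_time = t0, end_time = t0 + dur,
    vessel_id = if (platform == "vessel") {
      sprintf("VES%02d", sample(config$n_vessels, n_events, replace = TRUE))
    } else NA_character_,
    lon = lonlat[, 1], lat = lonlat[, 2],
    n_photos = n_photos)
  sightings$individual_ids <- idlist
  list(sightings = sightings, attendance = att)
}

#' Explode a sighting table into a photo log
#'
#' Inverse of sighting construction for testing the ingest path: each
#' sighting is expanded into its `n_photos` photographs at random times
#' within the sighting interval, each photograph showing a random subset
#' of the sighting's individuals (every individual is guaranteed at least
#' one photograph).
#'
#' @param sightings sighting data.frame.
#' @param seed integer seed.
#' @return photo-log data.frame in the [read_photos()] dialect.
#' @export
explode_photos <- function(sightings, seed = 1) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(sightings)), function(k) {
      s <- sightings[k, ]
      np <- s$n_photos
      tt <- sort(s$start_time + runif(np, 0,
        max(as.numeric(s$end_time) - as.numeric(s$start_time), 1)))
      inds <- s$individual_ids[[1]]
      per_photo <- replicate(np, inds[runif(length(inds)) < 0.4],
                             simplify = FALSE)
      if (length(inds)) {
        # guarantee coverage
        for (i in seq_along(inds)) {
          slot <- sample.int(np, 1)
          per_photo[[slot]] <- union(per_photo[[slot]], inds[i])
        }
      }
      data.frame(photo_id = sprintf("%s-P%04d", s$sighting_id, seq_len(np)),
                 timestamp = tt,
                 platform = s$platform,
                 vessel_id = s$vessel_id,
                 site_or_set_id = if (s$platform == "vessel") {
                   sub("^V[^-]*-", "", s$sighting_id)
                 } else "BAY1",
                 lon = s$lon, lat = s$lat,
                 individual_ids = I(per_photo))
    })
    do.call(rbind, out)
  })
}

#' Small targeted generators for null and planted association structure
#'
#' `simulate_null_groups()` draws sighting groups with independent random
#' membership (the null of no preferred association): each day holds
#' `groups_per_day` groups whose members are sampled without replacement
#' from the population. `simulate_clique_groups()` plants disjoint
#' always-together cliques, each sighted as a complete group on a random
#' subset of days. Both return a minimal sighting data.frame usable by
#' [compute_sri()] and [permutation_test()].
#'
#' @param n_individuals population size.
#' @param n_days number of observation days.
#' @param groups_per_day groups per day.
#' @param group_size members per group.
#' @param seed integer seed.
#' @return sighting data.frame.
#' @export
simulate_null_groups <- function(n_individuals = 20, n_days = 40,
                                 groups_per_day = 2, group_size = 5,
                                 seed = 1) {
  ids <- sprintf("I%02d", seq_len(n_individuals))
  with_seed(seed, {
    rows <- list()
    for (d in seq_len(n_days)) {
      t0 <- as.POSIXct("2010-01-01", tz = "UTC") + (d - 1) * 86400
      for (g in seq_len(groups_per_day)) {
        rows[[length(rows) + 1]] <- data.frame(
          sighting_id = sprintf("D%03dG%d", d, g), platform = "vessel",
          start_time = t0 + (g - 1) * 3600,
          end_time = t0 + (g - 1) * 3600 + 1800,
          vessel_id = sprintf("V%d", g), lon = 50, lat = -46,
          n_photos = 100L,
          individual_ids = I(list(sample(ids, group_size))))
      }
    }
    do.call(rbind, rows)
  })
}

#' @rdname simulate_null_groups
#' @param n_cliques number of planted cliques.
#' @param days_per_clique days on which each clique is sighted.
#' @export
simulate_clique_groups <- function(n_cliques = 2, group_size = 5,
                                   n_days = 40, days_per_clique = 25,
                                   seed = 1) {
  ids <- sprintf("I%02d", seq_len(n_cliques * group_size))
  cliques <- split(ids, rep(seq_len(n_cliques), each = group_size))
  with_seed(seed, {
    rows <- list()
    for (cl in seq_len(n_cliques)) {
      days <- sort(sample(n_days, days_per_clique))
      for (d in days) {
        t0 <- as.POSIXct("2010-01-01", tz = "UTC") + (d - 1) * 86400
        rows[[length(rows) + 1]] <- data.frame(
          sighting_id = sprintf("C%dD%03d", cl, d), platform = "vessel",
          start_time = t0 + cl * 3600, end_time = t0 + cl * 3600 + 1800,
          vessel_id = sprintf("V%d", cl), lon = 50, lat = -46,
          n_photos = 100L,
          individual_ids = I(list(cliques[[cl]])))
      }
    }
    do.call(rbind, rows)
  })
}

#' Planted beta-binomial dyads and planted block SRI matrices
#'
#' `simulate_dyads()` draws true dyadic association indices from
#' Beta(a, b) and observed together-counts from Binomial(d, true),
#' returning an `sri_matrix`-shaped object for
#' [social_differentiation()]. `simulate_block_sri()` builds an SRI
#' matrix with planted community blocks: within-unit dyads centred on
#' `within_mean`, between-unit dyads on `between_mean` (clipped to
#' [0, 1]), for community-recovery tests.
#'
#' @param n_dyads number of dyads (placed on a minimal individual set).
#' @param shape1,shape2 Beta parameters of the true indices.
#' @param d sampling-period denominator per dyad (scalar or vector).
#' @param seed integer seed.
#' @return an object of class `sri_matrix`.
#' @export
simulate_dyads <- function(n_dyads = 500, shape1 = 2, shape2 = 2, d = 100,
                           seed = 1) {
  n <- ceiling((1 + sqrt(1 + 8 * n_dyads)) / 2)
  ids <- sprintf("I%03d", seq_len(n))
  with_seed(seed, {
    xm <- dm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    ut <- which(upper.tri(xm), arr.ind = TRUE)
    ut <- ut[seq_len(n_dyads), , drop = FALSE]
    dd <- rep_len(d, n_dyads)
    true_p <- rbeta(n_dyads, shape1, shape2)
    xx <- rbinom(n_dyads, dd, true_p)
    for (k in seq_len(n_dyads)) {
      i <- ut[k, 1]; j <- ut[k, 2]
      xm[i, j] <- xm[j, i] <- xx[k]
      dm[i, j] <- dm[j, i] <- dd[k]
    }
    dm[is.na(dm) & upper.tri(dm)] <- 0
    dm[lower.tri(dm)] <- t(dm)[lower.tri(dm)]
    xm[is.na(xm) & dm == 0] <- 0
    diag(xm) <- diag(dm) <- NA_real_
    sri <- ifelse(dm > 0, xm / dm, 0)
    diag(sri) <- NA_real_
    structure(list(ids = ids, x = xm, d = dm, sri = sri,
                   sampling_period = "sighting", true_index = true_p),
              class = "sri_matrix")
  })
}

#' @rdname simulate_dyads
#' @param unit_sizes integer vector of planted block sizes.
#' @param within_mean,between_mean mean SRI within and between blocks.
#' @param noise_sd Gaussian noise added to each dyad before clipping.
#' @export
simulate_block_sri <- function(unit_sizes = c(1, 2, 2, 3, 3, 4, 4, 4, 5, 5,
                                              5, 6, 6, 6, 7, 8, 8),
                               within_mean = 0.6, between_mean = 0.05,
                               noise_sd = 0.08, d = 100, seed = 1) {
  n <- sum(unit_sizes)
  ids <- sprintf("I%03d", seq_len(n))
  block <- rep(seq_along(unit_sizes), unit_sizes)
  with_seed(seed, {
    mu <- ifelse(outer(block, block, "=="), within_mean, between_mean)
    sri <- pmin(pmax(mu + rnorm(n * n, 0, noise_sd), 0), 1)
    sri <- (sri + t(sri)) / 2
    dm <- matrix(d, n, n)
    xm <- round(sri * dm)
    sri <- xm / dm
    diag(sri) <- diag(xm) <- diag(dm) <- NA_real_
    dimnames(sri) <- dimnames(xm) <- dimnames(dm) <- list(ids, ids)
    structure(list(ids = ids, x = xm, d = dm, sri = sri,
                   sampling_period = "sighting",
                   true_membership = setNames(block, ids)),
              class = "sri_matrix")
  })
}

#' Parameter-recovery report for a full pipeline run
#'
#' Compares pipeline outputs against the generator's ground truth:
#' adjusted Rand index between detected and true unit partitions,
#' Spearman rank agreement between true per-unit occurrence
#' probabilities and the model's marginal estimates (detected units are
#' mapped to true units by maximal member overlap), the fraction of
#' estimate confidence intervals covering the truth, and the Spearman
#' agreement between planted and estimated spatial-range order (range
#' dispersion is common to all units by default, in which case that
#' component is skipped).
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param partition a [detect_units()] result.
#' @param emm optional [emmeans_units()] result.
#' @param spatial optional [range_proportions()] result.
#' @return list with `ari`, and where inputs permit `prob_spearman`,
#'   `ci_coverage`, `n_units_detected`, `n_units_true`.
#' @export
recovery_report <- function(truth, partition, emm = NULL, spatial = NULL) {
  out <- list(
    n_units_true = length(truth$units),
    n_units_detected = length(partition$units),
    ari = mclust::adjustedRandIndex(
      truth$membership[names(partition$membership)], partition$membership))
  if (!is.null(emm)) {
    map <- map_units(partition$units, truth$units)
    est <- emm$probabilities
    matched <- !is.na(map[est$unit])
    true_p <- truth$p_unit[map[est$unit[matched]]]
    out$prob_spearman <- suppressWarnings(
      cor(true_p, est$prob[matched], method = "spearman"))
    out$ci_coverage <- mean(true_p >= est$lower[matched] &
                              true_p <= est$upper[matched])
  }
  if (!is.null(spatial)) {
    s <- if (inherits(spatial, "spatial_range_summary")) spatial$summary else spatial
    map <- map_units(partition$units, truth$units)
    matched <- !is.na(map[s$unit])
    true_p <- truth$p_unit[map[s$unit[matched]]]
    out$sightings_spearman <- suppressWarnings(
      cor(true_p, s$n_sightings[matched], method = "spearman"))
  }
  out
}

# map detected unit label -> true unit label by maximal member overlap
map_units <- function(detected, true_units) {
  vapply(names(detected), function(u) {
    ov <- vapply(true_units, function(m) length(intersect(m, detected[[u]])), 1L)
    if (max(ov) == 0) NA_character_ else names(true_units)[which.max(ov)]
  }, "")
}
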