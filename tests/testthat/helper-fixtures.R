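# Small hand-built fixtures shared across test files.

utc <- function(s) as.POSIXct(s, tz = "UTC")

# one photo row
photo <- function(id, time, platform = "shore", bay = "B1", vessel = NA,
                  lon = 51.8, lat = -46.4, inds = character()) {
  data.frame(photo_id = id, timestamp = utc(time), platform = platform,
             vessel_id = vessel, site_or_set_id = bay, lon = lon, lat = lat,
             individual_ids = I(list(inds)))
}

# one sighting row
sighting <- function(id, time, inds, platform = "vessel", vessel = "V1",
                     n_photos = 100, lon = 50, lat = -46,
                     end = NULL) {
  t0 <- utc(time)
  data.frame(sighting_id = id, platform = platform, start_time = t0,
             end_time = if (is.null(end)) t0 + 1800 else utc(end),
             vessel_id = if (platform == "vessel") vessel else NA_character_,
             lon = lon, lat = lat, n_photos = n_photos,
             individual_ids = I(list(inds)))
}

sightings_df <- function(...) do.call(rbind, list(...))

# brute-force SRI oracle: direct enumeration over sampling periods
oracle_sri <- function(s, period) {
  ids <- sort(unique(unlist(s$individual_ids)))
  if (period == "sighting") {
    periods <- lapply(seq_len(nrow(s)), function(k) {
      list(groups = s$individual_ids[k])
    })
  } else {
    day <- as.Date(format(s$start_time, "%Y-%m-%d", tz = "UTC"))
    periods <- lapply(unique(day), function(d) {
      list(groups = s$individual_ids[day == d])
    })
  }
  n <- length(ids)
  x <- d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in periods) {
    gs <- lapply(p$groups, as.character)
    present <- unique(unlist(gs))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      ia <- ids[a]; ib <- ids[b]
      in_a <- ia %in% present; in_b <- ib %in% present
      if (in_a || in_b) d[a, b] <- d[b, a] <- d[a, b] + 1
      together <- any(vapply(gs, function(g) ia %in% g && ib %in% g, TRUE))
      if (together) x[a, b] <- x[b, a] <- x[a, b] + 1
    }
  }
  sri <- ifelse(d > 0, x / d, 0)
  diag(x) <- diag(d) <- diag(sri) <- NA
  list(x = x, d = d, sri = sri)
}

# gift-wrapping convex hull + triangle-fan area, independent of chull
oracle_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  start <- which.min(xy[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (xy[best, 1] - xy[p, 1]) * (xy[q, 2] - xy[p, 2]) -
        (xy[best, 2] - xy[p, 2]) * (xy[q, 1] - xy[p, 1])
      if (cr < 0 || (cr == 0 &&
                     sum((xy[q, ] - xy[p, ])^2) > sum((xy[best, ] - xy[p, ])^2)))
        best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("hull loop")
  }
  if (length(hull) < 3) return(0)
  h <- xy[hull, , drop = FALSE]
  a <- 0
  for (k in 2:(nrow(h) - 1)) {
    a <- a + ((h[k, 1] - h[1, 1]) * (h[k + 1, 2] - h[1, 2]) -
                (h[k + 1, 1] - h[1, 1]) * (h[k, 2] - h[1, 2])) / 2
  }
  abs(a)
}

# occurrence-table generator with planted per-unit probabilities
sim_records <- function(n_s, p_u, b_eff = NULL, seed = 1) {
  set.seed(seed)
  units <- sprintf("U%02d", seq_along(p_u))
  eff_lv <- c("very_low", "low", "medium", "high", "very_high")
  eff <- factor(sample(eff_lv, n_s, TRUE), levels = eff_lv)
  if (is.null(b_eff)) b_eff <- rep(0, 5)
  rec <- data.frame(sighting_id = rep(sprintf("s%04d", 1:n_s),
                                      each = length(p_u)),
                    unit = factor(rep(units, n_s)),
                    effort = rep(eff, each = length(p_u)),
                    timestamp = rep(utc("2010-01-01 00:00:00") +
                                      3600 * (1:n_s), each = length(p_u)))
  eta <- qlogis(p_u[as.integer(rec$unit)]) + b_eff[as.integer(rec$effort)]
  rec$present <- rbinom(nrow(rec), 1, plogis(eta))
  rec
}
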