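#' Assemble a photo-identification dataset
#'
#' A `kw_dataset` bundles a sighting table with the per-individual sighting
#' history derived from it. Sightings are the analysis unit throughout the
#' package: a spatio-temporally bounded set of photographs with the
#' individuals identified in them, taken either from shore (one bay, photos
#' chained while consecutive gaps stay under one hour) or from a fishing
#' vessel (one longline-set haul).
#'
#' @param sightings data.frame with columns `sighting_id`, `platform`
#'   (`"shore"` or `"vessel"`), `start_time`, `end_time` (POSIXct, UTC),
#'   `vessel_id` (NA for shore), `lon`, `lat`, `n_photos`, and
#'   `individual_ids` (a list column of character vectors).
#' @param individuals optional data.frame of per-individual photographic
#'   tenure (`individual_id`, `years` list column, `first_year`,
#'   `last_year`, `n_years`). When omitted it is derived from `sightings`.
#'   Tenure is a property of the photographic record: dataset restriction
#'   drops rows but never recomputes it.
#'
#' @return An object of class `kw_dataset`: a list with elements
#'   `sightings` and `individuals`.
#' @export
kw_dataset <- function(sightings, individuals = NULL) {
  req <- c("sighting_id", "platform", "start_time", "end_time", "vessel_id",
           "lon", "lat", "n_photos", "individual_ids")
  missing_cols <- setdiff(req, names(sightings))
  if (length(missing_cols)) {
    stopf("sightings table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(sightings$platform %in% c("shore", "vessel"))) {
    stopf("platform must be 'shore' or 'vessel'")
  }
  if (any(sightings$n_photos < 1)) stopf("every sighting needs n_photos >= 1")
  if (any(sightings$end_time < sightings$start_time)) {
    stopf("end_time before start_time in sighting(s): %s",
          paste(sightings$sighting_id[sightings$end_time < sightings$start_time],
                collapse = ", "))
  }
  ok_ll <- sightings$lat >= -90 & sightings$lat <= 90 &
    sightings$lon >= -180 & sightings$lon <= 180
  if (!all(ok_ll)) stopf("coordinates out of range in sighting(s): %s",
                         paste(sightings$sighting_id[!ok_ll], collapse = ", "))
  if (anyDuplicated(sightings$sighting_id)) stopf("duplicated sighting_id")
  sightings$individual_ids <- lapply(sightings$individual_ids,
                                     function(x) sort(unique(as.character(x))))
  if (is.null(individuals)) individuals <- derive_individuals(sightings)
  ref <- unique(unlist(sightings$individual_ids))
  unknown <- setdiff(ref, individuals$individual_id)
  if (length(unknown)) {
    stopf("sightings reference unknown individual(s): %s",
          paste(unknown, collapse = ", "))
  }
  structure(list(sightings = sightings, individuals = individuals),
            class = "kw_dataset")
}

derive_individuals <- function(sightings) {
  yr <- utc_year(sightings$start_time)
  ids <- sightings$individual_ids
  long_id <- unlist(ids)
  long_yr <- rep(yr, lengths(ids))
  if (!length(long_id)) {
    return(data.frame(individual_id = character(), first_year = integer(),
                      last_year = integer(), n_years = integer()))
  }
  tab <- split(long_yr, long_id)
  out <- data.frame(individual_id = names(tab),
                    first_year = vapply(tab, min, 1L),
                    last_year = vapply(tab, max, 1L),
                    n_years = vapply(tab, function(y) length(unique(y)), 1L),
                    row.names = NULL)
  out$years <- lapply(tab, function(y) sort(unique(y)))
  out[order(out$individual_id), , drop = FALSE]
}

#' @export
print.kw_dataset <- function(x, ...) {
  s <- x$sightings
  cat(sprintf("kw_dataset: %d sightings (%d shore, %d vessel), %d individuals\n",
              nrow(s), sum(s$platform == "shore"), sum(s$platform == "vessel"),
              nrow(x$individuals)))
  invisible(x)
}

#' @export
summary.kw_dataset <- function(object, ...) {
  s <- object$sightings
  n_ind <- lengths(s$individual_ids)
  list(n_sightings = nrow(s),
       n_shore = sum(s$platform == "shore"),
       n_vessel = sum(s$platform == "vessel"),
       n_individuals = nrow(object$individuals),
       n_days = length(unique(utc_date(s$start_time))),
       mean_individuals_per_sighting = mean(n_ind),
       sd_individuals_per_sighting = sd(n_ind),
       median_n_photos = median(s$n_photos),
       total_photos = sum(s$n_photos))
}

validate_photos <- function(photos, platform = NULL) {
  req <- c("photo_id", "timestamp", "platform", "site_or_set_id",
           "lon", "lat", "individual_ids")
  miss <- setdiff(req, names(photos))
  if (length(miss)) stopf("photo table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!inherits(photos$timestamp, "POSIXct")) {
    parsed <- parse_time(photos$timestamp)
    bad <- is.na(parsed) & !is.na(photos$timestamp)
    if (any(bad)) stopf("unparseable timestamp in photo row(s): %s",
                        paste(photos$photo_id[bad], collapse = ", "))
    photos$timestamp <- parsed
  }
  if (any(is.na(photos$timestamp))) {
    stopf("missing timestamp in photo row(s): %s",
          paste(photos$photo_id[is.na(photos$timestamp)], collapse = ", "))
  }
  if (!is.null(platform) && !all(photos$platform == platform)) {
    stopf("expected all photos to have platform '%s'; found: %s", platform,
          paste(unique(setdiff(photos$platform, platform)), collapse = ", "))
  }
  if (!is.list(photos$individual_ids)) {
    photos$individual_ids <- parse_id_list(photos$individual_ids)
  }
  photos
}

# NA-returning ISO-8601 parser (UTC); as.POSIXct itself errors on
# unrecognised strings, which would lose the offending row ids
parse_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

parse_id_list <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character() else {
      trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    }
  })
}

#' Chain shore photographs into sightings
#'
#' Within one bay, consecutive photographs (time-sorted) are chained into a
#' single sighting while each gap between consecutive photos stays strictly
#' below `gap_hours`; a gap at or above the threshold starts a new sighting.
#'
#' @param photos photo table (see [read_photos()]), all with
#'   `platform == "shore"`.
#' @param gap_hours maximum allowed gap between consecutive photographs of
#'   one sighting, in hours.
#' @return A sighting data.frame (one row per chain) suitable for
#'   [kw_dataset()]. The representative location is the mean of the photo
#'   coordinates.
#' @export
build_shore_sightings <- function(photos, gap_hours = 1) {
  photos <- validate_photos(photos, platform = "shore")
  photos <- photos[order(photos$site_or_set_id, photos$timestamp,
                         photos$photo_id), , drop = FALSE]
  out <- lapply(split(photos, photos$site_or_set_id), function(p) {
    gap <- c(Inf, diff(as.numeric(p$timestamp)) / 3600)
    chain <- cumsum(gap >= gap_hours)
    do.call(rbind, lapply(split(p, chain), aggregate_photo_chain))
  })
  out <- do.call(rbind, out)
  out$sighting_id <- sprintf("S%s-%03d", out$site_or_set_id, stats::ave(
    seq_len(nrow(out)), out$site_or_set_id, FUN = seq_along))
  out$platform <- "shore"
  out$vessel_id <- NA_character_
  rownames(out) <- NULL
  out[, c("sighting_id", "platform", "start_time", "end_time", "vessel_id",
          "site_or_set_id", "lon", "lat", "n_photos", "individual_ids")]
}

aggregate_photo_chain <- function(p) {
  data.frame(site_or_set_id = p$site_or_set_id[1],
             start_time = min(p$timestamp),
             end_time = max(p$timestamp),
             lon = mean(p$lon), lat = mean(p$lat),
             n_photos = nrow(p),
             individual_ids = I(list(sort(unique(unlist(p$individual_ids))))))
}

#' Aggregate vessel photographs into haul sightings
#'
#' One sighting per (vessel, longline-set) pair: all photographs taken during
#' the hauling of one longline set by one vessel form one sighting.
#'
#' @inheritParams build_shore_sightings
#' @return A sighting data.frame suitable for [kw_dataset()].
#' @export
build_vessel_sightings <- function(photos) {
  photos <- validate_photos(photos, platform = "vessel")
  if (!"vessel_id" %in% names(photos) || any(is.na(photos$vessel_id))) {
    stopf("vessel photos require a vessel_id")
  }
  if (any(is.na(photos$site_or_set_id))) {
    stopf("vessel photos require a longline-set id (site_or_set_id)")
  }
  key <- paste(photos$vessel_id, photos$site_or_set_id, sep = "\r")
  out <- do.call(rbind, lapply(split(photos, key), function(p) {
    cbind(aggregate_photo_chain(p), vessel_id = p$vessel_id[1])
  }))
  out$sighting_id <- sprintf("V%s-%s", out$vessel_id, out$site_or_set_id)
  out$platform <- "vessel"
  rownames(out) <- NULL
  out[, c("sighting_id", "platform", "start_time", "end_time", "vessel_id",
          "site_or_set_id", "lon", "lat", "n_photos", "individual_ids")]
}

#' Photographic-effort category of a sighting
#'
#' Five-level banding of the number of photographs taken during a sighting:
#' very_low (<25), low (25-49), medium (50-124), high (125-249),
#' very_high (>= 250).
#'
#' @param n_photos integer vector of photograph counts, each >= 1.
#' @return Factor with levels `very_low < low < medium < high < very_high`.
#' @export
effort_category <- function(n_photos) {
  if (any(is.na(n_photos)) || any(n_photos < 1)) {
    stopf("n_photos must be >= 1")
  }
  cut(n_photos, breaks = c(0, 24, 49, 124, 249, Inf),
      labels = c("very_low", "low", "medium", "high", "very_high"),
      ordered_result = TRUE)
}

#' Restrict a dataset to well-sampled individuals and sightings
#'
#' Applies the two bias-reduction filters used before network construction:
#' individuals must have been photographed in at least `min_years` distinct
#' calendar years and last photographed strictly after `min_last_year`
#' (i.e. presumed alive at the end of the study); sightings must carry at
#' least `min_photos_per_sighting` photographs so that all individuals
#' present can be assumed photographed. Individuals failing the tenure
#' filter are removed from all sightings; sightings left without any
#' retained individual are dropped; tenure metadata is kept as recorded, so
#' the operation is idempotent.
#'
#' @param ds a [kw_dataset()].
#' @param min_years minimum number of distinct years photographed.
#' @param min_last_year individuals must be last photographed strictly
#'   after this year.
#' @param min_photos_per_sighting minimum photographic effort per sighting.
#' @return The filtered `kw_dataset`.
#' @export
restrict_dataset <- function(ds, min_years = 6, min_last_year = 2019,
                             min_photos_per_sighting = 42) {
  stopifnot(inherits(ds, "kw_dataset"))
  if (min_photos_per_sighting < 1) stopf("min_photos_per_sighting must be >= 1")
  ind <- ds$individuals
  keep_ind <- ind$n_years >= min_years & ind$last_year > min_last_year
  kept_ids <- ind$individual_id[keep_ind]
  s <- ds$sightings[ds$sightings$n_photos >= min_photos_per_sighting, ,
                    drop = FALSE]
  s$individual_ids <- lapply(s$individual_ids, intersect, y = kept_ids)
  s <- s[lengths(s$individual_ids) > 0, , drop = FALSE]
  seen <- unique(unlist(s$individual_ids))
  ind <- ind[keep_ind & ind$individual_id %in% seen, , drop = FALSE]
  if (nrow(s) == 0 || nrow(ind) == 0) {
    stopf("empty after filtering (min_years = %d, last year > %d, >= %d photos)",
          min_years, min_last_year, min_photos_per_sighting)
  }
  rownames(s) <- rownames(ind) <- NULL
  kw_dataset(s, individuals = ind)
}

#' Suggest a per-sighting photographic-effort threshold
#'
#' Advisory threshold for [restrict_dataset()]: `ceiling(multiplier x mean
#' individuals identified per sighting)`. The median photograph count per
#' sighting (the minimum effort reached by half the sightings) is attached
#' as a cross-check; the operative threshold is always taken from
#' configuration, not from this suggestion.
#'
#' @param ds a [kw_dataset()].
#' @param multiplier multiplier on the mean number of individuals per
#'   sighting.
#' @return Integer threshold with attributes `mean_individuals`,
#'   `sd_individuals` and `median_n_photos`.
#' @export
suggest_photo_threshold <- function(ds, multiplier = 3) {
  stopifnot(inherits(ds, "kw_dataset"))
  n_ind <- lengths(ds$sightings$individual_ids)
  m <- mean(n_ind)
  structure(as.integer(ceiling(multiplier * m)),
            mean_individuals = m,
            sd_individuals = sd(n_ind),
            median_n_photos = median(ds$sightings$n_photos))
}

#' Read a photo log or sighting table from delimited text
#'
#' `read_photos()` expects one row per photograph with columns `photo_id`,
#' `timestamp` (ISO-8601, UTC), `platform`, `vessel_id`, `site_or_set_id`,
#' `lon`, `lat`, `individual_ids` (semicolon-separated). `read_sightings()`
#' expects the pre-aggregated one-row-per-sighting dialect written by
#' [write_sightings()].
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with `individual_ids` parsed into a list column.
#' @export
read_photos <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  validate_photos(df)
}

#' @rdname read_photos
#' @export
read_sightings <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  df$start_time <- parse_time(df$start_time)
  df$end_time <- parse_time(df$end_time)
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  df$n_photos <- as.integer(df$n_photos)
  df$vessel_id[df$vessel_id %in% c("", "NA")] <- NA_character_
  df$individual_ids <- parse_id_list(df$individual_ids)
  df
}

#' Write a sighting table as delimited text
#'
#' @param sightings sighting data.frame (e.g. `ds$sightings`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(sightings, path) {
  out <- sightings
  out$individual_ids <- vapply(out$individual_ids, paste, "", collapse = ";")
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$end_time <- format(out$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
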