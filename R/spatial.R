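EARTH_RADIUS_KM <- 6371.0088

#' Equal-area projection of longitude/latitude points
#'
#' Spherical Lambert azimuthal equal-area projection centred on
#' `center` (default: the centroid of the input points), returning
#' planar coordinates in kilometres. The projection preserves areas
#' exactly on the sphere, so polygon areas computed on the projected
#' plane are spherical-surface areas in square kilometres.
#'
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @param center optional `c(lon0, lat0)` projection centre.
#' @return Object of class `projected_points`: data.frame-like list with
#'   `x`, `y` (km), `lon`, `lat` and the `center` used.
#' @export
project_points <- function(lon, lat, center = NULL) {
  stopifnot(length(lon) == length(lat))
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) stopf("coordinates out of range")
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  rad <- pi / 180
  l0 <- center[1] * rad; f0 <- center[2] * rad
  l <- lon * rad; f <- lat * rad
  denom <- 1 + sin(f0) * sin(f) + cos(f0) * cos(f) * cos(l - l0)
  k <- sqrt(2 / denom)
  structure(list(x = EARTH_RADIUS_KM * k * cos(f) * sin(l - l0),
                 y = EARTH_RADIUS_KM * k *
                   (cos(f0) * sin(f) - sin(f0) * cos(f) * cos(l - l0)),
                 lon = lon, lat = lat, center = center),
            class = "projected_points")
}

#' Inverse of [project_points()]
#'
#' @param x,y projected coordinates in km.
#' @param center the `c(lon0, lat0)` centre used for projection.
#' @return list with `lon`, `lat` in degrees.
#' @export
unproject_points <- function(x, y, center) {
  rad <- pi / 180
  l0 <- center[1] * rad; f0 <- center[2] * rad
  rho <- sqrt(x^2 + y^2)
  out_lon <- rep(center[1], length(x))
  out_lat <- rep(center[2], length(x))
  nz <- rho > 0
  cc <- 2 * asin(pmin(1, rho[nz] / (2 * EARTH_RADIUS_KM)))
  f <- asin(cos(cc) * sin(f0) + y[nz] * sin(cc) * cos(f0) / rho[nz])
  l <- l0 + atan2(x[nz] * sin(cc),
                  rho[nz] * cos(f0) * cos(cc) - y[nz] * sin(f0) * sin(cc))
  out_lat[nz] <- f / rad
  out_lon[nz] <- l / rad
  list(lon = out_lon, lat = out_lat)
}

#' Minimum convex polygon area
#'
#' Area (km^2) of the convex hull of projected points; 0 when fewer than
#' three distinct non-collinear points exist. Invariant to point ordering
#' and duplication.
#'
#' @param points a [project_points()] object, or a two-column matrix /
#'   data.frame of planar coordinates in km.
#' @return Area in km^2, with the hull vertex coordinates as attribute
#'   `hull`.
#' @export
mcp_area <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 1) stopf("need at least one point")
  xy <- unique(xy)
  if (nrow(xy) < 3) return(structure(0, hull = xy))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  # shoelace formula
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  structure(area, hull = cbind(x = hx, y = hy))
}

as_xy <- function(points) {
  if (inherits(points, "projected_points")) {
    cbind(points$x, points$y)
  } else {
    as.matrix(points)[, 1:2, drop = FALSE]
  }
}

#' Graticule cells occupied by a set of sightings
#'
#' Bins longitude/latitude points on a fixed `cell_size_deg` graticule
#' (cell id = floor(lon / cell), floor(lat / cell), robust to floating
#' point representation of the division) and returns the distinct cells.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param cell_size_deg cell edge in degrees (default 0.1, roughly
#'   10 km x 10 km at these latitudes).
#' @return character vector of unique cell ids `"ix:iy"`, with attribute
#'   `n_cells`.
#' @export
grid_cells <- function(lon, lat, cell_size_deg = 0.1) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) stopf("coordinates out of range")
  ix <- floor(round(lon / cell_size_deg, 6))
  iy <- floor(round(lat / cell_size_deg, 6))
  cells <- unique(paste(ix, iy, sep = ":"))
  structure(cells, n_cells = length(cells))
}

#' Kernel utilisation distribution isopleth areas
#'
#' Bivariate Gaussian kernel density estimate on projected coordinates,
#' evaluated on a regular raster; the area of each isopleth is accumulated
#' over raster cells in decreasing density order until the stated
#' probability mass is enclosed. The default bandwidth is the ad-hoc
#' bivariate reference rule `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`
#' applied to both axes.
#'
#' @param points a [project_points()] object or planar km coordinates.
#' @param isopleths probability levels in percent (default 50 and 95).
#' @param bandwidth `"href"` or a numeric kernel standard deviation (km).
#' @param grid_n raster resolution per axis.
#' @return Named numeric vector of areas in km^2 (`ud50`, `ud95`, ...),
#'   with attributes `bandwidth` and `unreliable` (TRUE when fewer than 5
#'   points were supplied).
#' @export
kernel_ud <- function(points, isopleths = c(50, 95), bandwidth = "href",
                      grid_n = 200) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 2 || all(xy[, 1] == xy[1, 1]) && all(xy[, 2] == xy[1, 2])) {
    stopf("kernel UD needs at least two distinct points")
  }
  h <- if (identical(bandwidth, "href")) {
    sqrt((var(xy[, 1]) + var(xy[, 2])) / 2) * n^(-1 / 6)
  } else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) stopf("invalid bandwidth")
  pad <- 3.5 * h
  lims <- c(range(xy[, 1]) + c(-pad, pad), range(xy[, 2]) + c(-pad, pad))
  # MASS::kde2d uses dnorm with sd = h/4, so pass 4h for a kernel sd of h
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * h, n = grid_n, lims = lims)
  cell_area <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  p <- kd$z / sum(kd$z)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  areas <- vapply(isopleths, function(lev) {
    ncells <- which(cum >= lev / 100)[1]
    ncells * cell_area
  }, 0)
  structure(setNames(areas, paste0("ud", isopleths)),
            bandwidth = h, unreliable = n < 5)
}

#' Per-unit spatial depredation range summary
#'
#' For each social unit, the spatial extent of the depredation events at
#' which it was recorded (vessel sightings containing at least one
#' member), relative to the pooled "fishing area" (the same metrics over
#' the sightings of all units): MCP area and percentage, occupied
#' 0.1-degree graticule cells and percentage, and kernel UD50/UD95 areas.
#' Also returns per-calendar-year percentages (yearly denominators by
#' default, so each year is compared against that year's fishing area)
#' and cumulative expansion curves indexed by years since each unit's
#' first depredation sighting (whole-period denominator, so curves are
#' non-decreasing and end at the unit's overall percentage).
#'
#' @param ds a [kw_dataset()].
#' @param partition a [detect_units()] partition.
#' @param cell_size_deg graticule cell edge in degrees.
#' @param isopleths kernel UD probability levels (percent).
#' @param annual_denominator `"per_year"` (default) or `"whole_period"`
#'   for the annual percentage series.
#' @param min_ud_points minimum sightings required to report kernel UDs.
#' @return Object of class `spatial_range_summary`: list with `summary`
#'   (one row per unit), `annual` (unit, year, pct_mcp, pct_cells),
#'   `cumulative` (unit, years_since_first, pct_mcp, pct_cells), the
#'   pooled `fishing_area` metrics and the projection `center`.
#' @export
range_proportions <- function(ds, partition, cell_size_deg = 0.1,
                              isopleths = c(50, 95),
                              annual_denominator = c("per_year",
                                                     "whole_period"),
                              min_ud_points = 5) {
  annual_denominator <- match.arg(annual_denominator)
  stopifnot(inherits(ds, "kw_dataset"), inherits(partition, "unit_partition"))
  vs <- ds$sightings[ds$sightings$platform == "vessel", , drop = FALSE]
  units <- partition$units
  present <- vapply(vs$individual_ids, function(g)
    vapply(units, function(m) any(m %in% g), TRUE),
    logical(length(units)))
  present <- matrix(present, nrow = length(units),
                    dimnames = list(names(units), NULL))
  any_unit <- colSums(present) > 0
  vs <- vs[any_unit, , drop = FALSE]
  present <- present[, any_unit, drop = FALSE]
  if (!nrow(vs)) stopf("no vessel sightings with unit members")
  yr <- utc_year(vs$start_time)

  center <- c(mean(vs$lon), mean(vs$lat))
  pr_all <- project_points(vs$lon, vs$lat, center = center)
  xy <- cbind(pr_all$x, pr_all$y)
  pooled_mcp <- as.numeric(mcp_area(xy))
  pooled_cells <- attr(grid_cells(vs$lon, vs$lat, cell_size_deg), "n_cells")

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

  rows <- list(); annual <- list(); cumulative <- list()
  for (u in rownames(present)) {
    sel <- present[u, ]
    if (!any(sel)) {
      rows[[u]] <- data.frame(
        unit = u, n_sightings = 0L, years_sighted = 0L,
        mcp_area_km2 = 0, pct_fishing_area_mcp = 0, n_cells = 0L,
        pct_fishing_area_cells = 0, ud50_km2 = NA_real_, ud95_km2 = NA_real_)
      next
    }
    ux <- xy[sel, , drop = FALSE]
    ulon <- vs$lon[sel]; ulat <- vs$lat[sel]
    m <- as.numeric(mcp_area(ux))
    ncell <- attr(grid_cells(ulon, ulat, cell_size_deg), "n_cells")
    uds <- if (sum(sel) >= min_ud_points) {
      kernel_ud(ux, isopleths = isopleths)
    } else setNames(rep(NA_real_, length(isopleths)),
                    paste0("ud", isopleths))
    rows[[u]] <- data.frame(
      unit = u,
      n_sightings = sum(sel),
      years_sighted = length(unique(yr[sel])),
      mcp_area_km2 = m,
      pct_fishing_area_mcp = pct(m, pooled_mcp),
      n_cells = ncell,
      pct_fishing_area_cells = pct(ncell, pooled_cells),
      ud50_km2 = unname(uds[1]),
      ud95_km2 = unname(uds[length(uds)]))

    # annual series
    for (y in sort(unique(yr[sel]))) {
      ysel <- sel & yr == y
      den_m <- if (annual_denominator == "per_year") {
        as.numeric(mcp_area(xy[yr == y, , drop = FALSE]))
      } else pooled_mcp
      den_c <- if (annual_denominator == "per_year") {
        attr(grid_cells(vs$lon[yr == y], vs$lat[yr == y], cell_size_deg),
             "n_cells")
      } else pooled_cells
      annual[[length(annual) + 1]] <- data.frame(
        unit = u, year = y,
        pct_mcp = pct(as.numeric(mcp_area(xy[ysel, , drop = FALSE])), den_m),
        pct_cells = pct(attr(grid_cells(vs$lon[ysel], vs$lat[ysel],
                                        cell_size_deg), "n_cells"), den_c))
    }

    # cumulative expansion since first depredation sighting
    first <- min(yr[sel])
    for (k in 0:(max(yr[sel]) - first)) {
      csel <- sel & yr <= first + k
      cumulative[[length(cumulative) + 1]] <- data.frame(
        unit = u, years_since_first = k,
        pct_mcp = pct(as.numeric(mcp_area(xy[csel, , drop = FALSE])),
                      pooled_mcp),
        pct_cells = pct(attr(grid_cells(vs$lon[csel], vs$lat[csel],
                                        cell_size_deg), "n_cells"),
                        pooled_cells))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 annual = do.call(rbind, annual),
                 cumulative = do.call(rbind, cumulative),
                 fishing_area = list(mcp_km2 = pooled_mcp,
                                     n_cells = pooled_cells),
                 center = center,
                 annual_denominator = annual_denominator),
            class = "spatial_range_summary")
}

#' @export
print.spatial_range_summary <- function(x, ...) {
  cat(sprintf("spatial_range_summary: %d units; fishing area MCP %.0f km^2, %d cells\n",
              nrow(x$summary), x$fishing_area$mcp_km2, x$fishing_area$n_cells))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Rank correlation between range extent and years sighted
#'
#' Spearman rank correlation (two-sided; exact p for n <= 9 without ties,
#' t-approximation otherwise, ties handled by average ranks) between the
#' number of years each unit was sighted during depredation events and
#' each spatial-range metric.
#'
#' @param summaries the `summary` data.frame of a [range_proportions()]
#'   result (or the full object).
#' @return data.frame with one row per metric: `metric`, `rho`, `p_value`,
#'   `n`; `rho` is NA (flagged) when a variable has zero variance.
#' @export
spearman_range_vs_years <- function(summaries) {
  if (inherits(summaries, "spatial_range_summary")) {
    summaries <- summaries$summary
  }
  if (nrow(summaries) < 4) stopf("need at least 4 units")
  metrics <- c(mcp = "mcp_area_km2", ud95 = "ud95_km2", ud50 = "ud50_km2",
               cells = "n_cells")
  out <- lapply(names(metrics), function(m) {
    v <- summaries[[metrics[m]]]
    y <- summaries$years_sighted
    keep <- !is.na(v)
    if (length(unique(v[keep])) < 2 || length(unique(y[keep])) < 2) {
      return(data.frame(metric = m, rho = NA_real_, p_value = NA_real_,
                        n = sum(keep)))
    }
    ct <- suppressWarnings(cor.test(y[keep], v[keep], method = "spearman"))
    data.frame(metric = m, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(keep))
  })
  do.call(rbind, out)
}
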