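#' Configuration for the synthetic migration-track simulator
#'
#' Describes a migration itinerary: an ordered set of stopover sites
#' (center, stay length, within-site wandering scale), connected by
#' straight flight legs, sampled by a tracker whose duty cycle emits one
#' fix per i.i.d. uniform interval.  Defaults emulate the structure of
#' satellite tracks of large migratory waterbirds: fixes every 1-4 h,
#' multi-day stays, ~60 km/h flight.
#'
#' @param sites `data.frame` with columns `lat`, `lon` (site centers,
#'   decimal degrees), `stay_days` (> 0) and `radius_km` (s.d. of the
#'   within-site Gaussian scatter).
#' @param flight_speed_kmh Cruise speed on flight legs, km/h.
#' @param fix_interval_range_h Range (min, max) of the uniform inter-fix
#'   interval, hours.
#' @param jitter_km GPS noise s.d. added to every fix, km.
#' @param seed RNG seed; the simulation is fully reproducible given it.
#' @param years Integer year offsets; the whole itinerary is flown once
#'   per entry (e.g. `c(0, 1)` revisits every site one year later).
#' @param uniform Alternative mode: `list(n =, density_per_km2 =,
#'   center = c(lat, lon), time_gap_h =)` generates spatially uniform
#'   fixes with temporally scattered timestamps and no stopovers (used
#'   for noise-floor and scaling diagnostics); `sites` is ignored.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sites = NULL, flight_speed_kmh = 60,
                       fix_interval_range_h = c(1, 4), jitter_km = 0.05,
                       seed = 0L, years = 0L, uniform = NULL) {
  if (is.null(uniform)) {
    stopifnot(is.data.frame(sites), nrow(sites) >= 1,
              all(c("lat", "lon", "stay_days", "radius_km") %in% names(sites)))
    check_coords(sites$lat, sites$lon)
    if (any(sites$stay_days <= 0)) stop("stay_days must be > 0")
    if (any(sites$radius_km < 0)) stop("radius_km must be >= 0")
  } else {
    stopifnot(is.list(uniform),
              all(c("n", "density_per_km2", "center") %in% names(uniform)))
    if (is.null(uniform$time_gap_h)) uniform$time_gap_h <- 3
  }
  if (length(fix_interval_range_h) != 2 ||
      any(fix_interval_range_h <= 0) ||
      fix_interval_range_h[1] > fix_interval_range_h[2])
    stop("fix_interval_range_h must be (min, max) with 0 < min <= max")
  if (flight_speed_kmh <= 0) stop("flight_speed_kmh must be > 0")
  if (jitter_km < 0) stop("jitter_km must be >= 0")
  structure(list(sites = sites, flight_speed_kmh = flight_speed_kmh,
                 fix_interval_range_h = fix_interval_range_h,
                 jitter_km = jitter_km, seed = as.integer(seed),
                 years = as.integer(years), uniform = uniform),
            class = "sim_config")
}

SIM_EPOCH <- as.numeric(as.POSIXct("2023-01-01 00:00:00", tz = "UTC"))
YEAR_S <- 365 * 86400

#' Simulate a migration track with ground truth
#'
#' Emits fixes along the itinerary of a [sim_config()]: during a stay,
#' positions are the site center plus isotropic 2-D Gaussian scatter
#' (s.d. `radius_km`) in a local planar frame; on flight legs, positions
#' interpolate the straight planar line between consecutive site
#' centers at `flight_speed_kmh`.  Fix times advance by i.i.d. uniform
#' intervals throughout (the tracker's duty cycle does not depend on
#' behavior).  Timestamps are rounded to whole seconds so tracks
#' round-trip losslessly through CSV.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_track`:
#'   \describe{
#'     \item{`track`}{a [track()] of the emitted fixes,}
#'     \item{`truth`}{list with `labels` (per fix: 0-based stopover
#'       visit index, `-1` = flight) and `sites` (`data.frame` of
#'       planted visits: `visit`, `year`, `site`, `lat`, `lon`,
#'       `stay_days`, `arrival`, `departure` — actual first/last stay
#'       fix times).}
#'   }
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  if (!is.null(config$uniform)) return(simulate_uniform(config))

  iv <- config$fix_interval_range_h * 3600
  sites <- config$sites
  S <- nrow(sites)
  chunks <- list()  # each: list(t, lat, lon, lab)
  visit_rows <- list()
  visit <- -1L

  # fix times from t (inclusive) up to t_end (exclusive) at the tracker's
  # duty cycle; also returns the first fix time at or beyond t_end
  draw_times <- function(t, t_end) {
    gaps <- numeric(0)
    while (t + sum(gaps) < t_end) {
      need <- ceiling((t_end - t - sum(gaps)) / iv[1]) + 1L
      gaps <- c(gaps, runif(need, iv[1], iv[2]))
    }
    times <- t + cumsum(c(0, gaps))
    n <- sum(times < t_end)
    list(t = times[seq_len(n)], t_next = times[n + 1L])
  }

  for (y in config$years) {
    t <- SIM_EPOCH + y * YEAR_S
    for (s in seq_len(S)) {
      visit <- visit + 1L
      stay_end <- t + sites$stay_days[s] * 86400
      tm <- draw_times(t, stay_end)
      n <- length(tm$t)
      if (n == 0) stop("stay produced no fixes; intervals too long")
      sd_pos <- sqrt(sites$radius_km[s]^2 + config$jitter_km^2)
      g <- local_to_geo(rnorm(n, sd = sd_pos), rnorm(n, sd = sd_pos),
                        sites$lat[s], sites$lon[s])
      chunks[[length(chunks) + 1L]] <-
        list(t = tm$t, lat = g$lat, lon = g$lon, lab = rep(visit, n))
      visit_rows[[length(visit_rows) + 1L]] <- data.frame(
        visit = visit, year = y, site = s - 1L,
        lat = sites$lat[s], lon = sites$lon[s],
        stay_days = sites$stay_days[s],
        arrival = min(tm$t), departure = max(tm$t))
      t <- tm$t_next
      if (s < S) {
        d_km <- haversine_km(sites$lat[s], sites$lon[s],
                             sites$lat[s + 1], sites$lon[s + 1])
        leg_end <- stay_end + d_km / config$flight_speed_kmh * 3600
        tm <- draw_times(t, leg_end)
        m <- length(tm$t)
        if (m > 0) {
          olat <- mean(sites$lat[s:(s + 1)])
          olon <- mean(sites$lon[s:(s + 1)])
          pA <- project_local(sites$lat[s], sites$lon[s], olat, olon)
          pB <- project_local(sites$lat[s + 1], sites$lon[s + 1], olat, olon)
          frac <- (tm$t - stay_end) / (leg_end - stay_end)
          g <- local_to_geo(
            pA$x + frac * (pB$x - pA$x) + rnorm(m, sd = config$jitter_km),
            pA$y + frac * (pB$y - pA$y) + rnorm(m, sd = config$jitter_km),
            olat, olon)
          chunks[[length(chunks) + 1L]] <-
            list(t = tm$t, lat = g$lat, lon = g$lon, lab = rep(-1L, m))
        }
        t <- tm$t_next
      }
    }
  }
  t_all <- unlist(lapply(chunks, `[[`, "t"))
  lat_all <- unlist(lapply(chunks, `[[`, "lat"))
  lon_all <- unlist(lapply(chunks, `[[`, "lon"))
  lab_all <- as.integer(unlist(lapply(chunks, `[[`, "lab")))
  t_all <- round(t_all)
  tr <- track(time = t_all, lat = lat_all, lon = lon_all)
  sites_df <- do.call(rbind, visit_rows)
  sites_df$arrival <- as.POSIXct(round(sites_df$arrival),
                                 origin = "1970-01-01", tz = "UTC")
  sites_df$departure <- as.POSIXct(round(sites_df$departure),
                                   origin = "1970-01-01", tz = "UTC")
  structure(list(track = tr,
                 truth = list(labels = lab_all, sites = sites_df),
                 config = config),
            class = "sim_track")
}

# uniform mode: spatially uniform fixes over a square of area n/density,
# timestamps scattered so no temporal runs form
simulate_uniform <- function(config) {
  u <- config$uniform
  n <- as.integer(u$n)
  side <- sqrt(n / u$density_per_km2)
  x <- runif(n, -side / 2, side / 2)
  y <- runif(n, -side / 2, side / 2)
  g <- local_to_geo(x, y, u$center[1], u$center[2])
  tt <- SIM_EPOCH + sort(runif(n, 0, n * u$time_gap_h * 3600))
  tr <- track(time = round(tt), lat = g$lat, lon = g$lon)
  structure(list(track = tr,
                 truth = list(labels = rep(-1L, n),
                              sites = data.frame(
                                visit = integer(0), year = integer(0),
                                site = integer(0), lat = numeric(0),
                                lon = numeric(0), stay_days = numeric(0),
                                arrival = numeric(0), departure = numeric(0))),
                 config = config),
            class = "sim_track")
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("Synthetic track: %d fixes, %d planted stopover visit(s)\n",
              nrow(x$track), nrow(x$truth$sites)))
  invisible(x)
}

#' Library of named simulation scenarios
#'
#' Ready-made [sim_config()]s used throughout the package's validation:
#' \describe{
#'   \item{`two_stop_flyway`}{two 10-day stopovers 1,000 km apart joined
#'     by a ~17 h flight leg,}
#'   \item{`multi_stop_migration`}{six stopovers along a south-to-north
#'     flyway with stays of 14, 18, 7, 9, 16 and 7 days,}
#'   \item{`interannual_revisit`}{one 10-day stopover visited in two
#'     consecutive years at identical coordinates,}
#'   \item{`dense_blob`}{a single dense cluster of >10,000 fixes (60-day
#'     stay sampled at a 3-12 min duty cycle) stressing the convex-hull
#'     expansion,}
#'   \item{`uniform_noise`}{spatially uniform fixes with scattered
#'     timestamps; contains no stopover.}
#' }
#'
#' @param seed Seed stored in every returned config.
#' @return Named list of [sim_config()] objects.
#' @export
scenario_library <- function(seed = 0L) {
  list(
    two_stop_flyway = sim_config(
      sites = data.frame(lat = c(45, 45 + 1000 / 111.195), lon = c(100, 100),
                         stay_days = c(10, 10), radius_km = c(5, 5)),
      seed = seed),
    multi_stop_migration = sim_config(
      sites = data.frame(
        lat = c(30.0, 36.5, 43.0, 50.0, 58.0, 66.0),
        lon = c(113.0, 110.0, 107.0, 104.0, 101.0, 98.0),
        stay_days = c(14, 18, 7, 9, 16, 7),
        radius_km = rep(5, 6)),
      seed = seed),
    interannual_revisit = sim_config(
      sites = data.frame(lat = 29.0, lon = 112.8,
                         stay_days = 10, radius_km = 5),
      years = c(0L, 1L), seed = seed),
    dense_blob = sim_config(
      sites = data.frame(lat = 40, lon = 110, stay_days = 60, radius_km = 8),
      fix_interval_range_h = c(0.05, 0.2), jitter_km = 0.02,
      seed = seed),
    uniform_noise = sim_config(
      uniform = list(n = 1500L, density_per_km2 = 0.01,
                     center = c(45, 100), time_gap_h = 3),
      seed = seed)
  )
}

#' Generate a named scenario
#'
#' Convenience wrapper: `simulate_track(scenario_library(seed)[[name]])`.
#'
#' @param name One of the names of [scenario_library()].
#' @param seed RNG seed.
#' @return A `sim_track` (see [simulate_track()]).
#' @export
scenario_track <- function(name, seed = 0L) {
  lib <- scenario_library(seed)
  if (!name %in% names(lib))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  simulate_track(lib[[name]])
}
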