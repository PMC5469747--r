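# Synthetic-data generators: switching-CRW tracks with Argos-like
# observation, frontal chlorophyll scenes over a bathymetry grid, and
# lane-structured traffic rasters. Every generator is a pure function
# of (spec, seed) and carries its ground truth.

#' Default Argos location-class frequencies for simulated tags
#'
#' A realistic whale-tag class mix weighted toward the poorer classes.
#' @return Named numeric vector summing to 1 (classes 3,2,1,0,A,B).
#' @export
default_lc_frequencies <- function() {
  c(`3` = 0.08, `2` = 0.12, `1` = 0.18, `0` = 0.22, A = 0.22, B = 0.18)
}

#' Simulate a switching-CRW track with known states
#'
#' Behavioural states follow the two-state Markov chain with switching
#' probabilities `alpha` (initial state drawn from its stationary
#' distribution); displacements follow the first-difference correlated
#' random walk with state-dependent persistence and turning and
#' bivariate Gaussian process noise `Sigma`.
#'
#' @param params A `dcrws_params` object.
#' @param n_steps Number of regular positions (>= 3).
#' @param step_hours Regular time step in hours.
#' @param origin Length-2 start location (lon, lat, degrees).
#' @param seed Integer seed (required; generator is pure in (spec,
#'   seed)).
#' @param origin_time POSIXct start time.
#' @param initial_disp First displacement (degrees); process noise is
#'   added to it.
#' @return A `sim_truth` object: times, true path `x` (n x 2), states
#'   `b` (length n; interior entries give the regime of the transition
#'   leaving each node, ends mirrored), generating params and seed.
#' @export
simulate_dcrws <- function(params, n_steps, step_hours = 12,
                           origin = c(7.5, 43.0), seed,
                           origin_time = as.POSIXct("2012-09-22 00:00:00",
                                                    tz = "UTC"),
                           initial_disp = c(0.05, 0.05)) {
  stopifnot(inherits(params, "dcrws_params"), n_steps >= 3)
  set.seed(seed)
  n <- as.integer(n_steps)
  L <- t(chol(params$Sigma))
  noise <- function() as.numeric(L %*% rnorm(2))
  x <- matrix(NA_real_, n, 2)
  b <- integer(n)
  x[1, ] <- origin
  x[2, ] <- origin + initial_disp + noise()
  p1_stat <- params$alpha[2] / (1 - params$alpha[1] + params$alpha[2])
  b[2] <- if (runif(1) < p1_stat) 1L else 2L
  for (t in 2:(n - 1)) {
    x[t + 1, ] <- process_mean(x[t, ], x[t - 1, ], b[t], params) + noise()
    if (t + 1 <= n - 1) {
      p1 <- params$alpha[b[t]]
      b[t + 1] <- if (runif(1) < p1) 1L else 2L
    }
  }
  b[1] <- b[2]
  b[n] <- b[n - 1]
  structure(list(
    times = origin_time + (seq_len(n) - 1) * step_hours * 3600,
    x = x, b = b, params = params, seed = seed, step_hours = step_hours
  ), class = "sim_truth")
}

#' Observe a simulated track through the Argos error model
#'
#' Observation times are a Poisson process over the track span; each
#' fix takes the linearly interpolated true location plus independent
#' per-coordinate Student-t noise with the scale and degrees of freedom
#' of its sampled location class. Fixes are time-sorted.
#'
#' @param truth A `sim_truth`.
#' @param obs_rate_per_day Mean number of fixes per day (> 0).
#' @param lc_frequencies Named sampling frequencies over location
#'   classes (must sum to 1).
#' @param error_table Per-class `tau` (degrees) and `nu`.
#' @param seed Integer seed.
#' @param ptt Platform identifier for the generated fixes.
#' @return An `argos_fixes` data.frame.
#' @export
observe_argos <- function(truth, obs_rate_per_day = 3,
                          lc_frequencies = default_lc_frequencies(),
                          error_table = default_error_table(),
                          seed, ptt = "SIM1") {
  stopifnot(obs_rate_per_day > 0,
            isTRUE(all.equal(sum(lc_frequencies), 1)))
  set.seed(seed)
  span_s <- as.numeric(difftime(truth$times[length(truth$times)],
                                truth$times[1], units = "secs"))
  span_days <- span_s / 86400
  m <- rpois(1, obs_rate_per_day * span_days)
  if (m == 0)
    return(new_argos_fixes(character(), truth$times[0], numeric(),
                           numeric(), character()))
  ts <- sort(round(runif(m, 0, span_s)))
  tt <- as.numeric(truth$times)
  lon <- stats::approx(tt, truth$x[, 1], xout = as.numeric(truth$times[1]) + ts)$y
  lat <- stats::approx(tt, truth$x[, 2], xout = as.numeric(truth$times[1]) + ts)$y
  lc <- sample(names(lc_frequencies), m, replace = TRUE,
               prob = lc_frequencies)
  row <- match(lc, error_table$lc)
  tau <- error_table$tau[row]
  nu <- error_table$nu[row]
  lon <- lon + tau * rt(m, df = nu)
  lat <- lat + tau * rt(m, df = nu)
  new_argos_fixes(rep(ptt, m), truth$times[1] + ts, lon, lat, lc)
}

#' Simulate a chlorophyll / bathymetry / traffic scene
#'
#' Builds co-registered daily chlorophyll-a fields containing a
#' meridional front (sigmoidal transition in log-chlorophyll between
#' two plateau levels, optionally drifting by day), a bathymetry field
#' monotone offshore with an optional land margin, and an integer
#' traffic raster with high values only along specified shipping lanes
#' (values clamped to \[0, 409\]).
#'
#' @param grid A `scene_grid`.
#' @param front_spec List: `lon` (front centre), `width_deg`
#'   (transition band width), `chl_low`, `chl_high` (plateau levels,
#'   mg m^-3), `drift_deg_per_day`.
#' @param depth_spec List: `shallow_edge` ("west" or "east"),
#'   `max_depth_m`, `land_margin_deg` (strip of land cells along the
#'   shallow edge).
#' @param lane_spec List of lanes, each a list with `from`, `to`
#'   (lon/lat pairs), `width_cells`, `value`.
#' @param n_days Number of daily chlorophyll fields.
#' @param seed Integer seed (multiplicative chlorophyll noise).
#' @param chl_noise_sd SD of lognormal small-scale chlorophyll noise
#'   (0 for analytically exact fields).
#' @return A `sim_scene`: grid, `chl` (list of daily matrices),
#'   `depth` (m, positive down), `land` (logical), `traffic` (integer
#'   matrix), `days` (1..n_days) and the spec echo.
#' @export
simulate_scene <- function(grid,
                           front_spec = list(lon = 5, width_deg = 0.2,
                                             chl_low = 0.1, chl_high = 0.8,
                                             drift_deg_per_day = 0),
                           depth_spec = list(shallow_edge = "east",
                                             max_depth_m = 2500,
                                             land_margin_deg = 0),
                           lane_spec = list(),
                           n_days = 1, seed = 1, chl_noise_sd = 0) {
  stopifnot(inherits(grid, "scene_grid"))
  front_spec <- utils::modifyList(list(lon = 5, width_deg = 0.2,
                                       chl_low = 0.1, chl_high = 0.8,
                                       drift_deg_per_day = 0), front_spec)
  depth_spec <- utils::modifyList(list(shallow_edge = "east",
                                       max_depth_m = 2500,
                                       land_margin_deg = 0), depth_spec)
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  lon_m <- matrix(grid$lon, nlat, nlon, byrow = TRUE)

  # bathymetry: linear ramp from the shallow edge, land on the margin
  if (depth_spec$shallow_edge == "east") {
    off <- grid$lon_range[2] - lon_m
  } else {
    off <- lon_m - grid$lon_range[1]
  }
  land <- off < depth_spec$land_margin_deg
  ramp <- off - depth_spec$land_margin_deg
  ramp[ramp < 0] <- 0
  depth <- ramp / max(diff(grid$lon_range) - depth_spec$land_margin_deg,
                      1e-9) * depth_spec$max_depth_m
  depth[land] <- 0

  # daily chlorophyll: sigmoid in log space across longitude
  w <- front_spec$width_deg / 4   # logistic scale; ~width across the band
  chl <- lapply(seq_len(n_days), function(d) {
    centre <- front_spec$lon + (d - 1) * front_spec$drift_deg_per_day
    s <- 1 / (1 + exp(-(lon_m - centre) / w))
    logc <- log(front_spec$chl_low) +
      (log(front_spec$chl_high) - log(front_spec$chl_low)) * s
    f <- exp(logc)
    if (chl_noise_sd > 0)
      f <- f * exp(matrix(rnorm(nlat * nlon, 0, chl_noise_sd), nlat, nlon))
    f[land] <- NA_real_
    f
  })

  traffic <- matrix(0L, nlat, nlon)
  for (lane in lane_spec) {
    lane <- utils::modifyList(list(width_cells = 1, value = 400), lane)
    traffic <- rasterize_lane(traffic, grid, lane$from, lane$to,
                              lane$width_cells, lane$value)
  }
  traffic[] <- pmin(pmax(traffic, 0L), 409L)

  structure(list(grid = grid, chl = chl, depth = depth, land = land,
                 traffic = traffic, days = seq_len(n_days), seed = seed,
                 front_spec = front_spec, depth_spec = depth_spec,
                 lane_spec = lane_spec),
            class = "sim_scene")
}

# Mark cells within width_cells - 1 (Chebyshev) of the from->to line,
# sampled densely along it.
rasterize_lane <- function(traffic, grid, from, to, width_cells, value) {
  steps <- max(2L, ceiling(max(abs(to - from)) / (grid$cell_deg / 4)))
  f <- seq(0, 1, length.out = steps)
  pts <- cbind(from[1] + f * (to[1] - from[1]),
               from[2] + f * (to[2] - from[2]))
  rc <- grid_cell_of(grid, pts[, 1], pts[, 2])
  rc <- rc[stats::complete.cases(rc), , drop = FALSE]
  r <- width_cells - 1L
  for (k in seq_len(nrow(rc))) {
    ii <- pmax(1L, rc[k, 1] - r):pmin(nrow(traffic), rc[k, 1] + r)
    jj <- pmax(1L, rc[k, 2] - r):pmin(ncol(traffic), rc[k, 2] + r)
    traffic[ii, jj] <- as.integer(value)
  }
  traffic
}

#' Write the ground truth of a simulated track
#'
#' Writes the true path and states as CSV and the generating parameters
#' and seed as JSON (`<path>.json`).
#'
#' @param truth A `sim_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(time = format(truth$times, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lon = sprintf("%.17g", truth$x[, 1]),
               lat = sprintf("%.17g", truth$x[, 2]),
               b = truth$b),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  p <- truth$params
  jsonlite::write_json(
    list(gamma = p$gamma, theta = p$theta, alpha = p$alpha,
         Sigma = p$Sigma, seed = truth$seed,
         step_hours = truth$step_hours),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write all scene layers to a directory
#'
#' Plain-text grids with JSON sidecars: `chl_day<k>.tsv`, `depth.tsv`,
#' `land.tsv`, `traffic.tsv`.
#'
#' @param scene A `sim_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in scene$days)
    write_grid_layer(ifelse(is.na(scene$chl[[d]]), -1, scene$chl[[d]]),
                     scene$grid, file.path(dir, sprintf("chl_day%d.tsv", d)))
  write_grid_layer(scene$depth, scene$grid, file.path(dir, "depth.tsv"))
  write_grid_layer(scene$land * 1L, scene$grid, file.path(dir, "land.tsv"))
  write_grid_layer(scene$traffic, scene$grid, file.path(dir, "traffic.tsv"))
  invisible(dir)
}

#' Read a scene written by `write_scene`
#'
#' @param dir Directory containing the layers.
#' @return A `sim_scene`-like list (grid, chl, depth, land, traffic,
#'   days).
#' @export
read_scene <- function(dir) {
  files <- list.files(dir, pattern = "^chl_day[0-9]+\\.tsv$")
  days <- sort(as.integer(sub("^chl_day([0-9]+)\\.tsv$", "\\1", files)))
  if (!length(days)) stop("no chlorophyll layers found in ", dir)
  first <- read_grid_layer(file.path(dir, sprintf("chl_day%d.tsv", days[1])))
  grid <- first$grid
  chl <- lapply(days, function(d) {
    m <- read_grid_layer(file.path(dir, sprintf("chl_day%d.tsv", d)))$layer
    m[m < 0] <- NA_real_
    m
  })
  structure(list(grid = grid, chl = chl,
                 depth = read_grid_layer(file.path(dir, "depth.tsv"))$layer,
                 land = read_grid_layer(file.path(dir, "land.tsv"))$layer > 0,
                 traffic = read_grid_layer(file.path(dir, "traffic.tsv"))$layer,
                 days = days),
            class = "sim_scene")
}
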