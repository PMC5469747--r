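# Daily potential-feeding-habitat masks from chlorophyll-a fronts, a
# chlorophyll concentration window and a minimum depth; aggregation to
# frequency-of-occurrence maps; position-to-habitat proximity.

#' Detect chlorophyll-a fronts by log-gradient thresholding
#'
#' A cell is flagged when the centred-finite-difference horizontal
#' gradient magnitude of log chlorophyll-a reaches the threshold
#' (expressed per 100 km of ln chl-a, so doubling the field everywhere
#' leaves the mask unchanged).
#'
#' @param chla Chlorophyll matrix (mg m^-3, NA on land) on `grid`.
#' @param grid A `scene_grid`.
#' @param threshold_per_100km Gradient threshold on ln chl-a per 100 km.
#' @param dilate_cells Optional binary dilation radius (cells).
#' @return Logical front mask.
#' @export
detect_fronts <- function(chla, grid, threshold_per_100km = 0.5,
                          dilate_cells = 0) {
  if (nrow(chla) < 3 || ncol(chla) < 3)
    stop("grid must be at least 3 x 3")
  stopifnot(all(dim(chla) == grid_dim(grid)))
  if (any(chla <= 0, na.rm = TRUE))
    stop("chlorophyll must be positive on sea cells")
  lc <- log(chla)
  kmdeg <- EARTH_R_KM * pi / 180
  dy_km <- grid$cell_deg * kmdeg
  dx_km <- grid$cell_deg * kmdeg * cos(grid$lat * pi / 180)  # per lat row
  nlat <- nrow(lc); nlon <- ncol(lc)
  gx <- matrix(NA_real_, nlat, nlon)
  gy <- matrix(NA_real_, nlat, nlon)
  gx[, 2:(nlon - 1)] <- (lc[, 3:nlon] - lc[, 1:(nlon - 2)]) / 2
  gx[, 1] <- lc[, 2] - lc[, 1]
  gx[, nlon] <- lc[, nlon] - lc[, nlon - 1]
  gx <- gx / dx_km
  gy[2:(nlat - 1), ] <- (lc[3:nlat, ] - lc[1:(nlat - 2), ]) / 2
  gy[1, ] <- lc[2, ] - lc[1, ]
  gy[nlat, ] <- lc[nlat, ] - lc[nlat - 1, ]
  gy <- gy / dy_km
  mag <- sqrt(gx^2 + gy^2)
  mask <- !is.na(mag) & mag >= threshold_per_100km / 100
  if (dilate_cells > 0) mask <- dilate_mask(mask, dilate_cells)
  mask
}

# Binary dilation with a square structuring element of radius r cells.
dilate_mask <- function(mask, r) {
  out <- mask
  nlat <- nrow(mask); nlon <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(nlat, nlat + di)
    ti <- max(1, 1 - di):min(nlat, nlat - di)
    sj <- max(1, 1 + dj):min(nlon, nlon + dj)
    tj <- max(1, 1 - dj):min(nlon, nlon - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

#' Daily habitat suitability mask
#'
#' A cell is suitable iff it is front-adjacent (within the dilation
#' radius of a detected front), its chlorophyll lies in
#' `[chl_min, chl_max]`, its depth is at least `depth_min`, and it is a
#' sea cell.
#'
#' @param chla Chlorophyll matrix (mg m^-3).
#' @param fronts Logical front mask (undilated).
#' @param depth Depth matrix (m, positive down).
#' @param land Logical land mask (TRUE = land), or NULL.
#' @param config List: `chl_min`, `chl_max` (mg m^-3), `depth_min` (m),
#'   `dilate_cells`.
#' @return Logical suitability mask.
#' @export
habitat_mask <- function(chla, fronts, depth, land = NULL,
                         config = list(chl_min = 0.05, chl_max = 0.5,
                                       depth_min = 200, dilate_cells = 2)) {
  config <- utils::modifyList(list(chl_min = 0.05, chl_max = 0.5,
                                   depth_min = 200, dilate_cells = 2),
                              config)
  if (!all(dim(chla) == dim(fronts)) || !all(dim(chla) == dim(depth)))
    stop("chlorophyll, front and depth layers must share the grid")
  if (is.null(land)) land <- matrix(FALSE, nrow(chla), ncol(chla))
  if (!all(dim(land) == dim(chla)))
    stop("land mask must share the grid")
  fr <- if (config$dilate_cells > 0)
    dilate_mask(fronts, config$dilate_cells) else fronts
  ok <- fr & !is.na(chla) & chla >= config$chl_min &
    chla <= config$chl_max & depth >= config$depth_min & !land
  ok[is.na(ok)] <- FALSE
  ok
}

#' Build a daily habitat stack for a scene
#'
#' Convenience wrapper running `detect_fronts` and `habitat_mask` for
#' every day of a simulated scene.
#'
#' @param scene A `sim_scene`.
#' @param config Habitat config plus `front_threshold_per_100km`.
#' @return A `habitat_stack`: list with `grid`, `days`, `masks` and the
#'   config used.
#' @export
habitat_stack <- function(scene,
                          config = list(chl_min = 0.05, chl_max = 0.5,
                                        depth_min = 200, dilate_cells = 2,
                                        front_threshold_per_100km = 0.5)) {
  config <- utils::modifyList(list(chl_min = 0.05, chl_max = 0.5,
                                   depth_min = 200, dilate_cells = 2,
                                   front_threshold_per_100km = 0.5), config)
  masks <- lapply(scene$days, function(d) {
    fr <- detect_fronts(scene$chl[[d]], scene$grid,
                        config$front_threshold_per_100km)
    habitat_mask(scene$chl[[d]], fr, scene$depth, scene$land, config)
  })
  structure(list(grid = scene$grid, days = scene$days, masks = masks,
                 config = config),
            class = "habitat_stack")
}

#' Frequency-of-occurrence map over a window of days
#'
#' @param stack A `habitat_stack`.
#' @param window Days to aggregate (must all be present).
#' @return Matrix in \[0, 1\]: per cell, fraction of window days
#'   suitable.
#' @export
habitat_frequency <- function(stack, window = stack$days) {
  if (!length(window)) stop("window must be non-empty")
  missing <- setdiff(window, stack$days)
  if (length(missing))
    stop("day(s) missing from stack: ", paste(missing, collapse = ", "))
  idx <- match(window, stack$days)
  Reduce(`+`, lapply(stack$masks[idx], function(m) m * 1)) / length(window)
}

#' Percentage of a region's sea area that is suitable
#'
#' @param mask Logical suitability mask on `grid`.
#' @param grid A `scene_grid`.
#' @param region Two-column lon/lat polygon (ring).
#' @param land Optional logical land mask; sea area is the denominator.
#' @return Percentage in \[0, 100\].
#' @export
habitat_area_fraction <- function(mask, grid, region, land = NULL) {
  stopifnot(all(dim(mask) == grid_dim(grid)))
  if (is.null(land)) land <- matrix(FALSE, nrow(mask), ncol(mask))
  pts <- cbind(rep(grid$lon, each = length(grid$lat)),
               rep(grid$lat, times = length(grid$lon)))
  inside <- matrix(mgcv::in.out(close_ring(region), pts),
                   length(grid$lat), length(grid$lon))
  sea <- inside & !land
  if (!any(sea)) stop("region does not intersect the grid's sea cells")
  areas <- matrix(cell_area_km2(grid), nrow(mask), ncol(mask))
  100 * sum(areas[sea & mask]) / sum(areas[sea])
}

close_ring <- function(poly) {
  poly <- as.matrix(poly[, 1:2])
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Reduce estimated locations to one daily position per platform
#'
#' The daily position is the per-platform mean of that day's estimated
#' locations.
#'
#' @param locations Data frame with `ptt`, `state_time` (POSIXct),
#'   `lon`, `lat` (e.g. rows of `posterior_locations`).
#' @return Data frame with `ptt`, `day` (Date), `lon`, `lat`.
#' @export
daily_positions <- function(locations) {
  day <- as.Date(locations$state_time, tz = "UTC")
  agg <- stats::aggregate(locations[, c("lon", "lat")],
                          by = list(ptt = locations$ptt, day = day), mean)
  agg[order(agg$ptt, agg$day), , drop = FALSE]
}

#' Distance from daily positions to the nearest suitable habitat
#'
#' Great-circle (haversine, R = 6371 km) distance from each position to
#' the nearest suitable cell centre of the same day's mask; 0 km when
#' the position's own cell is suitable. Days whose mask is empty yield
#' a missing distance, excluded from the summary fraction.
#'
#' @param positions Data frame with `ptt`, `day`, `lon`, `lat` (one row
#'   per platform per day). `day` is matched against `stack$days`
#'   (integers) or dates coerced to integer day numbers.
#' @param stack A `habitat_stack`.
#' @param threshold_km Proximity threshold; the summary fraction counts
#'   distances strictly below it.
#' @return A `proximity_result`: per-position distances and the
#'   summary (`fraction_within`, `n`, `n_missing`).
#' @export
distance_to_habitat <- function(positions, stack, threshold_km = 7) {
  grid <- stack$grid
  pday <- as.integer(positions$day)
  if (!all(pday %in% as.integer(stack$days)))
    stop("no habitat mask for day(s): ",
         paste(unique(pday[!pday %in% as.integer(stack$days)]),
               collapse = ", "))
  dist_km <- rep(NA_real_, nrow(positions))
  for (i in seq_len(nrow(positions))) {
    mask <- stack$masks[[match(pday[i], as.integer(stack$days))]]
    if (!any(mask)) next
    rc <- grid_cell_of(grid, positions$lon[i], positions$lat[i])
    if (!is.na(rc[1, 1]) && mask[rc[1, 1], rc[1, 2]]) {
      dist_km[i] <- 0
      next
    }
    idx <- which(mask, arr.ind = TRUE)
    cells <- cbind(grid$lon[idx[, 2]], grid$lat[idx[, 1]])
    d <- geosphere::distHaversine(c(positions$lon[i], positions$lat[i]),
                                  cells, r = EARTH_R_KM)
    dist_km[i] <- min(d)
  }
  ok <- !is.na(dist_km)
  structure(list(
    positions = cbind(positions, distance_km = dist_km),
    fraction_within = if (any(ok)) mean(dist_km[ok] < threshold_km) else NA,
    threshold_km = threshold_km,
    n = sum(ok), n_missing = sum(!ok)
  ), class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity: %.1f%% of %d positions within %g km (%d missing)>\n",
              100 * x$fraction_within, x$n, x$threshold_km, x$n_missing))
  invisible(x)
}
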