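# Kernel utilisation distributions, isopleth home ranges and the
# minimum bounding geometry. All area computation happens in a Lambert
# azimuthal equal-area projection centred on the position centroid so
# isopleth masses and km^2 areas are area-true.

EARTH_R_KM <- 6371

#' Lambert azimuthal equal-area projection
#'
#' Projects lon/lat (degrees) to planar km about `center`; inverse via
#' `unproject_laea`.
#'
#' @param lonlat Two-column matrix or data.frame (lon, lat).
#' @param center Length-2 projection centre (lon, lat).
#' @return Two-column matrix of x, y in km.
#' @export
project_laea <- function(lonlat, center) {
  lonlat <- as.matrix(lonlat)
  lam <- lonlat[, 1] * pi / 180
  phi <- lonlat[, 2] * pi / 180
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  k <- sqrt(2 / (1 + sin(phi0) * sin(phi) +
                   cos(phi0) * cos(phi) * cos(lam - lam0)))
  cbind(x = EARTH_R_KM * k * cos(phi) * sin(lam - lam0),
        y = EARTH_R_KM * k * (cos(phi0) * sin(phi) -
                                sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' @rdname project_laea
#' @param xy Two-column matrix of x, y in km.
#' @export
unproject_laea <- function(xy, center) {
  xy <- as.matrix(xy)
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  rho <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * EARTH_R_KM)))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) +
                       xy[, 2] * sin(c_ang) * cos(phi0) / pmax(rho, 1e-12)))
  lam <- lam0 + atan2(xy[, 1] * sin(c_ang),
                      rho * cos(c_ang) * cos(phi0) -
                        xy[, 2] * sin(c_ang) * sin(phi0))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# Shoelace area of a simple polygon (ring need not be closed).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Minimum bounding geometry of a set of positions
#'
#' The convex hull of all positions, computed in the equal-area
#' projection.
#'
#' @param positions Two-column matrix or data.frame of lon, lat.
#' @param center Optional projection centre; defaults to the position
#'   centroid.
#' @return An `mbg` object: hull vertices in lon/lat and km, area in
#'   km^2, projection centre.
#' @export
minimum_bounding_geometry <- function(positions, center = NULL) {
  ll <- as.matrix(positions[, 1:2])
  ll <- unique(ll[stats::complete.cases(ll), , drop = FALSE])
  if (nrow(ll) < 3) stop("need at least 3 distinct positions")
  sv <- svd(scale(ll, scale = FALSE))$d
  if (sv[2] <= 1e-8 * sv[1])
    stop("positions are collinear; hull is degenerate")
  if (is.null(center)) center <- colMeans(ll)
  xy <- project_laea(ll, center)
  h <- grDevices::chull(xy)
  hull_xy <- xy[h, , drop = FALSE]
  area <- polygon_area(hull_xy)
  if (area <= 1e-9) stop("positions are collinear; hull is degenerate")
  structure(list(lonlat = ll[h, , drop = FALSE], xy_km = hull_xy,
                 area_km2 = area, center = center),
            class = "mbg")
}

#' @export
print.mbg <- function(x, ...) {
  cat(sprintf("<mbg: %d vertices, %.1f km2>\n", nrow(x$xy_km), x$area_km2))
  invisible(x)
}

# Silverman's per-axis reference-rule bandwidth:
# h_j = 0.9 * min(sd_j, IQR_j/1.34) * n^(-1/5).
silverman_bw <- function(v) {
  n <- length(v)
  s <- min(stats::sd(v), stats::IQR(v) / 1.34)
  if (s <= 0) s <- stats::sd(v)
  if (s <= 0) stop("degenerate positions: zero spread")
  0.9 * s * n^(-1 / 5)
}

#' Kernel utilisation distribution on an equal-area grid
#'
#' Gaussian product-kernel density of the positions, evaluated on a
#' regular grid in the equal-area projection. Cells on the barrier are
#' set to zero and the density renormalised to unit mass over sea
#' cells (mask-and-renormalise barrier handling).
#'
#' @param positions Two-column matrix/data.frame of lon, lat (degrees).
#' @param bandwidth_km Optional per-axis bandwidths (km); default
#'   Silverman's reference rule per axis.
#' @param grid_n Cells per axis.
#' @param margin_factor Grid margin in bandwidths around the positions.
#' @param barrier Optional barrier: a function `(x_km, y_km) ->
#'   logical` (TRUE = barrier), or a logical matrix conforming to the
#'   grid.
#' @param center Optional projection centre (lon, lat).
#' @return A `ud_grid` object.
#' @export
kde_ud <- function(positions, bandwidth_km = NULL, grid_n = 128,
                   margin_factor = 3.5, barrier = NULL, center = NULL) {
  ll <- as.matrix(positions[, 1:2])
  ll <- ll[stats::complete.cases(ll), , drop = FALSE]
  if (nrow(unique(ll)) < 2) stop("need at least 2 distinct positions")
  if (is.null(center)) center <- colMeans(ll)
  xy <- project_laea(ll, center)
  n <- nrow(xy)
  if (is.null(bandwidth_km))
    bandwidth_km <- c(silverman_bw(xy[, 1]), silverman_bw(xy[, 2]))
  stopifnot(all(bandwidth_km > 0))
  mx <- margin_factor * bandwidth_km
  xr <- range(xy[, 1]) + c(-1, 1) * mx[1]
  yr <- range(xy[, 2]) + c(-1, 1) * mx[2]
  xg <- seq(xr[1], xr[2], length.out = grid_n)
  yg <- seq(yr[1], yr[2], length.out = grid_n)
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  Fx <- stats::dnorm(outer(xg, xy[, 1], "-") / bandwidth_km[1]) /
    bandwidth_km[1]
  Fy <- stats::dnorm(outer(yg, xy[, 2], "-") / bandwidth_km[2]) /
    bandwidth_km[2]
  dens <- (Fy %*% t(Fx)) / n   # [row = y, col = x]
  bar <- NULL
  if (!is.null(barrier)) {
    bar <- if (is.function(barrier)) {
      outer(yg, xg, function(y, x) barrier(x, y))
    } else {
      stopifnot(all(dim(barrier) == c(grid_n, grid_n)))
      barrier
    }
    dens[bar] <- 0
  }
  mass <- sum(dens) * dx * dy
  if (mass <= 0) stop("all probability mass fell on barrier cells")
  dens <- dens / mass
  structure(list(x = xg, y = yg, dx = dx, dy = dy,
                 density = dens, cell_area_km2 = dx * dy,
                 bandwidth_km = bandwidth_km, center = center,
                 barrier = bar, n_positions = n),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid %dx%d cells of %.2f km, bw (%.2f, %.2f) km, n=%d>\n",
              length(x$y), length(x$x), x$dx, x$bandwidth_km[1],
              x$bandwidth_km[2], x$n_positions))
  invisible(x)
}

#' Isopleth (superlevel set) of a utilisation distribution
#'
#' Cells are sorted by density (descending, ties broken by cell index
#' for determinism) and the smallest prefix whose cumulative mass
#' reaches `level` defines the region.
#'
#' @param ud A `ud_grid`.
#' @param level Probability mass in (0, 1].
#' @return List: logical cell `mask`, attained `mass`, `area_km2`,
#'   `n_cells`, `level`.
#' @export
isopleth <- function(ud, level) {
  if (length(level) != 1 || level <= 0 || level > 1)
    stop("level must be in (0, 1]")
  d <- as.vector(ud$density)
  ord <- order(-d, seq_along(d))
  cmass <- cumsum(d[ord]) * ud$cell_area_km2
  k <- which(cmass >= level - 1e-12)[1]
  if (is.na(k)) k <- sum(d > 0)
  sel <- ord[seq_len(k)]
  sel <- sel[d[sel] > 0]
  mask <- matrix(FALSE, nrow(ud$density), ncol(ud$density))
  mask[sel] <- TRUE
  list(mask = mask, mass = sum(d[sel]) * ud$cell_area_km2,
       area_km2 = length(sel) * ud$cell_area_km2,
       n_cells = length(sel), level = level)
}

#' Core and total home ranges (50% and 90% isopleths)
#'
#' @param ud A `ud_grid`.
#' @return A `home_ranges` object with `chr`, `thr` (isopleth results)
#'   and the `ud` they were derived from.
#' @export
home_ranges <- function(ud) {
  structure(list(chr = isopleth(ud, 0.5), thr = isopleth(ud, 0.9),
                 ud = ud),
            class = "home_ranges")
}

#' @export
print.home_ranges <- function(x, ...) {
  cat(sprintf("<home_ranges: CHR %.1f km2 (mass %.3f), THR %.1f km2 (mass %.3f)>\n",
              x$chr$area_km2, x$chr$mass, x$thr$area_km2, x$thr$mass))
  invisible(x)
}

#' Export home-range cell regions as GeoJSON (cell-polygon union)
#'
#' Each region is written as a MultiPolygon of its grid cells
#' (unprojected back to lon/lat), with level and area attributes.
#'
#' @param home A `home_ranges` object.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_home_ranges_geojson <- function(home, path) {
  ud <- home$ud
  cell_poly <- function(iy, ix) {
    xs <- ud$x[ix] + c(-0.5, 0.5, 0.5, -0.5, -0.5) * ud$dx
    ys <- ud$y[iy] + c(-0.5, -0.5, 0.5, 0.5, -0.5) * ud$dy
    ll <- unproject_laea(cbind(xs, ys), ud$center)
    list(lapply(seq_len(5), function(k) c(ll[k, 1], ll[k, 2])))
  }
  feat <- function(iso, name) {
    idx <- which(iso$mask, arr.ind = TRUE)
    list(type = "Feature",
         properties = list(region = name, level = iso$level,
                           area_km2 = iso$area_km2, mass = iso$mass),
         geometry = list(type = "MultiPolygon",
                         coordinates = unname(lapply(seq_len(nrow(idx)),
                           function(k) cell_poly(idx[k, 1], idx[k, 2])))))
  }
  jsonlite::write_json(
    list(type = "FeatureCollection",
         features = list(feat(home$chr, "CHR"), feat(home$thr, "THR"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a utilisation distribution as a plain-text grid
#'
#' Density matrix as TSV plus a JSON sidecar with the projected grid
#' definition.
#'
#' @param ud A `ud_grid`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ud_grid <- function(ud, path) {
  utils::write.table(ud$density, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(x_km = ud$x, y_km = ud$y, center = ud$center,
         bandwidth_km = ud$bandwidth_km, cell_area_km2 = ud$cell_area_km2),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
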