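# High-traffic extraction within the minimum bounding geometry and
# percentage overlap of home ranges with high-traffic areas. Overlap is
# computed on cell sets (exact with respect to the UD discretisation).

#' Validate a traffic raster
#'
#' @param values Integer matrix conforming to `grid`, values in
#'   \[0, 409\].
#' @param grid A `scene_grid`.
#' @return A `traffic_raster` object.
#' @export
traffic_raster <- function(values, grid) {
  stopifnot(all(dim(values) == grid_dim(grid)))
  if (any(values < 0 | values > 409, na.rm = TRUE))
    stop("traffic values must lie in [0, 409]")
  structure(list(values = values, grid = grid), class = "traffic_raster")
}

#' Extract high-traffic cells within the MBG
#'
#' Cells inside the minimum bounding geometry whose traffic density
#' satisfies the rule. The default rule flags cells at or above the
#' 90th percentile of the nonzero in-MBG values; an absolute threshold
#' is available via `rule = list(type = "absolute", threshold = v)`.
#'
#' @param traffic A `traffic_raster` (or `sim_scene`, whose traffic
#'   layer is used).
#' @param mbg An `mbg` object or two-column lon/lat polygon.
#' @param rule List: `type` ("quantile" or "absolute") plus `q` or
#'   `threshold`.
#' @return List: logical `mask` of high-traffic cells, the `grid`,
#'   `threshold` used and `rule` echo.
#' @export
extract_high_traffic <- function(traffic, mbg,
                                 rule = list(type = "quantile", q = 0.9)) {
  if (inherits(traffic, "sim_scene"))
    traffic <- traffic_raster(traffic$traffic, traffic$grid)
  stopifnot(inherits(traffic, "traffic_raster"))
  grid <- traffic$grid
  poly <- if (inherits(mbg, "mbg")) mbg$lonlat else as.matrix(mbg[, 1:2])
  pts <- cbind(rep(grid$lon, each = length(grid$lat)),
               rep(grid$lat, times = length(grid$lon)))
  inside <- matrix(mgcv::in.out(close_ring(poly), pts),
                   length(grid$lat), length(grid$lon))
  if (!any(inside)) stop("traffic raster does not intersect the MBG")
  vals <- traffic$values[inside]
  nz <- vals[vals > 0]
  if (rule$type == "quantile") {
    if (!length(nz))
      return(list(mask = inside & FALSE, grid = grid,
                  threshold = Inf, rule = rule))
    threshold <- stats::quantile(nz, rule$q %||% 0.9, names = FALSE)
  } else if (rule$type == "absolute") {
    threshold <- rule$threshold
  } else stop("unknown rule type: ", rule$type)
  list(mask = inside & traffic$values >= threshold & traffic$values > 0,
       grid = grid, threshold = threshold, rule = rule)
}

#' Percentage overlap of home ranges with high-traffic areas
#'
#' `pct_thr = 100 * area(THR intersect high-traffic) / area(THR)` and
#' analogously for the CHR, with all geometries clipped to the MBG.
#' `high_traffic` may be the result of `extract_high_traffic` (lon/lat
#' raster pathway; UD cells are matched to traffic cells through the
#' inverse equal-area projection) or a logical matrix on the UD grid
#' itself (direct cell pathway).
#'
#' @param home A `home_ranges` object.
#' @param high_traffic `extract_high_traffic` result or logical matrix
#'   on the UD grid.
#' @param mbg Optional `mbg` (or lon/lat polygon) for clipping; NULL
#'   skips clipping.
#' @return An `overlap_report`: `pct_thr`, `pct_chr`, component areas
#'   (km^2) and the threshold rule used.
#' @export
overlap_percentages <- function(home, high_traffic, mbg = NULL) {
  stopifnot(inherits(home, "home_ranges"))
  ud <- home$ud
  nlat <- length(ud$y); nlon <- length(ud$x)
  if (is.matrix(high_traffic)) {
    stopifnot(all(dim(high_traffic) == c(nlat, nlon)))
    ht_ud <- high_traffic
    rule <- "direct cell mask"
  } else {
    centres_xy <- cbind(rep(ud$x, each = nlat), rep(ud$y, times = nlon))
    centres_ll <- unproject_laea(centres_xy, ud$center)
    rc <- grid_cell_of(high_traffic$grid, centres_ll[, 1], centres_ll[, 2])
    ht_ud <- matrix(FALSE, nlat, nlon)
    okc <- !is.na(rc[, 1])
    ht_ud[okc] <- high_traffic$mask[cbind(rc[okc, 1], rc[okc, 2])]
    rule <- high_traffic$rule
  }
  clip <- matrix(TRUE, nlat, nlon)
  if (!is.null(mbg)) {
    poly <- if (inherits(mbg, "mbg")) mbg$lonlat else as.matrix(mbg[, 1:2])
    centres_xy <- cbind(rep(ud$x, each = nlat), rep(ud$y, times = nlon))
    centres_ll <- unproject_laea(centres_xy, ud$center)
    clip <- matrix(mgcv::in.out(close_ring(poly), centres_ll), nlat, nlon)
  }
  a <- ud$cell_area_km2
  thr <- home$thr$mask & clip
  chr <- home$chr$mask & clip
  area_thr <- sum(thr) * a
  area_chr <- sum(chr) * a
  if (area_thr <= 0 || area_chr <= 0)
    stop("zero-area home range after clipping")
  area_thr_ht <- sum(thr & ht_ud) * a
  area_chr_ht <- sum(chr & ht_ud) * a
  structure(list(
    pct_thr = 100 * area_thr_ht / area_thr,
    pct_chr = 100 * area_chr_ht / area_chr,
    areas_km2 = c(thr = area_thr, chr = area_chr,
                  thr_high_traffic = area_thr_ht,
                  chr_high_traffic = area_chr_ht),
    rule = rule
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap: %.1f%% of THR, %.1f%% of CHR in high traffic>\n",
              x$pct_thr, x$pct_chr))
  invisible(x)
}

#' Write an overlap report as JSON
#'
#' @param report An `overlap_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(report, path) {
  jsonlite::write_json(list(pct_thr = report$pct_thr,
                            pct_chr = report$pct_chr,
                            areas_km2 = as.list(report$areas_km2),
                            rule = report$rule),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
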