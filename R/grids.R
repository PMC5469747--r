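# Lightweight lon/lat raster container shared by the scene, habitat and
# traffic modules. Layers are matrices [nlat x nlon]; row i corresponds
# to lat[i] (increasing), column j to lon[j] (increasing); values are
# cell-centre samples.

#' Define a regular lon/lat grid
#'
#' @param lon_range,lat_range Extent in decimal degrees (cell edges).
#' @param cell_deg Cell size in degrees (same in lon and lat).
#' @return A `scene_grid` object with cell-centre coordinate vectors.
#' @export
scene_grid <- function(lon_range, lat_range, cell_deg) {
  stopifnot(cell_deg > 0, diff(lon_range) > 0, diff(lat_range) > 0)
  nlon <- max(1L, round(diff(lon_range) / cell_deg))
  nlat <- max(1L, round(diff(lat_range) / cell_deg))
  structure(list(
    lon = lon_range[1] + (seq_len(nlon) - 0.5) * cell_deg,
    lat = lat_range[1] + (seq_len(nlat) - 0.5) * cell_deg,
    cell_deg = cell_deg,
    lon_range = lon_range, lat_range = lat_range
  ), class = "scene_grid")
}

#' @export
print.scene_grid <- function(x, ...) {
  cat(sprintf("<scene_grid %d x %d cells of %.4g deg, lon [%g, %g], lat [%g, %g]>\n",
              length(x$lat), length(x$lon), x$cell_deg,
              x$lon_range[1], x$lon_range[2], x$lat_range[1], x$lat_range[2]))
  invisible(x)
}

grid_dim <- function(grid) c(length(grid$lat), length(grid$lon))

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

# Cell areas in km^2, one value per latitude row (equirectangular cell
# on the sphere, R = 6371 km).
cell_area_km2 <- function(grid) {
  kmdeg <- 6371 * pi / 180
  (grid$cell_deg * kmdeg) * (grid$cell_deg * kmdeg * cos(grid$lat * pi / 180))
}

# Row/col index of the cell containing a point; NA outside the grid.
grid_cell_of <- function(grid, lon, lat) {
  j <- floor((lon - grid$lon_range[1]) / grid$cell_deg) + 1
  i <- floor((lat - grid$lat_range[1]) / grid$cell_deg) + 1
  j[lon == grid$lon_range[2]] <- length(grid$lon)
  i[lat == grid$lat_range[2]] <- length(grid$lat)
  bad <- i < 1 | i > length(grid$lat) | j < 1 | j > length(grid$lon)
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

#' Write a grid layer as plain text with a JSON grid-definition sidecar
#'
#' The layer is written as a TSV matrix (rows = latitude, south to
#' north) and the grid definition to `<path>.json`.
#'
#' @param layer Matrix conforming to `grid`.
#' @param grid A `scene_grid`.
#' @param path Output path for the TSV matrix.
#' @return `path`, invisibly.
#' @export
write_grid_layer <- function(layer, grid, path) {
  stopifnot(all(dim(layer) == grid_dim(grid)))
  utils::write.table(layer, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(lon_range = grid$lon_range, lat_range = grid$lat_range,
         cell_deg = grid$cell_deg, nlat = nrow(layer), nlon = ncol(layer)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid layer written by `write_grid_layer`
#'
#' @param path Path to the TSV matrix (a `<path>.json` sidecar must
#'   exist).
#' @return List with `layer` (matrix) and `grid` (`scene_grid`).
#' @export
read_grid_layer <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layer <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(layer) <- NULL
  grid <- scene_grid(side$lon_range, side$lat_range, side$cell_deg)
  stopifnot(all(dim(layer) == grid_dim(grid)))
  list(layer = layer, grid = grid)
}
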