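#' Define a regular longitude--latitude grid
#'
#' Builds the grid geometry the gridded analysis operates on: cell-centre
#' coordinates at a fixed resolution (0.5 degrees by default, the resolution
#' of the ISIMIP-style forcing the models were designed for) and spherical
#' cell areas in km^2.
#'
#' Cell area follows the exact spherical formula
#' \eqn{A = R^2 \, \Delta\lambda \,(\sin\phi_2 - \sin\phi_1)} with
#' \eqn{R = 6371} km, so areas shrink towards the poles and a full global
#' grid integrates to the Earth's surface area (5.10e8 km^2).
#'
#' @param nlon,nlat Number of grid columns (longitude) and rows (latitude).
#' @param resolution Cell size in degrees.
#' @param lon_min,lat_min Western/southern edge of the grid, degrees.
#' @return An object of class `fire_grid`: list with `lon`, `lat` (cell-centre
#'   vectors), `resolution`, `cells` (data.frame of `cell_id`, `lon`, `lat`,
#'   `area_km2` in row-major order, longitude varying fastest).
#' @export
#' @examples
#' g <- fire_grid(nlon = 40, nlat = 20, lat_min = 40)
#' sum(g$cells$area_km2)
fire_grid <- function(nlon = 40, nlat = 20, resolution = 0.5,
                      lon_min = 0, lat_min = -nlat * resolution / 2) {
  if (length(nlon) != 1 || !is.finite(nlon) || nlon < 1)
    stop("invalid grid: nlon must be a positive integer")
  if (length(nlat) != 1 || !is.finite(nlat) || nlat < 1)
    stop("invalid grid: nlat must be a positive integer")
  if (resolution <= 0) stop("invalid grid: resolution must be positive")
  if (lat_min < -90 || lat_min + nlat * resolution > 90 + 1e-9)
    stop("invalid grid: lat range [", lat_min, ", ",
         lat_min + nlat * resolution, "] exceeds [-90, 90]")
  nlon <- as.integer(nlon); nlat <- as.integer(nlat)
  lon <- lon_min + (seq_len(nlon) - 0.5) * resolution
  lat <- lat_min + (seq_len(nlat) - 0.5) * resolution
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  cells$cell_id <- seq_len(nrow(cells))
  cells$area_km2 <- cell_area_km2(cells$lat, resolution)
  structure(
    list(lon = lon, lat = lat, resolution = resolution,
         nlon = nlon, nlat = nlat,
         cells = cells[, c("cell_id", "lon", "lat", "area_km2")]),
    class = "fire_grid"
  )
}

#' Spherical area of grid cells
#'
#' @param lat_center Cell-centre latitudes, degrees north.
#' @param resolution Cell size, degrees.
#' @param radius_km Earth radius, km.
#' @return Cell areas, km^2.
#' @export
cell_area_km2 <- function(lat_center, resolution = 0.5, radius_km = 6371) {
  half <- resolution / 2
  dlam <- resolution * pi / 180
  radius_km^2 * dlam *
    (sin(pmin(lat_center + half, 90) * pi / 180) -
     sin(pmax(lat_center - half, -90) * pi / 180))
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf("fire_grid: %d x %d cells at %.2f deg (lon %.2f..%.2f, lat %.2f..%.2f)\n",
              x$nlon, x$nlat, x$resolution,
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  total area %.4g km^2\n", sum(x$cells$area_km2)))
  invisible(x)
}

n_cells <- function(grid) nrow(grid$cells)
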