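#' Define a regular longitude-latitude grid
#'
#' All gridded fields in a run share one grid. Cells are cell-center
#' registered: the stored coordinates are cell midpoints, and the extent
#' arguments are the outer cell edges. The default steps correspond to the
#' 0.5 degree x 0.667 degree resolution of nested regional chemical-transport
#' simulations.
#'
#' @param lon_min,lon_max,lat_min,lat_max Outer edges of the domain, degrees.
#' @param dlon Longitude step in degrees (default 2/3).
#' @param dlat Latitude step in degrees (default 0.5).
#' @return An object of class `ch_grid` with cell-center coordinate vectors
#'   `lon` (ascending) and `lat` (ascending), cell counts `nlon`, `nlat`.
#' @examples
#' g <- ch_grid(100, 116, 20, 35)
#' c(g$nlon, g$nlat)
#' @export
ch_grid <- function(lon_min, lon_max, lat_min, lat_max,
                    dlon = 2 / 3, dlat = 0.5) {
  ch_check(lon_max > lon_min && lat_max > lat_min,
           "grid extent must be positive in both axes")
  nlon <- round((lon_max - lon_min) / dlon)
  nlat <- round((lat_max - lat_min) / dlat)
  ch_check(abs(nlon * dlon - (lon_max - lon_min)) < 1e-6 * dlon &&
           abs(nlat * dlat - (lat_max - lat_min)) < 1e-6 * dlat,
           "grid extent is not an integer number of steps (%g x %g requested)",
           (lon_max - lon_min) / dlon, (lat_max - lat_min) / dlat)
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    dlon = dlon, dlat = dlat, nlon = nlon, nlat = nlat,
    lon = lon_min + dlon * (seq_len(nlon) - 0.5),
    lat = lat_min + dlat * (seq_len(nlat) - 0.5),
    registration = "center"
  ), class = "ch_grid")
}

#' @export
print.ch_grid <- function(x, ...) {
  cat(sprintf("<ch_grid> %d x %d cells (lat x lon), dlat=%g dlon=%.4g\n",
              x$nlat, x$nlon, x$dlat, x$dlon))
  cat(sprintf("  lon [%g, %g], lat [%g, %g], cell-center registered\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  a$nlon == b$nlon && a$nlat == b$nlat &&
    max(abs(c(a$lon - b$lon, a$lat - b$lat))) <= tol
}

## Empty field on a grid: matrix [nlat, nlon], lat ascending in rows.
ch_field <- function(grid, value = 0) {
  matrix(value, nrow = grid$nlat, ncol = grid$nlon,
         dimnames = list(NULL, NULL))
}

check_field <- function(x, grid, name = "field") {
  ch_check(is.matrix(x) && nrow(x) == grid$nlat && ncol(x) == grid$nlon,
           "%s has dimensions %s, grid expects %d x %d (lat x lon)",
           name, paste(dim(x), collapse = " x "), grid$nlat, grid$nlon)
  ch_check(all(is.finite(x)), "%s contains non-finite values", name)
  invisible(x)
}

#' Assign each grid cell to the nearest of a set of centroids
#'
#' Province geometry enters the pipeline only as a cell-to-province label
#' map; this helper builds one by nearest-centroid (Voronoi) assignment of
#' cell centers, which is how the synthetic scenarios lay out provinces.
#'
#' @param grid A [ch_grid()].
#' @param centroids Matrix or data.frame with columns `lon`, `lat`, one row
#'   per province, in province order.
#' @return Integer matrix `[nlat, nlon]` of province indices.
#' @export
province_cell_map <- function(grid, centroids) {
  centroids <- as.data.frame(centroids)
  ch_check(all(c("lon", "lat") %in% names(centroids)),
           "centroids need lon and lat columns")
  lon <- matrix(grid$lon, grid$nlat, grid$nlon, byrow = TRUE)
  lat <- matrix(grid$lat, grid$nlat, grid$nlon)
  d2 <- vapply(seq_len(nrow(centroids)), function(i) {
    (lon - centroids$lon[i])^2 + (lat - centroids$lat[i])^2
  }, ch_field(grid))
  map <- apply(d2, c(1, 2), which.min)
  matrix(as.integer(map), grid$nlat, grid$nlon)
}
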