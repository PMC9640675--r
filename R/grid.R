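# Spatial frame: latitude/longitude cell edges, spherical cell areas and an
# ocean mask. All gridded fields in the package live on one of these grids.

#' Earth radius used throughout, in metres.
#' @keywords internal
EARTH_RADIUS_M <- 6.371e6

#' Build a regular latitude-longitude grid geometry
#'
#' Constructs the spatial frame used by every gridded field in the package:
#' cell edges, exact spherical cell areas and an ocean mask. Cell areas follow
#' the spherical formula \eqn{R_e^2 \Delta\lambda (\sin\phi_t - \sin\phi_b)},
#' so the areas of all cells (land and ocean) sum to the area of the sphere,
#' \eqn{4\pi R_e^2}.
#'
#' @param res_lat Latitude resolution in degrees; 180 must be divisible by it.
#' @param res_lon Longitude resolution in degrees; 360 must be divisible by
#'   it. Defaults to `res_lat`.
#' @param ocean_mask Optional logical matrix (`n_lat` x `n_lon`) marking ocean
#'   cells. The default is an all-ocean ("aquaplanet") mask; a land template
#'   can be injected here.
#' @return An object of class `ocean_grid`: a list with `lat_edges`,
#'   `lon_edges`, `lat_centers`, `lon_centers`, `cell_area` (m^2 matrix,
#'   latitude by longitude) and `ocean_mask`.
#' @examples
#' g <- generate_grid(2, 2.5)
#' sum(g$cell_area) / (4 * pi * 6.371e6^2)  # ~1
#' @export
generate_grid <- function(res_lat, res_lon = res_lat, ocean_mask = NULL) {
  stopifnot_scalar_number(res_lat, "res_lat")
  stopifnot_scalar_number(res_lon, "res_lon")
  if (res_lat < 0.1 || res_lat > 90)
    abort_config("latitude resolution must be in [0.1, 90] degrees")
  if (res_lon < 0.1 || res_lon > 360)
    abort_config("longitude resolution must be in [0.1, 360] degrees")
  n_lat <- 180 / res_lat
  n_lon <- 360 / res_lon
  if (abs(n_lat - round(n_lat)) > 1e-9 || abs(n_lon - round(n_lon)) > 1e-9)
    abort_config("180 and 360 must be divisible by the lat/lon resolutions")
  n_lat <- as.integer(round(n_lat)); n_lon <- as.integer(round(n_lon))

  lat_edges <- seq(-90, 90, length.out = n_lat + 1L)
  lon_edges <- seq(0, 360, length.out = n_lon + 1L)
  lat_centers <- (lat_edges[-1L] + lat_edges[-(n_lat + 1L)]) / 2
  lon_centers <- (lon_edges[-1L] + lon_edges[-(n_lon + 1L)]) / 2

  cell_area <- cell_areas(lat_edges, lon_edges)
  if (is.null(ocean_mask)) {
    ocean_mask <- matrix(TRUE, n_lat, n_lon)
  } else {
    if (!is.logical(ocean_mask) || !identical(dim(ocean_mask), dim(cell_area)))
      abort_shape("ocean_mask must be a logical matrix matching the grid shape")
  }

  structure(
    list(lat_edges = lat_edges, lon_edges = lon_edges,
         lat_centers = lat_centers, lon_centers = lon_centers,
         cell_area = cell_area, ocean_mask = ocean_mask),
    class = "ocean_grid")
}

#' Spherical cell areas from edge vectors
#'
#' @param lat_edges,lon_edges Monotone edge vectors in degrees.
#' @return Matrix of areas (m^2), `length(lat_edges)-1` rows.
#' @keywords internal
cell_areas <- function(lat_edges, lon_edges) {
  phi <- lat_edges * pi / 180
  dlam <- diff(lon_edges) * pi / 180
  band <- EARTH_RADIUS_M^2 * diff(sin(phi))   # per unit radian of longitude
  outer(band, dlam)
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf("<ocean_grid> %d x %d cells (%.3g x %.3g deg), %d ocean cells\n",
              length(x$lat_centers), length(x$lon_centers),
              diff(x$lat_edges[1:2]), diff(x$lon_edges[1:2]),
              sum(x$ocean_mask)))
  invisible(x)
}

#' Area-weighted global integral of an areal field
#'
#' Integrates a field in g N m^-2 yr^-1 over the ocean cells of its grid and
#' converts to Tg N yr^-1 (1 Tg = 1e12 g).
#'
#' @param field A `gridded_field` or a bare numeric matrix on `grid`.
#' @param grid An `ocean_grid`.
#' @return Scalar, Tg N yr^-1.
#' @export
global_integral <- function(field, grid) {
  v <- field_values(field)
  if (!identical(dim(v), dim(grid$cell_area)))
    abort_shape("field shape does not match grid shape")
  sum(v[grid$ocean_mask] * grid$cell_area[grid$ocean_mask]) / 1e12
}

#' Area-weighted mean over ocean cells
#' @keywords internal
area_weighted_mean <- function(values, grid) {
  w <- grid$cell_area[grid$ocean_mask]
  sum(values[grid$ocean_mask] * w) / sum(w)
}
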