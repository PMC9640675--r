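# Lossless text serialization of ocean states: a one-row-per-cell CSV body
# preceded by '#'-comment attribute lines (era, grid edges, per-variable
# units). Doubles are written with %.17g so the round trip is bit-exact.

STATE_CORE_VARS <- c("ph_t", "po4", "dop", "nf", "r_tr")

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an ocean state to a self-describing CSV file
#'
#' The header comment lines carry the era, the grid edge vectors and the units
#' of each variable; the body has one row per grid cell with lat/lon indices,
#' the ocean flag and every field. Values round-trip bit-for-bit through
#' [read_state()].
#'
#' @param state An `ocean_state`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_state <- function(state, path) {
  g <- state$grid
  aux_names <- names(state$aux_limits)
  vars <- c(STATE_CORE_VARS, paste0("aux_limit_", aux_names))
  flds <- c(list(state$ph_t, state$po4, state$dop, state$nf, state$r_tr),
            unname(state$aux_limits))
  units <- vapply(flds, function(f) f$units, character(1))

  hdr <- c(
    "# trichoproj ocean_state v1",
    paste0("# era: ", state$era),
    paste0("# lat_edges: ", paste(fmt17(g$lat_edges), collapse = " ")),
    paste0("# lon_edges: ", paste(fmt17(g$lon_edges), collapse = " ")),
    paste0("# units: ", paste(sprintf("%s=%s", vars, units), collapse = ";")))

  idx <- expand.grid(lat = seq_along(g$lat_centers),
                     lon = seq_along(g$lon_centers))
  cols <- c(list(lat_index = idx$lat, lon_index = idx$lon,
                 ocean = as.integer(g$ocean_mask[cbind(idx$lat, idx$lon)])),
            stats::setNames(lapply(flds, function(f)
              fmt17(f$values[cbind(idx$lat, idx$lon)])), vars))
  body <- do.call(paste, c(cols, sep = ","))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, paste(c("lat_index", "lon_index", "ocean", vars),
                          collapse = ","), body), con)
  invisible(path)
}

#' Read an ocean state written by [write_state()]
#'
#' @param path File path.
#' @return An `ocean_state`.
#' @export
read_state <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("trichoproj ocean_state", hdr[1]))
    abort_format("not a trichoproj ocean_state file")

  get_attr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) abort_format(sprintf("missing header attribute '%s'", key))
    trimws(sub(paste0("# ", key, ":"), "", ln[1], fixed = TRUE))
  }
  era <- get_attr("era")
  lat_edges <- as.numeric(strsplit(get_attr("lat_edges"), " +")[[1]])
  lon_edges <- as.numeric(strsplit(get_attr("lon_edges"), " +")[[1]])
  units_map <- strsplit(strsplit(get_attr("units"), ";")[[1]], "=")
  units <- stats::setNames(vapply(units_map, `[`, character(1), 2),
                           vapply(units_map, `[`, character(1), 1))

  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                         colClasses = "character")
  for (v in c(STATE_CORE_VARS, "lat_index", "lon_index", "ocean"))
    if (!v %in% names(tab))
      abort_format(sprintf("missing required variable '%s'", v))

  n_lat <- length(lat_edges) - 1L; n_lon <- length(lon_edges) - 1L
  mk <- function(col) {
    m <- matrix(NA_real_, n_lat, n_lon)
    m[cbind(as.integer(tab$lat_index), as.integer(tab$lon_index))] <-
      as.numeric(col)
    m
  }
  mask <- matrix(FALSE, n_lat, n_lon)
  mask[cbind(as.integer(tab$lat_index), as.integer(tab$lon_index))] <-
    as.integer(tab$ocean) == 1L
  grid <- generate_grid(diff(lat_edges[1:2]), diff(lon_edges[1:2]),
                        ocean_mask = mask)

  gf <- function(v) gridded_field(v, units[[v]], mk(tab[[v]]), era)
  aux_vars <- grep("^aux_limit_", names(tab), value = TRUE)
  structure(
    list(era = era, grid = grid,
         ph_t = gf("ph_t"), po4 = gf("po4"), dop = gf("dop"),
         nf = gf("nf"), r_tr = gf("r_tr"),
         aux_limits = stats::setNames(lapply(aux_vars, gf),
                                      sub("^aux_limit_", "", aux_vars))),
    class = "ocean_state")
}
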