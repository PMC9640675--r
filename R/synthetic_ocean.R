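# Seeded synthetic gridded-ocean fields for two eras (1981-2000, 2081-2100),
# standing in for Earth-system-model (CESM/BEC-like) output so the projection
# pipeline is testable end to end without external downloads.

ERAS <- c("1981-2000", "2081-2100")

#' Construct a gridded field
#'
#' @param name Variable identifier.
#' @param units Unit string.
#' @param values Numeric matrix on the grid (NA on land).
#' @param era Era label, one of `"1981-2000"`, `"2081-2100"`.
#' @return A `gridded_field` object.
#' @export
gridded_field <- function(name, units, values, era) {
  if (!era %in% ERAS) abort_config(sprintf("unknown era '%s'", era))
  structure(list(name = name, units = units, values = values, era = era),
            class = "gridded_field")
}

#' Extract the value matrix from a field or matrix
#' @keywords internal
field_values <- function(field) {
  if (inherits(field, "gridded_field")) field$values else field
}

#' @export
print.gridded_field <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<gridded_field> %s [%s], era %s, %d x %d, range [%.4g, %.4g]\n",
              x$name, x$units, x$era, nrow(x$values), ncol(x$values),
              min(v), max(v)))
  invisible(x)
}

#' Configuration for the synthetic ocean generator
#'
#' Defaults encode the study conditions of the projection: a global marine N2
#' fixation of 155 Tg N yr^-1 in 1981-2000 falling to 130 Tg N yr^-1 by
#' 2081-2100 under a high-emission scenario, a Trichodesmium contribution
#' whose area-weighted mean matches the corresponding global Trichodesmium
#' integrals (60 and 47.4 Tg N yr^-1), and era-mean surface pH of 8.05
#' (historic) and 7.80 (end of century) on the total scale.
#'
#' @param res_lat,res_lon Grid resolution in degrees.
#' @param nf_target_tg Named per-era global N2 fixation targets, Tg N yr^-1.
#' @param r_tr_target Named per-era area-weighted mean Trichodesmium fraction.
#' @param ph_mean Named per-era mean pH (total scale).
#' @param ph_spread Per-cell pH standard deviation.
#' @param po4_meanlog,po4_sdlog Log-normal parameters for phosphate
#'   (mmol m^-3).
#' @param dop_ratio,dop_sdlog DOP is `dop_ratio * PO4` times log-normal noise
#'   with `sdlog = dop_sdlog`.
#' @param nf_envelope_width_deg Latitudinal e-folding half width (degrees) of
#'   the tropical N2-fixation envelope.
#' @param nf_sdlog Log-normal noise on the N2 fixation field.
#' @param aux_ranges Named list of 2-vectors: uniform ranges for auxiliary
#'   (non-P) limitation factors.
#' @param seed Integer seed; identical config implies identical output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(res_lat = 2, res_lon = 2.5,
                             nf_target_tg = c("1981-2000" = 155, "2081-2100" = 130),
                             r_tr_target = c("1981-2000" = 60 / 155,
                                             "2081-2100" = 47.4 / 130),
                             ph_mean = c("1981-2000" = 8.05, "2081-2100" = 7.80),
                             ph_spread = 0.03,
                             po4_meanlog = log(0.03), po4_sdlog = 1,
                             dop_ratio = 1.5, dop_sdlog = 0.3,
                             nf_envelope_width_deg = 25,
                             nf_sdlog = 0.5,
                             aux_ranges = list(fe = c(0.1, 0.9),
                                               n = c(0.3, 1.0)),
                             seed = 1L) {
  cfg <- list(res_lat = res_lat, res_lon = res_lon,
              nf_target_tg = nf_target_tg, r_tr_target = r_tr_target,
              ph_mean = ph_mean, ph_spread = ph_spread,
              po4_meanlog = po4_meanlog, po4_sdlog = po4_sdlog,
              dop_ratio = dop_ratio, dop_sdlog = dop_sdlog,
              nf_envelope_width_deg = nf_envelope_width_deg,
              nf_sdlog = nf_sdlog, aux_ranges = aux_ranges,
              seed = as.integer(seed))
  if (any(cfg$nf_target_tg <= 0) || any(cfg$r_tr_target <= 0))
    abort_config("synthetic targets must be positive")
  if (cfg$ph_spread < 0) abort_config("ph_spread must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate one era's synthetic ocean state
#'
#' All draws come from a single generator stream seeded from
#' `config$seed` and the era, in a documented order: pH, PO4, DOP noise, N2
#' fixation noise, R_Tr noise, then each auxiliary limitation factor in list
#' order. The N2 fixation field is a tropical-peaked latitude envelope times
#' log-normal noise, rescaled so its area-weighted global integral equals the
#' configured target exactly; R_Tr is a smooth latitude-dependent fraction
#' plus noise, clipped to \[0, 1\] and iteratively rescaled so its
#' area-weighted mean matches the configured target within 1 percent.
#'
#' @param config A [synthetic_config()].
#' @param era `"1981-2000"` or `"2081-2100"`.
#' @param grid Optional pre-built `ocean_grid`; defaults to the configured
#'   resolution with an all-ocean mask.
#' @return An `ocean_state`: list with `era`, `grid`, and gridded fields
#'   `ph_t` (total-scale pH), `po4`, `dop` (mmol m^-3), `nf`
#'   (g N m^-2 yr^-1), `r_tr` (fraction), `aux_limits` (named list of
#'   fractions).
#' @export
generate_ocean_state <- function(config, era, grid = NULL) {
  if (!inherits(config, "synthetic_config")) abort_config("config must be a synthetic_config")
  if (!era %in% ERAS) abort_config(sprintf("unknown era '%s'", era))
  if (is.null(grid)) grid <- generate_grid(config$res_lat, config$res_lon)

  # one stream per (seed, era); era index keeps the two eras independent
  set.seed(config$seed + 7919L * (match(era, ERAS) - 1L))
  nl <- length(grid$lat_centers); no <- length(grid$lon_centers)
  shape <- c(nl, no)
  latm <- matrix(grid$lat_centers, nl, no)

  draw <- function(fun, ...) matrix(fun(nl * no, ...), nl, no)

  ph <- draw(stats::rnorm, mean = config$ph_mean[[era]], sd = config$ph_spread)
  ph <- pmin(pmax(ph, 7.0 + 1e-6), 9.0 - 1e-6)

  # oligotrophic-gyre structure: phosphate depressed in the subtropics
  gyre <- -0.8 * exp(-((abs(latm) - 25) / 12)^2)
  po4 <- exp(config$po4_meanlog + gyre + config$po4_sdlog * draw(stats::rnorm))
  dop <- config$dop_ratio * po4 *
    exp(config$dop_sdlog * draw(stats::rnorm) - config$dop_sdlog^2 / 2)

  env <- exp(-(latm / config$nf_envelope_width_deg)^2)
  nf <- env * exp(config$nf_sdlog * draw(stats::rnorm) - config$nf_sdlog^2 / 2)
  nf[!grid$ocean_mask] <- NA_real_
  tot <- sum(nf[grid$ocean_mask] * grid$cell_area[grid$ocean_mask]) / 1e12
  nf <- nf * (config$nf_target_tg[[era]] / tot)

  rtr <- 0.5 * exp(-(latm / 35)^2) + 0.05 * draw(stats::rnorm)
  rtr <- rescale_fraction(rtr, grid, config$r_tr_target[[era]])

  aux <- lapply(config$aux_ranges, function(rg)
    draw(stats::runif, min = rg[1], max = rg[2]))

  mask_na <- function(v) { v[!grid$ocean_mask] <- NA_real_; v }
  gf <- function(name, units, v) gridded_field(name, units, mask_na(v), era)

  structure(
    list(era = era, grid = grid,
         ph_t = gf("ph_t", "pH (total scale)", ph),
         po4  = gf("po4", "mmol m-3", po4),
         dop  = gf("dop", "mmol m-3", dop),
         nf   = gf("nf", "g N m-2 yr-1", nf),
         r_tr = gf("r_tr", "1", rtr),
         aux_limits = lapply(names(aux), function(nm)
           gf(paste0("aux_limit_", nm), "1", aux[[nm]])) |>
           stats::setNames(names(aux))),
    class = "ocean_state")
}

# clip to [0,1] and rescale until the area-weighted mean hits the target
rescale_fraction <- function(x, grid, target, tol = 0.01, max_iter = 50L) {
  x <- pmin(pmax(x, 0), 1)
  for (i in seq_len(max_iter)) {
    m <- area_weighted_mean(x, grid)
    if (abs(m - target) <= tol * target) break
    x <- pmin(pmax(x * (target / m), 0), 1)
  }
  x
}

#' @export
print.ocean_state <- function(x, ...) {
  cat(sprintf("<ocean_state> era %s on %d x %d grid\n", x$era,
              length(x$grid$lat_centers), length(x$grid$lon_centers)))
  for (f in c(list(x$ph_t, x$po4, x$dop, x$nf, x$r_tr), x$aux_limits)) print(f)
  cat(sprintf("  global NF integral: %.4g Tg N yr-1; area-weighted mean R_Tr: %.4g\n",
              global_integral(x$nf, x$grid),
              area_weighted_mean(x$r_tr$values, x$grid)))
  invisible(x)
}

#' Validate the invariants of an ocean state
#'
#' Checks field shapes against the grid, the \[0, 1\] bounds on `r_tr` and the
#' auxiliary limitation factors, non-negativity of concentrations and rates,
#' and the (7, 9) pH range on ocean cells.
#'
#' @param state An `ocean_state`.
#' @return Invisibly `TRUE`; aborts with a domain/shape error otherwise.
#' @export
validate_ocean_state <- function(state) {
  g <- state$grid
  ocean <- g$ocean_mask
  flds <- c(list(state$ph_t, state$po4, state$dop, state$nf, state$r_tr),
            state$aux_limits)
  for (f in flds) {
    if (!identical(dim(f$values), dim(g$cell_area)))
      abort_shape(sprintf("field '%s' shape does not match grid", f$name))
    if (any(!is.finite(f$values[ocean])))
      abort_domain(sprintf("field '%s' has missing values on ocean cells", f$name))
  }
  chk <- function(cond, msg) if (!cond) abort_domain(msg)
  chk(all(state$ph_t$values[ocean] > 7 & state$ph_t$values[ocean] < 9),
      "ph_t outside (7, 9)")
  chk(all(state$po4$values[ocean] >= 0), "negative po4")
  chk(all(state$dop$values[ocean] >= 0), "negative dop")
  chk(all(state$nf$values[ocean] >= 0), "negative nf")
  chk(all(state$r_tr$values[ocean] >= 0 & state$r_tr$values[ocean] <= 1),
      "r_tr outside [0, 1]")
  for (f in state$aux_limits)
    chk(all(f$values[ocean] >= 0 & f$values[ocean] <= 1),
        sprintf("%s outside [0, 1]", f$name))
  invisible(TRUE)
}
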