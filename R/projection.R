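# The projection itself: linear hydrogen-ion scalings of Trichodesmium N2
# fixation calibrated on the laboratory [H+] interval, applied per grid cell
# to the reference climatology NF * R_Tr and integrated to Tg N yr^-1.

#' Convert total-scale pH to hydrogen-ion concentration (and back)
#'
#' @param ph_t pH on the total scale, in (0, 14).
#' @return `[H+]` in mol L^-1.
#' @export
h_from_ph <- function(ph_t) {
  v <- field_values(ph_t)
  if (any(v <= 0 | v >= 14, na.rm = TRUE))
    abort_domain("pH must lie in (0, 14)")
  10^(-v)
}

#' @param h Hydrogen-ion concentration, mol L^-1, > 0.
#' @rdname h_from_ph
#' @export
ph_from_h <- function(h) {
  if (any(h <= 0, na.rm = TRUE)) abort_domain("[H+] must be > 0")
  -log10(h)
}

# shared linear coordinate on the calibration interval
h_fraction <- function(h_s, params) {
  if (!(params$h1 > params$h0)) abort_config("need h1 > h0")
  if (any(field_values(h_s) <= 0, na.rm = TRUE))
    abort_domain("[H+] must be > 0")
  (field_values(h_s) - params$h0) / (params$h1 - params$h0)
}

#' Acidification scaling factor, P-replete form
#'
#' N2 fixation is assumed to decline linearly with `[H+]`:
#' `factor = 1 + oa * ([H+]_s - h0) / (h1 - h0)`, interpolated inside and
#' extrapolated outside the calibration interval, clamped below at 0 (a
#' fixation rate cannot go negative). At `h0` the factor is 1; at `h1` it is
#' `1 + oa` (0.816 at the default -18.4% decline).
#'
#' @param h_s Simulated hydrogen-ion concentration(s), mol L^-1.
#' @param params An [effect_params()].
#' @return Dimensionless multiplicative factor(s).
#' @export
oa_scaling_factor <- function(h_s, params = effect_params()) {
  pmax(1 + params$oa * h_fraction(h_s, params), 0)
}

#' Acidification scaling factor, P-limited form
#'
#' Under P limitation acidification reduces both C biomass and the C
#' biomass-specific N2 fixation rate; the combined factor is the product
#' `(1 + oap_c * x) * (1 + oap_n * x)` with `x = ([H+]_s - h0)/(h1 - h0)`,
#' each bracket clamped below at 0 before multiplying. At `h1` with the
#' default parameters the factor is `0.608 * 0.899 = 0.5466`, a ~45%
#' reduction.
#'
#' @inheritParams oa_scaling_factor
#' @export
oap_scaling_factor <- function(h_s, params = effect_params()) {
  x <- h_fraction(h_s, params)
  pmax(1 + params$oap_c * x, 0) * pmax(1 + params$oap_n * x, 0)
}

#' Project Trichodesmium N2 fixation under acidification
#'
#' Forms the reference climatology `NF_Tr = NF * R_Tr` per cell and applies
#' the hydrogen-ion scaling: under `scenario = "oa_only"` the P-replete factor
#' everywhere; under `"oa_plus_p"` the stronger P-limited factor on the cells
#' of `p_mask` and the P-replete factor elsewhere. Global area-weighted
#' integrals (Tg N yr^-1) of the reference, projection and their difference
#' are attached.
#'
#' @param state An `ocean_state` (the climatology being scaled).
#' @param params An [effect_params()].
#' @param p_mask Logical matrix of P-limited cells (required for
#'   `oa_plus_p`; ignored for `oa_only`).
#' @param scenario `"oa_only"` or `"oa_plus_p"`.
#' @return An `nf_projection` object: gridded `reference`, `projected`,
#'   `delta` fields, scalars `global_reference`, `global_projected`,
#'   `global_delta` (Tg N yr^-1), the scenario, the parameters, and
#'   `any_factor_above_one` flagging alkaline-side extrapolation beyond the
#'   anchor.
#' @export
project_nf <- function(state, params = effect_params(), p_mask = NULL,
                       scenario = c("oa_only", "oa_plus_p")) {
  scenario <- match.arg(scenario)
  g <- state$grid
  for (nm in c("nf", "r_tr", "ph_t"))
    if (is.null(state[[nm]])) abort_config(sprintf("state is missing field '%s'", nm))
  nf <- field_values(state$nf); rtr <- field_values(state$r_tr)
  if (!identical(dim(nf), dim(g$cell_area)) || !identical(dim(rtr), dim(nf)))
    abort_shape("state fields do not share the grid geometry")

  h_s <- h_from_ph(state$ph_t)
  fac <- oa_scaling_factor(h_s, params)
  if (scenario == "oa_plus_p") {
    if (is.null(p_mask)) abort_config("scenario 'oa_plus_p' needs a P-limited mask")
    pm <- field_values(p_mask)
    if (!identical(dim(pm), dim(nf))) abort_shape("p_mask shape does not match state")
    fac_p <- oap_scaling_factor(h_s, params)
    use_p <- !is.na(pm) & pm
    fac[use_p] <- fac_p[use_p]
  }

  reference <- nf * rtr
  projected <- reference * fac
  delta <- projected - reference

  mk <- function(name, v) gridded_field(name, "g N m-2 yr-1", v, state$era)
  res <- list(
    reference = mk("nf_tr_reference", reference),
    projected = mk(sprintf("nf_tr_%s", scenario), projected),
    delta = mk("nf_tr_delta", delta),
    global_reference = global_integral(reference, g),
    global_projected = global_integral(projected, g),
    scenario = scenario, era = state$era, params = params,
    grid = g,
    any_factor_above_one = any(fac > 1, na.rm = TRUE))
  res$global_delta <- res$global_projected - res$global_reference
  structure(res, class = "nf_projection")
}

#' @export
print.nf_projection <- function(x, ...) {
  cat(sprintf("<nf_projection> scenario %s, era %s\n", x$scenario, x$era))
  cat(sprintf("  reference: %8.3f Tg N yr-1\n", x$global_reference))
  cat(sprintf("  projected: %8.3f Tg N yr-1\n", x$global_projected))
  cat(sprintf("  delta:     %8.3f Tg N yr-1 (%.2f%%)\n", x$global_delta,
              100 * x$global_delta / x$global_reference))
  if (x$any_factor_above_one)
    cat("  note: some cells sit on the alkaline side of the anchor (factor > 1)\n")
  invisible(x)
}

#' @export
summary.nf_projection <- function(object, ...) {
  d <- field_values(object$delta)
  structure(list(
    scenario = object$scenario, era = object$era,
    global_reference = object$global_reference,
    global_projected = object$global_projected,
    global_delta = object$global_delta,
    percent_delta = 100 * object$global_delta / object$global_reference,
    cell_delta_range = range(d, na.rm = TRUE),
    params = object$params,
    any_factor_above_one = object$any_factor_above_one),
    class = "summary.nf_projection")
}

#' @export
print.summary.nf_projection <- function(x, ...) {
  cat(sprintf("Projection of Trichodesmium N2 fixation (%s, era %s)\n",
              x$scenario, x$era))
  cat(sprintf("  global reference %.3f, projected %.3f, delta %.3f Tg N yr-1 (%.2f%%)\n",
              x$global_reference, x$global_projected, x$global_delta,
              x$percent_delta))
  cat(sprintf("  per-cell delta range: [%.3g, %.3g] g N m-2 yr-1\n",
              x$cell_delta_range[1], x$cell_delta_range[2]))
  print(x$params)
  invisible(x)
}
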