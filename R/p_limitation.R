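# Dual-substrate Michaelis-Menten phosphorus limitation. Both dissolved
# inorganic (PO4) and organic (DOP) phosphorus contribute to one limiting
# factor through a shared denominator; the PO4 half-saturation is lower than
# the DOP one, encoding phosphate as the preferred P source.

#' Phosphorus limitation parameters
#'
#' Half-saturation constants for phosphate and DOP uptake. The numerical
#' values are not observationally constrained here; only their ratio is (the
#' phosphate half-saturation is about 5 times lower than the DOP one). The
#' defaults are package choices, fully overridable.
#'
#' @param k_po4 Phosphate half-saturation, mmol m^-3 (default 0.01).
#' @param k_dop DOP half-saturation, mmol m^-3 (default `5 * k_po4`).
#' @return A `p_limitation_params` list.
#' @export
p_limitation_params <- function(k_po4 = 0.01, k_dop = 5 * k_po4) {
  if (k_po4 <= 0 || k_dop <= 0)
    abort_config("half-saturation constants must be > 0")
  structure(list(k_po4 = k_po4, k_dop = k_dop), class = "p_limitation_params")
}

#' Dual-substrate Michaelis-Menten P limitation factors
#'
#' Computes, element-wise over scalars, vectors or gridded fields,
#' \deqn{V^{PO_4} = \frac{PO_4/K^{PO_4}}{1 + PO_4/K^{PO_4} + DOP/K^{DOP}},
#'       \quad
#'       V^{DOP} = \frac{DOP/K^{DOP}}{1 + PO_4/K^{PO_4} + DOP/K^{DOP}},}
#' and the total P limiting factor \eqn{V^P = V^{PO_4} + V^{DOP}}, bounded in
#' \[0, 1) for finite concentrations and approaching 1 at saturation.
#'
#' @param po4,dop Concentrations (mmol m^-3), >= 0; `gridded_field`s or
#'   numerics of a common shape.
#' @param params A [p_limitation_params()].
#' @return List with `v_po4`, `v_dop`, `v_p` (same shape as the inputs).
#' @export
p_limitation_factors <- function(po4, dop, params = p_limitation_params()) {
  pv <- field_values(po4); dv <- field_values(dop)
  if (any(pv < 0, na.rm = TRUE) || any(dv < 0, na.rm = TRUE))
    abort_domain("concentrations must be >= 0")
  sp <- pv / params$k_po4
  sd_ <- dv / params$k_dop
  den <- 1 + sp + sd_
  list(v_po4 = sp / den, v_dop = sd_ / den, v_p = (sp + sd_) / den)
}

#' Identify P-limited grid cells
#'
#' In `argmin` mode (default) a cell is P-limited iff its P limiting factor is
#' strictly below every auxiliary (non-P) limitation factor there; ties
#' resolve to not-P-limited, so the stronger P-limited scaling is applied
#' conservatively. In `threshold` mode a cell is P-limited iff `v_p <
#' threshold`.
#'
#' @param v_p P limiting factor: `gridded_field` or matrix.
#' @param aux_limits Named list of auxiliary limitation fields on the same
#'   geometry (ignored in threshold mode).
#' @param mode `"argmin"` or `"threshold"`.
#' @param threshold In (0, 1), threshold mode only.
#' @return Logical matrix; NA where `v_p` is NA.
#' @export
p_limited_mask <- function(v_p, aux_limits = list(), mode = c("argmin", "threshold"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  vp <- field_values(v_p)
  if (mode == "threshold") {
    if (!(threshold > 0 && threshold < 1))
      abort_config("threshold must be in (0, 1)")
    return(vp < threshold)
  }
  if (!length(aux_limits))
    abort_config("argmin mode needs at least one auxiliary limitation field")
  out <- !is.na(vp)
  out[is.na(vp)] <- NA
  for (aux in aux_limits) {
    av <- field_values(aux)
    if (!identical(dim(av), dim(vp)))
      abort_shape("auxiliary limitation field shape does not match v_p")
    out <- out & (vp < av)
  }
  out
}
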