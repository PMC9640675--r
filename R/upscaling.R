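# nifH-based diazotroph upscaling: convert marker-gene abundances to
# group-specific volumetric N2 fixation rates and derive each group's
# contribution fraction (R_Tr for Trichodesmium).

#' Per-group diazotroph conversion parameters
#'
#' Group-specific values actually used belong in an editable table (see
#' [read_group_params()]); the defaults here are placeholders exercising the
#' arithmetic, not literature constants.
#'
#' @param group Group identifier (e.g. "Trichodesmium", "UCYN-A", "UCYN-B",
#'   "Richelia").
#' @param nifh_copies_per_cell nifH gene copies per cell, > 0.
#' @param cell_rate Cell-specific N2 fixation rate, fmol N cell^-1 h^-1, >= 0.
#' @param active_hours Daily hours of active fixation, in (0, 24\]
#'   (default 12).
#' @return A `diazotroph_group_params` list.
#' @export
diazotroph_group_params <- function(group, nifh_copies_per_cell, cell_rate,
                                    active_hours = 12) {
  if (nifh_copies_per_cell <= 0) abort_domain("nifh_copies_per_cell must be > 0")
  if (cell_rate < 0) abort_domain("cell_rate must be >= 0")
  if (!(active_hours > 0 && active_hours <= 24))
    abort_config("active_hours must lie in (0, 24]")
  structure(list(group = group,
                 nifh_copies_per_cell = nifh_copies_per_cell,
                 cell_rate = cell_rate, active_hours = active_hours),
            class = "diazotroph_group_params")
}

#' Read a diazotroph group parameter table
#'
#' @param path CSV with columns `group, nifh_copies_per_cell,
#'   cell_rate_fmol_h, active_hours`.
#' @return Named list of [diazotroph_group_params()].
#' @export
read_group_params <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  tab <- utils::read.csv(path)
  need <- c("group", "nifh_copies_per_cell", "cell_rate_fmol_h", "active_hours")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort_format(sprintf("group parameter CSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  out <- lapply(seq_len(nrow(tab)), function(i)
    diazotroph_group_params(tab$group[i], tab$nifh_copies_per_cell[i],
                            tab$cell_rate_fmol_h[i], tab$active_hours[i]))
  stats::setNames(out, tab$group)
}

#' Volumetric group rate from nifH abundance
#'
#' `rate = abundance / nifh_copies_per_cell * cell_rate`: gene copies per
#' litre are converted to cells per litre, then multiplied by the
#' cell-specific rate.
#'
#' @param abundance nifH copies L^-1, >= 0 (scalar, vector or field).
#' @param params A [diazotroph_group_params()].
#' @return fmol N L^-1 h^-1.
#' @export
group_rate_from_nifh <- function(abundance, params) {
  a <- field_values(abundance)
  if (any(a < 0, na.rm = TRUE)) abort_domain("abundance must be >= 0")
  a / params$nifh_copies_per_cell * params$cell_rate
}

#' Scale an hourly rate to a daily rate
#'
#' @param hourly_rate fmol N L^-1 h^-1, >= 0.
#' @param active_hours Daily active hours in (0, 24] (default 12).
#' @return fmol N L^-1 d^-1.
#' @export
daily_rate <- function(hourly_rate, active_hours = 12) {
  if (!(active_hours > 0 && active_hours <= 24))
    abort_config("active_hours must lie in (0, 24]")
  if (any(field_values(hourly_rate) < 0, na.rm = TRUE))
    abort_domain("hourly rate must be >= 0")
  field_values(hourly_rate) * active_hours
}

#' Contribution fraction of each diazotroph group
#'
#' `fraction_g = rate_g / sum(rates)` per sample or per grid cell;
#' Trichodesmium's fraction is the R_Tr used by the projection. Cells where
#' the total rate is zero have undefined fractions and are returned as NA
#' (flagged, to be excluded from masks).
#'
#' @param group_rates Named list (or named numeric vector) of per-group
#'   rates, each >= 0 and of a common shape.
#' @return Named list/vector of fractions of the same shape; NA where the
#'   total is 0. Errors if every total is 0.
#' @export
contribution_fraction <- function(group_rates) {
  vals <- lapply(group_rates, field_values)
  for (v in vals)
    if (any(v < 0, na.rm = TRUE)) abort_domain("rates must be >= 0")
  total <- Reduce(`+`, vals)
  if (all(total == 0, na.rm = TRUE))
    abort("total rate is zero everywhere: fractions undefined",
          "trichoproj_undefined_fraction_error")
  total[total == 0] <- NA_real_
  lapply(vals, function(v) v / total)
}

#' Default parametric abundance regressor
#'
#' A deterministic response surface standing behind the pluggable abundance
#' model contract: log10 abundance linear in a temperature proxy,
#' `log10(a) = intercept_log10 + slope * t`, floored at 0 copies L^-1. The
#' contract is a list with a `predict(predictors)` function returning one
#' abundance matrix per group; any learned model honouring it can be plugged
#' into [map_abundance()].
#'
#' @param intercept_log10,slope Named numeric vectors (one entry per group).
#' @return An `abundance_regressor`.
#' @export
parametric_regressor <- function(intercept_log10 = c(Trichodesmium = 5),
                                 slope = c(Trichodesmium = 0.05)) {
  groups <- names(intercept_log10)
  structure(list(
    groups = groups,
    predict = function(predictors) {
      t_proxy <- field_values(predictors[["temperature"]])
      if (is.null(t_proxy)) abort_config("predictors must include 'temperature'")
      stats::setNames(lapply(groups, function(g)
        10^(intercept_log10[[g]] + slope[[g]] * t_proxy)), groups)
    }),
    class = "abundance_regressor")
}

#' Map environmental predictors to per-group nifH abundance fields
#'
#' Applies a pluggable abundance model over gridded predictors. The bundled
#' default is the deterministic [parametric_regressor()], so the pipeline runs
#' with no learned weights; a trained model with the same `predict` contract
#' can be substituted.
#'
#' @param predictors Named list of gridded predictor fields (matrices or
#'   `gridded_field`s) sharing one geometry.
#' @param regressor An `abundance_regressor`.
#' @return Named list of abundance matrices (copies L^-1), one per group.
#' @export
map_abundance <- function(predictors, regressor = parametric_regressor()) {
  mats <- lapply(predictors, field_values)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L) abort_shape("predictor fields do not share one geometry")
  out <- regressor$predict(predictors)
  for (g in names(out))
    if (any(field_values(out[[g]]) < 0, na.rm = TRUE))
      abort(sprintf("regressor produced negative abundance for group '%s'", g),
            "trichoproj_contract_violation_error")
  out
}
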