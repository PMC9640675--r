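# Chemostat culture arithmetic: normalized rates, elemental ratios, percent
# changes, paired tests and P-quota bookkeeping. calibrate_effects() packages
# the treatment contrasts as the effect parameters of the projection model.

#' Percent change between treatments
#'
#' @param ambient Reference value (> 0).
#' @param acidified Treatment value.
#' @return `100 * (acidified - ambient) / ambient`, sign preserved.
#' @examples
#' percent_change(332, 202)  # POC:POP decline, -39.2 to one decimal
#' @export
percent_change <- function(ambient, acidified) {
  if (any(!is.finite(ambient)) || any(ambient <= 0))
    abort_domain("ambient value must be > 0")
  100 * (acidified - ambient) / ambient
}

#' Biomass-normalized rate
#'
#' Divides a per-cell rate by a per-cell elemental quota, e.g. N2 fixation per
#' unit cellular carbon (fmol N (fmol C)^-1 h^-1).
#'
#' @param rate_per_cell Rate, >= 0.
#' @param quota_per_cell Quota, > 0.
#' @export
normalized_rate <- function(rate_per_cell, quota_per_cell) {
  if (any(!is.finite(quota_per_cell)) || any(quota_per_cell <= 0))
    abort_domain("quota must be > 0")
  rate_per_cell / quota_per_cell
}

#' Molar stoichiometric ratio of two cellular quotas
#'
#' @param numerator_quota,denominator_quota Per-cell quotas on the same basis,
#'   both > 0.
#' @export
stoichiometric_ratio <- function(numerator_quota, denominator_quota) {
  if (any(numerator_quota <= 0) || any(denominator_quota <= 0))
    abort_domain("quotas must be > 0")
  numerator_quota / denominator_quota
}

#' Build a culture table of paired replicate measurements
#'
#' @param treatment Character, `"ambient"` or `"acidified"` per row.
#' @param replicate Replicate id per row; each acidified replicate must have
#'   an ambient partner with the same id.
#' @param n2_fix_per_cell,c_fix_per_cell Rates, fmol (N or C) cell^-1 h^-1.
#' @param poc,pon,pop Cellular quotas, fmol (C, N or P) cell^-1.
#' @return A `culture_table` data frame.
#' @export
culture_table <- function(treatment, replicate, n2_fix_per_cell,
                          c_fix_per_cell, poc, pon, pop) {
  tab <- data.frame(treatment = as.character(treatment),
                    replicate = as.character(replicate),
                    n2_fix_per_cell = n2_fix_per_cell,
                    c_fix_per_cell = c_fix_per_cell,
                    poc = poc, pon = pon, pop = pop)
  validate_culture_table(tab)
  class(tab) <- c("culture_table", "data.frame")
  tab
}

validate_culture_table <- function(tab) {
  if (!all(tab$treatment %in% c("ambient", "acidified")))
    abort_domain("treatment must be 'ambient' or 'acidified'")
  num <- c("n2_fix_per_cell", "c_fix_per_cell", "poc", "pon", "pop")
  if (any(!is.finite(as.matrix(tab[num]))) || any(as.matrix(tab[num]) <= 0))
    abort_domain("all culture measurements must be > 0")
  amb <- sort(tab$replicate[tab$treatment == "ambient"])
  acd <- sort(tab$replicate[tab$treatment == "acidified"])
  if (!identical(amb, acd))
    abort("acidified replicates are not paired with ambient replicates",
          "trichoproj_pairing_error")
  if (length(amb) < 2) abort_domain("need >= 2 paired replicates")
  invisible(TRUE)
}

#' Read / write culture tables as CSV
#' @param path CSV path with header columns `treatment, replicate,
#'   n2_fix_per_cell, c_fix_per_cell, poc, pon, pop`.
#' @rdname culture_io
#' @export
read_culture_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  tab <- utils::read.csv(path)
  need <- c("treatment", "replicate", "n2_fix_per_cell", "c_fix_per_cell",
            "poc", "pon", "pop")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort_format(sprintf("culture CSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  do.call(culture_table, tab[need])
}

#' @param table A `culture_table`.
#' @rdname culture_io
#' @export
write_culture_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Effect parameters of the hydrogen-ion scaling model
#'
#' The calibration constants applied per grid cell: the hydrogen-ion anchor
#' concentrations `h0 = 10^-8.01` and `h1 = 10^-7.81` mol L^-1 bounding the
#' laboratory pH interval, the P-replete decline `oa = -18.4%` of the C
#' biomass-specific N2 fixation rate over that interval, and the P-limited
#' declines of C biomass (`oap_c = -39.2%`, from POC:POP) and C
#' biomass-specific N2 fixation rate (`oap_n = -10.1%`).
#'
#' @param h0,h1 Anchor hydrogen-ion concentrations, mol L^-1, `h1 > h0 > 0`.
#' @param oa,oap_c,oap_n Fractional declines over `[h0, h1]`, each in (-1, 0].
#' @return An `effect_params` object.
#' @export
effect_params <- function(h0 = 10^-8.01, h1 = 10^-7.81,
                          oa = -0.184, oap_c = -0.392, oap_n = -0.101) {
  if (!(h1 > h0 && h0 > 0)) abort_config("need h1 > h0 > 0")
  for (v in c(oa, oap_c, oap_n))
    if (!(v > -1 && v <= 0))
      abort_config("effect fractions must lie in (-1, 0]")
  structure(list(h0 = h0, h1 = h1, oa = oa, oap_c = oap_c, oap_n = oap_n),
            class = "effect_params")
}

#' @export
print.effect_params <- function(x, ...) {
  cat("Hydrogen-ion effect parameters\n")
  cat(sprintf("  anchor [H+]: %.4g -> %.4g mol L-1 (pH %.2f -> %.2f)\n",
              x$h0, x$h1, -log10(x$h0), -log10(x$h1)))
  cat(sprintf("  oa (P-replete rate decline):      %+.1f%%\n", 100 * x$oa))
  cat(sprintf("  oap_C (P-limited biomass):        %+.1f%%\n", 100 * x$oap_c))
  cat(sprintf("  oap_N (P-limited specific rate):  %+.1f%%\n", 100 * x$oap_n))
  invisible(x)
}

#' @export
coef.effect_params <- function(object, ...) {
  unlist(object[c("oa", "oap_c", "oap_n")])
}

#' Calibrate effect parameters from a paired culture table
#'
#' Derives the P-limited effect parameters from treatment contrasts:
#' `oap_c` is the fractional change of the treatment-mean POC:POP ratio
#' (acidified vs ambient) and `oap_n` that of the treatment-mean C
#' biomass-specific N2 fixation rate (`n2_fix_per_cell / poc`). Contrasts are
#' computed on treatment means by default, matching how culture stoichiometry
#' is conventionally reported; `per_pair = TRUE` averages per-pair percent
#' changes instead. The P-replete decline `oa` is not derivable from a
#' P-limited table and is accepted as an external constant.
#'
#' @param table A [culture_table()] with >= 2 paired replicates.
#' @param h0,h1 Anchor hydrogen-ion concentrations, mol L^-1.
#' @param oa External P-replete decline fraction (default -0.184).
#' @param per_pair If `TRUE`, average per-pair fractional changes rather than
#'   contrasting treatment means.
#' @return An [effect_params()] object.
#' @export
calibrate_effects <- function(table, h0 = 10^-8.01, h1 = 10^-7.81,
                              oa = -0.184, per_pair = FALSE) {
  validate_culture_table(table)
  tab <- as.data.frame(table)
  tab$poc_pop <- stoichiometric_ratio(tab$poc, tab$pop)
  tab$n2_per_c <- normalized_rate(tab$n2_fix_per_cell, tab$poc)

  contrast <- function(var) {
    if (per_pair) {
      wide <- merge(tab[tab$treatment == "ambient", c("replicate", var)],
                    tab[tab$treatment == "acidified", c("replicate", var)],
                    by = "replicate", suffixes = c("_amb", "_acd"))
      mean(percent_change(wide[[paste0(var, "_amb")]],
                          wide[[paste0(var, "_acd")]])) / 100
    } else {
      m <- tapply(tab[[var]], tab$treatment, mean)
      percent_change(m[["ambient"]], m[["acidified"]]) / 100
    }
  }
  effect_params(h0 = h0, h1 = h1, oa = oa,
                oap_c = contrast("poc_pop"), oap_n = contrast("n2_per_c"))
}

#' Paired Student's t-test on ambient/acidified pairs
#'
#' Classic paired t on the within-pair differences (delegated to
#' [stats::t.test()]), with degrees of freedom `n - 1`. The one-tailed option
#' tests for a decline under acidification (acidified < ambient) and equals
#' half the two-tailed p in that direction.
#'
#' @param ambient,acidified Paired measurement vectors, same length >= 2.
#' @param tails 1 or 2.
#' @return List with `t`, `p`, `df`.
#' @export
paired_t_test <- function(ambient, acidified, tails = 2) {
  if (length(ambient) != length(acidified))
    abort_domain("ambient and acidified must have equal length")
  if (length(ambient) < 2) abort_domain("need >= 2 pairs")
  if (!tails %in% c(1, 2)) abort_domain("tails must be 1 or 2")
  d <- acidified - ambient
  if (stats::sd(d) == 0)
    abort("all paired differences identical: zero variance",
          "trichoproj_degenerate_variance_error")
  alt <- if (tails == 1) "less" else "two.sided"
  tt <- stats::t.test(acidified, ambient, paired = TRUE, alternative = alt)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Cell density from filament measurements
#'
#' Average cell length is total sampled filament length over total sampled
#' cell count; density is total filament length per mL divided by the average
#' cell length.
#'
#' @param total_filament_length_per_ml Total filament length in 1 mL, um.
#' @param sampled_filament_lengths Lengths of ~20 sampled filaments, um.
#' @param sampled_cell_counts Cell counts of the same filaments.
#' @return Cells mL^-1.
#' @export
cells_per_ml <- function(total_filament_length_per_ml,
                         sampled_filament_lengths, sampled_cell_counts) {
  if (length(sampled_filament_lengths) != length(sampled_cell_counts))
    abort_domain("sampled lengths and counts must have equal length")
  if (sum(sampled_cell_counts) <= 0)
    abort_domain("total sampled cell count must be > 0")
  avg_cell <- sum(sampled_filament_lengths) / sum(sampled_cell_counts)
  total_filament_length_per_ml / avg_cell
}

AVOGADRO <- 6.02214076e23

#' Phosphorus quota held in genomic DNA
#'
#' Counts 2 P atoms per base pair (one phosphate per nucleotide on each
#' strand) over a polyploid genome complement.
#'
#' @param genome_bp Genome size in base pairs (Trichodesmium erythraeum
#'   IMS101: 7,750,108 bp).
#' @param ploidy_copies Genome copies per cell (default 100, the polyploidy
#'   assumed under P limitation).
#' @return fmol P cell^-1.
#' @export
dna_p_quota <- function(genome_bp, ploidy_copies = 100) {
  if (genome_bp <= 0 || ploidy_copies <= 0)
    abort_domain("genome size and ploidy must be > 0")
  atoms <- 2 * genome_bp * ploidy_copies
  atoms / AVOGADRO * 1e15
}

#' Phosphorus content of an RNA mass
#'
#' One P per nucleotide residue at the average residue mass of 320.5 g mol^-1
#' within a polynucleotide.
#'
#' @param rna_mass_ng RNA mass in ng, >= 0.
#' @return nmol P.
#' @export
rna_p_quota <- function(rna_mass_ng) {
  if (any(rna_mass_ng < 0)) abort_domain("RNA mass must be >= 0")
  rna_mass_ng / 320.5
}

#' Convert acetylene-reduction ethylene production to N2 fixation
#'
#' Applies the conventional 4:1 ethylene:N2 conversion of the acetylene
#' reduction assay.
#'
#' @param ethylene_rate Ethylene production rate, >= 0 (any unit basis).
#' @return N2 fixation rate on the same basis.
#' @export
ethylene_to_n2 <- function(ethylene_rate) {
  if (any(ethylene_rate < 0)) abort_domain("ethylene rate must be >= 0")
  ethylene_rate / 4
}

#' Simulate a paired culture table with known multiplicative effects
#'
#' Generates `n` paired replicates around ambient means, applies exact
#' multiplicative treatment effects to the acidified arm, and (optionally)
#' multiplies every measurement by log-normal replicate noise. With
#' `noise_sd = 0`, [calibrate_effects()] recovers the injected effects
#' exactly.
#'
#' @param n Number of replicate pairs (default 3, the chemostat design).
#' @param ambient_means Named list of ambient means for `n2_fix_per_cell`,
#'   `c_fix_per_cell`, `poc`, `pon`, `pop`. Defaults give the reported
#'   P-limited stoichiometry (POC:POP 332, PON:POP 48).
#' @param effects Named list of multiplicative treatment effects on the same
#'   measurements. Defaults reproduce the reported declines (POC -22%,
#'   PON -18%, POP +28%, cell-specific N2 fixation -30%, C fixation -17%).
#' @param noise_sd Log-normal sdlog of replicate noise (0 = deterministic).
#' @param seed Integer seed.
#' @return A [culture_table()].
#' @export
simulate_culture_table <- function(n = 3,
                                   ambient_means = list(
                                     n2_fix_per_cell = 1.6,
                                     c_fix_per_cell = 20,
                                     poc = 332, pon = 48, pop = 1),
                                   effects = list(
                                     n2_fix_per_cell = 0.70,
                                     c_fix_per_cell = 0.83,
                                     poc = 0.78, pon = 0.82, pop = 1.28),
                                   noise_sd = 0, seed = 1L) {
  if (n < 2) abort_domain("need n >= 2 pairs")
  set.seed(seed)
  vars <- c("n2_fix_per_cell", "c_fix_per_cell", "poc", "pon", "pop")
  rows <- list()
  for (tr in c("ambient", "acidified")) {
    vals <- lapply(vars, function(v) {
      base <- ambient_means[[v]] * if (tr == "acidified") effects[[v]] else 1
      base * exp(stats::rnorm(n, 0, noise_sd))
    })
    rows[[tr]] <- data.frame(treatment = tr, replicate = as.character(seq_len(n)),
                             stats::setNames(vals, vars))
  }
  tab <- rbind(rows$ambient, rows$acidified)
  do.call(culture_table, tab)
}
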