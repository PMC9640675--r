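test_that("percent change reproduces the reported stoichiometry declines", {
  # POC:POP 332:1 -> 202:1 and PON:POP 48:1 -> 31:1
  expect_equal(round(percent_change(332, 202), 1), -39.2)
  expect_equal(round(percent_change(48, 31)), -35)
  expect_identical(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), class = "trichoproj_domain_error")
})

test_that("percent change is scale invariant and flips sign with direction", {
  set.seed(21)
  for (i in 1:25) {
    a <- rexp(1) + 0.1; b <- rexp(1) + 0.1; k <- rexp(1) + 0.1
    expect_equal(percent_change(k * a, k * b), percent_change(a, b),
                 tolerance = 1e-12)
    expect_identical(sign(percent_change(a, b)), -sign(percent_change(b, a)))
  }
})

test_that("normalized rates and stoichiometric ratios follow the arithmetic", {
  expect_equal(normalized_rate(10, 5), 2)
  expect_equal(normalized_rate(0, 5), 0)
  expect_error(normalized_rate(1, 0), class = "trichoproj_domain_error")
  expect_equal(stoichiometric_ratio(48, 1), 48)
  expect_equal(stoichiometric_ratio(3, 3), 1)
  # POC:POP 202 vs 332 is the same contrast percent_change reports
  expect_equal(stoichiometric_ratio(202, 1) / stoichiometric_ratio(332, 1) - 1,
               percent_change(332, 202) / 100, tolerance = 1e-12)
  expect_error(stoichiometric_ratio(-1, 2), class = "trichoproj_domain_error")
})

test_that("mean normalized rates match a brute-force replicate loop", {
  set.seed(31)
  rate <- rexp(6) + 0.1; quota <- rexp(6) + 0.1
  oracle <- 0
  for (i in 1:6) oracle <- oracle + rate[i] / quota[i]
  oracle <- oracle / 6
  expect_equal(mean(normalized_rate(rate, quota)), oracle, tolerance = 1e-12)
})

test_that("calibration recovers the printed treatment-mean contrasts", {
  tab <- culture_table(
    treatment = rep(c("ambient", "acidified"), each = 3),
    replicate = rep(1:3, 2),
    n2_fix_per_cell = c(1.6, 1.7, 1.5, 0.88, 0.90, 0.85),
    c_fix_per_cell = rep(1, 6),
    poc = c(332, 340, 324, 202, 206, 198),
    pon = c(48, 49, 47, 31, 32, 30),
    pop = rep(1, 6))
  p <- calibrate_effects(tab)
  # treatment-mean POC:POP goes 332 -> 202
  expect_equal(p$oap_c, (202 - 332) / 332, tolerance = 1e-12)
  expect_s3_class(p, "effect_params")
  expect_equal(unname(coef(p)["oa"]), -0.184)
})

test_that("identical treatments give zero effects; unpaired tables error", {
  tab <- culture_table(
    treatment = rep(c("ambient", "acidified"), each = 2),
    replicate = rep(1:2, 2),
    n2_fix_per_cell = rep(1.5, 4), c_fix_per_cell = rep(20, 4),
    poc = rep(300, 4), pon = rep(45, 4), pop = rep(1, 4))
  p <- calibrate_effects(tab)
  expect_equal(p$oap_c, 0)
  expect_equal(p$oap_n, 0)
  expect_error(
    culture_table(treatment = c("ambient", "ambient", "acidified"),
                  replicate = c(1, 2, 1),
                  n2_fix_per_cell = rep(1, 3), c_fix_per_cell = rep(1, 3),
                  poc = rep(1, 3), pon = rep(1, 3), pop = rep(1, 3)),
    class = "trichoproj_pairing_error")
})

test_that("calibration equals brute-force recomputation on a random table", {
  tab <- simulate_culture_table(n = 4, noise_sd = 0.05, seed = 17L)
  p <- calibrate_effects(tab)
  df <- as.data.frame(tab)
  mean_of <- function(tr, f) mean(f(df[df$treatment == tr, ]))
  oc <- mean_of("acidified", \(d) d$poc / d$pop) /
    mean_of("ambient", \(d) d$poc / d$pop) - 1
  on <- mean_of("acidified", \(d) d$n2_fix_per_cell / d$poc) /
    mean_of("ambient", \(d) d$n2_fix_per_cell / d$poc) - 1
  expect_equal(p$oap_c, oc, tolerance = 1e-12)
  expect_equal(p$oap_n, on, tolerance = 1e-12)
})

test_that("known multiplicative effects are recovered exactly without noise and within Monte Carlo error with noise", {
  eff <- list(n2_fix_per_cell = 0.70, c_fix_per_cell = 0.83,
              poc = 0.78, pon = 0.82, pop = 1.28)
  tab0 <- simulate_culture_table(n = 3, effects = eff, noise_sd = 0)
  p0 <- calibrate_effects(tab0)
  expect_equal(p0$oap_c, 0.78 / 1.28 - 1, tolerance = 1e-12)
  expect_equal(p0$oap_n, 0.70 / 0.78 - 1, tolerance = 1e-12)
  # with replicate noise, many-replicate calibration concentrates on the truth
  tabn <- simulate_culture_table(n = 200, effects = eff, noise_sd = 0.05,
                                 seed = 99L)
  pn <- calibrate_effects(tabn)
  expect_equal(pn$oap_c, 0.78 / 1.28 - 1, tolerance = 0.05)
  expect_equal(pn$oap_n, 0.70 / 0.78 - 1, tolerance = 0.05)
})

test_that("per-pair calibration averages pairwise contrasts", {
  tab <- simulate_culture_table(n = 3, noise_sd = 0.05, seed = 3L)
  p <- calibrate_effects(tab, per_pair = TRUE)
  df <- as.data.frame(tab)
  amb <- df[df$treatment == "ambient", ]; acd <- df[df$treatment == "acidified", ]
  amb <- amb[order(amb$replicate), ]; acd <- acd[order(acd$replicate), ]
  expect_equal(p$oap_c,
               mean((acd$poc / acd$pop) / (amb$poc / amb$pop) - 1),
               tolerance = 1e-12)
})

test_that("culture table CSV round-trips and rejects missing columns", {
  tab <- simulate_culture_table(n = 3, noise_sd = 0.1, seed = 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_culture_table(tab, path)
  back <- read_culture_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("treatment,replicate,poc\nambient,1,1", bad)
  expect_error(read_culture_table(bad), class = "trichoproj_format_error")
})

test_that("paired t matches the textbook formula oracle", {
  amb <- c(1, 2, 3, 4); acd <- c(2, 4, 5, 7)
  res <- paired_t_test(amb, acd)
  d <- acd - amb
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$df, 3)
})

test_that("paired t symmetry, tails and degenerate cases behave", {
  d <- 0.5
  amb <- c(1, 2, 3, 4)
  res <- paired_t_test(amb, amb + c(d, -d, d, -d))
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # one-tailed p is half the two-tailed p in the favored (decline) direction
  set.seed(5)
  for (i in 1:10) {
    a <- rexp(5) + 1; b <- a * runif(5, 0.5, 0.95)
    expect_equal(paired_t_test(a, b, tails = 1)$p,
                 paired_t_test(a, b, tails = 2)$p / 2, tolerance = 1e-12)
  }
  # tiny differences against large spread: no significance
  expect_gt(paired_t_test(c(10, 1, 5), c(10.01, 0.98, 5.02))$p, 0.05)
  expect_error(paired_t_test(c(1, 2), c(2, 3)),
               class = "trichoproj_degenerate_variance_error")
  expect_error(paired_t_test(1, 2), class = "trichoproj_domain_error")
})

test_that("cell density from filaments follows the averaging rule", {
  expect_equal(cells_per_ml(1e6, rep(100, 20), rep(20, 20)), 2e5)
  expect_equal(cells_per_ml(100, 100, 10), 10)
  set.seed(41)
  lens <- runif(20, 50, 400); counts <- pmax(1, rpois(20, lens / 6))
  total <- 5e5
  oracle <- total / (sum(lens) / sum(counts))
  expect_equal(cells_per_ml(total, lens, counts), oracle, tolerance = 1e-12)
  expect_error(cells_per_ml(100, c(10, 20), c(0, 0)),
               class = "trichoproj_domain_error")
})

test_that("DNA and RNA phosphorus quotas follow atom/mass bookkeeping", {
  # 2 P per bp x 7,750,108 bp x 100 copies = 1.5500216e9 atoms = 2.574 fmol
  atoms <- 2 * 7750108 * 100
  expect_equal(dna_p_quota(7750108, 100), atoms / 6.02214076e23 * 1e15,
               tolerance = 1e-12)
  expect_equal(round(dna_p_quota(7750108, 100), 3), 2.574)
  expect_equal(dna_p_quota(1, 1) * 1e-15 * 6.02214076e23, 2, tolerance = 1e-9)
  expect_error(dna_p_quota(7750108, 0), class = "trichoproj_domain_error")
  # 1 ug RNA at 320.5 g/mol per residue = 3.120 nmol P
  expect_equal(round(rna_p_quota(1000), 3), 3.120)
  expect_identical(rna_p_quota(0), 0)
  expect_equal(rna_p_quota(320.5), 1)
  expect_error(rna_p_quota(-1), class = "trichoproj_domain_error")
})

test_that("acetylene reduction converts 4:1 to N2 fixation", {
  expect_equal(ethylene_to_n2(8), 2)
  expect_identical(ethylene_to_n2(0), 0)
  expect_equal(ethylene_to_n2(1), 0.25)
  expect_error(ethylene_to_n2(-1), class = "trichoproj_domain_error")
})
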