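test_that("pH <-> [H+] conversion is exact and validated", {
  expect_equal(h_from_ph(8), 1e-8, tolerance = 1e-15)
  expect_equal(h_from_ph(7.81), 10^-7.81, tolerance = 1e-15)
  set.seed(2)
  x <- runif(20, 6, 9)
  expect_equal(ph_from_h(h_from_ph(x)), x, tolerance = 1e-12)
  expect_error(h_from_ph(-1), class = "trichoproj_domain_error")
  expect_error(ph_from_h(0), class = "trichoproj_domain_error")
})

test_that("the P-replete scaling factor interpolates linearly between anchors", {
  p <- effect_params()
  expect_equal(oa_scaling_factor(p$h0, p), 1, tolerance = 1e-12)
  expect_equal(oa_scaling_factor(p$h1, p), 0.816, tolerance = 1e-12)
  expect_equal(oa_scaling_factor((p$h0 + p$h1) / 2, p), 0.908, tolerance = 1e-12)
  # extrapolation below the lower anchor gives factors above 1
  expect_gt(oa_scaling_factor(p$h0 * 0.5, p), 1)
})

test_that("the P-limited scaling factor is the product of two clamped brackets", {
  p <- effect_params()
  expect_equal(oap_scaling_factor(p$h0, p), 1, tolerance = 1e-12)
  expect_equal(oap_scaling_factor(p$h1, p), 0.608 * 0.899, tolerance = 1e-12)
  # midpoint: (1 - 0.196) * (1 - 0.0505)
  expect_equal(oap_scaling_factor((p$h0 + p$h1) / 2, p),
               (1 - 0.196) * (1 - 0.0505), tolerance = 1e-12)
  # far extrapolation clamps each bracket at zero rather than going negative
  h_far <- p$h0 + 10 * (p$h1 - p$h0)
  expect_gte(oap_scaling_factor(h_far, p), 0)
  expect_gte(oa_scaling_factor(h_far, p), 0)
})

test_that("both factors are non-increasing in [H+] and the P-limited one is stronger at the endpoint", {
  p <- effect_params()
  hs <- seq(p$h0, p$h0 + 3 * (p$h1 - p$h0), length.out = 80)
  for (f in list(oa_scaling_factor, oap_scaling_factor)) {
    v <- f(hs, p)
    expect_true(all(diff(v) <= 1e-15))
  }
  expect_lt(oap_scaling_factor(p$h1, p), oa_scaling_factor(p$h1, p))
  expect_equal(c(oap_scaling_factor(p$h1, p), oa_scaling_factor(p$h1, p)),
               c(0.5466, 0.816), tolerance = 1e-3)
})

test_that("a uniform all-P-limited ocean at pH 7.81 loses 45.34% (oa_plus_p) and 18.4% (oa_only)", {
  st <- uniform_state(nf = 1, r_tr = 0.5, ph = 7.81)
  mask <- all_true_mask(st$grid)
  pr <- project_nf(st, effect_params(), p_mask = mask, scenario = "oa_plus_p")
  ratio <- pr$projected$values / pr$reference$values
  expect_equal(unique(as.numeric(ratio)), 0.546592, tolerance = 1e-9)
  expect_equal(100 * pr$global_delta / pr$global_reference, -45.3408,
               tolerance = 1e-6)
  po <- project_nf(st, effect_params(), scenario = "oa_only")
  expect_equal(100 * po$global_delta / po$global_reference, -18.4,
               tolerance = 1e-9)
})

test_that("at the lower anchor pH the projection equals the reference in every scenario", {
  st <- uniform_state(ph = 8.01)
  mask <- all_true_mask(st$grid)
  for (sc in c("oa_only", "oa_plus_p")) {
    pr <- project_nf(st, effect_params(), p_mask = mask, scenario = sc)
    expect_equal(pr$delta$values, pr$reference$values * 0, tolerance = 1e-12)
    expect_equal(pr$global_delta, 0, tolerance = 1e-12)
  }
})

test_that("with an all-false mask oa_plus_p reduces exactly to oa_only", {
  cfg <- synthetic_config(res_lat = 15, res_lon = 15, seed = 12L)
  st <- generate_ocean_state(cfg, "2081-2100")
  none <- matrix(FALSE, length(st$grid$lat_centers), length(st$grid$lon_centers))
  a <- project_nf(st, effect_params(), p_mask = none, scenario = "oa_plus_p")
  b <- project_nf(st, effect_params(), scenario = "oa_only")
  expect_identical(a$projected$values, b$projected$values)
  expect_identical(a$global_projected, b$global_projected)
})

test_that("projection bookkeeping: deltas are consistent and declines are cell-wise non-positive past the anchor", {
  cfg <- synthetic_config(res_lat = 15, res_lon = 15,
                          ph_mean = c("1981-2000" = 8.0, "2081-2100" = 7.85),
                          ph_spread = 0.02, seed = 6L)
  st <- generate_ocean_state(cfg, "2081-2100")
  mask <- p_limited_mask(p_limitation_factors(st$po4, st$dop)$v_p,
                         st$aux_limits)
  pr <- project_nf(st, effect_params(), p_mask = mask, scenario = "oa_plus_p")
  expect_equal(pr$global_delta, pr$global_projected - pr$global_reference,
               tolerance = 1e-9)
  ocean <- st$grid$ocean_mask
  past <- ocean & (h_from_ph(st$ph_t) >= effect_params()$h0)
  expect_true(all(pr$delta$values[past] <= 1e-15))
  # oa_plus_p is never weaker than oa_only on P-limited cells past the anchor
  po <- project_nf(st, effect_params(), scenario = "oa_only")
  sel <- past & !is.na(mask) & mask
  expect_true(all(pr$projected$values[sel] <= po$projected$values[sel] + 1e-15))
})

test_that("projection errors: missing mask, bad geometry, missing fields", {
  st <- uniform_state()
  expect_error(project_nf(st, effect_params(), scenario = "oa_plus_p"),
               class = "trichoproj_config_error")
  bad <- st; bad$nf$values <- matrix(1, 2, 2)
  expect_error(project_nf(bad, effect_params(), scenario = "oa_only"),
               class = "trichoproj_shape_error")
  noph <- st; noph$ph_t <- NULL
  expect_error(project_nf(noph, effect_params(), scenario = "oa_only"),
               class = "trichoproj_config_error")
})

test_that("summary and print surface the global integrals", {
  st <- uniform_state(ph = 7.9)
  pr <- project_nf(st, effect_params(), scenario = "oa_only")
  s <- summary(pr)
  expect_equal(s$percent_delta, 100 * pr$global_delta / pr$global_reference)
  expect_output(print(pr), "Tg N yr-1")
})
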