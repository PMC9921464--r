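test_that("Vickers hardness follows the 136-degree pyramid geometry", {
  hv <- vickers_hardness(1, 1)
  expect_equal(hv$HV_kgf_mm2, 2 * sin(68 * pi / 180), tolerance = 1e-12)
  expect_equal(hv$HV_kgf_mm2, 1.8544, tolerance = 1e-4)
  expect_equal(hv$HV_MPa, 9.80665 * hv$HV_kgf_mm2)
  # doubling the diagonal at fixed force quarters the hardness
  expect_equal(vickers_hardness(1, 2)$HV_kgf_mm2, hv$HV_kgf_mm2 / 4)
  expect_error(vickers_hardness(1, 0), "> 0")
  expect_error(vickers_hardness(-1, 1), "> 0")
})

test_that("Oliver-Pharr analysis inverts the forward model", {
  cfg <- indent_sim_config(target_modulus_MPa = 900, target_hardness_MPa = 60,
                           noise_sd = 0, seed = 1)
  res <- analyze_indentation_curve(generate_indentation_curve(cfg))
  expect_equal(res$H_IT_MPa, 60, tolerance = 0.01)
  expect_equal(res$E_IT_MPa, 900, tolerance = 0.02)
  # creep over the hold: C_IT = 100 * c * log(1 + t_hold)
  expect_equal(res$C_IT_pct, 100 * 0.02 * log1p(6), tolerance = 0.01)
  expect_gt(res$eta_IT, 0); expect_lte(res$eta_IT, 1)
  # Tabor chain from the recovered hardness
  expect_identical(tabor_yield_estimate(res$H_IT_MPa), res$H_IT_MPa / 3)
})

test_that("zero creep gives a flat hold and C_IT = 0", {
  cfg <- indent_sim_config(creep_coefficient = 0, noise_sd = 0)
  cur <- generate_indentation_curve(cfg)
  h_hold <- cur$depth_um[cur$segment == "hold"]
  expect_lt(diff(range(h_hold)), 1e-12)
  expect_equal(analyze_indentation_curve(cur)$C_IT_pct, 0, tolerance = 1e-9)
})

test_that("recovery holds across the (H, E) grid corners", {
  for (H in c(30, 120)) for (E in c(400, 1500)) {
    cfg <- indent_sim_config(target_modulus_MPa = E, target_hardness_MPa = H,
                             noise_sd = 0)
    res <- analyze_indentation_curve(generate_indentation_curve(cfg))
    expect_lt(abs(res$H_IT_MPa - H) / H, 0.01)
    expect_lt(abs(res$E_IT_MPa - E) / E, 0.02)
  }
})

test_that("H_M and H_IT stay proportional along a physical hardness-modulus sweep", {
  # h_c/h_max, and with it H_M/H_IT, is set by the E/H ratio; real UHMWPE
  # hardness and modulus scale together, so the ratio is probed at fixed E/H
  ratios <- vapply(seq(30, 120, length.out = 5), function(H) {
    cfg <- indent_sim_config(target_modulus_MPa = 12.5 * H,
                             target_hardness_MPa = H, noise_sd = 0)
    res <- analyze_indentation_curve(generate_indentation_curve(cfg))
    res$H_M_MPa / res$H_IT_MPa
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.10)
})

test_that("H_IT and H_M are invariant to load/depth scaling (P -> cP, h -> sqrt(c) h)", {
  cfg <- indent_sim_config(noise_sd = 0)
  cur <- generate_indentation_curve(cfg)
  c_scale <- 4
  scaled <- indentation_curve(cur$time_s, c_scale * cur$load_mN,
                              sqrt(c_scale) * cur$depth_um, cur$segment)
  r1 <- analyze_indentation_curve(cur)
  r2 <- analyze_indentation_curve(scaled)
  expect_equal(r2$H_IT_MPa, r1$H_IT_MPa, tolerance = 1e-6)
  expect_equal(r2$H_M_MPa, r1$H_M_MPa, tolerance = 1e-6)
})

test_that("an elastic curve (unloading retracing loading) gives eta_IT = 1", {
  h <- seq(0, 10, length.out = 50)
  P <- 5 * h^2
  # unloading branch retraces the loading branch from the peak down
  cur <- indentation_curve(
    time_s = seq_len(100),
    load_mN = c(P, rev(P)),
    depth_um = c(h, rev(h)),
    segment = c(rep("loading", 50), rep("unloading", 50)))
  il <- cur$segment == "loading"; iu <- cur$segment == "unloading"
  w_tot <- pracma::trapz(cur$depth_um[il], cur$load_mN[il])
  w_el <- -pracma::trapz(cur$depth_um[iu], cur$load_mN[iu])
  expect_equal(w_el / w_tot, 1, tolerance = 1e-9)
})

test_that("indent aggregation averages replicates and flags n < 10", {
  agg <- aggregate_indents(rep(5.5, 10), region = "U", location = "central")
  expect_equal(agg$mean, 5.5)
  expect_equal(agg$sd, 0)
  expect_false(agg$below_minimum)
  expect_true(aggregate_indents(rep(5.5, 5), "U", "central")$below_minimum)
  expect_error(aggregate_indents(numeric(0), "U", "central"), ">= 1")
})

test_that("the per-liner property summary yields the six standardized values", {
  set.seed(42)
  indents <- expand.grid(region = c("U", "W"),
                         location = c("max_oxidation", "central"),
                         rep = 1:10, stringsAsFactors = FALSE)
  indents$value <- 60 + (indents$region == "U") * 2 +
    (indents$location == "max_oxidation") * 5 + rnorm(nrow(indents), 0, 0.1)
  out <- summarize_property(indents, property = "HV")
  expect_length(out, 6)
  expect_named(out, c("HV(max,U)", "HV(max,W)", "HV(max,UW)",
                      "HV(ave,U)", "HV(ave,W)", "HV(ave,UW)"))
  # UW pools U and W indents
  expect_equal(out[["HV(max,UW)"]]$n, 20)
  expect_equal(out[["HV(max,UW)"]]$mean,
               mean(indents$value[indents$location == "max_oxidation"]))
  expect_false(any(vapply(out, `[[`, logical(1), "below_minimum")))
})

test_that("the Tabor yield estimate is H/3 and rejects non-positive hardness", {
  expect_equal(tabor_yield_estimate(60), 20)
  expect_error(tabor_yield_estimate(0), "> 0")
})
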