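test_that("band integration matches the analytic Gaussian oracle", {
  # unit-area Gaussian (sigma = 5) centred in a +/-30 cm^-1 window, 2 cm^-1 grid
  wn <- seq(4000, 400, by = -2)
  ab <- 1 / (5 * sqrt(2 * pi)) * exp(-(wn - 1500)^2 / (2 * 5^2))
  sp <- ir_spectrum(wn, ab, 0, "U")
  band <- list(name = "test", lower = 1470, upper = 1530,
               baseline = "two_point_linear")
  expect_equal(as.numeric(integrate_band(sp, band)), 1.0, tolerance = 0.005)

  # zero spectrum -> zero area
  sp0 <- ir_spectrum(wn, rep(0, length(wn)), 0, "U")
  expect_equal(as.numeric(integrate_band(sp0, band)), 0)

  # straight-line spectrum: the two-point baseline subtracts the ramp exactly
  spl <- ir_spectrum(wn, 0.3 + 1e-4 * wn, 0, "U")
  expect_equal(as.numeric(integrate_band(spl, band)), 0, tolerance = 1e-12)

  # limits outside the spectrum range are an error
  expect_error(integrate_band(sp, list(name = "x", lower = 100, upper = 300,
                                       baseline = "none")),
               "outside spectrum range")
})

test_that("negative noisy areas are clipped to zero and flagged", {
  wn <- seq(2000, 1000, by = -2)
  ab <- -1 / (5 * sqrt(2 * pi)) * exp(-(wn - 1500)^2 / (2 * 5^2))
  sp <- ir_spectrum(wn, ab, 0, "U")
  a <- integrate_band(sp, list(name = "neg", lower = 1470, upper = 1530,
                               baseline = "two_point_linear"))
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "clipped"))
})

test_that("index formulas follow the band-area ratios", {
  sig <- std_sigmas()
  # A1720 = A1370 -> OI = 1; A1897/A1303 = 3 -> CI = 0.75
  sp <- gaussian_spectrum(list(carbonyl_1720 = 1, reference_1370 = 1,
                               vinylene_965 = 0.2, crystalline_1897 = 3,
                               amorphous_1303 = 1), sig)
  idx <- compute_indexes(sp)
  expect_equal(idx$OI, 1.0, tolerance = 0.005)
  expect_equal(idx$VI, 0.2, tolerance = 0.005)
  expect_equal(idx$CI, 0.75, tolerance = 0.005)

  # constructed A1720 = 2.5 * A1370
  sp2 <- gaussian_spectrum(list(carbonyl_1720 = 2.5, reference_1370 = 1,
                                vinylene_965 = 0.05, crystalline_1897 = 1,
                                amorphous_1303 = 1), sig)
  expect_equal(compute_indexes(sp2)$OI, 2.5, tolerance = 0.005)

  # zero reference band -> error naming the band
  sp3 <- gaussian_spectrum(list(carbonyl_1720 = 1, reference_1370 = 0,
                                vinylene_965 = 0, crystalline_1897 = 1,
                                amorphous_1303 = 1), sig)
  expect_error(compute_indexes(sp3), "A1370")
})

test_that("indexes are invariant to absorbance scaling and axis reversal", {
  sig <- std_sigmas()
  sp <- gaussian_spectrum(list(carbonyl_1720 = 1.7, reference_1370 = 0.9,
                               vinylene_965 = 0.12, crystalline_1897 = 1.4,
                               amorphous_1303 = 1.1), sig)
  ref <- compute_indexes(sp)
  for (c_scale in c(0.01, 3, 1000)) {
    sc <- ir_spectrum(sp$wavenumber, c_scale * sp$absorbance, 0, "U")
    got <- compute_indexes(sc)
    expect_equal(got$OI, ref$OI, tolerance = 1e-12)
    expect_equal(got$VI, ref$VI, tolerance = 1e-12)
    expect_equal(got$CI, ref$CI, tolerance = 1e-12)
  }
  rev_sp <- ir_spectrum(rev(sp$wavenumber), rev(sp$absorbance), 0, "U")
  expect_equal(compute_indexes(rev_sp)$OI, ref$OI, tolerance = 1e-12)
})

test_that("CI lies in [0,1) and increases with the crystalline/amorphous ratio", {
  sig <- std_sigmas()
  cas <- c(0.1, 0.5, 1, 3, 10, 50)
  cis <- vapply(cas, function(ca) {
    sp <- gaussian_spectrum(list(carbonyl_1720 = 1, reference_1370 = 1,
                                 vinylene_965 = 0.1, crystalline_1897 = ca,
                                 amorphous_1303 = 1), sig)
    compute_indexes(sp)$CI
  }, numeric(1))
  expect_true(all(cis >= 0 & cis < 1))
  expect_true(all(diff(cis) > 0))
})

test_that("profiles preserve depth order and constant scans give constant profiles", {
  ls <- flat_linescan(oi = 0.8, vi = 0.05, ci = 0.5, n = 6)
  pr <- build_profiles(ls)
  expect_length(pr$OI$value, 6)
  expect_equal(pr$OI$depth_um, linescan_depths(ls))
  for (kind in c("OI", "VI", "CI")) {
    expect_lt(diff(range(pr[[kind]]$value)), 1e-9)
  }
})

test_that("camel-profile maximum is located at the configured peak depth", {
  cfg <- linescan_sim_config(thickness_um = 3000, step_um = 100,
                             oi_peak_heights = c(2.5, 1.2),
                             oi_peak_depths_um = c(500, 400),
                             oi_peak_widths_um = c(250, 250),
                             noise_sd = 0, seed = 7)
  pr <- build_profiles(generate_linescan_pair(cfg)$U)
  d_at_max <- pr$OI$depth_um[which.max(pr$OI$value)]
  expect_lte(abs(d_at_max - 500), cfg$step_um)
})

test_that("the standardized index set has exactly 15 members with the UW identities", {
  cfg <- linescan_sim_config(thickness_um = 2000, noise_sd = 0, seed = 2)
  pair <- generate_linescan_pair(cfg)
  idx <- extract_standard_indexes(build_profiles(pair$U), build_profiles(pair$W))
  expect_length(idx, 15)
  expect_named(idx, c("OI(max,U)", "OI(max,W)", "OI(max,UW)",
                      "OI(ave,U)", "OI(ave,W)", "OI(ave,UW)",
                      "VI(ave,U)", "VI(ave,W)", "VI(ave,UW)",
                      "CI(max,U)", "CI(max,W)", "CI(max,UW)",
                      "CI(ave,U)", "CI(ave,W)", "CI(ave,UW)"))
  expect_identical(idx[["OI(max,UW)"]],
                   max(idx[["OI(max,U)"]], idx[["OI(max,W)"]]))
  expect_identical(idx[["CI(max,UW)"]],
                   max(idx[["CI(max,U)"]], idx[["CI(max,W)"]]))
  expect_false(any(grepl("VI\\(max", names(idx))))
})

test_that("flat profiles make all six OI fields equal and camel construction recovers peak/plateau", {
  # flat OI = 0.4 in both regions
  u <- build_profiles(flat_linescan(0.4, 0.05, 0.5, region = "U"))
  w <- build_profiles(flat_linescan(0.4, 0.05, 0.5, region = "W"))
  idx <- extract_standard_indexes(u, w)
  oi_fields <- idx[grepl("^OI", names(idx))]
  expect_equal(unname(oi_fields), rep(0.4, 6), tolerance = 0.005)

  # constructed camel: peaks 2.0 / 1.2 (apex OI), plateau 0.5
  cfg <- linescan_sim_config(oi_peak_heights = c(2.0, 1.2), oi_plateau = 0.5,
                             worn_attenuation = 1, noise_sd = 0, seed = 3)
  pair <- generate_linescan_pair(cfg)
  idx2 <- extract_standard_indexes(build_profiles(pair$U), build_profiles(pair$W))
  expect_equal(idx2[["OI(max,U)"]], 2.0, tolerance = 0.01)
  expect_equal(idx2[["OI(ave,U)"]], 0.5, tolerance = 0.01)
})

test_that("edge exclusion and central fraction are honoured with errors on empty regions", {
  u <- build_profiles(flat_linescan(0.4, 0.05, 0.5, region = "U", n = 5))
  w <- build_profiles(flat_linescan(0.4, 0.05, 0.5, region = "W", n = 5))
  expect_error(extract_standard_indexes(u, w, edge_exclude = 3),
               "smaller margin")
  expect_error(extract_standard_indexes(u, w, central_fraction = 0),
               "central_fraction")
  expect_silent(extract_standard_indexes(u, w, edge_exclude = 1))
})

test_that("severity classification uses the low/critical OI thresholds", {
  expect_equal(as.character(classify_oxidation_severity(0.5)), "low")
  expect_equal(as.character(classify_oxidation_severity(3.5)), "critical")
  expect_equal(as.character(classify_oxidation_severity(2.0)), "intermediate")
  # boundary values map to intermediate (strict inequalities)
  expect_equal(as.character(classify_oxidation_severity(c(1, 3))),
               c("intermediate", "intermediate"))
  expect_equal(as.character(classify_oxidation_severity(0.999999)), "low")
  expect_error(classify_oxidation_severity(-0.1), ">= 0")
})
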