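test_that("generators are bit-reproducible for a fixed seed and leave the RNG alone", {
  cfg <- linescan_sim_config(thickness_um = 1000, noise_sd = 0.002, seed = 11)
  p1 <- generate_linescan_pair(cfg)
  set.seed(999); before <- runif(3)
  set.seed(999)
  p2 <- generate_linescan_pair(cfg)
  after <- runif(3)
  expect_identical(p1, p2)
  expect_identical(before, after)   # caller RNG stream untouched

  icfg <- indent_sim_config(noise_sd = 0.01, seed = 4)
  expect_identical(generate_indentation_curve(icfg),
                   generate_indentation_curve(icfg))

  ccfg <- cohort_sim_config(n_liners = 25, seed = 5)
  expect_identical(generate_cohort(ccfg)$records, generate_cohort(ccfg)$records)
})

test_that("config validation errors name the offending field", {
  expect_error(linescan_sim_config(thickness_um = -1), "thickness_um")
  expect_error(linescan_sim_config(oi_peak_heights = c(-1, 1)), "oi_peak_heights")
  expect_error(linescan_sim_config(ci_powerlaw_k = 0.9, ci_powerlaw_n = 1),
               "ci_powerlaw_k")
  expect_error(linescan_sim_config(worn_attenuation = 2), "worn_attenuation")
  expect_error(indent_sim_config(unload_exponent = 3), "unload_exponent")
  expect_error(indent_sim_config(target_hardness_MPa = 0), "target_hardness_MPa")
  expect_error(cohort_sim_config(group_weights = c(gIRR = 0.5, EtO = 0.4)),
               "group_weights")
  expect_error(cohort_sim_config(n_liners = 0), "n_liners")
})

test_that("line scans have ceil(thickness/step)+1 spectra and close the indexing loop", {
  cfg <- linescan_sim_config(thickness_um = 1050, step_um = 100, noise_sd = 0,
                             seed = 2)
  pair <- generate_linescan_pair(cfg)
  expect_length(pair$U$spectra, ceiling(1050 / 100) + 1)
  expect_length(pair$W$spectra, ceiling(1050 / 100) + 1)

  cfg2 <- linescan_sim_config(oi_peak_heights = c(2.0, 1.5),
                              noise_sd = 0, seed = 2)
  pair2 <- generate_linescan_pair(cfg2)
  pu <- build_profiles(pair2$U)
  # configured apex OI recovered within 5%
  expect_lt(abs(max(pu$OI$value) - 2.0) / 2.0, 0.05)
  # flat VI construction: profile sd below 1e-3
  expect_lt(sd(pu$VI$value), 1e-3)
  # closed loop: central plateau within 1% (peaks at 600/7400 um sit 4 sigma
  # clear of the 2000-6000 um central band), CI = k * OI^n within 1% pointwise
  central <- pu$OI$value[pu$OI$depth_um >= 2000 & pu$OI$depth_um <= 6000]
  expect_lt(abs(mean(central) - cfg2$oi_plateau) / cfg2$oi_plateau, 0.01)
  ci_target <- cfg2$ci_powerlaw_k * pu$OI$value^cfg2$ci_powerlaw_n
  expect_lt(max(abs(pu$CI$value - ci_target) / ci_target), 0.01)
})

test_that("the worn scan's articulating-surface peak is attenuated", {
  cfg <- linescan_sim_config(thickness_um = 3000, oi_peak_heights = c(2.5, 1.0),
                             oi_peak_depths_um = c(500, 500),
                             worn_attenuation = 0.5, noise_sd = 0, seed = 6)
  pair <- generate_linescan_pair(cfg)
  pu <- build_profiles(pair$U); pw <- build_profiles(pair$W)
  near_surface <- pu$OI$depth_um <= 1000
  apex_u <- max(pu$OI$value[near_surface])
  apex_w <- max(pw$OI$value[near_surface])
  # amplitude above plateau halves
  expect_equal((apex_w - cfg$oi_plateau) / (apex_u - cfg$oi_plateau), 0.5,
               tolerance = 0.02)
})

test_that("indentation forward model honours hold creep and stays reproducible", {
  cur0 <- generate_indentation_curve(indent_sim_config(creep_coefficient = 0))
  h_hold <- cur0$depth_um[cur0$segment == "hold"]
  expect_lt(diff(range(h_hold)), 1e-12)

  cfg <- indent_sim_config(target_modulus_MPa = 900, noise_sd = 0)
  res <- analyze_indentation_curve(generate_indentation_curve(cfg))
  expect_lt(abs(res$E_IT_MPa - 900) / 900, 0.02)
})

test_that("cohorts have the requested size, valid records and constructed group shift", {
  db <- generate_cohort(cohort_sim_config(n_liners = 50, seed = 9))
  expect_equal(nrow(db$records), 50)
  viol <- lapply(seq_len(50), function(i) validate_record(db$records[i, ]))
  expect_true(all(lengths(viol) == 0))

  # Delta = 1.0, sd = 0.5, n = 30/group: observed difference within 3 SE
  db2 <- generate_cohort(two_group_cfg(n = 60, delta = 1.0, sd = 0.5, seed = 21))
  rec <- db2$records
  a <- rec[["OI(max,UW)"]][rec$sterilization == "gIRR"]
  b <- rec[["OI(max,UW)"]][rec$sterilization == "EtO"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - 1.0), 3 * se)
})

test_that("cohort group frequencies follow the configured weights", {
  db <- generate_cohort(cohort_sim_config(n_liners = 10000, seed = 13))
  counts <- table(db$records$sterilization)[c("gIRR", "EtO", "HCHO")]
  gof <- chisq.test(counts, p = c(0.60, 0.25, 0.15))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort indexes respect the CI power-law coupling and UW identities", {
  db <- generate_cohort(cohort_sim_config(n_liners = 200, seed = 17))
  rec <- db$records
  expect_equal(rec[["CI(max,UW)"]],
               pmin(0.55 * rec[["OI(max,UW)"]]^0.12, 0.999), tolerance = 1e-12)
  expect_equal(rec[["OI(max,UW)"]],
               pmax(rec[["OI(max,U)"]], rec[["OI(max,W)"]]), tolerance = 1e-12)
  expect_true(all(rec[["CI(ave,UW)"]] < 1))
})
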