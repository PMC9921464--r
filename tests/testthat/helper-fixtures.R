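# Shared fixtures: all built in code at test time.

# spectrum that is a single unit-area Gaussian at `center` (plus optional
# extra bands), on the standard 2 cm^-1 grid
gaussian_spectrum <- function(areas, sigmas, depth = 0, region = "U",
                              wn = seq(4000, 400, by = -2)) {
  ab <- numeric(length(wn))
  for (b in names(areas)) {
    ab <- ab + areas[[b]] / (sigmas[[b]] * sqrt(2 * pi)) *
      exp(-(wn - b_center(b))^2 / (2 * sigmas[[b]]^2))
  }
  ir_spectrum(wn, ab, depth_um = depth, region = region)
}

b_center <- function(name) {
  c(carbonyl_1720 = 1720, reference_1370 = 1370, vinylene_965 = 965,
    crystalline_1897 = 1897, amorphous_1303 = 1303)[[name]]
}

std_sigmas <- function() {
  c(carbonyl_1720 = 10, reference_1370 = 6, vinylene_965 = 3.5,
    crystalline_1897 = 10, amorphous_1303 = 6)
}

# flat-profile line scan: every spectrum realizes the same (oi, vi, ci)
flat_linescan <- function(oi, vi, ci, region = "U", n = 5, step = 100,
                          liner_id = "FIX-1") {
  sig <- std_sigmas()
  ca <- ci / (1 - ci)
  areas <- c(carbonyl_1720 = oi, reference_1370 = 1, vinylene_965 = vi,
             crystalline_1897 = ca, amorphous_1303 = 1)
  spectra <- lapply(seq_len(n) - 1L, function(i) {
    sp <- gaussian_spectrum(as.list(areas), sig, depth = i * step, region = region)
    sp
  })
  ir_linescan(liner_id, region, spectra)
}

# minimal valid liner record as a one-row data frame
valid_record <- function(liner_id = "CZ-001", ...) {
  rec <- list(liner_id = liner_id, country = "CZ", joint = "THR",
              implantation_year = 1995, in_vivo_months = 120,
              patient_age_at_implant = 65, patient_bmi = 27.5,
              patient_weight = 80, crosslinking = "none",
              radiation_dose = NA, thermal_treatment = "none",
              sterilization = "gIRR", failure_reason = "wear")
  dots <- list(...)
  rec[names(dots)] <- dots
  as.data.frame(rec, check.names = FALSE, stringsAsFactors = FALSE)
}

# cohort config for calibration studies: two sterilization groups with
# normal OI distributions and no failure-reason offsets
two_group_cfg <- function(n = 60, delta = 0, sd = 0.5, seed = 1) {
  cohort_sim_config(
    n_liners = n,
    group_weights = c(gIRR = 0.5, EtO = 0.5),
    group_oi_mean = c(gIRR = 2 + delta, EtO = 2),
    group_oi_sd = c(gIRR = sd, EtO = sd),
    failure_oi_offsets = c(wear = 0, mechanical = 0, infection = 0, other = 0),
    exact_counts = TRUE, seed = seed)
}

# Welch p-value for OI(max,UW) between the two sterilization groups
cohort_welch_p <- function(db) {
  rec <- db$records
  a <- rec[["OI(max,UW)"]][rec$sterilization == "gIRR"]
  b <- rec[["OI(max,UW)"]][rec$sterilization == "EtO"]
  compare_groups(a, b, method = "welch_t")$p
}
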