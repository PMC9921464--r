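#' Indenter and analysis constants for Vickers instrumented indentation
#'
#' Standard Oliver-Pharr / ISO 14577 constants for a Vickers diamond
#' pyramid (angle between nonadjacent faces 136 degrees): geometric
#' intercept factor epsilon, King correction beta, projected-area
#' coefficient (A_p = c_A * h_c^2) and surface-area coefficient for Martens
#' hardness (A_s = 26.43 * h^2), elastic constants of the diamond indenter
#' and the Poisson ratio of the specimen (0.46 for UHMWPE).
#'
#' @param epsilon Geometric factor in h_c = h_max - epsilon * P_max / S.
#' @param beta Stiffness correction factor.
#' @param c_area Projected-area coefficient (24.504 for an ideal Vickers tip).
#' @param c_surface Surface-area coefficient used for Martens hardness.
#' @param E_indenter_GPa Indenter (diamond) Young modulus in GPa.
#' @param nu_indenter Indenter Poisson ratio.
#' @param nu_specimen Specimen Poisson ratio.
#' @return Named list of constants.
#' @export
indenter_constants <- function(epsilon = 0.75, beta = 1.012,
                               c_area = 24.504, c_surface = 26.43,
                               E_indenter_GPa = 1141, nu_indenter = 0.07,
                               nu_specimen = 0.46) {
  k <- list(epsilon = epsilon, beta = beta, c_area = c_area,
            c_surface = c_surface, E_indenter_GPa = E_indenter_GPa,
            nu_indenter = nu_indenter, nu_specimen = nu_specimen,
            face_angle_deg = 136)
  if (any(vapply(k, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all indenter constants must be positive numbers", call. = FALSE)
  }
  if (epsilon > 1) stop("epsilon must lie in (0, 1]", call. = FALSE)
  k
}

#' Vickers hardness from force and indent diagonal
#'
#' H_V = 2 sin(136/2 deg) * F / d^2 = 1.8544 * F / d^2 in kgf/mm^2, the
#' conventional Vickers number, with the megapascal equivalent
#' 9.80665 * H_V.
#'
#' @param force_kgf Indentation force in kilogram-force (> 0).
#' @param diagonal_mm Mean indent diagonal in millimetres (> 0).
#' @return List with `HV_kgf_mm2` and `HV_MPa`.
#' @export
vickers_hardness <- function(force_kgf, diagonal_mm) {
  if (any(!is.finite(force_kgf)) || any(force_kgf <= 0)) {
    stop("force must be > 0", call. = FALSE)
  }
  if (any(!is.finite(diagonal_mm)) || any(diagonal_mm <= 0)) {
    stop("diagonal must be > 0", call. = FALSE)
  }
  hv <- 2 * sin(136 / 2 * pi / 180) * force_kgf / diagonal_mm^2
  list(HV_kgf_mm2 = hv, HV_MPa = 9.80665 * hv)
}

#' Tabor estimate of the yield stress from a hardness value
#'
#' For semicrystalline polymers such as UHMWPE the Vickers, Martens and
#' indentation hardnesses are mutually proportional and proportional to
#' the macroscopic yield stress Y: H ~ 3 Y, hence Y = H / 3.
#'
#' @param H_MPa Hardness in MPa (> 0).
#' @return Yield stress estimate in MPa.
#' @export
tabor_yield_estimate <- function(H_MPa) {
  if (any(!is.finite(H_MPa)) || any(H_MPa <= 0)) {
    stop("hardness must be > 0", call. = FALSE)
  }
  H_MPa / 3
}

# MPa -> mN/um^2 (1 MPa = 1e-3 mN/um^2)
.MPA_TO_MN_UM2 <- 1e-3

segment_idx <- function(curve, seg) which(curve$segment == seg)

#' Oliver-Pharr analysis of one instrumented indentation curve
#'
#' Evaluates a single Vickers indent recorded as a load-depth-time curve:
#' the unloading branch is fitted with the power law P = B (h - h_f)^m over
#' the 98 to 40 percent load fraction, the contact stiffness
#' S = dP/dh at maximum depth follows from the fit, and from it the contact
#' depth h_c = h_max - epsilon P_max / S, the projected area
#' A_p = c_A h_c^2, the indentation hardness H_IT = P_max / A_p, the reduced
#' modulus E_r = sqrt(pi) S / (2 beta sqrt(A_p)) and the indentation
#' modulus E_IT. Martens hardness H_M = P_max / (26.43 h_max^2), the
#' indentation creep C_IT = 100 (h2 - h1) / h1 over the hold segment, and
#' the elastic part of the indentation work eta_IT = W_elast / W_total from
#' trapezoidal work integrals complete the property set.
#'
#' @param curve An [indentation_curve()].
#' @param constants [indenter_constants()].
#' @param fit_range Load fractions of P_max bounding the unloading fit
#'   (default `c(0.98, 0.40)`).
#' @return List of single-indent properties: `H_IT_MPa`, `E_IT_MPa`,
#'   `H_M_MPa`, `C_IT_pct` (NA when there is no hold segment), `eta_IT`,
#'   `S_mN_um`, `h_max_um`, `h_c_um`, `h_f_um`, `m`, `P_max_mN`.
#' @export
analyze_indentation_curve <- function(curve, constants = indenter_constants(),
                                      fit_range = c(0.98, 0.40)) {
  stopifnot(inherits(curve, "indentation_curve"))
  k <- constants
  iu <- segment_idx(curve, "unloading")
  P_max <- max(curve$load_mN)
  h_max <- curve$depth_um[iu[1]]

  Pu <- curve$load_mN[iu]; hu <- curve$depth_um[iu]
  sel <- Pu <= fit_range[1] * P_max & Pu >= fit_range[2] * P_max
  if (sum(sel) < 5L) {
    stop("too few unloading points in the fit range; cannot determine stiffness",
         call. = FALSE)
  }
  hf0 <- min(hu) - 1e-6
  m0 <- 1.5
  B0 <- P_max / max(h_max - hf0, 1e-9)^m0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P ~ B * (h - hf)^m,
      data = list(P = Pu[sel], h = hu[sel]),
      start = list(B = B0, hf = hf0, m = m0),
      lower = c(B = 1e-12, hf = -Inf, m = 1.001),
      upper = c(B = Inf, hf = min(hu[sel]) - 1e-9, m = 2.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("unloading power-law fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  B <- cf[["B"]]; h_f <- cf[["hf"]]; m <- cf[["m"]]
  S <- m * B * (h_max - h_f)^(m - 1)  # mN/um
  if (!is.finite(S) || S <= 0) stop("non-positive contact stiffness", call. = FALSE)
  h_c <- h_max - k$epsilon * P_max / S
  if (h_c <= 0) stop("non-positive contact depth; curve not analyzable", call. = FALSE)
  A_p <- k$c_area * h_c^2                                  # um^2
  H_IT <- (P_max / A_p) / .MPA_TO_MN_UM2                   # MPa
  E_r <- sqrt(pi) * S / (2 * k$beta * sqrt(A_p))           # mN/um^2
  E_r_MPa <- E_r / .MPA_TO_MN_UM2
  # invert 1/E_r = (1-nu^2)/E_IT + (1-nu_i^2)/E_i
  E_IT <- (1 - k$nu_specimen^2) /
    (1 / E_r_MPa - (1 - k$nu_indenter^2) / (k$E_indenter_GPa * 1000))
  H_M <- (P_max / (k$c_surface * h_max^2)) / .MPA_TO_MN_UM2

  ih <- segment_idx(curve, "hold")
  C_IT <- if (length(ih) >= 2L) {
    h1 <- curve$depth_um[ih[1]]; h2 <- curve$depth_um[ih[length(ih)]]
    100 * (h2 - h1) / h1
  } else NA_real_

  il <- segment_idx(curve, "loading")
  ilh <- c(il, ih)
  W_total <- pracma::trapz(curve$depth_um[ilh], curve$load_mN[ilh])
  W_elast <- -pracma::trapz(curve$depth_um[iu], curve$load_mN[iu])
  eta_IT <- W_elast / W_total
  if (!is.finite(eta_IT) || eta_IT <= 0) {
    stop("non-positive elastic work fraction; curve not physically ordered",
         call. = FALSE)
  }

  list(H_IT_MPa = H_IT, E_IT_MPa = E_IT, H_M_MPa = H_M, C_IT_pct = C_IT,
       eta_IT = eta_IT, S_mN_um = S, h_max_um = h_max, h_c_um = h_c,
       h_f_um = h_f, m = m, P_max_mN = P_max)
}

#' Aggregate replicate indents for one region and location
#'
#' The measurement protocol prescribes at least 10 independent indents per
#' surface, averaged. This returns mean, sample standard deviation and n
#' for a vector of per-indent values of one property, flagging results that
#' fall below the 10-indent minimum.
#'
#' @param values Numeric vector of per-indent values (length >= 1).
#' @param region `"U"`, `"W"` or `"UW"` (pooled).
#' @param location `"max_oxidation"` or `"central"`.
#' @param property Optional property name carried through to the output.
#' @return List with `mean`, `sd`, `n`, `below_minimum`, `region`,
#'   `location`, `property`.
#' @export
aggregate_indents <- function(values, region = c("U", "W", "UW"),
                              location = c("max_oxidation", "central"),
                              property = NA_character_) {
  region <- match.arg(region); location <- match.arg(location)
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stop("need >= 1 non-missing measurement", call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values),
       below_minimum = length(values) < 10L,
       region = region, location = location, property = property)
}

#' Per-liner six-value property summary
#'
#' Reduces a table of replicate indents (regions U/W at the max-oxidation
#' and central locations) to the six standardized per-liner values of one
#' property, e.g. for Vickers hardness: HV(max,U), HV(max,W), HV(max,UW),
#' HV(ave,U), HV(ave,W), HV(ave,UW). The max-oxidation location maps to the
#' "max" values and the central location to the "ave" values; UW pools the
#' U and W indents.
#'
#' @param indents Data frame with columns `region` ("U"/"W"), `location`
#'   ("max_oxidation"/"central") and `value` (one row per indent).
#' @param property Property name used in the output column labels
#'   (default `"HV"`).
#' @return Named list of six [aggregate_indents()] results, names
#'   `HV(max,U)` ... `HV(ave,UW)`.
#' @export
summarize_property <- function(indents, property = "HV") {
  need <- c("region", "location", "value")
  if (!all(need %in% names(indents))) {
    stop("indents must have columns region, location, value", call. = FALSE)
  }
  if (!all(indents$region %in% c("U", "W")) ||
      !all(indents$location %in% c("max_oxidation", "central"))) {
    stop("region must be U/W and location max_oxidation/central", call. = FALSE)
  }
  pick <- function(reg, loc) {
    v <- indents$value[indents$location == loc &
                         (reg == "UW" | indents$region == reg)]
    if (length(v) < 1L) {
      stop(sprintf("no indents for region %s, location %s", reg, loc),
           call. = FALSE)
    }
    aggregate_indents(v, region = reg, location = loc, property = property)
  }
  out <- list(pick("U", "max_oxidation"), pick("W", "max_oxidation"),
              pick("UW", "max_oxidation"), pick("U", "central"),
              pick("W", "central"), pick("UW", "central"))
  names(out) <- paste0(property, "(", c(rep("max", 3), rep("ave", 3)), ",",
                       rep(c("U", "W", "UW"), 2), ")")
  out
}
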