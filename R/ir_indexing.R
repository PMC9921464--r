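#' Analytical band definitions for UHMWPE infrared indexing
#'
#' Integration windows and baseline mode for the five analytical bands used
#' by the oxidation (OI), trans-vinylene (VI) and crystallinity (CI)
#' indexes. The literature fixes the band centers (1720, 1370, 965, 1897 and
#' 1303 cm^-1); the window limits below follow common ASTM F2120/F2381
#' practice and are fully configurable.
#'
#' @param overrides Optional named list; each element a list with any of
#'   `lower`, `upper`, `baseline` to override a band's defaults. Names must
#'   be among `carbonyl_1720`, `reference_1370`, `vinylene_965`,
#'   `crystalline_1897`, `amorphous_1303`.
#' @return Named list of band definitions, each a list with `name`, `lower`,
#'   `upper` (cm^-1) and `baseline` (`"two_point_linear"` or `"none"`).
#' @export
default_band_definitions <- function(overrides = NULL) {
  bands <- list(
    carbonyl_1720    = list(name = "carbonyl_1720",    lower = 1650, upper = 1800, baseline = "two_point_linear"),
    reference_1370   = list(name = "reference_1370",   lower = 1330, upper = 1396, baseline = "two_point_linear"),
    vinylene_965     = list(name = "vinylene_965",     lower = 950,  upper = 980,  baseline = "two_point_linear"),
    crystalline_1897 = list(name = "crystalline_1897", lower = 1850, upper = 1985, baseline = "two_point_linear"),
    amorphous_1303   = list(name = "amorphous_1303",   lower = 1250, upper = 1330, baseline = "two_point_linear")
  )
  if (!is.null(overrides)) {
    if (!all(names(overrides) %in% names(bands))) {
      stop("unknown band name(s): ",
           paste(setdiff(names(overrides), names(bands)), collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) {
      for (f in intersect(names(overrides[[nm]]), c("lower", "upper", "baseline"))) {
        bands[[nm]][[f]] <- overrides[[nm]][[f]]
      }
    }
  }
  for (b in bands) {
    if (!is.numeric(b$lower) || !is.numeric(b$upper) || b$lower >= b$upper) {
      stop("band ", b$name, ": lower limit must be below upper limit", call. = FALSE)
    }
    if (!b$baseline %in% c("two_point_linear", "none")) {
      stop("band ", b$name, ": baseline must be two_point_linear or none",
           call. = FALSE)
    }
  }
  bands
}

#' Baseline-corrected band area
#'
#' Integrates the absorbance curve over a band window using the composite
#' trapezoid rule on the native wavenumber grid. For the
#' `two_point_linear` baseline the straight line joining the absorbance
#' values at the two integration limits is subtracted before integration
#' (standard two-point baseline correction). Negative results (possible in
#' noisy spectra) are clipped to zero and flagged.
#'
#' @param sp An [ir_spectrum()].
#' @param band A band definition (see [default_band_definitions()]).
#' @return Band area in absorbance * cm^-1 (>= 0), with attribute
#'   `clipped` = TRUE when a negative raw area was clipped to zero.
#' @export
integrate_band <- function(sp, band) {
  stopifnot(inherits(sp, "ir_spectrum"))
  w <- sp$wavenumber; a <- sp$absorbance
  if (band$lower < min(w) || band$upper > max(w)) {
    stop(sprintf("band %s: integration limits [%g, %g] outside spectrum range [%g, %g]",
                 band$name %||% "?", band$lower, band$upper, min(w), max(w)),
         call. = FALSE)
  }
  # ascending order for integration
  o <- order(w)
  w <- w[o]; a <- a[o]
  inside <- w > band$lower & w < band$upper
  a_lo <- stats::approx(w, a, xout = band$lower)$y
  a_hi <- stats::approx(w, a, xout = band$upper)$y
  wx <- c(band$lower, w[inside], band$upper)
  ax <- c(a_lo, a[inside], a_hi)
  if (identical(band$baseline, "two_point_linear")) {
    base <- a_lo + (a_hi - a_lo) * (wx - band$lower) / (band$upper - band$lower)
    ax <- ax - base
  }
  area <- pracma::trapz(wx, ax)
  clipped <- FALSE
  if (area < 0) {
    area <- 0
    clipped <- TRUE
  }
  structure(area, clipped = clipped)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Oxidation, trans-vinylene and crystallinity indexes of one spectrum
#'
#' Computes the three standard UHMWPE degradation indexes from
#' baseline-corrected band areas:
#' \deqn{OI = A_{1720}/A_{1370}, \quad VI = A_{965}/A_{1370}, \quad
#'       CI = CA/(CA+1), \; CA = A_{1897}/A_{1303}.}
#' OI is proportional to the C=O concentration (oxidative degradation), VI
#' to the absorbed radiation dose and CI to the crystalline volume
#' fraction.
#'
#' @param sp An [ir_spectrum()].
#' @param bands Band definitions from [default_band_definitions()].
#' @return A list with `OI`, `VI`, `CI`, `CA` and `areas` (named numeric
#'   vector of the five band areas, with `clipped` attribute listing any
#'   clipped bands).
#' @export
compute_indexes <- function(sp, bands = default_band_definitions()) {
  raw <- lapply(bands, function(b) integrate_band(sp, b))
  areas <- vapply(raw, as.numeric, numeric(1))
  clipped <- names(bands)[vapply(raw, function(a) isTRUE(attr(a, "clipped")), logical(1))]
  if (areas[["reference_1370"]] <= 0) {
    stop("reference band area A1370 is zero; OI and VI are undefined", call. = FALSE)
  }
  if (areas[["amorphous_1303"]] <= 0) {
    stop("amorphous band area A1303 is zero; CI is undefined", call. = FALSE)
  }
  ca <- areas[["crystalline_1897"]] / areas[["amorphous_1303"]]
  out <- list(
    OI = areas[["carbonyl_1720"]] / areas[["reference_1370"]],
    VI = areas[["vinylene_965"]] / areas[["reference_1370"]],
    CI = ca / (ca + 1),
    CA = ca,
    areas = structure(areas, clipped = clipped)
  )
  out
}

#' Index depth profile
#'
#' @param kind `"OI"`, `"VI"` or `"CI"`.
#' @param depth_um Strictly increasing depths (um).
#' @param value Index values (unitless, >= 0; CI additionally < 1).
#' @param region `"U"` or `"W"`.
#' @param liner_id Identifier string.
#' @return An object of class `index_profile`.
#' @export
index_profile <- function(kind = c("OI", "VI", "CI"), depth_um, value,
                          region = c("U", "W"), liner_id) {
  kind <- match.arg(kind); region <- match.arg(region)
  depth_um <- as.numeric(depth_um); value <- as.numeric(value)
  if (length(depth_um) != length(value) || length(value) < 1L) {
    stop("invariant violated: depths and values must have equal positive length",
         call. = FALSE)
  }
  if (any(diff(depth_um) <= 0)) {
    stop("invariant violated: profile depths must be strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("invariant violated: index values must be finite and >= 0", call. = FALSE)
  }
  if (kind == "CI" && any(value >= 1)) {
    stop("invariant violated: CI values must lie in [0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, depth_um = depth_um, value = value,
                 region = region, liner_id = liner_id),
            class = "index_profile")
}

#' @export
print.index_profile <- function(x, ...) {
  cat(sprintf("<index_profile> %s, liner %s region %s, %d points, max %.3g\n",
              x$kind, x$liner_id, x$region, length(x$value), max(x$value)))
  invisible(x)
}

#' Build OI, VI and CI depth profiles from a line scan
#'
#' Applies [compute_indexes()] to every spectrum of a line scan and
#' assembles the results into three depth profiles.
#'
#' @param ls An [ir_linescan()].
#' @param bands Band definitions.
#' @return A list with elements `OI`, `VI`, `CI`, each an [index_profile()].
#' @export
build_profiles <- function(ls, bands = default_band_definitions()) {
  stopifnot(inherits(ls, "ir_linescan"))
  depths <- linescan_depths(ls)
  idx <- lapply(seq_along(ls$spectra), function(i) {
    tryCatch(compute_indexes(ls$spectra[[i]], bands),
             error = function(e) {
               stop(sprintf("at depth %g um: %s", depths[i], conditionMessage(e)),
                    call. = FALSE)
             })
  })
  mk <- function(kind) {
    index_profile(kind, depths, vapply(idx, `[[`, numeric(1), kind),
                  region = ls$region, liner_id = ls$liner_id)
  }
  list(OI = mk("OI"), VI = mk("VI"), CI = mk("CI"))
}

#' Export index profiles as a data frame
#'
#' @param profiles Result of [build_profiles()].
#' @return Data frame with columns liner_id, region, depth_um, OI, VI, CI.
#' @export
profiles_to_data_frame <- function(profiles) {
  p <- profiles$OI
  data.frame(liner_id = p$liner_id, region = p$region, depth_um = p$depth_um,
             OI = profiles$OI$value, VI = profiles$VI$value,
             CI = profiles$CI$value, check.names = FALSE)
}

profile_max <- function(p, edge_exclude = 0L) {
  n <- length(p$value)
  keep <- seq_len(n)
  if (edge_exclude > 0L) {
    if (n - 2L * edge_exclude < 1L) {
      stop("edge_exclude leaves no profile points; use a smaller margin",
           call. = FALSE)
    }
    keep <- (edge_exclude + 1L):(n - edge_exclude)
  }
  max(p$value[keep])
}

central_values <- function(p, central_fraction) {
  span <- max(p$depth_um) - min(p$depth_um)
  mid <- (max(p$depth_um) + min(p$depth_um)) / 2
  half <- central_fraction * span / 2
  v <- p$value[p$depth_um >= mid - half & p$depth_um <= mid + half]
  if (length(v) < 1L) {
    stop("central region contains no profile points; increase central_fraction",
         call. = FALSE)
  }
  v
}

#' The 15 standardized per-liner indexes
#'
#' Reduces the six index profiles of a liner (OI/VI/CI for the unworn and
#' worn regions) to the standardized scalar set: maximum values of OI and CI
#' per region and for the combined (UW) data, average values of OI, VI and
#' CI over the central region of the profile, again per region and
#' combined. VI maxima are not determined because VI profiles are flat, so
#' the set has exactly 15 members.
#'
#' Maxima are taken over the whole profile after optionally dropping
#' `edge_exclude` points at each end (surface points can carry edge
#' artifacts). Averages are taken over the central `central_fraction` of the
#' depth span, centred at mid-depth; the combined (UW) average pools the
#' central-region values of both regions. The combined maximum is the larger
#' of the two regional maxima.
#'
#' @param profiles_u,profiles_w Results of [build_profiles()] for the unworn
#'   and worn line scans of the same liner.
#' @param central_fraction Fraction of the depth span defining the central
#'   averaging region (default 0.5).
#' @param edge_exclude Number of points dropped at each profile end before
#'   taking maxima (default 0).
#' @return Named numeric vector of length 15, class `standard_index_set`,
#'   with names `OI(max,U)` ... `CI(ave,UW)`.
#' @export
extract_standard_indexes <- function(profiles_u, profiles_w,
                                     central_fraction = 0.5,
                                     edge_exclude = 0L) {
  for (p in c(profiles_u, profiles_w)) stopifnot(inherits(p, "index_profile"))
  if (profiles_u$OI$region != "U" || profiles_w$OI$region != "W") {
    stop("profiles_u must come from region U and profiles_w from region W",
         call. = FALSE)
  }
  if (profiles_u$OI$liner_id != profiles_w$OI$liner_id) {
    stop("U and W profiles must come from the same liner", call. = FALSE)
  }
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must lie in (0, 1]", call. = FALSE)
  }
  mx <- function(kind) {
    u <- profile_max(profiles_u[[kind]], edge_exclude)
    w <- profile_max(profiles_w[[kind]], edge_exclude)
    c(U = u, W = w, UW = max(u, w))
  }
  av <- function(kind) {
    u <- central_values(profiles_u[[kind]], central_fraction)
    w <- central_values(profiles_w[[kind]], central_fraction)
    c(U = mean(u), W = mean(w), UW = mean(c(u, w)))
  }
  oi_max <- mx("OI"); ci_max <- mx("CI")
  oi_ave <- av("OI"); vi_ave <- av("VI"); ci_ave <- av("CI")
  out <- c(
    "OI(max,U)" = oi_max[["U"]], "OI(max,W)" = oi_max[["W"]], "OI(max,UW)" = oi_max[["UW"]],
    "OI(ave,U)" = oi_ave[["U"]], "OI(ave,W)" = oi_ave[["W"]], "OI(ave,UW)" = oi_ave[["UW"]],
    "VI(ave,U)" = vi_ave[["U"]], "VI(ave,W)" = vi_ave[["W"]], "VI(ave,UW)" = vi_ave[["UW"]],
    "CI(max,U)" = ci_max[["U"]], "CI(max,W)" = ci_max[["W"]], "CI(max,UW)" = ci_max[["UW"]],
    "CI(ave,U)" = ci_ave[["U"]], "CI(ave,W)" = ci_ave[["W"]], "CI(ave,UW)" = ci_ave[["UW"]]
  )
  class(out) <- c("standard_index_set", class(out))
  out
}

#' @export
print.standard_index_set <- function(x, ...) {
  cat("<standard_index_set> 15 standardized indexes:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Oxidation severity classification
#'
#' Classifies a maximum oxidation index using the thresholds established
#' for UHMWPE liners: oxidative damage is "low" when OI < 1 (a negative
#' impact on mechanical properties is hard to demonstrate) and "critical"
#' when OI > 3 (long-term load-bearing ability compromised). Values in
#' between, including the boundary values 1 and 3, are "intermediate".
#'
#' @param oi_max Numeric vector of maximum oxidation indexes (>= 0).
#' @return Factor with levels `low`, `intermediate`, `critical`.
#' @export
classify_oxidation_severity <- function(oi_max) {
  oi_max <- as.numeric(oi_max)
  if (any(!is.finite(oi_max)) || any(oi_max < 0)) {
    stop("oi_max must be finite and >= 0", call. = FALSE)
  }
  out <- ifelse(oi_max < 1, "low", ifelse(oi_max > 3, "critical", "intermediate"))
  factor(out, levels = c("low", "intermediate", "critical"))
}
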