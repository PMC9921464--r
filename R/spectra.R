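#' Infrared spectrum at one depth
#'
#' Constructs a validated absorbance spectrum measured at a given distance
#' from the articulating surface of a liner section. Wavenumbers are
#' canonicalized to descending order (FTIR convention); input may be given
#' in either direction.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   monotone in either direction, length >= 2.
#' @param absorbance Numeric vector of absorbance values (unitless), same
#'   length as `wavenumber`.
#' @param depth_um Distance from the articulating surface in micrometres
#'   (finite, >= 0).
#' @param region Region label, `"U"` (unworn) or `"W"` (worn).
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, depth_um, region = c("U", "W")) {
  region <- match.arg(region)
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) < 2L) {
    stop("invariant violated: wavenumber/absorbance arrays must have length >= 2",
         call. = FALSE)
  }
  if (length(wavenumber) != length(absorbance)) {
    stop("invariant violated: wavenumber and absorbance must have equal length",
         call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(absorbance)) {
    stop("invariant violated: spectrum arrays must not contain NA", call. = FALSE)
  }
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    stop("invariant violated: wavenumbers must be strictly monotone", call. = FALSE)
  }
  if (length(depth_um) != 1L || !is.finite(depth_um) || depth_um < 0) {
    stop("invariant violated: depth_um must be a single finite value >= 0",
         call. = FALSE)
  }
  if (d[1] > 0) { # store descending
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         depth_um = as.numeric(depth_um), region = region),
    class = "ir_spectrum"
  )
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.0f-%.0f cm^-1, depth %.1f um, region %s\n",
              length(x$wavenumber), max(x$wavenumber), min(x$wavenumber),
              x$depth_um, x$region))
  invisible(x)
}

#' Infrared line scan through a liner section
#'
#' An ordered depth series of spectra for one region (worn or unworn) of one
#' liner, i.e. a 1D line scan from the articulating surface toward the back
#' surface.
#'
#' @param liner_id Non-empty identifier string.
#' @param region `"U"` or `"W"`; all member spectra must carry this region.
#' @param spectra List of [ir_spectrum()] objects with strictly increasing
#'   depths, length >= 2.
#' @return An object of class `ir_linescan`.
#' @export
ir_linescan <- function(liner_id, region = c("U", "W"), spectra) {
  region <- match.arg(region)
  if (!is.character(liner_id) || length(liner_id) != 1L || !nzchar(liner_id)) {
    stop("invariant violated: liner_id must be a non-empty string", call. = FALSE)
  }
  if (!is.list(spectra) || length(spectra) < 2L) {
    stop("invariant violated: a line scan needs >= 2 spectra", call. = FALSE)
  }
  ok <- vapply(spectra, inherits, logical(1), "ir_spectrum")
  if (!all(ok)) {
    stop("invariant violated: all elements of `spectra` must be ir_spectrum objects",
         call. = FALSE)
  }
  regs <- vapply(spectra, `[[`, character(1), "region")
  if (!all(regs == region)) {
    stop("invariant violated: all spectra must share the line scan's region",
         call. = FALSE)
  }
  depths <- vapply(spectra, `[[`, numeric(1), "depth_um")
  if (any(diff(depths) <= 0)) {
    stop("invariant violated: spectrum depths must be strictly increasing",
         call. = FALSE)
  }
  structure(list(liner_id = liner_id, region = region, spectra = spectra),
            class = "ir_linescan")
}

#' @export
print.ir_linescan <- function(x, ...) {
  d <- linescan_depths(x)
  cat(sprintf("<ir_linescan> liner %s, region %s, %d spectra, depths %.0f-%.0f um\n",
              x$liner_id, x$region, length(x$spectra), min(d), max(d)))
  invisible(x)
}

#' Depths of a line scan
#'
#' @param ls An [ir_linescan()].
#' @return Numeric vector of depths (um), strictly increasing.
#' @export
linescan_depths <- function(ls) {
  stopifnot(inherits(ls, "ir_linescan"))
  vapply(ls$spectra, `[[`, numeric(1), "depth_um")
}

#' Instrumented indentation load-depth-time record
#'
#' One Vickers indent recorded as synchronized time, load and depth arrays
#' with a segment label per sample. Segments must appear as contiguous
#' blocks in the order loading, hold, unloading (the hold block may be
#' empty).
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param load_mN Load in millinewtons.
#' @param depth_um Penetration depth in micrometres.
#' @param segment Character/factor vector with values `"loading"`, `"hold"`,
#'   `"unloading"`.
#' @return An object of class `indentation_curve`.
#' @export
indentation_curve <- function(time_s, load_mN, depth_um, segment) {
  time_s <- as.numeric(time_s); load_mN <- as.numeric(load_mN)
  depth_um <- as.numeric(depth_um); segment <- as.character(segment)
  n <- length(time_s)
  if (n < 10L) {
    stop("invariant violated: indentation curve needs >= 10 samples", call. = FALSE)
  }
  if (length(load_mN) != n || length(depth_um) != n || length(segment) != n) {
    stop("invariant violated: time, load, depth and segment must have equal length",
         call. = FALSE)
  }
  if (anyNA(time_s) || any(diff(time_s) <= 0)) {
    stop("invariant violated: time must be strictly increasing", call. = FALSE)
  }
  allowed <- c("loading", "hold", "unloading")
  if (!all(segment %in% allowed)) {
    stop("invariant violated: segment labels must be loading/hold/unloading",
         call. = FALSE)
  }
  runs <- rle(segment)
  if (anyDuplicated(runs$values)) {
    stop("invariant violated: each segment must be one contiguous block",
         call. = FALSE)
  }
  expected <- allowed[allowed %in% runs$values]
  if (!identical(runs$values, expected) ||
      !all(c("loading", "unloading") %in% runs$values)) {
    stop("invariant violated: segments must appear in order loading -> hold -> unloading",
         call. = FALSE)
  }
  structure(list(time_s = time_s, load_mN = load_mN, depth_um = depth_um,
                 segment = segment),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf("<indentation_curve> %d samples, P_max %.1f mN, h_max %.2f um (%s)\n",
              length(x$time_s), max(x$load_mN), max(x$depth_um),
              paste(rle(x$segment)$values, collapse = "/")))
  invisible(x)
}
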