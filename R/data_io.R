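# Text dialects for IR line scans and indentation curves.
#
# Long-CSV line scan: columns (liner_id, region, depth_um, wavenumber,
# absorbance), one row per spectral point.
# JCAMP multi-block: one ##TITLE...##END block per spectrum with
# ##XUNITS=1/CM, ##YUNITS=ABSORBANCE, depth carried in a $$DEPTH_UM comment
# and (wavenumber, absorbance) pairs under ##XYDATA=(XY..XY).
# Indentation CSV: columns (time_s, load_mN, depth_um, segment).
# Floats are serialized with 12 significant digits so write -> read is the
# identity to well below 1e-9 relative.

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write an IR line scan to a text file
#'
#' @param ls An [ir_linescan()].
#' @param path Output path.
#' @param dialect `"csv"` (long CSV) or `"jcamp"` (minimal JCAMP-DX
#'   multi-block).
#' @return `path`, invisibly.
#' @export
write_linescan <- function(ls, path, dialect = c("csv", "jcamp")) {
  stopifnot(inherits(ls, "ir_linescan"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rows <- do.call(rbind, lapply(ls$spectra, function(sp) {
      data.frame(liner_id = ls$liner_id, region = ls$region,
                 depth_um = fmt_num(sp$depth_um),
                 wavenumber = fmt_num(sp$wavenumber),
                 absorbance = fmt_num(sp$absorbance),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in ls$spectra) {
      writeLines(c(
        sprintf("##TITLE=%s region=%s", ls$liner_id, ls$region),
        "##JCAMP-DX=4.24",
        "##DATA TYPE=INFRARED SPECTRUM",
        sprintf("$$DEPTH_UM=%s", fmt_num(sp$depth_um)),
        "##XUNITS=1/CM",
        "##YUNITS=ABSORBANCE",
        sprintf("##NPOINTS=%d", length(sp$wavenumber)),
        "##XYDATA=(XY..XY)"
      ), con)
      writeLines(paste(fmt_num(sp$wavenumber), fmt_num(sp$absorbance),
                       sep = ", "), con)
      writeLines("##END=", con)
    }
  }
  invisible(path)
}

#' Read an IR line scan from a text file
#'
#' Accepts wavenumbers in either direction (canonicalized on
#' construction). Duplicate depths, missing columns and non-monotone
#' wavenumber axes are rejected with context.
#'
#' @param path Input path.
#' @param dialect `"csv"` or `"jcamp"`.
#' @return An [ir_linescan()].
#' @export
read_linescan <- function(path, dialect = c("csv", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("liner_id", "region", "depth_um", "wavenumber", "absorbance")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("line-scan CSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (length(unique(df$liner_id)) != 1L || length(unique(df$region)) != 1L) {
      stop("line-scan CSV must contain exactly one liner_id and one region",
           call. = FALSE)
    }
    depths <- sort(unique(df$depth_um))
    spectra <- lapply(depths, function(d) {
      sub <- df[df$depth_um == d, ]
      tryCatch(
        ir_spectrum(sub$wavenumber, sub$absorbance, depth_um = d,
                    region = df$region[1]),
        error = function(e) stop(sprintf("at depth %g um: %s", d,
                                         conditionMessage(e)), call. = FALSE))
    })
    ir_linescan(df$liner_id[1], df$region[1], spectra)
  } else {
    lines <- readLines(path)
    starts <- grep("^##TITLE=", lines)
    ends <- grep("^##END=", lines)
    if (length(starts) == 0L || length(starts) != length(ends)) {
      stop("malformed JCAMP file: unbalanced ##TITLE/##END blocks", call. = FALSE)
    }
    liner_id <- region <- NULL
    spectra <- vector("list", length(starts))
    depths_seen <- numeric(0)
    for (b in seq_along(starts)) {
      blk <- lines[starts[b]:ends[b]]
      title <- sub("^##TITLE=", "", blk[1])
      m <- regmatches(title, regexec("^(\\S+) region=(\\S+)$", title))[[1]]
      if (length(m) != 3L) {
        stop("block ", b, ": ##TITLE must be '<liner_id> region=<U|W>'",
             call. = FALSE)
      }
      liner_id <- liner_id %||% m[2]; region <- region %||% m[3]
      dline <- grep("^\\$\\$DEPTH_UM=", blk, value = TRUE)
      if (length(dline) != 1L) {
        stop("block ", b, ": missing $$DEPTH_UM comment", call. = FALSE)
      }
      depth <- as.numeric(sub("^\\$\\$DEPTH_UM=", "", dline))
      if (depth %in% depths_seen) {
        stop("block ", b, sprintf(": duplicate depth %g um", depth), call. = FALSE)
      }
      depths_seen <- c(depths_seen, depth)
      i0 <- grep("^##XYDATA=", blk)
      if (length(i0) != 1L) stop("block ", b, ": missing ##XYDATA", call. = FALSE)
      xy <- blk[(i0 + 1):(length(blk) - 1L)]
      parts <- strsplit(xy, ",")
      wn <- as.numeric(vapply(parts, `[[`, character(1), 1))
      ab <- as.numeric(vapply(parts, `[[`, character(1), 2))
      spectra[[b]] <- tryCatch(
        ir_spectrum(wn, ab, depth_um = depth, region = region),
        error = function(e) stop("block ", b, ": ", conditionMessage(e),
                                 call. = FALSE))
    }
    o <- order(depths_seen)
    ir_linescan(liner_id, region, spectra[o])
  }
}

#' Write an indentation curve to CSV
#'
#' @param curve An [indentation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indentation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "indentation_curve"))
  df <- data.frame(time_s = fmt_num(curve$time_s),
                   load_mN = fmt_num(curve$load_mN),
                   depth_um = fmt_num(curve$depth_um),
                   segment = curve$segment, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indentation curve from CSV
#'
#' @param path CSV with columns `time_s`, `load_mN`, `depth_um`, `segment`.
#' @return A validated [indentation_curve()].
#' @export
read_indentation_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("time_s", "load_mN", "depth_um", "segment")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("indentation CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  indentation_curve(df$time_s, df$load_mN, df$depth_um, df$segment)
}
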