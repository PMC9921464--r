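# MDBASE-style statistics layer: Pearson correlations with p-values,
# pairwise-complete correlation matrices with heatmap export, power-law
# structure-property fits, type-7 quartile/Tukey boxplot statistics,
# two-group comparisons and scatter-matrix regression summaries.

records_of <- function(db) {
  if (inherits(db, "retrieval_db")) db$records else as.data.frame(db, check.names = FALSE)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation over the pairwise-complete observations, with
#' the two-sided p-value from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @param labels Optional length-2 character vector of variable names.
#' @return List with `labels`, `n`, `r`, `p`.
#' @export
pearson_with_p <- function(x, y, labels = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(labels = labels, n = n, r = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise-complete correlation matrix
#'
#' Pearson r, p and pair counts for every pair of the selected numeric
#' columns, using pairwise deletion of missing values (micromechanical
#' properties are typically measured for a subset of liners only; listwise
#' deletion would discard most records). Cells with fewer than 3 complete
#' pairs or zero variance are flagged NA.
#'
#' @param db A [retrieval_db()] or data frame.
#' @param columns Character vector of >= 2 column names.
#' @return Object of class `correlation_matrix`: list with symmetric
#'   matrices `r` (unit diagonal), `p` and `n`.
#' @export
correlation_matrix <- function(db, columns) {
  df <- records_of(db)
  if (length(columns) < 2L) stop("need >= 2 columns", call. = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss)) {
    stop("unknown column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  k <- length(columns)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nm[i, i] <- sum(!is.na(df[[columns[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      res <- tryCatch(
        pearson_with_p(df[[columns[i]]], df[[columns[j]]],
                       labels = columns[c(i, j)]),
        error = function(e) NULL)
      if (!is.null(res)) {
        r[i, j] <- r[j, i] <- res$r
        p[i, j] <- p[j, i] <- res$p
        nm[i, j] <- nm[j, i] <- res$n
      }
    }
  }
  structure(list(r = r, p = p, n = nm), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> Pearson r (pairwise complete):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Heatmap of a correlation matrix
#'
#' Renders Pearson r as a heatmap (darker red = stronger correlation), a
#' pure function of the statistics object.
#'
#' @param cm A [correlation_matrix()] result.
#' @param path Optional output file (png/svg/pdf by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_correlation_heatmap <- function(cm, path = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  cols <- colnames(cm$r)
  d <- expand.grid(x = cols, y = cols, stringsAsFactors = FALSE)
  d$r <- as.vector(cm$r)
  d$x <- factor(d$x, levels = cols)
  d$y <- factor(d$y, levels = rev(cols))
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(min(0, min(cm$r, na.rm = TRUE)), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 7, height = 6, dpi = 150)
  invisible(g)
}

#' Fit a power law y = k x^n
#'
#' Nonlinear least squares in the original space (Levenberg-Marquardt),
#' initialized from ordinary least squares on log-log axes. This is the
#' relationship the crystallinity index follows as a function of the
#' oxidation index (CI = k OI^n): fast, almost linear growth at low
#' oxidation, slower growth at high oxidation.
#'
#' @param x,y Positive numeric vectors (>= 3 points).
#' @return Object of class `power_law_fit`: list with `k`, `n`, `rss`,
#'   `se_k`, `se_n`, `fitted`.
#' @export
fit_power_law <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("power-law fit needs strictly positive x and y", call. = FALSE)
  }
  ll <- stats::lm(log(y) ~ log(x))
  k0 <- exp(unname(stats::coef(ll)[1])); n0 <- unname(stats::coef(ll)[2])
  rss0 <- sum((y - k0 * x^n0)^2)
  if (rss0 <= 1e-24 * sum(y^2)) {
    # the log-log initialization already interpolates the data (noise-free
    # power law); refinement would only feed a singular gradient to the
    # optimizer
    return(structure(list(k = k0, n = n0, rss = rss0, se_k = 0, se_n = 0,
                          fitted = k0 * x^n0),
                     class = "power_law_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ k * x^n, data = list(x = x, y = y),
                      start = list(k = k0, n = n0),
                      lower = c(k = 1e-12, n = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(sprintf("power-law fit did not converge (log-log fallback: k=%.6g, n=%.6g): %s",
                   k0, n0, conditionMessage(e)), call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k = NA_real_, n = NA_real_))
  structure(list(k = unname(cf[["k"]]), n = unname(cf[["n"]]),
                 rss = sum(stats::resid(fit)^2),
                 se_k = unname(se[["k"]]), se_n = unname(se[["n"]]),
                 fitted = stats::fitted(fit)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g (rss %.3g)\n", x$k, x$n, x$rss))
  invisible(x)
}

#' Boxplot statistics for one group
#'
#' Five-number summary with quartiles by linear interpolation (quantile
#' type 7). In `"tukey"` whisker mode (default) the whiskers end at the
#' most extreme observations within 1.5 IQR of the quartiles and points
#' beyond are listed as outliers; `"minmax"` mode draws whiskers at the
#' sample extremes with no outliers.
#'
#' @param values Numeric vector (>= 1 non-missing value).
#' @param group Group label.
#' @param whisker_mode `"tukey"` or `"minmax"`.
#' @return Object of class `boxplot_stats`: list with `group`, `n`, `min`,
#'   `q1`, `median`, `q3`, `max`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values, group = "all", whisker_mode = c("tukey", "minmax")) {
  whisker_mode <- match.arg(whisker_mode)
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need >= 1 non-missing value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  if (whisker_mode == "tukey") {
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- values[values >= lo_fence & values <= hi_fence]
    outliers <- sort(values[values < lo_fence | values > hi_fence])
    wl <- min(inside); wh <- max(inside)
  } else {
    outliers <- numeric(0)
    wl <- min(values); wh <- max(values)
  }
  structure(list(group = group, n = length(values), min = min(values),
                 q1 = q[1], median = q[2], q3 = q[3], max = max(values),
                 whisker_low = wl, whisker_high = wh, outliers = outliers),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("<boxplot_stats> %s (n=%d): min %.3g | Q1 %.3g | med %.3g | Q3 %.3g | max %.3g, %d outlier(s)\n",
              x$group, x$n, x$min, x$q1, x$median, x$q3, x$max,
              length(x$outliers)))
  invisible(x)
}

#' Grouped boxplot statistics from a database column
#'
#' @param db A [retrieval_db()] or data frame.
#' @param value_col Numeric column to summarize.
#' @param group_col Grouping column (e.g. `"sterilization"` or
#'   `"failure_reason"`).
#' @param whisker_mode Passed to [boxplot_stats()].
#' @return Named list of [boxplot_stats()] per group level present.
#' @export
grouped_boxplot_stats <- function(db, value_col, group_col,
                                  whisker_mode = "tukey") {
  df <- records_of(db)
  for (col in c(value_col, group_col)) {
    if (!col %in% names(df)) stop("unknown column: ", col, call. = FALSE)
  }
  groups <- sort(unique(stats::na.omit(df[[group_col]])))
  out <- lapply(groups, function(g) {
    v <- df[[value_col]][!is.na(df[[group_col]]) & df[[group_col]] == g]
    v <- v[!is.na(v)]
    if (length(v) < 1L) return(NULL)
    boxplot_stats(v, group = g, whisker_mode = whisker_mode)
  })
  names(out) <- groups
  out[!vapply(out, is.null, logical(1))]
}

#' Grouped boxplot figure
#'
#' @param db A [retrieval_db()] or data frame.
#' @param value_col,group_col Columns as in [grouped_boxplot_stats()].
#' @param path Optional output file.
#' @return The ggplot object, invisibly.
#' @export
plot_group_boxplots <- function(db, value_col, group_col, path = NULL) {
  df <- records_of(db)
  d <- df[!is.na(df[[group_col]]) & !is.na(df[[value_col]]),
          c(group_col, value_col)]
  names(d) <- c("group", "value")
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 18, outlier.size = 2.5) +
    ggplot2::labs(x = group_col, y = value_col) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 6, height = 4, dpi = 150)
  invisible(g)
}

#' Two-group comparison
#'
#' Welch's t test (default; robust to the unequal group variances typical
#' of sterilization cohorts) or the Mann-Whitney rank test, two-sided.
#' When both groups are constant with equal means, p = 1 by convention.
#'
#' @param a,b Numeric vectors (>= 2 non-missing values each).
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @param labels Length-2 group labels.
#' @return Object of class `group_comparison`: list with `labels`, `n`,
#'   `means`, `statistic`, `p`, `method`.
#' @export
compare_groups <- function(a, b, method = c("welch_t", "mann_whitney"),
                           labels = c("a", "b")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(labels = labels, n = c(length(a), length(b)),
                            means = c(mean(a), mean(b)), statistic = 0,
                            p = 1, method = method),
                       class = "group_comparison"))
    }
    stop("both groups constant with different means; test degenerate",
         call. = FALSE)
  }
  res <- if (method == "welch_t") {
    stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  } else {
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  }
  structure(list(labels = labels, n = c(length(a), length(b)),
                 means = c(mean(a), mean(b)),
                 statistic = unname(res$statistic), p = res$p.value,
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s): means %.3g / %.3g, p = %.4g\n",
              x$labels[1], x$labels[2], x$method, x$means[1], x$means[2], x$p))
  invisible(x)
}

#' Scatter-matrix regression summary
#'
#' For every ordered pair of the selected columns: the ordinary
#' least-squares line, the pointwise 95% confidence half-width of the mean
#' response evaluated at each observed x, and the Pearson r and p (equal to
#' [pearson_with_p()] by construction). The diagonal carries histogram
#' summaries (bin edges and counts).
#'
#' @param db A [retrieval_db()] or data frame.
#' @param columns Character vector of >= 2 column names.
#' @return List with `pairs` (data frame: x, y, n, slope, intercept, r, p,
#'   ci_halfwidth_at_mean, degenerate), `ci_bands` (per-pair data frames of
#'   x, fit, half-width), and `histograms` (per-column bin edges/counts).
#' @export
scatter_matrix_summary <- function(db, columns) {
  df <- records_of(db)
  if (length(columns) < 2L) stop("need >= 2 columns", call. = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  pairs <- expand.grid(x = columns, y = columns, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, ]
  bands <- list()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xc <- pairs$x[i]; yc <- pairs$y[i]
    ok <- stats::complete.cases(df[[xc]], df[[yc]])
    x <- df[[xc]][ok]; y <- df[[yc]][ok]
    degenerate <- length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0
    if (degenerate) {
      return(data.frame(x = xc, y = yc, n = length(x), slope = NA, intercept = NA,
                        r = NA, p = NA, ci_halfwidth_at_mean = NA,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
    pr <- stats::predict(fit, newdata = data.frame(x = x),
                         interval = "confidence", level = 0.95)
    hw <- (pr[, "upr"] - pr[, "lwr"]) / 2
    bands[[paste(xc, yc, sep = " ~ ")]] <<-
      data.frame(x = x, fit = pr[, "fit"], halfwidth = hw)
    ct <- pearson_with_p(x, y, labels = c(xc, yc))
    hw_at_mean <- hw[which.min(abs(x - mean(x)))]
    data.frame(x = xc, y = yc, n = length(x),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = ct$r, p = ct$p, ci_halfwidth_at_mean = hw_at_mean,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  hists <- lapply(columns, function(cl) {
    v <- df[[cl]][!is.na(df[[cl]])]
    if (length(v) < 1L) return(NULL)
    h <- graphics::hist(v, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(hists) <- columns
  list(pairs = do.call(rbind, rows), ci_bands = bands, histograms = hists)
}

#' Scatter-matrix figure
#'
#' @param db A [retrieval_db()] or data frame.
#' @param columns Columns to plot pairwise.
#' @param path Optional output file.
#' @return The ggplot object, invisibly.
#' @export
plot_scatter_matrix <- function(db, columns, path = NULL) {
  df <- records_of(db)
  pieces <- list()
  for (xc in columns) for (yc in columns) {
    if (xc == yc) next
    ok <- stats::complete.cases(df[[xc]], df[[yc]])
    pieces[[paste(xc, yc)]] <- data.frame(px = xc, py = yc,
                                          x = df[[xc]][ok], y = df[[yc]][ok],
                                          stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, pieces)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, color = "darkred") +
    ggplot2::facet_grid(py ~ px, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 8, height = 8, dpi = 150)
  invisible(g)
}

#' Benjamini-Hochberg adjustment helper for exported p-value tables
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (BH).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
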