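# Method comparison between acquisition schemes: Bland-Altman limits of
# agreement and the Wilcoxon signed-rank test on paired per-slice summaries.

#' Bland-Altman analysis of paired measurements
#'
#' Differences d = a - b; reports mean difference, SD of the differences
#' (n - 1 denominator), and the limits of agreement mean +/- 1.96 SD,
#' together with the per-pair plot data (mean vs difference).
#'
#' @param a,b Paired numeric vectors (same units, same length >= 2).
#' @param label Optional grouping vector (e.g. slice) carried into the plot
#'   data.
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`, `loa`
#'   (lower, upper), `n`, `data` (mean, diff, label).
#' @export
bland_altman <- function(a, b, label = NULL) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least 2 complete pairs")
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(
    mean_diff = md, sd_diff = sdd,
    loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
    n = n,
    data = data.frame(mean = (a + b) / 2, diff = d,
                      label = if (is.null(label)) NA else label[ok])),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  cols <- if (all(is.na(x$data$label))) "black" else
    as.integer(factor(x$data$label)) + 1
  graphics::plot(x$data$mean, x$data$diff, col = cols, pch = 15,
                 xlab = "mean of pair", ylab = "difference", ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Wilcoxon signed-rank test on paired data
#'
#' Two-sided test of symmetric-about-zero paired differences. Zero
#' differences are dropped (with a warning); ties receive midranks. The
#' exact null distribution is used for n <= `exact_max` untied differences,
#' the normal approximation with continuity correction otherwise. If all
#' differences are zero the test is degenerate and p = 1 is returned with a
#' warning.
#'
#' @param a,b Paired numeric vectors, or `a` a vector of differences with
#'   `b` missing.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List: `statistic` (V, sum of positive-difference ranks), `p`,
#'   `n` (nonzero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_max = 25) {
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  d <- d[is.finite(d)]
  nz <- d != 0
  if (sum(!nz) > 0) {
    if (!any(nz)) {
      warning("all differences are zero: degenerate test, p = 1")
      return(list(statistic = NA_real_, p = 1, n = 0L,
                  method = "degenerate"))
    }
    warning("dropping ", sum(!nz), " zero difference(s)")
    d <- d[nz]
  }
  n <- length(d)
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= exact_max && !ties
  res <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value, n = n,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Compare two schemes on one metric
#'
#' Convenience wrapper combining [bland_altman()] and
#' [wilcoxon_signed_rank()] on index-aligned per-(subject, slice) means.
#'
#' @param a,b Paired summary vectors for schemes A and B.
#' @param metric Metric name.
#' @param labels Scheme labels, length 2.
#' @param group Optional grouping (slice) for the plot data.
#' @return Object of class `comparison_result`.
#' @export
compare_schemes <- function(a, b, metric = "MD", labels = c("A", "B"),
                            group = NULL) {
  ba <- bland_altman(a, b, label = group)
  wt <- wilcoxon_signed_rank(a, b)
  structure(list(metric = metric, labels = labels, bland_altman = ba,
                 wilcoxon = wt,
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 p = wt$p, n = ba$n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s - %s = %.4g +/- %.4g (p = %.3g, n = %d)\n",
              x$metric, x$labels[1], x$labels[2],
              x$mean_diff, x$sd_diff, x$p, x$n))
  invisible(x)
}

#' Scheme summary and pairwise-difference table
#'
#' Builds the standard two-part report from per-(subject, slice) metric
#' means of the four acquisition schemes (motion-compensation order M2/M3
#' crossed with maximum b-value): per-scheme global mean +/- SD (median and
#' IQR for E2A), and pairwise difference rows with the mean +/- SD of the
#' paired differences, the difference as a percentage of the first
#' (reference) scheme's mean, and the Wilcoxon signed-rank p-value.
#' Percentages are rounded only in the formatted text, never in the stored
#' values.
#'
#' @param df Long data frame with columns `scheme`, `subject`, `slice`,
#'   `metric`, `value`.
#' @param comparisons List of 2-vectors of scheme names to compare; default:
#'   all pairs sharing a motion order or sharing a b-value, if the four
#'   standard schemes are present.
#' @return List of class `scheme_table`: `per_scheme` data frame,
#'   `differences` data frame.
#' @export
scheme_table <- function(df, comparisons = NULL) {
  stopifnot(all(c("scheme", "subject", "slice", "metric", "value") %in%
                  names(df)))
  schemes <- unique(df$scheme)
  metrics <- unique(df$metric)
  per_scheme <- do.call(rbind, lapply(schemes, function(sc) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- df$value[df$scheme == sc & df$metric == m]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(scheme = sc, metric = m, n = sum(is.finite(v)),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                 median = q[2], q25 = q[1], q75 = q[3])
    }))
  }))
  if (is.null(comparisons)) {
    std <- c("M2_b450", "M2_b1000", "M3_b450", "M3_b1000")
    comparisons <- if (all(std %in% schemes)) {
      list(c("M2_b450", "M2_b1000"), c("M3_b450", "M3_b1000"),
           c("M2_b450", "M3_b450"), c("M2_b1000", "M3_b1000"))
    } else if (length(schemes) == 2) {
      list(schemes)
    } else {
      utils::combn(schemes, 2, simplify = FALSE)
    }
  }
  diff_rows <- list()
  for (cmp in comparisons) {
    for (m in metrics) {
      da <- df[df$scheme == cmp[1] & df$metric == m, ]
      db <- df[df$scheme == cmp[2] & df$metric == m, ]
      key <- function(x) paste(x$subject, x$slice)
      common <- intersect(key(da), key(db))
      if (length(common) < 2) {
        diff_rows[[length(diff_rows) + 1]] <- data.frame(
          scheme_a = cmp[1], scheme_b = cmp[2], metric = m, n = NA_integer_,
          mean_diff = NA_real_, sd_diff = NA_real_, pct_diff = NA_real_,
          p = NA_real_, note = "missing scheme data")
        next
      }
      va <- da$value[match(common, key(da))]
      vb <- db$value[match(common, key(db))]
      cr <- compare_schemes(va, vb, metric = m, labels = cmp)
      ref_mean <- mean(va, na.rm = TRUE)
      diff_rows[[length(diff_rows) + 1]] <- data.frame(
        scheme_a = cmp[1], scheme_b = cmp[2], metric = m, n = cr$n,
        mean_diff = cr$mean_diff, sd_diff = cr$sd_diff,
        pct_diff = 100 * cr$mean_diff / ref_mean, p = cr$p, note = "")
    }
  }
  structure(list(per_scheme = per_scheme,
                 differences = do.call(rbind, diff_rows)),
            class = "scheme_table")
}

#' @export
print.scheme_table <- function(x, ...) {
  cat("Per-scheme summaries:\n")
  ps <- x$per_scheme
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %-9s %-5s %.4g +/- %.4g (median %.4g [%.4g, %.4g])\n",
                ps$scheme[i], ps$metric[i], ps$mean[i], ps$sd[i],
                ps$median[i], ps$q25[i], ps$q75[i]))
  }
  cat("Pairwise differences (A - B, % of scheme A):\n")
  dd <- x$differences
  for (i in seq_len(nrow(dd))) {
    if (nzchar(dd$note[i])) {
      cat(sprintf("  %s vs %s %-5s : %s\n", dd$scheme_a[i], dd$scheme_b[i],
                  dd$metric[i], dd$note[i]))
    } else {
      cat(sprintf("  %s vs %s %-5s : %.4g +/- %.4g (%.0f%%, p = %.2g)\n",
                  dd$scheme_a[i], dd$scheme_b[i], dd$metric[i],
                  dd$mean_diff[i], dd$sd_diff[i], dd$pct_diff[i], dd$p[i]))
    }
  }
  invisible(x)
}
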