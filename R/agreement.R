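#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Shapiro-Wilk test with the argument
#' checking used by the normality gate of [paired_compare()].
#'
#' @param values Numeric vector, `3 <= n <= 5000`, not constant.
#' @return List with `W` and `p`.
#' @export
normality_test <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("Shapiro-Wilk is undefined for a constant sample", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Normality-gated paired comparison
#'
#' Tests the paired differences `a - b` for normality with Shapiro-Wilk at
#' level `alpha`; when normality is not rejected a two-tailed paired t-test
#' is used, otherwise a two-tailed Wilcoxon matched-pairs signed-rank test
#' (zero differences dropped, exact null distribution for n <= 25 and no
#' ties, normal approximation with continuity correction above). Identical
#' samples short-circuit to `p = 1` with the `identical_samples` flag.
#'
#' @param a,b Paired numeric vectors of equal length `>= 3` (e.g. a metric
#'   per volume under two methods or raters).
#' @param alpha Significance level (default 0.05).
#' @param label Optional measurement label carried into the result.
#' @return Object of class `comparison_result`: `test_used` (`"paired_t"`,
#'   `"wilcoxon"` or `"none"`), `statistic`, `p_value`, `alpha`,
#'   `normality_p` (Shapiro-Wilk on the differences), `significant`, `n`,
#'   `identical_samples`, `label`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, label = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    res <- list(test_used = "none", statistic = NA_real_, p_value = 1,
                alpha = alpha, normality_p = NA_real_, significant = FALSE,
                n = n, identical_samples = TRUE, label = label)
    class(res) <- "comparison_result"
    return(res)
  }
  if (stats::sd(d) <= 1e-12 * mean(abs(d))) {
    # constant non-zero shift: zero-variance differences, overwhelming evidence
    res <- list(test_used = "paired_t", statistic = Inf, p_value = 0,
                alpha = alpha, normality_p = NA_real_, significant = TRUE,
                n = n, identical_samples = FALSE, label = label)
    class(res) <- "comparison_result"
    return(res)
  }
  norm_p <- normality_test(d)$p
  if (norm_p >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    test_used <- "paired_t"
    statistic <- unname(tt$statistic); p_value <- tt$p.value
  } else {
    dnz <- d[d != 0]
    if (length(dnz) == 0) {
      statistic <- NA_real_; p_value <- 1
    } else {
      exact <- length(dnz) <= 25 && !any(duplicated(abs(dnz)))
      wt <- suppressWarnings(stats::wilcox.test(
        dnz, alternative = "two.sided", exact = exact, correct = TRUE))
      statistic <- unname(wt$statistic); p_value <- wt$p.value
    }
    test_used <- "wilcoxon"
  }
  res <- list(test_used = test_used, statistic = statistic, p_value = p_value,
              alpha = alpha, normality_p = norm_p,
              significant = p_value < alpha, n = n,
              identical_samples = FALSE, label = label)
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result>%s %s: statistic %.4g, p = %.4g (%s at alpha %.2f), n = %d\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha, x$n))
  if (x$identical_samples) cat("  samples identical\n")
  else if (is.finite(x$normality_p %||% NA))
    cat(sprintf("  normality gate: Shapiro-Wilk p = %.4g on the differences\n",
                x$normality_p))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Differences `a - b` against per-pair means; bias is the mean difference,
#' limits of agreement are `bias +/- 1.96 * sd` with the `n - 1` standard
#' deviation.
#'
#' @param a,b Paired numeric vectors of equal length `>= 3`. For signed STV
#'   analyses orient as (method, manual reference) so the bias reads as the
#'   method's systematic offset.
#' @param label Optional measurement label (e.g. `"STV (cm^3)"`).
#' @return Object of class `bland_altman_summary`: `means`, `differences`,
#'   `bias`, `sd`, `loa_lower`, `loa_upper`, `n`, `label`.
#' @export
bland_altman <- function(a, b, label = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  res <- list(means = (a + b) / 2, differences = d, bias = bias, sd = s,
              loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
              n = length(a), label = label)
  class(res) <- "bland_altman_summary"
  res
}

#' @export
print.bland_altman_summary <- function(x, ...) {
  cat(sprintf("<bland_altman_summary>%s n = %d, bias %.4g, sd %.4g, LoA [%.4g, %.4g]\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$bias, x$sd, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-pair differences against means with the bias and 1.96-sd limits of
#' agreement drawn as horizontal lines.
#'
#' @param x A [bland_altman()] summary.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman_summary <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of methods", ylab = "Difference",
                 main = x$label %||% "Bland-Altman", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Write Bland-Altman plot data as CSV
#'
#' @param ba A [bland_altman()] summary.
#' @param path Output `.csv` path (columns `mean`, `difference`).
#' @return `path`, invisibly.
#' @export
save_bland_altman_csv <- function(ba, path) {
  utils::write.csv(data.frame(mean = ba$means, difference = ba$differences),
                   path, row.names = FALSE)
  invisible(path)
}

#' Per-metric paired comparison report between two methods
#'
#' For every shared metric column, reports mean and SD under each method and
#' the normality-gated paired test between them, mirroring the layout of the
#' standard performance tables.
#'
#' @param records_a,records_b `data.frame`s of per-volume metric records for
#'   the two methods (same volumes, same order, `>= 3` rows). An `id` column,
#'   when present in both, must match.
#' @param metrics Metric columns to compare; defaults to the numeric columns
#'   shared by both tables.
#' @param alpha Significance level.
#' @return `data.frame` with one row per metric: `metric, mean_a, sd_a,
#'   mean_b, sd_b, test_used, p_value, significant, identical_samples`.
#' @export
compare_methods_report <- function(records_a, records_b, metrics = NULL,
                                   alpha = 0.05) {
  if (nrow(records_a) != nrow(records_b))
    stop("methods must be evaluated on matched volume sets", call. = FALSE)
  if (nrow(records_a) < 3)
    stop("need at least 3 matched volumes", call. = FALSE)
  if ("id" %in% names(records_a) && "id" %in% names(records_b) &&
      !identical(records_a$id, records_b$id))
    stop("volume ids of the two methods do not match", call. = FALSE)
  if (is.null(metrics)) {
    shared <- intersect(names(records_a), names(records_b))
    metrics <- shared[vapply(shared, function(m)
      is.numeric(records_a[[m]]) && is.numeric(records_b[[m]]), logical(1))]
    metrics <- setdiff(metrics, c("id", "seed"))
  }
  rows <- lapply(metrics, function(m) {
    va <- records_a[[m]]; vb <- records_b[[m]]
    keep <- is.finite(va) & is.finite(vb)
    va <- va[keep]; vb <- vb[keep]
    if (length(va) < 3) {
      return(data.frame(metric = m, mean_a = mean(va), sd_a = stats::sd(va),
                        mean_b = mean(vb), sd_b = stats::sd(vb),
                        test_used = NA_character_, p_value = NA_real_,
                        significant = NA, identical_samples = NA))
    }
    cmp <- paired_compare(va, vb, alpha = alpha, label = m)
    data.frame(metric = m, mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               test_used = cmp$test_used, p_value = cmp$p_value,
               significant = cmp$significant,
               identical_samples = cmp$identical_samples)
  })
  do.call(rbind, rows)
}
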