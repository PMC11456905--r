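#' Exact paired Wilcoxon signed-rank test
#'
#' The statistic is the sum of the (mid)ranks of the positive paired
#' differences after dropping zero differences. For `n <= 20` retained
#' pairs the two-sided p-value comes from the exact null distribution over
#' all `2^n` equiprobable sign assignments (evaluated by the
#' generating-function recursion, which enumerates the same distribution),
#' as `2 * min(P(W <= w), P(W >= w))` capped at 1. For `n > 20` a normal
#' approximation with tie correction is used and flagged in the result.
#'
#' @param standard,sparing paired numeric vectors of equal length; the
#'   differences tested are `standard - sparing`. Alternatively pass the
#'   differences directly as `standard` and omit `sparing`.
#' @return a list of class `wilcoxon_exact`: `statistic` (W), `p_value`,
#'   `n_used` (pairs after dropping zeros), `method` ("exact" or
#'   "normal_approx"), `degenerate` (all differences zero).
#' @export
wilcoxon_exact <- function(standard, sparing = NULL) {
  d <- if (is.null(sparing)) as.numeric(standard)
       else {
         if (length(standard) != length(sparing))
           stop("paired samples must have equal length", call. = FALSE)
         as.numeric(standard) - as.numeric(sparing)
       }
  if (length(d) < 1) stop("need at least one pair", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, p_value = 1, n_used = 0L,
                          method = "exact", degenerate = TRUE),
                     class = "wilcoxon_exact"))
  r <- rank(abs(d))                      # midranks for ties
  W <- sum(r[d > 0])
  if (n <= 20) {
    ## exact null: counts over all 2^n sign assignments; work on doubled
    ## ranks so midranks become integers
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))     # counts[w + 1] = #assignments with 2W = w
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- round(2 * W)
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, n_used = n, method = method,
                 degenerate = FALSE), class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank (%s): W = %.4g, n = %d, p = %.4g%s\n",
              x$method, x$statistic, x$n_used, x$p_value,
              if (x$degenerate) " [all differences zero]" else ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quantiles by linear interpolation between order statistics (the common
#' type-7 convention of [stats::quantile()]).
#'
#' @param values numeric vector, non-empty.
#' @return named numeric: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Cohort comparison of standard versus sparing plans
#'
#' One row per (structure, quantity): median and IQR per arm, the exact
#' paired Wilcoxon signed-rank p-value, and the mean paired difference
#' (standard minus sparing). With a single patient p-values are reported
#' as `NA` and flagged.
#'
#' @param per_patient_metrics data frame with columns `patient`,
#'   `structure`, `quantity`, `standard`, `sparing` (one row per patient
#'   and metric; both arms present for every patient).
#' @return an object of class `comparison_report` (a data frame) with
#'   columns `structure`, `quantity`, medians/quartiles per arm,
#'   `mean_diff`, `p_value`, `p_method`.
#' @export
compare_cohort <- function(per_patient_metrics) {
  m <- per_patient_metrics
  need <- c("patient", "structure", "quantity", "standard", "sparing")
  if (!all(need %in% names(m)))
    stop("metrics must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(m$standard)) || any(!is.finite(m$sparing)))
    stop("both arms must be present for every patient", call. = FALSE)
  key <- interaction(m$structure, m$quantity, drop = TRUE)
  pats <- sort(unique(m$patient))
  rows <- lapply(split(m, key), function(g) {
    if (!setequal(g$patient, pats) || anyDuplicated(g$patient))
      stop("mismatched patient sets across metrics", call. = FALSE)
    g <- g[order(g$patient), ]
    qs <- median_iqr(g$standard); qp <- median_iqr(g$sparing)
    if (nrow(g) >= 2) {
      wt <- wilcoxon_exact(g$standard, g$sparing)
      p <- wt$p_value; meth <- if (wt$degenerate) "degenerate" else wt$method
    } else { p <- NA_real_; meth <- "not_applicable" }
    data.frame(structure = g$structure[1], quantity = g$quantity[1],
               n = nrow(g),
               standard_median = qs[["median"]], standard_q1 = qs[["q1"]],
               standard_q3 = qs[["q3"]],
               sparing_median = qp[["median"]], sparing_q1 = qp[["q1"]],
               sparing_q3 = qp[["q3"]],
               mean_diff = mean(g$standard - g$sparing),
               p_value = p, p_method = meth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  fmt <- function(m, a, b) sprintf("%.4g (%.4g, %.4g)", m, a, b)
  cat(sprintf("<comparison_report> %d metrics, n = %d patients\n",
              nrow(x), x$n[1]))
  tab <- data.frame(structure = x$structure, quantity = x$quantity,
                    standard = fmt(x$standard_median, x$standard_q1, x$standard_q3),
                    sparing = fmt(x$sparing_median, x$sparing_q1, x$sparing_q3),
                    p = signif(x$p_value, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
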