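#' Paired differences between two measurement methods
#'
#' Pairs the two series by id, drops incomplete pairs and records how many
#' were excluded (e.g. radiographs one method could not read).
#'
#' @param values_a,values_b Numeric measurement vectors.
#' @param ids Optional pairing ids (default positional pairing).
#' @return Object of class `paired_differences` with fields `ids`,
#'   `values_a`, `values_b`, `diffs` (a - b), `n`, `n_excluded`.
#' @export
paired_differences <- function(values_a, values_b, ids = NULL) {
  if (length(values_a) != length(values_b))
    stop("values_a and values_b must have equal length")
  if (is.null(ids)) ids <- seq_along(values_a)
  else if (length(ids) != length(values_a))
    stop("ids must have one entry per pair")
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  keep <- is.finite(a) & is.finite(b)
  structure(list(ids = ids[keep], values_a = a[keep], values_b = b[keep],
                 diffs = a[keep] - b[keep], n = sum(keep),
                 n_excluded = sum(!keep)),
            class = "paired_differences")
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference), 95% limits of agreement (bias +/- 1.96 sd of the
#' differences) and confidence intervals for all three. The bias CI is the
#' usual t interval. Two LoA CI constructions are offered: the classic
#' approximate interval LoA +/- t * sd * sqrt(3/n), and the exact MOVER
#' interval, which combines the t interval for the mean with the chi-square
#' interval for the SD and is asymmetric about the LoA.
#'
#' @param pairs A `paired_differences`, or a numeric vector of differences.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param method `"exact"` (MOVER, default) or `"approximate"`.
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `bias_ci`,
#'   `loa_lower`, `loa_upper`, `loa_lower_ci`, `loa_upper_ci`, `n`,
#'   `n_excluded`, `method`.
#' @export
bland_altman <- function(pairs, alpha = 0.05, method = c("exact", "approximate")) {
  method <- match.arg(method)
  if (inherits(pairs, "paired_differences")) {
    d <- pairs$diffs; n_excl <- pairs$n_excluded
  } else {
    d <- as.numeric(pairs); d <- d[is.finite(d)]; n_excl <- 0L
  }
  n <- length(d)
  if (n < 2L) stop("Bland-Altman analysis needs at least 2 paired differences")
  z <- stats::qnorm(0.975)
  bias <- mean(d); s <- stats::sd(d)
  df <- n - 1L
  tq <- stats::qt(1 - alpha / 2, df)
  if (s == 0) {
    warning("zero variance of differences; limits of agreement degenerate to the bias")
    ci0 <- c(bias, bias)
    return(structure(list(bias = bias, sd_diff = 0, bias_ci = ci0,
                          loa_lower = bias, loa_upper = bias,
                          loa_lower_ci = ci0, loa_upper_ci = ci0,
                          n = n, n_excluded = n_excl, method = method),
                     class = "bland_altman"))
  }
  bias_ci <- bias + c(-1, 1) * tq * s / sqrt(n)
  loa_l <- bias - z * s; loa_u <- bias + z * s
  if (method == "approximate") {
    half <- tq * s * sqrt(3 / n)
    loa_l_ci <- loa_l + c(-1, 1) * half
    loa_u_ci <- loa_u + c(-1, 1) * half
  } else {
    ## MOVER: CI for mu from t; CI for z*sigma from chi-square
    mean_half <- tq * s / sqrt(n)
    sd_hi <- z * s * (sqrt(df / stats::qchisq(alpha / 2, df)) - 1)
    sd_lo <- z * s * (1 - sqrt(df / stats::qchisq(1 - alpha / 2, df)))
    up <- sqrt(mean_half^2 + sd_hi^2)
    dn <- sqrt(mean_half^2 + sd_lo^2)
    loa_u_ci <- c(loa_u - dn, loa_u + up)
    loa_l_ci <- c(loa_l - up, loa_l + dn)
  }
  structure(list(bias = bias, sd_diff = s, bias_ci = bias_ci,
                 loa_lower = loa_l, loa_upper = loa_u,
                 loa_lower_ci = loa_l_ci, loa_upper_ci = loa_u_ci,
                 n = n, n_excluded = n_excl, method = method),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> n = %d (%d excluded), method = %s\n",
              x$n, x$n_excluded, x$method))
  cat(sprintf("  bias %6.2f  [%.2f; %.2f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LoA  %6.2f  [%.2f; %.2f]  to  %6.2f  [%.2f; %.2f]\n",
              x$loa_lower, x$loa_lower_ci[1], x$loa_lower_ci[2],
              x$loa_upper, x$loa_upper_ci[1], x$loa_upper_ci[2]))
  invisible(x)
}

#' Descriptive summary of a long-format measurement table
#'
#' Per metric, side and reader: n, mean, SD (n-1 denominator), min, max and
#' the linearly interpolated quartiles Q1 and Q3 (R quantile type 7).
#'
#' @param table Data frame with at least `metric`, `side`, `value`;
#'   `reader_id` used when present.
#' @return Data frame of group summaries.
#' @export
summarize_measurements <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("metric", "side", "value") %in% names(table)))
  keys <- intersect(c("metric", "side", "reader_id"), names(table))
  groups <- unique(table[keys])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(table))
    for (k in keys) sel <- sel & table[[k]] == groups[i, k]
    v <- table$value[sel]
    data.frame(groups[i, , drop = FALSE], n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v),
               q1 = unname(stats::quantile(v, 0.25, type = 7)),
               q3 = unname(stats::quantile(v, 0.75, type = 7)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
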