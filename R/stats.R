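#' Paired measurement series
#'
#' @param values_a,values_b equal-length finite numeric vectors (same
#'   units)
#' @param labels optional identifiers
#' @return an object of class `PairedSeries`
#' @export
paired_series <- function(values_a, values_b, labels = NULL) {
  if (length(values_a) != length(values_b))
    stop("PairedSeries: lengths differ")
  if (length(values_a) < 1) stop("PairedSeries: need at least one pair")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    stop("PairedSeries: values must be finite")
  if (is.null(labels)) labels <- seq_along(values_a)
  structure(list(labels = labels, values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b)),
            class = "PairedSeries")
}

as_paired <- function(pairs, a = NULL, b = NULL) {
  if (inherits(pairs, "PairedSeries")) return(pairs)
  paired_series(pairs, a)
}

# exact distribution of W+ over signed midranks: dynamic program on the
# generating polynomial prod (1 + x^(2 r_i)) / 2^n (ranks doubled so
# midranks become integers).  Equivalent to enumerating all 2^n sign
# assignments, but O(n * sum r).
signrank_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p  # p[w + 1] = P(2 W+ = w)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Statistic `W = min(W+, W-)` over signed midranks of the nonzero
#' differences (zero differences dropped).  For `n <= 25` the two-sided p
#' is exact, from the full distribution of `W+` under random signs
#' (tie-aware; identical to enumerating all `2^n` sign patterns); beyond
#' that a normal approximation with continuity and tie correction is used.
#'
#' @param pairs a [paired_series()], or a numeric vector with `b`
#' @param b optional second series
#' @param zero_policy only `"drop"` is implemented
#' @param exact_max largest n for the exact distribution (default 25)
#' @return list `W`, `n` (nonzero pairs), `p_value`, `method`
#' @export
wilcoxon_signed_rank <- function(pairs, b = NULL, zero_policy = "drop",
                                 exact_max = 25) {
  zero_policy <- match.arg(zero_policy, "drop")
  ps <- as_paired(pairs, b)
  d <- ps$values_a - ps$values_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate: no nonzero pairs")
  r <- rank(abs(d))  # midranks for ties
  wplus <- sum(r[d > 0])
  wminus <- sum(r[d < 0])
  W <- min(wplus, wminus)
  if (n <= exact_max) {
    dist <- signrank_exact_dist(as.integer(round(2 * r)))
    w2 <- round(2 * wplus)
    total <- length(dist) - 1
    lower <- sum(dist[seq_len(w2 + 1)])              # P(W+ <= wplus)
    upper <- sum(dist[(w2 + 1):(total + 1)])          # P(W+ >= wplus)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (wplus - mu - sign(wplus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(W = W, W_plus = wplus, W_minus = wminus, n = n, p_value = p,
       method = method)
}

#' Pearson product-moment correlation
#'
#' @param pairs a [paired_series()], or a numeric vector with `b`
#' @param b optional second series
#' @return r in `[-1, 1]`
#' @export
pearson_r <- function(pairs, b = NULL) {
  ps <- as_paired(pairs, b)
  x <- ps$values_a
  y <- ps$values_b
  if (length(x) < 2) stop("pearson_r: need at least 2 pairs")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("pearson_r: zero variance in a series")
  max(-1, min(1, sum(xc * yc) / (sx * sy)))
}

#' Bland-Altman agreement with nonparametric limits
#'
#' For non-normally distributed differences the limits of agreement are
#' `median(d) -/+ k * IQR(d)` with `k = 1.45` by default; quartiles use
#' linear interpolation between order statistics.  `center = "mean"` gives
#' the classical mean-centering.
#'
#' @param pairs a [paired_series()], or a numeric vector with `b`
#' @param b optional second series
#' @param k limit factor (default 1.45)
#' @param center `"median"` (default) or `"mean"`
#' @return a `BlandAltmanResult`: `means`, `differences`, `center`,
#'   `limit_low`, `limit_high`, `k`
#' @export
bland_altman <- function(pairs, b = NULL, k = 1.45,
                         center = c("median", "mean")) {
  center <- match.arg(center)
  ps <- as_paired(pairs, b)
  if (length(ps$values_a) < 2) stop("bland_altman: need at least 2 pairs")
  d <- ps$values_a - ps$values_b
  m <- (ps$values_a + ps$values_b) / 2
  ctr <- if (center == "median") stats::median(d) else mean(d)
  iqr <- diff(stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7))
  structure(list(means = m, differences = d, center = ctr,
                 limit_low = ctr - k * iqr, limit_high = ctr + k * iqr,
                 k = k),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman: center %.4g, limits [%.4g, %.4g] (k = %.2f x IQR)\n",
              x$center, x$limit_low, x$limit_high, x$k))
  invisible(x)
}

#' Read paired data from CSV (`label, value_a, value_b`)
#' @param path CSV file
#' @return a [paired_series()]
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path)
  paired_series(df$value_a, df$value_b, labels = df$label)
}
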