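#' Mean and standard error of the mean
#'
#' @param values Numeric vector, `n >= 1`.
#' @return A list of class `group_summary`: `n`, `mean`, `sem`
#'   (sample sd with `n - 1` denominator, divided by `sqrt(n)`).
#'   For `n = 1` the SEM is reported as 0 with a warning.
#' @examples
#' group_summary(c(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n == 1L) {
    warning("n = 1: SEM reported as 0")
    sem <- 0
  } else {
    sem <- stats::sd(values) / sqrt(n)
  }
  structure(list(n = n, mean = mean(values), sem = sem),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g ± %.3g, n = %d\n", x$mean, x$sem, x$n))
  invisible(x)
}

#' Unpaired two-sided t-test
#'
#' Student (pooled-variance) or Welch variant, from raw samples or from
#' printed summary statistics (mean, SEM, n per group), so figure-legend
#' summaries can be cross-checked without raw data.
#'
#' @param a,b In `mode = "raw"`: numeric vectors (each `n >= 2`). In
#'   `mode = "summary"`: lists with elements `mean`, `sem`, `n`.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @param mode `"raw"` or `"summary"`.
#' @return A list of class `test_result`: `t`, `df`, `p` (two-sided),
#'   `stars` (conventional scheme), `variant`, `mode`.
#' @examples
#' ttest_unpaired(list(mean = 3, sem = 0.56, n = 14),
#'                list(mean = 0.36, sem = 0.23, n = 14),
#'                mode = "summary")
#' @export
ttest_unpaired <- function(a, b, variant = c("student", "welch"),
                           mode = c("raw", "summary")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (mode == "raw") {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2L || length(b) < 2L)
      stop("raw mode needs n >= 2 per sample")
    s1 <- list(mean = mean(a), sd = stats::sd(a), n = length(a))
    s2 <- list(mean = mean(b), sd = stats::sd(b), n = length(b))
  } else {
    for (s in list(a, b))
      stopifnot(is.list(s), all(c("mean", "sem", "n") %in% names(s)))
    s1 <- list(mean = a$mean, sd = a$sem * sqrt(a$n), n = a$n)
    s2 <- list(mean = b$mean, sd = b$sem * sqrt(b$n), n = b$n)
    if (s1$sd == 0 && s2$sd == 0) {
      if (s1$mean == s2$mean) {
        res <- structure(list(t = 0, df = s1$n + s2$n - 2, p = 1,
                              stars = "ns", variant = variant, mode = mode),
                         class = "test_result")
        return(res)
      }
      # distinct means with zero spread: evidence is unbounded
      res <- structure(list(t = Inf * sign(s1$mean - s2$mean),
                            df = s1$n + s2$n - 2, p = 0,
                            stars = "****", variant = variant, mode = mode),
                       class = "test_result")
      return(res)
    }
  }
  n1 <- s1$n; n2 <- s2$n
  v1 <- s1$sd^2; v2 <- s2$sd^2
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (s1$mean - s2$mean) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p = p, stars = p_to_stars(p),
                 variant = variant, mode = mode),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.3g (%s), %s %s-mode\n",
              x$t, x$df, x$p, x$stars, x$variant, x$mode))
  invisible(x)
}

#' Significance star labels for p-values
#'
#' Two schemes are offered. `"conventional"` (default) uses strict
#' inequalities at 0.05 / 0.01 / 0.001 / 0.0001 — the scheme every
#' published (p, stars) pair in the source figure legends actually
#' follows. `"gp"` reproduces the GraphPad-style thresholds printed in
#' the methods (0.0001 / 0.0002 / 0.0021 / 0.0332, with `<=` semantics);
#' the printed "0.332" is treated as the evident typo for 0.0332.
#'
#' @param p A p-value in `[0, 1]`.
#' @param scheme `"conventional"` or `"gp"`.
#' @return One of `"****"`, `"***"`, `"**"`, `"*"`, `"ns"`.
#' @examples
#' p_to_stars(0.04)    # "*"
#' p_to_stars(0.0075)  # "**"
#' @export
p_to_stars <- function(p, scheme = c("conventional", "gp")) {
  scheme <- match.arg(scheme)
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (scheme == "conventional") {
    if (p < 0.0001) "****"
    else if (p < 0.001) "***"
    else if (p < 0.01) "**"
    else if (p < 0.05) "*"
    else "ns"
  } else {
    if (p <= 0.0001) "****"
    else if (p <= 0.0002) "***"
    else if (p <= 0.0021) "**"
    else if (p <= 0.0332) "*"
    else "ns"
  }
}

#' 95% Fisher-z confidence interval for a correlation coefficient
#'
#' `tanh(atanh(r) +/- z * / sqrt(n - 3))` with the normal quantile for
#' the requested confidence level.
#'
#' @param r Sample Pearson correlation, in `(-1, 1)`.
#' @param n Sample size, `> 3`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric length-2 vector `(low, high)`.
#' @examples
#' pearson_ci(0.52, 47)  # c(0.27, 0.70) to two decimals
#' @export
pearson_ci <- function(r, n, conf = 0.95) {
  if (abs(r) >= 1) stop("|r| must be < 1 for a Fisher-z interval")
  if (n <= 3) stop("n must exceed 3")
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(r)
  tanh(c(z - zq / sqrt(n - 3), z + zq / sqrt(n - 3)))
}

#' Pearson correlation with Fisher-z CI and least-squares line
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @param conf Confidence level for the Fisher-z interval.
#' @return A list of class `corr_result`: `r`, `n`, `ci_low`, `ci_high`,
#'   `r_squared`, `p` (two-sided, `t = r sqrt(n-2) / sqrt(1-r^2)` on
#'   `n - 2` df), `slope`, `intercept`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30)
#' pearson_regression(x, y)
#' @export
pearson_regression <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  if (abs(r) < 1) {
    ci <- if (n > 3) pearson_ci(r, n, conf) else c(NA_real_, NA_real_)
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  } else {
    ci <- c(r, r); p <- 0
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2],
                 r_squared = r^2, p = p, slope = slope,
                 intercept = intercept),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf(
    "r = %.3g (95%% CI %.3g to %.3g), R^2 = %.3g, p = %.3g, y = %.3g x + %.3g, n = %d\n",
    x$r, x$ci_low, x$ci_high, x$r_squared, x$p, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Figure-legend style summary string
#'
#' Formats a two-group comparison the way figure legends print them,
#' e.g. `"groupA: 3 +/- 0.56, n = 14; groupB: 0.36 +/- 0.23, n = 14;
#' p = 1e-04 (****)"`.
#'
#' @param label_a,label_b Group names.
#' @param summary_a,summary_b [group_summary()] objects.
#' @param test A `test_result` from [ttest_unpaired()].
#' @return A single string.
#' @export
legend_string <- function(label_a, summary_a, label_b, summary_b, test) {
  sprintf("%s: %.3g ± %.3g, n = %d; %s: %.3g ± %.3g, n = %d; p = %.3g (%s)",
          label_a, summary_a$mean, summary_a$sem, summary_a$n,
          label_b, summary_b$mean, summary_b$sem, summary_b$n,
          test$p, test$stars)
}
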