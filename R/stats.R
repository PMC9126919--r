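#' Shared statistical kernel
#'
#' Small wrappers around base R inference used throughout the pipeline:
#' one-sample and paired t-tests that never throw on degenerate
#' (zero-variance) input, Benjamini-Hochberg FDR, permutation p-values and
#' Pearson correlation with explicit missing-value semantics. Brain-wide
#' loops over hundreds of parcels must not abort because one parcel is
#' pathological, so degenerate inputs yield flagged rows instead of errors.
#'
#' @name stats-kernel
NULL

#' One-sample t-test against zero (or another null value)
#'
#' Two-tailed one-sample t-test with Cohen's d (`mean / sd`) and the 95%
#' confidence interval of the mean. Zero-variance input is flagged as
#' `degenerate` rather than raising an error: when every value equals the
#' null the result is `t = 0, p = 1`; when every value equals some other
#' constant, `t` is reported as signed `Inf` with `p = 0`.
#'
#' @param x Numeric vector, `NA`s dropped. Needs at least 2 values.
#' @param mu Null value of the mean (default 0).
#' @param conf_level Confidence level for the CI of the mean.
#' @return A one-row tibble with columns `n`, `estimate`, `t`, `df`, `p`,
#'   `d`, `ci_low`, `ci_high`, `degenerate`.
#' @examples
#' one_sample_t(c(2, 4, 6))
#' @export
one_sample_t <- function(x, mu = 0, conf_level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) {
    stop("one_sample_t() needs at least 2 non-missing values, got ", n)
  }
  m <- mean(x)
  s <- stats::sd(x)
  # mirrors t.test's "essentially constant" guard, but flags instead of
  # erroring so parcel-wise loops survive degenerate cells
  if (s == 0 || s / sqrt(n) < 10 * .Machine$double.eps * abs(m)) {
    s <- 0
  }
  if (s == 0) {
    if (m == mu) {
      return(tibble::tibble(
        n = n, estimate = m, t = 0, df = n - 1L, p = 1,
        d = 0, ci_low = m, ci_high = m, degenerate = TRUE
      ))
    }
    sgn <- sign(m - mu)
    return(tibble::tibble(
      n = n, estimate = m, t = sgn * Inf, df = n - 1L, p = 0,
      d = sgn * Inf, ci_low = m, ci_high = m, degenerate = TRUE
    ))
  }
  fit <- stats::t.test(x, mu = mu, conf.level = conf_level)
  tibble::tibble(
    n = n,
    estimate = m,
    t = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p = fit$p.value,
    d = (m - mu) / s,
    ci_low = fit$conf.int[1],
    ci_high = fit$conf.int[2],
    degenerate = FALSE
  )
}

#' Paired t-test
#'
#' Reduces to [one_sample_t()] on the element-wise differences `x - y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @inheritParams one_sample_t
#' @return A one-row tibble, see [one_sample_t()].
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) {
    stop("paired_t(): lengths differ (", length(x), " vs ", length(y), ")")
  }
  one_sample_t(x - y, mu = 0, conf_level = conf_level)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control across a family of p-values. Returns BH-adjusted
#' q-values (via [stats::p.adjust()]) and the rejection decision at level
#' `q`; rejecting where `q_value <= q` is equivalent to the classical
#' step-up rule.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed; `NA`
#'   entries are never rejected).
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p`, `q_value`, `rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("bh_fdr(): p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("bh_fdr(): q must lie in (0, 1)")
  qv <- rep(NA_real_, length(p))
  qv[ok] <- stats::p.adjust(p[ok], method = "BH")
  tibble::tibble(
    p = p,
    q_value = qv,
    rejected = !is.na(qv) & qv <= q
  )
}

#' Permutation p-value
#'
#' One-tailed p-value as the proportion of null values greater than or
#' equal to the observed statistic (ties count). The literal proportion may
#' be exactly 0; `smoothing = TRUE` applies the add-one rule
#' `(1 + count) / (1 + n)` which keeps p-values strictly positive for
#' downstream FDR stability.
#'
#' @param observed Observed statistic (scalar).
#' @param null Numeric vector of null statistics, non-empty.
#' @param smoothing Apply add-one smoothing? Default `FALSE` (literal rule).
#' @return Scalar p-value.
#' @export
perm_pvalue <- function(observed, null, smoothing = FALSE) {
  if (length(null) < 1) stop("perm_pvalue(): empty null distribution")
  cnt <- sum(null >= observed)
  if (smoothing) (1 + cnt) / (1 + length(null)) else cnt / length(null)
}

#' Pearson correlation with explicit degenerate handling
#'
#' Standard product-moment correlation over complete pairs. Returns `NA`
#' (rather than erroring or warning) when fewer than 2 complete pairs
#' remain or either variable is constant, so callers decide how to treat
#' undefined cells.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar correlation or `NA_real_`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_r(): lengths differ (", length(x), " vs ", length(y), ")")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Run `expr` under `seed` when given, leaving the global RNG state alone;
# with seed = NULL the current RNG stream is used (and advanced).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
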