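#' Signed divergence of the width-based from the image-based estimate
#'
#' `100 * (wAL - iAL) / iAL`, the per-leaf relative difference referenced to
#' the image-based area.
#'
#' @param wal Width-based area estimate(s), cm^2.
#' @param ial Image-based area estimate(s), cm^2; must be > 0.
#' @return Signed percentage(s).
#' @examples
#' divergence_percent(1.05, 1.0) # +5
#' @export
divergence_percent <- function(wal, ial) {
  if (any(!is.finite(ial)) || any(ial <= 0)) {
    stop("invalid-reference: image-based area must be > 0", call. = FALSE)
  }
  100 * (wal - ial) / ial
}

#' Zero-intercept regression between two area estimators
#'
#' Fits Y = bX through the origin (least squares, b = sum(xy) / sum(x^2)).
#' Two R^2 conventions are reported: `r.squared` is referenced to the mean of
#' y (1 - RSS/TSS about the mean), the non-vacuous statement for tightly
#' clustered areas; `r.squared.origin` is the regression-through-origin
#' convention referenced to zero.
#'
#' @param x,y Numeric vectors of equal length (n >= 2); x not all zero.
#' @return An object of class `origin_fit` wrapping the underlying `lm`.
#' @examples
#' f <- fit_origin_regression(1:3, 2 * (1:3))
#' glance(f)
#' @export
fit_origin_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("degenerate-regression: need n >= 2", call. = FALSE)
  if (all(x == 0)) stop("degenerate-regression: all x are zero", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x, data = data.frame(x = x, y = y))
  rss <- sum(stats::resid(fit)^2)
  structure(
    list(fit = fit, n = length(x),
         slope = unname(stats::coef(fit)[1]),
         r_squared = 1 - rss / sum((y - mean(y))^2),
         r_squared_origin = 1 - rss / sum(y^2)),
    class = "origin_fit"
  )
}

#' @importFrom generics tidy
#' @method tidy origin_fit
#' @export
tidy.origin_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = "slope", estimate = s[1, 1], std.error = s[1, 2],
                 statistic = s[1, 3], p.value = s[1, 4])
}

#' @importFrom generics glance
#' @method glance origin_fit
#' @export
glance.origin_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r.squared = x$r_squared,
                 r.squared.origin = x$r_squared_origin, n = x$n)
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> Y = %.4f X, R^2 = %.4f (origin-referenced %.4f), n = %d\n",
              x$slope, x$r_squared, x$r_squared_origin, x$n))
  invisible(x)
}

#' Paired comparison of two area estimators
#'
#' Standard paired t-test on the per-leaf differences (two-sided p from the t
#' distribution on n - 1 df) with a Shapiro-Wilk normality check on the same
#' differences. A zero difference variance makes t undefined; the result is
#' then flagged degenerate rather than raising an error, since identical
#' estimators are a legitimate (perfect-agreement) outcome.
#'
#' @param a,b Numeric vectors of equal length, n >= 3.
#' @return A one-row tibble: `n`, `mean_diff`, `t`, `df`, `p`, `shapiro_p`,
#'   `degenerate`.
#' @export
paired_area_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("degenerate-test: need n >= 3 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(n = n, mean_diff = mean(d), t = NA_real_,
                          df = n - 1, p = NA_real_, shapiro_p = NA_real_,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  sw <- stats::shapiro.test(d)
  tibble::tibble(n = n, mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 shapiro_p = sw$p.value, degenerate = FALSE)
}

#' Agreement analysis between width-based and image-based areas
#'
#' The method-comparison summary for paired area estimates: per-leaf signed
#' divergence, zero-intercept regression of the width-based on the
#' image-based estimate, and a paired t-test with a normality check.
#'
#' @param data A data frame of paired estimates.
#' @param wal,ial Columns (tidy-eval) holding the width-based and image-based
#'   areas, cm^2. Defaults `wAL_cm2`, `iAL_cm2`.
#' @param label Optional identifier column.
#' @return An object of class `area_agreement`; see [glance.area_agreement()]
#'   for the one-row summary and [tidy.area_agreement()] for per-leaf rows.
#' @examples
#' pairs <- tibble::tibble(wAL_cm2 = c(1, 1.5, 1.9), iAL_cm2 = c(1.02, 1.49, 1.88))
#' glance(area_agreement(pairs))
#' @export
area_agreement <- function(data, wal = wAL_cm2, ial = iAL_cm2, label = NULL) {
  wal <- rlang::eval_tidy(rlang::enquo(wal), data)
  ial <- rlang::eval_tidy(rlang::enquo(ial), data)
  lab <- rlang::eval_tidy(rlang::enquo(label), data)
  if (is.null(lab)) lab <- seq_along(wal)
  per_leaf <- tibble::tibble(
    label = lab, wAL_cm2 = wal, iAL_cm2 = ial,
    divergence_pct = divergence_percent(wal, ial)
  )
  structure(
    list(per_leaf = per_leaf,
         fit = fit_origin_regression(ial, wal),
         test = paired_area_test(ial, wal)),
    class = "area_agreement"
  )
}

#' @rdname area_agreement
#' @param x An `area_agreement` object.
#' @param ... Unused.
#' @importFrom generics tidy
#' @method tidy area_agreement
#' @export
tidy.area_agreement <- function(x, ...) x$per_leaf

#' @rdname area_agreement
#' @importFrom generics glance
#' @method glance area_agreement
#' @export
glance.area_agreement <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$per_leaf),
    max_abs_divergence_pct = max(abs(x$per_leaf$divergence_pct)),
    slope = x$fit$slope,
    r.squared = x$fit$r_squared,
    t = x$test$t, p = x$test$p, shapiro_p = x$test$shapiro_p,
    degenerate = x$test$degenerate
  )
}

#' @export
print.area_agreement <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<area_agreement> n = %d leaves\n  Y = %.4f X, R^2 = %.4f\n  max |divergence| = %.2f%%\n  paired t = %s, p = %s (Shapiro-Wilk p = %s)\n",
    g$n, g$slope, g$r.squared, g$max_abs_divergence_pct,
    fmt_or_na(g$t), fmt_or_na(g$p), fmt_or_na(g$shapiro_p)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA (degenerate)" else sprintf("%.4f", v)
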