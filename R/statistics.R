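#' Construct a log-normal fit object
#'
#' Container for a log-normal size-distribution fit in the median/shape
#' parameterisation: `mu_star` is the median (nm) and `sigma_star` the
#' multiplicative shape (dimensionless, >= 1); 68.3% of the fitted model's
#' mass lies in `[mu_star / sigma_star, mu_star * sigma_star]`.
#'
#' @param mu_star scale (median), nm.
#' @param sigma_star multiplicative shape, >= 1.
#' @param ci_mu,ci_sigma optional length-2 bootstrap 95% CIs.
#' @param n sample size behind the fit.
#' @param n_boot bootstrap replicates used for the CIs.
#' @return A list of class `lognormal_fit`.
#' @export
lognormal_fit <- function(mu_star, sigma_star, ci_mu = NULL, ci_sigma = NULL,
                          n = NA_integer_, n_boot = NA_integer_) {
  check_positive(mu_star, "mu_star")
  if (sigma_star < 1) stop("`sigma_star` must be >= 1", call. = FALSE)
  for (ci in list(ci_mu, ci_sigma)) {
    if (!is.null(ci) && (length(ci) != 2L || ci[1L] > ci[2L])) {
      stop("confidence intervals must be length-2 with lo <= hi",
           call. = FALSE)
    }
  }
  structure(list(mu_star = mu_star, sigma_star = sigma_star,
                 ci_mu = ci_mu, ci_sigma = ci_sigma,
                 n = n, n_boot = n_boot),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  fmt_ci <- function(v, ci, dg) {
    if (is.null(ci)) return(sprintf("%.*f", dg, v))
    sprintf("%.*f [-%.*f, +%.*f]", dg, v, dg, v - ci[1L], dg, ci[2L] - v)
  }
  cat("<lognormal_fit>\n")
  cat("  scale mu* :", fmt_ci(x$mu_star, x$ci_mu, 1L), "nm\n")
  cat("  shape sig*:", fmt_ci(x$sigma_star, x$ci_sigma, 3L), "\n")
  if (!is.na(x$n)) cat("  n =", x$n, "\n")
  invisible(x)
}

#' Fit a log-normal size distribution
#'
#' Closed-form log-moment estimator: `mu_star = exp(mean(log(x)))` (geometric
#' mean) and `sigma_star = exp(sd(log(x)))` (geometric standard deviation),
#' which is exact for log-normal data. 95% confidence intervals come from a
#' seeded percentile bootstrap; pass `n_boot = 0` to skip them. The histogram
#' method fits bin centres weighted by counts — an approximation appropriate
#' for binned instrument exports.
#'
#' @param x a [diameter_sample()], numeric vector (nm) or [size_histogram()].
#' @param n_boot bootstrap replicates for the CIs (0 to skip).
#' @param level confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @param ... passed to methods.
#' @return A [lognormal_fit()].
#' @export
fit_lognormal <- function(x, ...) UseMethod("fit_lognormal")

#' @rdname fit_lognormal
#' @export
fit_lognormal.default <- function(x, n_boot = 10000, level = 0.95,
                                  seed = NULL, ...) {
  values <- as_diameter_values(x)
  if (length(values) < 3L) {
    stop("log-normal fit needs at least 3 values", call. = FALSE)
  }
  lx <- log(values)
  fit <- lognormal_fit(exp(mean(lx)), exp(sd(lx)),
                       n = length(values), n_boot = n_boot)
  if (n_boot > 0) {
    alpha <- (1 - level) / 2
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        r <- lx[sample.int(length(lx), replace = TRUE)]
        c(exp(mean(r)), exp(sd(r)))
      }, numeric(2L))
    })
    fit$ci_mu <- unname(quantile(boots[1L, ], c(alpha, 1 - alpha)))
    fit$ci_sigma <- unname(quantile(boots[2L, ], c(alpha, 1 - alpha)))
  }
  fit
}

#' @rdname fit_lognormal
#' @export
fit_lognormal.size_histogram <- function(x, ...) {
  w <- x$counts
  keep <- w > 0
  lc <- log(x$bin_centers[keep]); w <- w[keep]
  n <- sum(w)
  if (n < 3) stop("histogram must hold at least 3 counts", call. = FALSE)
  m <- sum(w * lc) / n
  s <- sqrt(sum(w * (lc - m)^2) / (n - 1))
  lognormal_fit(exp(m), exp(s), n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `x` with replacement `n_boot` times, evaluates `statistic` on
#' each resample, and returns the percentile interval. A degenerate
#' (constant) statistic yields a zero-width interval, not an error.
#'
#' @param x numeric vector or [diameter_sample()].
#' @param statistic function of a numeric vector returning one number.
#' @param n_boot number of resamples (>= 1000).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 10000, level = 0.95,
                         seed = NULL) {
  values <- if (inherits(x, "diameter_sample")) unclass(x) else as.numeric(x)
  if (length(values) < 2L) {
    stop("bootstrap needs at least 2 observations", call. = FALSE)
  }
  if (n_boot < 1000) stop("`n_boot` must be at least 1000", call. = FALSE)
  alpha <- (1 - level) / 2
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1L))
  })
  unname(quantile(boots, c(alpha, 1 - alpha)))
}

#' Arithmetic mean with a bootstrap confidence interval
#'
#' @inheritParams bootstrap_ci
#' @return A list of class `mean_ci` with `mean`, `ci`, `n`, `n_boot`,
#'   `level`.
#' @export
mean_with_ci <- function(x, n_boot = 10000, level = 0.95, seed = NULL) {
  values <- if (inherits(x, "diameter_sample")) unclass(x) else as.numeric(x)
  if (!length(values)) stop("empty sample", call. = FALSE)
  ci <- if (length(values) == 1L) {
    c(values, values)
  } else {
    bootstrap_ci(values, mean, n_boot = n_boot, level = level, seed = seed)
  }
  structure(list(mean = mean(values), ci = ci, n = length(values),
                 n_boot = n_boot, level = level),
            class = "mean_ci")
}

#' @export
print.mean_ci <- function(x, ...) {
  cat(sprintf("mean %.1f [-%.1f, +%.1f] nm (n = %d, %g%% bootstrap CI)\n",
              x$mean, x$mean - x$ci[1L], x$ci[2L] - x$mean, x$n,
              100 * x$level))
  invisible(x)
}

#' Are two means significantly different by the CI-overlap rule?
#'
#' `TRUE` iff the two confidence intervals are disjoint. Intervals touching
#' at a single point count as overlapping (conservative), so the result is
#' `FALSE` there.
#'
#' @param a,b [mean_with_ci()] results (or lists with a `ci` element).
#' @return Logical.
#' @export
ci_overlap_significant <- function(a, b) {
  stopifnot(length(a$ci) == 2L, length(b$ci) == 2L)
  a$ci[2L] < b$ci[1L] || b$ci[2L] < a$ci[1L]
}

#' NTA/AFM median-ratio statistic
#'
#' If the log-normal shapes of the hydrodynamic (NTA) and geometric (AFM)
#' diameter distributions agree, the hydrodynamic distribution is a linearly
#' scaled copy of the geometric one and the scaling constant is the ratio of
#' the medians, `mu_star_NTA / mu_star_AFM` — proposed as a physical
#' characteristic of a vesicle population. The shape-compatibility flag is
#' `TRUE` when the two shape CIs overlap (or, lacking CIs, when the shapes
#' differ by at most `shape_tol`); the ratio is still reported, with a
#' warning, when shapes are incompatible.
#'
#' @param fit_nta,fit_afm [lognormal_fit()]s of the hydrodynamic and
#'   geometric diameters.
#' @param shape_tol absolute shape tolerance used when either fit lacks a
#'   shape CI.
#' @return A list with `ratio` and `shapes_compatible`.
#' @export
#' @examples
#' nta_afm_ratio(lognormal_fit(149.2, 1.461), lognormal_fit(71.1, 1.431))
nta_afm_ratio <- function(fit_nta, fit_afm, shape_tol = 0.05) {
  stopifnot(inherits(fit_nta, "lognormal_fit"),
            inherits(fit_afm, "lognormal_fit"))
  ratio <- fit_nta$mu_star / fit_afm$mu_star
  compatible <- if (!is.null(fit_nta$ci_sigma) &&
                    !is.null(fit_afm$ci_sigma)) {
    !(fit_nta$ci_sigma[2L] < fit_afm$ci_sigma[1L] ||
      fit_afm$ci_sigma[2L] < fit_nta$ci_sigma[1L])
  } else {
    abs(fit_nta$sigma_star - fit_afm$sigma_star) <= shape_tol
  }
  if (!compatible) {
    warning("shape parameters are not compatible; the median ratio is not ",
            "a pure scaling constant", call. = FALSE)
  }
  list(ratio = ratio, shapes_compatible = compatible)
}
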