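# Causal estimators for two-sample MR on harmonized summary statistics:
# per-variant Wald ratios, the fixed-effect inverse-variance-weighted (IVW)
# combination, the weighted-median estimator with parametric-bootstrap SE,
# and MR-Egger regression whose intercept estimates average directional
# pleiotropy.  All estimators consume the harmonized tibble produced by
# harmonize_tables() (columns beta_x, se_x, beta_y, se_y).

#' Confidence interval and two-sided p-value for a Wald statistic
#'
#' @param beta Point estimate.
#' @param se Standard error, strictly positive.
#' @param dist Reference distribution: `"normal"` or `"t"`.
#' @param df Degrees of freedom (required for `dist = "t"`).
#' @param level Confidence level (default 0.95).
#' @return Named list with `ci_low`, `ci_high`, `pval`.
#' @export
#' @examples
#' wald_inference(0.168, 0.038)
wald_inference <- function(beta, se, dist = c("normal", "t"), df = NULL,
                           level = 0.95) {
  dist <- match.arg(dist)
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort("se must be finite and > 0", class = "mrpipe_usage_error")
  }
  a <- (1 - level) / 2
  if (dist == "normal") {
    q <- qnorm(1 - a)
    p <- 2 * pnorm(-abs(beta / se))
  } else {
    if (is.null(df)) abort("df required for the t distribution")
    q <- qt(1 - a, df = df)
    p <- 2 * pt(-abs(beta / se), df = df)
  }
  list(ci_low = beta - q * se, ci_high = beta + q * se,
       pval = pmax(p, .Machine$double.xmin))
}

#' Bonferroni-adjusted significance threshold
#'
#' Returns `alpha / n_tests` exactly; display layers round to 3 significant
#' figures (0.05 over 25 instruments prints as 0.002).
#'
#' @param n_tests Number of tests (instrument count in the per-exposure
#'   convention used here); at least 1.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The adjusted p-value threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    abort("n_tests must be a single integer >= 1", class = "mrpipe_usage_error")
  }
  alpha / n_tests
}

#' Per-variant Wald ratio estimates
#'
#' The ratio estimate for one instrument is `beta_y / beta_x`, with
#' first-order standard error `se_y / |beta_x|` (exposure-side uncertainty
#' ignored) and inverse-variance weight `beta_x^2 / se_y^2`.
#'
#' @param h Harmonized-instrument tibble (see [harmonize_tables()]).
#' @return Tibble with `variant_id`, `theta`, `se_theta`, `weight`.
#' @export
wald_ratio <- function(h) {
  if (any(h$beta_x == 0)) {
    abort("degenerate instrument: beta_x = 0 has no ratio estimate",
          class = "mrpipe_degenerate")
  }
  tibble::tibble(
    variant_id = h$variant_id,
    theta = h$beta_y / h$beta_x,
    se_theta = h$se_y / abs(h$beta_x),
    weight = h$beta_x^2 / h$se_y^2
  )
}

new_mr_fit <- function(estimator, beta, se, n_snps, dist = "normal",
                       df = NULL, data = NULL, extra = list()) {
  inf <- wald_inference(beta, se, dist = dist, df = df)
  structure(
    c(list(estimator = estimator, beta = beta, se = se,
           ci_low = inf$ci_low, ci_high = inf$ci_high, pval = inf$pval,
           n_snps = n_snps, dist = dist, df = df, data = data),
      extra),
    class = "mr_fit"
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-instrument ratio estimates in a fixed-effect
#' inverse-variance-weighted average: with weights
#' `w_j = beta_x_j^2 / se_y_j^2`, the estimate is `sum(w * theta) / sum(w)`
#' and its standard error `sqrt(1 / sum(w))`.  Equivalent to weighted
#' least-squares regression of `beta_y` on `beta_x` through the origin with
#' weights `1 / se_y^2`, and (for uncorrelated variants) to two-stage least
#' squares on individual-level data.  Inference uses normal quantiles.
#'
#' @param h Harmonized-instrument tibble with at least 1 row.
#' @return An `mr_fit` object; see [tidy.mr_fit()].
#' @export
mr_ivw <- function(h) {
  if (nrow(h) < 1L) abort("IVW needs at least 1 instrument",
                          class = "mrpipe_empty_input")
  r <- wald_ratio(h)
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  new_mr_fit("IVW", beta, se, nrow(h), data = h)
}

# Weighted median of ratio estimates: order the thetas, form standardized
# cumulative weights s_j = cumsum(w')_j - w'_j/2, and interpolate linearly
# to s = 0.5.
wm_point <- function(theta, weight) {
  ord <- order(theta)
  th <- theta[ord]
  wp <- weight[ord] / sum(weight)
  s <- cumsum(wp) - wp / 2
  m <- length(th)
  if (s[1] >= 0.5) return(th[1])
  if (s[m] <= 0.5) return(th[m])
  j <- max(which(s < 0.5))
  th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-instrument ratio estimates, each carrying
#' probability mass proportional to its inverse variance.  Consistent when
#' instruments holding more than 50% of the weight are valid, so it
#' tolerates pleiotropy in a minority of the weight where IVW does not.
#' The standard error is the standard deviation of the estimate over
#' `n_boot` parametric-bootstrap replicates (each replicate redraws
#' `beta_x` and `beta_y` from normal distributions centred at the observed
#' values with the observed standard errors); inference uses normal
#' quantiles.
#'
#' @param h Harmonized-instrument tibble with at least 3 rows.
#' @param n_boot Bootstrap replicates (default 1000; below 100 a warning
#'   flags degraded inference).
#' @param seed Integer seed for the bootstrap; required, so results are
#'   reproducible by construction.
#' @return An `mr_fit` object.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  if (nrow(h) < 3L) abort("weighted median needs at least 3 instruments",
                          class = "mrpipe_empty_input")
  if (missing(seed)) abort("a bootstrap seed is required",
                           class = "mrpipe_usage_error")
  if (n_boot < 100) warn("n_boot < 100: bootstrap SE will be unreliable")
  r <- wald_ratio(h)
  beta <- wm_point(r$theta, r$weight)
  m <- nrow(h)
  boot <- withr::with_seed(seed, {
    bx <- matrix(rnorm(m * n_boot, h$beta_x, h$se_x), nrow = m)
    by <- matrix(rnorm(m * n_boot, h$beta_y, h$se_y), nrow = m)
    vapply(seq_len(n_boot), function(b) {
      wm_point(by[, b] / bx[, b], bx[, b]^2 / h$se_y^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_fit("weighted_median", beta, se, m, data = h,
             extra = list(n_boot = n_boot, seed = seed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1 / se_y^2`), after orienting every
#' instrument so `beta_x >= 0` (both betas negated where needed, which
#' leaves ratio estimates unchanged but makes the intercept interpretable).
#' The slope is a pleiotropy-corrected causal estimate; the intercept
#' estimates the average directional pleiotropic effect, and an intercept
#' distinct from zero is evidence against the exclusion restriction.
#' Standard errors use the weighted-regression residual standard deviation
#' floored at 1 (variance never deflated below the reported `se_y`);
#' p-values and confidence intervals use the t distribution with `m - 2`
#' degrees of freedom.
#'
#' @param h Harmonized-instrument tibble with at least 3 rows.
#' @return An `mr_fit` object carrying both the slope block and the
#'   intercept block (`intercept`, `intercept_se`, `intercept_ci_low`,
#'   `intercept_ci_high`, `intercept_pval`).
#' @export
mr_egger <- function(h) {
  m <- nrow(h)
  if (m < 3L) abort("MR-Egger needs at least 3 instruments",
                    class = "mrpipe_empty_input")
  flip <- h$beta_x < 0
  bx <- ifelse(flip, -h$beta_x, h$beta_x)
  by <- ifelse(flip, -h$beta_y, h$beta_y)
  if (length(unique(bx)) == 1L) {
    abort("singular design: all |beta_x| identical", class = "mrpipe_degenerate")
  }
  w <- 1 / h$se_y^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- if (sigma > 0) max(1, sigma) / sigma else 1
  est <- coef(fit)
  ses <- sm$coefficients[, "Std. Error"] * infl
  df <- m - 2L
  int_inf <- wald_inference(est[1], max(ses[1], .Machine$double.xmin),
                            dist = "t", df = df)
  f <- new_mr_fit("mr_egger", unname(est[2]),
                  max(unname(ses[2]), .Machine$double.xmin),
                  m, dist = "t", df = df, data = h,
                  extra = list(
                    intercept = unname(est[1]),
                    intercept_se = unname(ses[1]),
                    intercept_ci_low = int_inf$ci_low,
                    intercept_ci_high = int_inf$ci_high,
                    intercept_pval = int_inf$pval,
                    sigma = sigma
                  ))
  f
}

#' Run all three estimators on a harmonized instrument set
#'
#' Convenience wrapper returning one tidy row per estimator with the shared
#' result schema (the MR-Egger row also fills the intercept columns).
#'
#' @inheritParams mr_weighted_median
#' @return Tibble with columns `estimator`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `intercept`, `intercept_se`,
#'   `intercept_ci_low`, `intercept_ci_high`, `intercept_pval`.
#' @export
mr_estimates <- function(h, n_boot = 1000, seed) {
  fits <- list(mr_ivw(h), mr_weighted_median(h, n_boot = n_boot, seed = seed),
               mr_egger(h))
  dplyr::bind_rows(lapply(fits, glance))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit: %s, %d instruments>\n", x$estimator, x$n_snps))
  cat(sprintf("  causal estimate: %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$intercept)) {
    cat(sprintf("  pleiotropy intercept: %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
                x$intercept, x$intercept_ci_low, x$intercept_ci_high,
                x$intercept_pval))
  }
  invisible(x)
}

#' Tidy an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per model term (`causal_effect`, and
#'   `pleiotropy_intercept` for MR-Egger): `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  out <- tibble::tibble(
    estimator = x$estimator,
    term = "causal_effect",
    estimate = x$beta, std.error = x$se, statistic = x$beta / x$se,
    p.value = x$pval, conf.low = x$ci_low, conf.high = x$ci_high
  )
  if (!is.null(x$intercept)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      estimator = x$estimator,
      term = "pleiotropy_intercept",
      estimate = x$intercept, std.error = x$intercept_se,
      statistic = x$intercept / x$intercept_se,
      p.value = x$intercept_pval,
      conf.low = x$intercept_ci_low, conf.high = x$intercept_ci_high
    ))
  }
  out
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return One-row tibble in the shared result schema (intercept columns
#'   `NA` for estimators without an intercept).
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator, n_snps = x$n_snps,
    beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    pval = x$pval,
    intercept = x$intercept %||% NA_real_,
    intercept_se = x$intercept_se %||% NA_real_,
    intercept_ci_low = x$intercept_ci_low %||% NA_real_,
    intercept_ci_high = x$intercept_ci_high %||% NA_real_,
    intercept_pval = x$intercept_pval %||% NA_real_
  )
}
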