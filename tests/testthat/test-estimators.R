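hz <- function(beta_x, beta_y, se_y, se_x = 0.008) {
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_along(beta_x)),
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    eaf_x = 0.3, eaf_y = 0.3, action = "none"
  )
}

test_that("Wald ratios follow the first-order arithmetic", {
  r <- wald_ratio(hz(0.1, 0.02, 0.005))
  expect_equal(r$theta, 0.2)
  expect_equal(r$se_theta, 0.05)
  expect_equal(r$weight, 400)
  # null outcome effect
  expect_equal(wald_ratio(hz(0.1, 0, 0.005))$theta, 0)
  # simultaneous sign flip leaves ratio and weight unchanged
  r2 <- wald_ratio(hz(-0.1, -0.02, 0.005))
  expect_equal(r2$theta, r$theta)
  expect_equal(r2$weight, r$weight)
  expect_error(wald_ratio(hz(0, 0.02, 0.005)), class = "mrpipe_degenerate")
})

test_that("IVW reduces to the Wald ratio for a single instrument", {
  h <- hz(0.1, 0.02, 0.005)
  f <- mr_ivw(h)
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, 0.05)
  expect_equal(f$n_snps, 1L)
})

test_that("IVW equals the hand-summed weighted mean on equal weights", {
  # three instruments, each with weight beta_x^2/se_y^2 = 100
  h <- hz(rep(0.1, 3), c(0.02, 0.03, 0.01), rep(0.01, 3))
  f <- mr_ivw(h)
  expect_equal(unique(wald_ratio(h)$weight), 100)
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, sqrt(1 / 300))
  expect_equal(f$ci_low, 0.2 - qnorm(0.975) * sqrt(1 / 300))
  # cross-check against regression through the origin
  expect_equal(f$beta, ivw_wls_oracle(h), tolerance = 1e-12)
})

test_that("IVW matches the WLS-through-origin oracle on random inputs", {
  for (seed in 1:10) {
    h <- rand_harmonized(25, seed)
    f <- mr_ivw(h)
    expect_equal(f$beta, ivw_wls_oracle(h), tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the inverse-variance-weighted CDF", {
  # degenerate: all ratios equal
  h0 <- hz(c(0.1, 0.2, 0.05), 0.2 * c(0.1, 0.2, 0.05), c(0.01, 0.02, 0.03))
  f0 <- quiet(mr_weighted_median(h0, n_boot = 100, seed = 1))
  expect_equal(f0$beta, 0.2)
  # equal weights, thetas {0.1, 0.2, 0.3}: s_2 = 0.5 exactly -> middle
  h1 <- hz(rep(0.1, 3), c(0.01, 0.02, 0.03), rep(0.01, 3))
  f1 <- quiet(mr_weighted_median(h1, n_boot = 100, seed = 1))
  expect_equal(f1$beta, 0.2)
  # estimate always lies within the range of the per-SNP ratios
  for (seed in 1:10) {
    h <- rand_harmonized(11, seed)
    f <- quiet(mr_weighted_median(h, n_boot = 100, seed = seed))
    th <- wald_ratio(h)$theta
    expect_gte(f$beta, min(th))
    expect_lte(f$beta, max(th))
  }
})

test_that("weighted median bootstrap is seeded and guards its inputs", {
  h <- rand_harmonized(10, 4)
  f1 <- mr_weighted_median(h, n_boot = 200, seed = 99)
  f2 <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_equal(f1$se, f2$se)
  expect_error(mr_weighted_median(h[1:2, ], seed = 1),
               class = "mrpipe_empty_input")
  expect_error(mr_weighted_median(h), class = "mrpipe_usage_error")
  expect_warning(mr_weighted_median(h, n_boot = 50, seed = 1),
                 "n_boot < 100")
})

test_that("MR-Egger recovers an exact linear relationship", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  h <- hz(bx, 0.01 + 0.3 * bx, rep(0.01, 4))
  f <- mr_egger(h)
  expect_equal(f$intercept, 0.01, tolerance = 1e-10)
  expect_equal(f$beta, 0.3, tolerance = 1e-10)
  expect_equal(f$sigma, 0, tolerance = 1e-7)
  # exact fit through the origin: no exclusion-restriction violation
  h0 <- hz(bx, 0.25 * bx, rep(0.01, 4))
  f0 <- mr_egger(h0)
  expect_equal(f0$intercept, 0, tolerance = 1e-12)
  expect_equal(f0$beta, 0.25, tolerance = 1e-12)
})

test_that("MR-Egger matches the weighted normal-equations oracle", {
  for (seed in 1:10) {
    h <- rand_harmonized(30, seed)
    f <- mr_egger(h)
    o <- egger_ne_oracle(h)
    expect_equal(f$beta, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$se, o$slope_se, tolerance = 1e-10)
    expect_equal(f$intercept_se, o$intercept_se, tolerance = 1e-10)
  }
  expect_error(mr_egger(rand_harmonized(2, 1)), class = "mrpipe_empty_input")
  expect_error(mr_egger(hz(rep(0.1, 4), rnorm(4), rep(0.01, 4))),
               class = "mrpipe_degenerate")
})

test_that("estimators are invariant to ordering and allele re-coding", {
  h <- rand_harmonized(20, 31)
  perm <- withr::with_seed(2, sample(20))
  flip <- withr::with_seed(3, sample(c(TRUE, FALSE), 20, replace = TRUE))
  hr <- dplyr::mutate(h,
                      beta_x = ifelse(flip, -beta_x, beta_x),
                      beta_y = ifelse(flip, -beta_y, beta_y))[perm, ]
  expect_equal(mr_ivw(h)$beta, mr_ivw(hr)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta,
               mr_weighted_median(hr, n_boot = 100, seed = 1)$beta,
               tolerance = 1e-12)
  fe <- mr_egger(h); fr <- mr_egger(hr)
  expect_equal(fe$beta, fr$beta, tolerance = 1e-12)
  expect_equal(fe$intercept, fr$intercept, tolerance = 1e-12)
})

test_that("Bonferroni thresholds reproduce the printed per-exposure values", {
  expect_identical(bonferroni_threshold(25), 0.002)
  expect_equal(signif(bonferroni_threshold(41), 3), 0.00122)
  expect_identical(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), class = "mrpipe_usage_error")
})

test_that("Wald inference matches the normal quantile identities", {
  i0 <- wald_inference(0, 0.1)
  expect_equal(i0$pval, 1)
  expect_equal(i0$ci_low, -i0$ci_high)
  i1 <- wald_inference(qnorm(0.975), 1)
  expect_equal(i1$pval, 0.05, tolerance = 1e-12)
  expect_equal(i1$ci_low, 0, tolerance = 1e-12)
  expect_error(wald_inference(0.1, 0), class = "mrpipe_usage_error")
})

test_that("a published-style CI reconstructs from its midpoint and width", {
  # CI (0.093, 0.242): se = width / (2 z), beta = midpoint
  se <- (0.242 - 0.093) / (2 * qnorm(0.975))
  inf <- wald_inference((0.242 + 0.093) / 2, se)
  expect_equal(round(inf$ci_low, 3), 0.093)
  expect_equal(round(inf$ci_high, 3), 0.242)
})

test_that("tidy and glance expose the broom-style schema", {
  h <- rand_harmonized(12, 6)
  f <- mr_egger(h)
  td <- tidy(f)
  expect_equal(td$term, c("causal_effect", "pleiotropy_intercept"))
  expect_true(all(c("estimate", "std.error", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  gl <- glance(mr_ivw(h))
  expect_equal(nrow(gl), 1L)
  expect_true(is.na(gl$intercept))
  est <- quiet(mr_estimates(h, n_boot = 100, seed = 2))
  expect_equal(est$estimator, c("IVW", "weighted_median", "mr_egger"))
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
})
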