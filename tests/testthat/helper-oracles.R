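# Shared helpers: quiet wrappers, random harmonized inputs, and the
# independent regression oracles the estimator tests compare against.

quiet <- function(expr) suppressMessages(expr)

# identity column map: read back files written by write_sumstats()
identity_map <- function() {
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  stats::setNames(cols, cols)
}

# random harmonized-instrument tibble, exposure effects of either sign
rand_harmonized <- function(m, seed) {
  withr::with_seed(seed, tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(m)),
    effect_allele = "A", other_allele = "G",
    beta_x = runif(m, 0.03, 0.2) * sample(c(-1, 1), m, replace = TRUE),
    se_x = runif(m, 0.004, 0.01),
    beta_y = runif(m, -0.05, 0.05),
    se_y = runif(m, 0.01, 0.03),
    eaf_x = runif(m, 0.1, 0.9), eaf_y = runif(m, 0.1, 0.9),
    action = "none"
  ))
}

# oracle for IVW: weighted least squares of beta_y on beta_x through the
# origin with weights 1/se_y^2, via lm()
ivw_wls_oracle <- function(h) {
  fit <- stats::lm(beta_y ~ beta_x + 0, data = h, weights = 1 / h$se_y^2)
  unname(stats::coef(fit)[1])
}

# oracle for MR-Egger: explicit weighted normal-equations solve with the
# beta_x >= 0 orientation, residual-sd inflation floored at 1
egger_ne_oracle <- function(h) {
  s <- ifelse(h$beta_x < 0, -1, 1)
  x <- h$beta_x * s
  y <- h$beta_y * s
  w <- 1 / h$se_y^2
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  b <- solve(XtWX, t(X) %*% (w * y))
  r <- y - X %*% b
  m <- length(y)
  sigma2 <- sum(w * r^2) / (m - 2)
  covb <- solve(XtWX) * sigma2
  ses <- sqrt(diag(covb))
  sigma <- sqrt(sigma2)
  if (sigma > 0) ses <- ses * max(1, sigma) / sigma
  list(intercept = unname(b[1]), slope = unname(b[2]),
       intercept_se = unname(ses[1]), slope_se = unname(ses[2]),
       sigma = sigma)
}

# run the default selection + harmonization + one estimator on a simulated
# data set (no file IO), used by the property and acceptance simulations
sim_harmonized <- function(scn) {
  s <- simulate_two_sample(scn)
  h <- quiet(harmonize_tables(
    prune_ld(filter_genomewide(s$exposure), ld = s$ld), s$outcome))
  list(h = h, truth = s$truth, sim = s)
}
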