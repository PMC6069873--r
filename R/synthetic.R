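# Synthetic two-sample GWAS summary statistics with known ground truth.
# The generator emulates the consortium-scale setting the estimators are
# built for: strong, independently drawn per-SNP exposure effects with
# meta-analysis-scale standard errors, outcome effects produced under a
# linear causal model with an optional pleiotropy regime, block LD
# structure, and optional allele-coding corruption (swaps, strand flips,
# palindromic variants) of the outcome table.

#' Define a simulation scenario
#'
#' Every field has a default chosen to mirror a consortium-scale exposure
#' (tens of instruments, exposure SEs near 0.008 as in a meta-analysis of
#' roughly 2e5 samples, outcome SEs 0.01–0.03) so that simulated power is
#' comparable to a real central-obesity-on-birth-size analysis.
#'
#' @param n_snps Number of instruments to simulate.
#' @param beta_causal True causal effect (outcome SD per exposure SD).
#' @param pleiotropy Pleiotropy regime for direct variant-on-outcome
#'   effects `alpha_j`: `"none"` (`alpha = 0`), `"balanced"`
#'   (`alpha ~ N(0, tau^2)`), or `"directional"` (`alpha ~ N(mu, tau^2)`).
#'   Direct effects are drawn independently of instrument strength, so the
#'   InSIDE condition holds.
#' @param mu Mean direct effect under `"directional"` (default 0.02).
#' @param tau SD of direct effects (default 0.01 balanced, 0.005
#'   directional).
#' @param frac_invalid Fraction of instruments receiving a direct effect
#'   (default 1); lower it to study estimators under a minority of invalid
#'   instruments.
#' @param gamma_range Range of true per-SNP exposure effects, drawn
#'   uniform and positive; the default (0.08, 0.20) with `se_x = 0.008`
#'   keeps every observed exposure p-value far below 5e-8, so simulated
#'   instruments pass the genome-wide filter by construction.
#' @param se_x,se_y Standard-error magnitudes for the exposure and outcome
#'   studies; a scalar or a `(low, high)` range sampled per SNP.
#' @param n_ld_blocks Number of LD blocks; 0 (default) emits no LD entries
#'   (independent instruments).  Blocks partition the SNPs consecutively.
#' @param block_r2 Within-block pairwise r-squared (default 0.9).
#' @param frac_palindromic Fraction of SNPs given A/T or C/G allele pairs.
#' @param frac_allele_corrupted Fraction of outcome records whose allele
#'   coding is corrupted (swap, strand flip, or both, equally likely).
#' @param seed Integer seed; the generator splits it into independent
#'   streams for effects, noise, and allele bookkeeping, so toggling
#'   corruption does not change the effect draws.
#' @return A validated `sim_scenario` list.
#' @export
sim_scenario <- function(n_snps = 35, beta_causal = 0.2,
                         pleiotropy = c("none", "balanced", "directional"),
                         mu = 0.02, tau = NULL, frac_invalid = 1,
                         gamma_range = c(0.08, 0.20),
                         se_x = 0.008, se_y = c(0.01, 0.03),
                         n_ld_blocks = 0, block_r2 = 0.9,
                         frac_palindromic = 0, frac_allele_corrupted = 0,
                         seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (is.null(tau)) tau <- if (pleiotropy == "directional") 0.005 else 0.01
  stopifnot(
    n_snps >= 1, tau >= 0, all(gamma_range > 0), length(gamma_range) == 2,
    gamma_range[1] <= gamma_range[2],
    frac_invalid >= 0, frac_invalid <= 1,
    frac_palindromic >= 0, frac_palindromic <= 1,
    frac_allele_corrupted >= 0, frac_allele_corrupted <= 1,
    all(se_x > 0), all(se_y > 0), n_ld_blocks >= 0,
    block_r2 >= 0, block_r2 <= 1
  )
  structure(list(
    n_snps = as.integer(n_snps), beta_causal = beta_causal,
    pleiotropy = pleiotropy, mu = mu, tau = tau,
    frac_invalid = frac_invalid, gamma_range = gamma_range,
    se_x = se_x, se_y = se_y,
    n_ld_blocks = as.integer(n_ld_blocks), block_r2 = block_r2,
    frac_palindromic = frac_palindromic,
    frac_allele_corrupted = frac_allele_corrupted,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

draw_se <- function(spec, n) {
  if (length(spec) == 2L) runif(n, spec[1], spec[2]) else rep(spec, n)
}

# non-palindromic allele pairs (effect/other), excluding A/T and C/G
NONPAL_PAIRS <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(ea = b, oa = b, stringsAsFactors = FALSE)
  g <- g[g$ea != g$oa & g$oa != chartr("ACGT", "TGCA", g$ea), ]
  g
}

#' Simulate a two-sample MR data set
#'
#' Per SNP `j`: true exposure effect `gamma_j ~ U(gamma_range)`; direct
#' effect `alpha_j` per the pleiotropy regime; observed
#' `beta_x_j ~ N(gamma_j, se_x_j^2)` and
#' `beta_y_j ~ N(beta_causal * gamma_j + alpha_j, se_y_j^2)`; p-values from
#' the observed statistics.  Block LD entries are emitted into the LD
#' table; the requested fraction of outcome records is allele-corrupted
#' (the correct harmonization action is recorded in the truth record).
#'
#' @param scn A [sim_scenario()].
#' @return List with `exposure`, `outcome` (summary-statistic tibbles),
#'   `ld` (LD tibble), and `truth` — every generating value plus the
#'   per-variant corruption bookkeeping, sufficient to reconstruct the data
#'   from the seed.
#' @export
simulate_two_sample <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  n <- scn$n_snps
  ids <- sprintf("rs%04d", seq_len(n))
  sub_seeds <- withr::with_seed(scn$seed,
                                sample.int(.Machine$integer.max - 1L, 3L))

  # stream 1: effects
  eff <- withr::with_seed(sub_seeds[1], {
    gamma <- runif(n, scn$gamma_range[1], scn$gamma_range[2])
    n_invalid <- if (scn$pleiotropy == "none") 0L else
      as.integer(ceiling(scn$frac_invalid * n))
    alpha <- numeric(n)
    if (n_invalid > 0L) {
      mu <- if (scn$pleiotropy == "directional") scn$mu else 0
      alpha[seq_len(n_invalid)] <- rnorm(n_invalid, mu, scn$tau)
    }
    list(gamma = gamma, alpha = alpha, n_invalid = n_invalid)
  })

  # stream 2: sampling noise
  noise <- withr::with_seed(sub_seeds[2], {
    se_x <- draw_se(scn$se_x, n)
    se_y <- draw_se(scn$se_y, n)
    list(se_x = se_x, se_y = se_y,
         beta_x = rnorm(n, eff$gamma, se_x),
         beta_y = rnorm(n, scn$beta_causal * eff$gamma + eff$alpha, se_y))
  })

  # stream 3: allele bookkeeping and corruption
  alle <- withr::with_seed(sub_seeds[3], {
    pal <- seq_len(n) %in% sample.int(n, round(scn$frac_palindromic * n))
    pair_idx <- sample.int(nrow(NONPAL_PAIRS), n, replace = TRUE)
    ea <- NONPAL_PAIRS$ea[pair_idx]
    oa <- NONPAL_PAIRS$oa[pair_idx]
    pal_ea <- sample(c("A", "C"), n, replace = TRUE)
    ea[pal] <- pal_ea[pal]
    oa[pal] <- strand_complement(ea[pal])
    eaf <- runif(n, 0.1, 0.9)
    corrupted <- seq_len(n) %in%
      sample.int(n, round(scn$frac_allele_corrupted * n))
    corruption <- rep("none", n)
    corruption[corrupted] <- sample(
      c("swap_sign", "strand_flip", "strand_flip_and_swap"),
      sum(corrupted), replace = TRUE)
    list(ea = ea, oa = oa, eaf = eaf, pal = pal, corruption = corruption)
  })

  base <- tibble::tibble(
    variant_id = ids,
    chrom = as.character(rep_len(1:22, n)),
    pos = seq_len(n) * 100000L,
    effect_allele = alle$ea, other_allele = alle$oa, eaf = alle$eaf
  )
  exposure <- dplyr::mutate(
    base,
    beta = noise$beta_x, se = noise$se_x,
    pval = pmax(2 * pnorm(-abs(noise$beta_x / noise$se_x)),
                .Machine$double.xmin),
    n = 224459L, trait = "exposure_sim", source = "synthetic"
  )
  outcome <- dplyr::mutate(
    base,
    beta = noise$beta_y, se = noise$se_y,
    pval = pmax(2 * pnorm(-abs(noise$beta_y / noise$se_y)),
                .Machine$double.xmin),
    n = 153781L, trait = "outcome_sim", source = "synthetic"
  )

  # corrupt outcome allele coding; harmonization must undo each action
  act <- alle$corruption
  sw <- act %in% c("swap_sign", "strand_flip_and_swap")
  fl <- act %in% c("strand_flip", "strand_flip_and_swap")
  ea <- outcome$effect_allele
  oa <- outcome$other_allele
  new_ea <- ifelse(sw, oa, ea)
  new_oa <- ifelse(sw, ea, oa)
  new_ea <- ifelse(fl, strand_complement(new_ea), new_ea)
  new_oa <- ifelse(fl, strand_complement(new_oa), new_oa)
  outcome$effect_allele <- new_ea
  outcome$other_allele <- new_oa
  outcome$beta <- ifelse(sw, -outcome$beta, outcome$beta)
  outcome$eaf <- ifelse(sw, 1 - outcome$eaf, outcome$eaf)

  ld <- ld_table()
  if (scn$n_ld_blocks > 0L) {
    block <- rep_len(seq_len(scn$n_ld_blocks), n)
    block <- sort(block)
    pairs <- do.call(rbind, lapply(split(ids, block), function(members) {
      if (length(members) < 2L) return(NULL)
      t(utils::combn(members, 2L))
    }))
    if (!is.null(pairs)) {
      ld <- ld_table(pairs[, 1], pairs[, 2], rep(scn$block_r2, nrow(pairs)))
    }
  }

  truth <- list(
    scenario = scn, sub_seeds = sub_seeds,
    variant_id = ids, gamma = eff$gamma, alpha = eff$alpha,
    invalid = seq_len(n) <= eff$n_invalid,
    se_x = noise$se_x, se_y = noise$se_y,
    beta_x = noise$beta_x, beta_y = noise$beta_y,
    eaf = alle$eaf, palindromic = alle$pal, corruption = alle$corruption
  )
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' A small deterministic worked fixture
#'
#' Five genome-wide-significant exposure SNPs plus one sub-threshold proxy
#' candidate, constructed (no random numbers) so that every selection and
#' harmonization branch fires exactly once when the pipeline runs with
#' default thresholds:
#' * `rs0002` is in LD with `rs0001` at r-squared 0.2 and is pruned;
#' * `rs0001` is absent from the outcome table and is replaced by the proxy
#'   `rs0006` (r-squared 0.9), which itself is not genome-wide significant;
#' * `rs0003` has swapped outcome alleles, `rs0004` strand-complement
#'   alleles, and `rs0005` is palindromic (dropped under the default
#'   policy).
#'
#' @param dir Optional directory; when given, `exposure.tsv`,
#'   `outcome.tsv` and `ld.tsv` are written there.
#' @return List with `exposure`, `outcome`, `ld` tibbles and `expected`,
#'   the hand-traced pipeline decisions.
#' @export
make_worked_fixture <- function(dir = NULL) {
  pv <- function(beta, se) 2 * pnorm(-abs(beta / se))
  exposure <- tibble::tibble(
    variant_id = sprintf("rs%04d", 1:6),
    chrom = as.character(1:6),
    pos = 1:6 * 1000L,
    effect_allele = c("A", "A", "C", "A", "A", "A"),
    other_allele  = c("G", "G", "T", "C", "T", "G"),
    eaf = c(0.30, 0.32, 0.45, 0.40, 0.20, 0.31),
    beta = c(0.10, 0.09, 0.08, 0.07, 0.06, 0.03),
    se = 0.008,
    pval = pv(c(0.10, 0.09, 0.08, 0.07, 0.06, 0.03), 0.008),
    n = 224459L, trait = "WHRadjBMI", source = "synthetic"
  )
  outcome <- tibble::tibble(
    variant_id = sprintf("rs%04d", 2:6),
    chrom = as.character(2:6),
    pos = 2:6 * 1000L,
    effect_allele = c("A", "T", "T", "T", "A"),
    other_allele  = c("G", "C", "G", "A", "G"),
    eaf = c(0.32, 0.55, 0.40, 0.80, 0.31),
    beta = c(0.017, -0.018, 0.013, -0.011, 0.005),
    se = 0.015,
    pval = pv(c(0.017, -0.018, 0.013, -0.011, 0.005), 0.015),
    n = 153781L, trait = "birth_weight", source = "synthetic"
  )
  ld <- ld_table(c("rs0001", "rs0001"), c("rs0002", "rs0006"), c(0.2, 0.9))
  expected <- list(
    significant = sprintf("rs%04d", 1:5),
    pruned = "rs0002",
    proxy = c(rs0001 = "rs0006"), proxy_r2 = 0.9,
    actions = c(rs0006 = "none", rs0003 = "swap_sign",
                rs0004 = "strand_flip", rs0005 = "dropped_palindromic"),
    harmonized_ids = c("rs0006", "rs0003", "rs0004")
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_sumstats(exposure, file.path(dir, "exposure.tsv"))
    write_sumstats(outcome, file.path(dir, "outcome.tsv"))
    write_ld_table(ld, file.path(dir, "ld.tsv"))
  }
  list(exposure = exposure, outcome = outcome, ld = ld, expected = expected)
}
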