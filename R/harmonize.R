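# Allele harmonization: express the outcome-study effect of every instrument
# on the exposure study's effect allele, resolving allele swaps, strand
# flips, and palindromic (A/T, C/G) variants.  Standard errors are never
# altered; irreconcilable or strand-ambiguous variants are dropped with a
# logged reason, never silently re-signed.

strand_complement <- function(allele) chartr("ACGT", "TGCA", allele)

is_palindromic <- function(effect_allele, other_allele) {
  other_allele == strand_complement(effect_allele)
}

# Vectorized core over paired exposure/outcome records (same variants, same
# order).  Returns a tibble with one row per pair and an `action` column;
# rows whose action starts with "dropped" carry the reason in `reason`.
harmonize_core <- function(variant_id,
                           ea_x, oa_x, beta_x, se_x, eaf_x,
                           ea_y, oa_y, beta_y, se_y, eaf_y,
                           palindromic_policy = c("drop", "infer-by-eaf"),
                           eaf_tolerance = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  m <- length(variant_id)
  action <- rep(NA_character_, m)
  reason <- rep(NA_character_, m)
  out_beta <- beta_y
  out_eaf <- eaf_y

  pal <- is_palindromic(ea_x, oa_x)
  same <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  flipped <- ea_y == strand_complement(ea_x) & oa_y == strand_complement(oa_x)
  flip_swap <- ea_y == strand_complement(oa_x) & oa_y == strand_complement(ea_x)

  # non-palindromic: allele letters identify the orientation uniquely
  np <- !pal
  action[np & same] <- "none"
  idx <- np & swapped
  action[idx] <- "swap_sign"
  out_beta[idx] <- -beta_y[idx]
  out_eaf[idx] <- 1 - eaf_y[idx]
  action[np & flipped] <- "strand_flip"
  idx <- np & flip_swap
  action[idx] <- "strand_flip_and_swap"
  out_beta[idx] <- -beta_y[idx]
  out_eaf[idx] <- 1 - eaf_y[idx]

  # palindromic: letters cannot distinguish a swap from a strand flip, so
  # the ambiguity branch governs whenever the allele *set* matches
  pal_match <- pal & (same | swapped | flipped | flip_swap)
  if (any(pal_match)) {
    if (palindromic_policy == "drop") {
      action[pal_match] <- "dropped_palindromic"
      reason[pal_match] <- "palindromic variant (strand ambiguous)"
    } else {
      # provisional orientation from the written letters, then check that
      # the effect-allele frequencies agree; if they sit on opposite sides
      # of 0.5 the provisional orientation is wrong and the sign flips.
      prov_neg <- pal_match & ea_y != ea_x
      q <- ifelse(prov_neg, 1 - eaf_y, eaf_y)
      b <- ifelse(prov_neg, -beta_y, beta_y)
      informative <- !is.na(eaf_x) & !is.na(q) &
        abs(eaf_x - 0.5) > eaf_tolerance & abs(q - 0.5) > eaf_tolerance
      same_side <- (eaf_x - 0.5) * (q - 0.5) > 0
      keep_i <- pal_match & informative & same_side
      flip_i <- pal_match & informative & !same_side
      drop_i <- pal_match & !informative
      action[keep_i] <- ifelse(prov_neg[keep_i], "swap_sign", "none")
      out_beta[keep_i] <- b[keep_i]
      out_eaf[keep_i] <- q[keep_i]
      action[flip_i] <- ifelse(prov_neg[flip_i],
                               "strand_flip", "strand_flip_and_swap")
      out_beta[flip_i] <- -b[flip_i]
      out_eaf[flip_i] <- 1 - q[flip_i]
      action[drop_i] <- "dropped_palindromic"
      reason[drop_i] <- "palindromic variant, frequencies uninformative"
    }
  }

  unresolved <- is.na(action)
  action[unresolved] <- "dropped_irreconcilable"
  reason[unresolved] <- "outcome alleles cannot be reconciled"

  tibble::tibble(
    variant_id = variant_id,
    effect_allele = ea_x, other_allele = oa_x,
    beta_x = beta_x, se_x = se_x,
    beta_y = out_beta, se_y = se_y,
    eaf_x = eaf_x, eaf_y = out_eaf,
    action = action, reason = reason
  )
}

#' Harmonize one exposure/outcome record pair
#'
#' Expresses the outcome effect on the exposure's effect allele.  The cases
#' are: identical alleles (no change); swapped alleles (outcome beta
#' negated, frequency complemented); strand-complement alleles (relabel
#' only); complement and swapped (relabel and negate); palindromic A/T or
#' C/G variants, for which the swap and strand-flip readings are
#' indistinguishable from the letters, handled by `palindromic_policy`
#' (`"drop"`, the default, or `"infer-by-eaf"`, which orients by allele
#' frequency when both studies' frequencies are farther than
#' `eaf_tolerance` from 0.5); anything else is irreconcilable and dropped.
#'
#' @param exposure_rec,outcome_rec One-row summary-statistic tibbles for the
#'   same variant.
#' @param palindromic_policy `"drop"` or `"infer-by-eaf"`.
#' @param eaf_tolerance Minimum distance of both frequencies from 0.5 for
#'   frequency-based orientation (default 0.08).
#' @return One-row tibble with `beta_x`, `se_x`, `beta_y`, `se_y`, the
#'   exposure-orientation alleles, and the `action` taken; a dropped variant
#'   has an action starting with `"dropped"` and a `reason`.
#' @export
#' @examples
#' ex <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'                      other_allele = "G", eaf = 0.3, beta = 0.05,
#'                      se = 0.01, pval = 1e-9)
#' out <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
#'                       other_allele = "A", eaf = 0.7, beta = -0.03,
#'                       se = 0.02, pval = 0.1)
#' harmonize_pair(ex, out)  # action swap_sign, beta_y = +0.03
harmonize_pair <- function(exposure_rec, outcome_rec,
                           palindromic_policy = c("drop", "infer-by-eaf"),
                           eaf_tolerance = 0.08) {
  if (exposure_rec$variant_id != outcome_rec$variant_id) {
    abort("exposure and outcome records refer to different variants",
          class = "mrpipe_usage_error")
  }
  harmonize_core(
    exposure_rec$variant_id,
    exposure_rec$effect_allele, exposure_rec$other_allele,
    exposure_rec$beta, exposure_rec$se, exposure_rec$eaf,
    outcome_rec$effect_allele, outcome_rec$other_allele,
    outcome_rec$beta, outcome_rec$se, outcome_rec$eaf,
    palindromic_policy = palindromic_policy,
    eaf_tolerance = eaf_tolerance
  )
}

#' Harmonize an instrument set against an outcome table
#'
#' Applies [harmonize_pair()] to every instrument present in the outcome
#' table (instruments absent from it are reported and skipped — run
#' [substitute_proxies()] first if proxies are wanted).  Output order
#' follows instrument order.  The full per-variant audit, including dropped
#' variants and reasons, is attached as attribute `"audit"` and retrievable
#' with [harmonization_audit()].
#'
#' @inheritParams harmonize_pair
#' @param instruments Instrument-set tibble (exposure orientation).
#' @param outcome Outcome summary-statistics tibble.
#' @return Tibble of harmonized instruments (columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `eaf_x`, `eaf_y`, `action`, plus provenance columns when present).
#' @export
harmonize_tables <- function(instruments, outcome,
                             palindromic_policy = c("drop", "infer-by-eaf"),
                             eaf_tolerance = 0.08) {
  present <- instruments$variant_id %in% outcome$variant_id
  if (any(!present)) {
    inform(paste0(sum(!present), " instrument(s) absent from the outcome ",
                  "table; skipped"))
  }
  ins <- instruments[present, , drop = FALSE]
  if (nrow(ins) == 0L) {
    abort("no instruments present in the outcome table",
          class = "mrpipe_empty_result")
  }
  oc <- outcome[match(ins$variant_id, outcome$variant_id), , drop = FALSE]
  h <- harmonize_core(
    ins$variant_id,
    ins$effect_allele, ins$other_allele, ins$beta, ins$se, ins$eaf,
    oc$effect_allele, oc$other_allele, oc$beta, oc$se, oc$eaf,
    palindromic_policy = palindromic_policy,
    eaf_tolerance = eaf_tolerance
  )
  for (col in c("provenance", "proxy_for", "proxy_r2")) {
    if (col %in% names(ins)) h[[col]] <- ins[[col]]
  }
  audit <- dplyr::select(h, "variant_id", "action", "reason")
  counts <- table(h$action)
  inform(paste0("harmonization actions: ",
                paste(names(counts), counts, sep = "=", collapse = ", ")))
  out <- h[!startsWith(h$action, "dropped"), , drop = FALSE]
  out$reason <- NULL
  if (nrow(out) == 0L) {
    abort("harmonization left no usable instruments",
          class = "mrpipe_empty_result")
  }
  attr(out, "audit") <- audit
  out
}

#' Retrieve the harmonization audit
#'
#' @param harmonized Output of [harmonize_tables()].
#' @return Tibble with one row per instrument considered: `variant_id`,
#'   `action`, `reason`.
#' @export
harmonization_audit <- function(harmonized) {
  attr(harmonized, "audit")
}

#' Write the harmonization audit log
#'
#' @param harmonized Output of [harmonize_tables()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_harmonization_audit <- function(harmonized, path) {
  audit <- harmonization_audit(harmonized)
  if (is.null(audit)) abort("no audit attached; not a harmonize_tables() result")
  readr::write_tsv(audit, path, progress = FALSE)
  invisible(path)
}
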