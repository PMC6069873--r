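# Instrument selection: genome-wide significance filter, greedy LD pruning,
# proxy substitution for instruments absent from the outcome study, and
# exclusion-list sensitivity subsets.  An instrument set is a summary-stat
# tibble with provenance columns (`provenance`, `proxy_for`, `proxy_r2`).

#' Filter to genome-wide-significant variants
#'
#' Keeps exactly the records with `pval` strictly below the threshold
#' (conventionally 5e-8), preserving order.
#'
#' @param tbl Summary-statistics tibble.
#' @param threshold Significance threshold; comparison is strict (`<`).
#' @return The filtered tibble (possibly empty, with a message).
#' @export
filter_genomewide <- function(tbl, threshold = 5e-8) {
  out <- dplyr::filter(tbl, .data$pval < threshold)
  if (nrow(out) == 0L) {
    inform(paste0("no variants reach p < ", format(threshold)))
  }
  out
}

as_instrument_set <- function(tbl) {
  if (!"provenance" %in% names(tbl)) tbl$provenance <- "original"
  if (!"proxy_for" %in% names(tbl)) tbl$proxy_for <- NA_character_
  if (!"proxy_r2" %in% names(tbl)) tbl$proxy_r2 <- NA_real_
  tbl
}

#' Prune correlated instruments by LD
#'
#' Greedy pruning: variants are ranked by ascending p-value (ties broken
#' lexicographically by `variant_id`, so the output is invariant to input row
#' order) and visited in rank order; a variant is kept iff its known
#' r-squared with every already-kept variant is at most `r2_max`.  A pair
#' with unknown r-squared is treated as independent unless `strict = TRUE`,
#' in which case an unknown pair among candidates is an error.
#'
#' @param tbl Non-empty summary-statistics tibble (typically the output of
#'   [filter_genomewide()]).
#' @param ld LD tibble from [ld_table()], or `NULL` for no LD information.
#' @param r2_max Maximum r-squared tolerated between kept instruments;
#'   pairs with r-squared strictly above it are pruned (default 0.05).
#' @param strict Error on unknown pairwise r-squared instead of assuming
#'   independence.
#' @return Instrument-set tibble in p-value order, provenance `"original"`.
#' @export
prune_ld <- function(tbl, ld = NULL, r2_max = 0.05, strict = FALSE) {
  if (nrow(tbl) == 0L) {
    abort("cannot prune an empty table", class = "mrpipe_empty_input")
  }
  ord <- order(tbl$pval, tbl$variant_id)
  tbl <- tbl[ord, , drop = FALSE]
  keep <- logical(nrow(tbl))
  kept_ids <- character(0)
  for (i in seq_len(nrow(tbl))) {
    id <- tbl$variant_id[i]
    r2 <- ld_lookup(ld, rep(id, length(kept_ids)), kept_ids)
    if (strict && anyNA(r2)) {
      abort(paste0("unknown r2 between ", id, " and a kept instrument ",
                   "(strict mode)"), class = "mrpipe_ld_unknown")
    }
    if (!any(r2 > r2_max, na.rm = TRUE)) {
      keep[i] <- TRUE
      kept_ids <- c(kept_ids, id)
    }
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(paste0("LD pruning discarded ", n_drop, " variant(s) with r2 > ",
                  format(r2_max)))
  }
  as_instrument_set(tbl[keep, , drop = FALSE])
}

#' Substitute proxies for instruments absent from the outcome study
#'
#' Each instrument missing from the outcome table is replaced by the
#' exposure-table variant that is also present in the outcome table and has
#' maximal known r-squared with it, provided that r-squared is strictly
#' greater than `r2_min`; ties are broken by smaller exposure p-value, then
#' lexicographic id.  Variants already in the instrument set are not eligible
#' proxies (substitution never duplicates an instrument).  An instrument with
#' no qualifying proxy is dropped with a message.  Provenance records the
#' original id and the proxy r-squared.
#'
#' @param instruments Instrument-set tibble (see [prune_ld()]).
#' @param outcome Outcome summary-statistics tibble.
#' @param exposure Full exposure summary-statistics tibble (the proxy pool;
#'   a proxy needs an exposure effect, so the pool is the intersection of the
#'   exposure and outcome tables).
#' @param ld LD tibble.
#' @param r2_min Minimum r-squared for an acceptable proxy; strict (`>`),
#'   default 0.8.
#' @return Instrument-set tibble with proxies substituted in place.
#' @export
substitute_proxies <- function(instruments, outcome, exposure, ld,
                               r2_min = 0.8) {
  instruments <- as_instrument_set(instruments)
  missing <- which(!instruments$variant_id %in% outcome$variant_id)
  if (length(missing) == 0L) return(instruments)
  drop <- integer(0)
  for (i in missing) {
    orig <- instruments$variant_id[i]
    pool <- dplyr::filter(
      exposure,
      .data$variant_id %in% outcome$variant_id,
      !.data$variant_id %in% instruments$variant_id
    )
    if (nrow(pool) > 0L) {
      r2 <- ld_lookup(ld, rep(orig, nrow(pool)), pool$variant_id)
      cand <- which(!is.na(r2) & r2 > r2_min)
    } else {
      cand <- integer(0)
    }
    if (length(cand) == 0L) {
      inform(paste0("instrument ", orig, " absent from outcome and no proxy ",
                    "with r2 > ", format(r2_min), "; dropped"))
      drop <- c(drop, i)
      next
    }
    best <- cand[order(-r2[cand], pool$pval[cand], pool$variant_id[cand])][1]
    repl <- as_instrument_set(pool[best, , drop = FALSE])
    repl$provenance <- "proxy"
    repl$proxy_for <- orig
    repl$proxy_r2 <- r2[best]
    instruments[i, ] <- repl[, names(instruments)]
    inform(paste0("instrument ", orig, " replaced by proxy ",
                  repl$variant_id, " (r2 = ", format(r2[best]), ")"))
  }
  if (length(drop) > 0L) instruments <- instruments[-drop, , drop = FALSE]
  instruments
}

#' Exclude instruments by id
#'
#' Set difference by `variant_id`, order preserved; used for sensitivity
#' re-analyses that remove variants with suspected pleiotropic pathways
#' (e.g. lipid- or insulin-associated loci).  Ids not present are ignored.
#'
#' @param instruments Instrument-set tibble.
#' @param exclusion_list Character vector of variant ids to remove, or a
#'   path to a one-id-per-line text file.
#' @return The reduced instrument-set tibble.
#' @export
exclude_variants <- function(instruments, exclusion_list) {
  if (length(exclusion_list) == 1L && file.exists(exclusion_list) &&
      !exclusion_list %in% instruments$variant_id) {
    exclusion_list <- readLines(exclusion_list)
    exclusion_list <- trimws(exclusion_list)
    exclusion_list <- exclusion_list[nzchar(exclusion_list)]
  }
  out <- dplyr::filter(instruments, !.data$variant_id %in% exclusion_list)
  inform(paste0("excluded ", nrow(instruments) - nrow(out),
                " instrument(s); ", nrow(out), " left"))
  out
}
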