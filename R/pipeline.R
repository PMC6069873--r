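# End-to-end orchestration: for each exposure-outcome pair, select
# instruments (significance filter, LD pruning, proxy substitution),
# harmonize alleles, run the three estimators, flag significance against a
# per-exposure Bonferroni threshold, and optionally re-run on an
# exclusion-reduced instrument set as a sensitivity analysis.

#' Analyse one exposure-outcome pair
#'
#' Runs the full pipeline
#' `filter_genomewide() |> prune_ld() |> substitute_proxies() |>`
#' `harmonize_tables() |> {IVW, weighted median, MR-Egger}` and returns a
#' tidy long table of estimates.  The Bonferroni threshold uses the final
#' post-harmonization instrument count (the divisor convention is recorded
#' in the output).
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param ld LD tibble (or `NULL`: all pairwise r-squared unknown, treated
#'   as independent).
#' @param exposure_label,outcome_label Labels for the output; default to
#'   the tables' `trait` column.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_prune LD-pruning r-squared ceiling (default 0.05).
#' @param r2_proxy Minimum proxy r-squared (default 0.8).
#' @param palindromic_policy,eaf_tolerance See [harmonize_tables()].
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @param exclude Optional variant ids (or one-id-per-line file) removed in
#'   a sensitivity re-analysis reported as `analysis = "sensitivity"`.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Long results tibble: `exposure`, `outcome`, `analysis`,
#'   `estimator`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   intercept columns, `bonferroni`, `significant`.  The harmonization
#'   audit is attached as attribute `"audit"`.
#' @export
mr_pair <- function(exposure, outcome, ld = NULL,
                    exposure_label = NULL, outcome_label = NULL,
                    p_threshold = 5e-8, r2_prune = 0.05, r2_proxy = 0.8,
                    palindromic_policy = "drop", eaf_tolerance = 0.08,
                    n_boot = 1000, seed = 1L, exclude = NULL, alpha = 0.05) {
  exposure_label <- exposure_label %||% exposure$trait[1] %||% "exposure"
  outcome_label <- outcome_label %||% outcome$trait[1] %||% "outcome"

  instruments <- exposure |>
    filter_genomewide(threshold = p_threshold) |>
    prune_ld(ld = ld, r2_max = r2_prune) |>
    substitute_proxies(outcome = outcome, exposure = exposure, ld = ld,
                       r2_min = r2_proxy)

  run_block <- function(ins, analysis) {
    h <- harmonize_tables(ins, outcome,
                          palindromic_policy = palindromic_policy,
                          eaf_tolerance = eaf_tolerance)
    est <- mr_estimates(h, n_boot = n_boot, seed = seed)
    thr <- bonferroni_threshold(nrow(h), alpha = alpha)
    out <- dplyr::mutate(
      est,
      exposure = exposure_label, outcome = outcome_label,
      analysis = analysis, bonferroni = thr,
      significant = .data$pval < thr,
      .before = 1
    )
    attr(out, "audit") <- harmonization_audit(h)
    out
  }

  res <- run_block(instruments, "main")
  if (!is.null(exclude)) {
    reduced <- exclude_variants(instruments, exclude)
    sens <- run_block(reduced, "sensitivity")
    audit <- attr(res, "audit")
    res <- dplyr::bind_rows(res, sens)
    attr(res, "audit") <- audit
  }
  res
}

read_analysis_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(length(config$exposures) >= 1, length(config$outcomes) >= 1)
  config
}

#' Run a full exposure-by-outcome analysis grid
#'
#' Orchestrates [mr_pair()] over every exposure-outcome combination in the
#' configuration, isolating failures per pair (a degenerate pair is
#' reported and skipped, never aborting the grid), and writes the results
#' table (TSV + JSON mirror), per-pair harmonization audits, instrument
#' counts, and a run log into the output directory.
#'
#' @param config A YAML file path or an equivalent list with entries:
#'   `exposures` (list of `label`, `path`, optional `exclude` file),
#'   `outcomes` (list of `label`, `path`), optional `ld` path, optional
#'   `column_map`, thresholds (`p_threshold`, `r2_prune`, `r2_proxy`),
#'   `palindromic_policy`, `eaf_tolerance`, `n_boot`, `seed`, `out_dir`.
#' @param out_dir Output directory (overrides the config entry).
#' @return The long results tibble, invisibly; files are written to
#'   `out_dir`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  cfg <- read_analysis_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% "mr_results"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cmap <- cfg$column_map %||% default_column_map()
  ld <- if (!is.null(cfg$ld)) read_ld_table(cfg$ld) else NULL
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  results <- list()
  counts <- list()
  for (ex in cfg$exposures) {
    exposure <- read_sumstats(ex$path, trait = ex$label, column_map = cmap)
    for (oc in cfg$outcomes) {
      outcome <- read_sumstats(oc$path, trait = oc$label, column_map = cmap)
      pair_id <- paste0(ex$label, "__", oc$label)
      res <- tryCatch(
        mr_pair(exposure, outcome, ld = ld,
                exposure_label = ex$label, outcome_label = oc$label,
                p_threshold = cfg$p_threshold %||% 5e-8,
                r2_prune = cfg$r2_prune %||% 0.05,
                r2_proxy = cfg$r2_proxy %||% 0.8,
                palindromic_policy = cfg$palindromic_policy %||% "drop",
                eaf_tolerance = cfg$eaf_tolerance %||% 0.08,
                n_boot = cfg$n_boot %||% 1000,
                seed = cfg$seed %||% 1L,
                exclude = ex$exclude),
        error = function(e) {
          note("pair ", pair_id, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      audit <- attr(res, "audit")
      if (!is.null(audit)) {
        readr::write_tsv(audit, file.path(out_dir,
                                          paste0("audit_", pair_id, ".tsv")),
                         progress = FALSE)
      }
      counts[[pair_id]] <- tibble::tibble(
        exposure = ex$label, outcome = oc$label,
        n_snps = res$n_snps[res$analysis == "main"][1],
        bonferroni = res$bonferroni[res$analysis == "main"][1]
      )
      note("pair ", pair_id, ": ", counts[[pair_id]]$n_snps,
           " instruments, Bonferroni threshold ",
           fmt_num(counts[[pair_id]]$bonferroni),
           " (divisor = post-harmonization count)")
      results[[pair_id]] <- res
    }
  }
  if (length(results) == 0L) {
    abort("no exposure-outcome pair produced results",
          class = "mrpipe_empty_result")
  }
  all_res <- dplyr::bind_rows(results)
  write_results(all_res, file.path(out_dir, "results.tsv"))
  readr::write_tsv(dplyr::bind_rows(counts),
                   file.path(out_dir, "instrument_counts.tsv"),
                   progress = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(all_res)
}

#' Qualitative robustness checklist across estimators
#'
#' For every exposure-outcome pair (and analysis block) reports the
#' standard two-sample MR robustness reading: do IVW and the weighted
#' median agree in sign, does the Egger intercept CI include zero (no
#' evidence of directional pleiotropy), and does the IVW p-value survive
#' the Bonferroni threshold.
#'
#' @param results Long results tibble from [mr_pair()]/[run_analysis()], or
#'   a `run_analysis()` output directory (its `results.json` is read).
#' @return Tibble with one row per pair and logical flags
#'   `sign_agreement`, `egger_intercept_includes_zero`,
#'   `ivw_bonferroni_significant`.
#' @export
compare_estimators <- function(results) {
  if (is.character(results)) {
    path <- file.path(results, "results.json")
    if (!file.exists(path)) abort(paste0("no results.json under ", results))
    results <- tibble::as_tibble(jsonlite::fromJSON(path))
  }
  if (!"analysis" %in% names(results)) results$analysis <- "main"
  results |>
    dplyr::group_by(.data$exposure, .data$outcome, .data$analysis) |>
    dplyr::group_modify(function(g, key) {
      ivw <- g[g$estimator == "IVW", ]
      wm <- g[g$estimator == "weighted_median", ]
      eg <- g[g$estimator == "mr_egger", ]
      if (nrow(ivw) == 0L || nrow(wm) == 0L || nrow(eg) == 0L) {
        abort("missing estimator output for a pair",
              class = "mrpipe_incomplete_group")
      }
      tibble::tibble(
        sign_agreement = sign(ivw$beta) == sign(wm$beta),
        egger_intercept_includes_zero =
          eg$intercept_ci_low <= 0 & eg$intercept_ci_high >= 0,
        ivw_bonferroni_significant = ivw$pval < ivw$bonferroni
      )
    }) |>
    dplyr::ungroup()
}
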