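# Result-table formatting and output: one display row per exposure-outcome
# pair with beta (95% CI) and p for IVW, weighted median and MR-Egger plus
# the Egger intercept block, written as TSV with a machine-readable JSON
# mirror of the unrounded long table.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(signif(x, 3), function(v) {
    format(v, scientific = v != 0 && abs(v) < 1e-4, trim = TRUE)
  }, character(1)))
}

fmt_ci <- function(est, lo, hi) {
  paste0(fmt_num(est), " (", fmt_num(lo), " to ", fmt_num(hi), ")")
}

#' Format MR results as a publication-style table
#'
#' One row per exposure-outcome pair (and analysis block), with each
#' estimator's beta, 95% CI and p-value rendered to 3 significant figures
#' and CIs as `"low to high"`.
#'
#' @param results Long results tibble (as produced by [mr_pair()] /
#'   [run_analysis()]): columns `exposure`, `outcome`, `analysis`,
#'   `estimator`, `n_snps`, `beta`, `ci_low`, `ci_high`, `pval` and the
#'   intercept columns.  Every group must contain all three estimators.
#' @return Wide display tibble.
#' @export
format_results <- function(results) {
  need <- c("IVW", "weighted_median", "mr_egger")
  if (!"analysis" %in% names(results)) results$analysis <- "main"
  groups <- dplyr::group_split(
    dplyr::group_by(results, .data$exposure, .data$outcome, .data$analysis)
  )
  rows <- purrr::map(groups, function(g) {
    missing <- setdiff(need, g$estimator)
    if (length(missing) > 0L) {
      abort(paste0("incomplete group ", g$exposure[1], " x ", g$outcome[1],
                   ": missing estimator(s) ", paste(missing, collapse = ", ")),
            class = "mrpipe_incomplete_group")
    }
    pick <- function(est) g[g$estimator == est, ][1, ]
    ivw <- pick("IVW"); wm <- pick("weighted_median"); eg <- pick("mr_egger")
    tibble::tibble(
      exposure = g$exposure[1], outcome = g$outcome[1],
      analysis = g$analysis[1], n_snps = ivw$n_snps,
      ivw_beta_ci = fmt_ci(ivw$beta, ivw$ci_low, ivw$ci_high),
      ivw_pval = fmt_num(ivw$pval),
      wm_beta_ci = fmt_ci(wm$beta, wm$ci_low, wm$ci_high),
      wm_pval = fmt_num(wm$pval),
      egger_beta_ci = fmt_ci(eg$beta, eg$ci_low, eg$ci_high),
      egger_pval = fmt_num(eg$pval),
      egger_intercept_ci = fmt_ci(eg$intercept, eg$intercept_ci_low,
                                  eg$intercept_ci_high),
      egger_intercept_pval = fmt_num(eg$intercept_pval)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write MR results (TSV + JSON mirror)
#'
#' Writes the formatted display table to `path` and the unrounded long
#' results to a `.json` file alongside it.
#'
#' @inheritParams format_results
#' @param path Output TSV path; the JSON mirror replaces the extension
#'   with `.json`.
#' @return The TSV path, invisibly.
#' @export
write_results <- function(results, path) {
  wide <- format_results(results)
  readr::write_tsv(wide, path, progress = FALSE)
  json_path <- sub("\\.[^./]*$", "", path)
  jsonlite::write_json(results, paste0(json_path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
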