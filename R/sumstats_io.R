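# Readers/writers and validation for GWAS summary-statistic tables and
# pairwise LD tables.  A summary-statistic table is an ordinary tibble with
# the standard columns below plus `trait` and `source` label columns, so it
# survives any dplyr verb.

SUMSTAT_COLS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)
REQUIRED_COLS <- c("variant_id", "effect_allele", "other_allele",
                   "beta", "se", "pval")

#' Default column map for consortium summary-statistics files
#'
#' Consortium files name their columns differently (GIANT-style headers use
#' `SNP`, `A1`, `A2`, `b`, `se`, `p`, `N`, `Freq1`); the map translates a
#' source header to the standard field names used throughout the package.
#' Override any entry to match your file.
#'
#' @return Named character vector: standard field -> source column name.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "Chr", pos = "Pos",
    effect_allele = "A1", other_allele = "A2", eaf = "Freq1",
    beta = "b", se = "se", pval = "p", n = "N")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant association statistics into the
#' standard tibble layout: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, plus `trait` and
#' `source` labels.  Alleles are coerced to upper case.  Rows violating the
#' record invariants (identical alleles, non-SNP alleles, `se <= 0`,
#' `pval` outside (0, 1], `eaf` outside [0, 1], duplicated `variant_id`) are
#' dropped with a message reporting the count; values are never silently
#' altered.
#'
#' @param path Path to a delimited text file with a header row.
#' @param trait Trait label for the table (e.g. `"WHRadjBMI"`).
#' @param source Source label (e.g. `"GIANT"`).
#' @param column_map Named character vector mapping standard fields to the
#'   file's column names; see [default_column_map()].  `chrom`, `pos`, `eaf`
#'   and `n` are optional: if their mapped column is absent they are filled
#'   with `NA`.  A missing *required* mapped column is an error.
#' @param delimiter Field delimiter (default tab).
#' @return A tibble of validated summary-statistic records.
#' @seealso [write_sumstats()], [read_ld_table()]
#' @export
read_sumstats <- function(path, trait = NA_character_, source = NA_character_,
                          column_map = default_column_map(),
                          delimiter = "\t") {
  if (!file.exists(path)) {
    abort(paste0("summary-statistics file not found: ", path))
  }
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  map <- utils::modifyList(as.list(default_column_map()), as.list(column_map))
  for (field in REQUIRED_COLS) {
    if (!map[[field]] %in% names(raw)) {
      abort(paste0("column '", map[[field]], "' (mapped to field '", field,
                   "') is missing from ", path), class = "mrpipe_config_error")
    }
  }
  pick <- function(field, default = NA) {
    cn <- map[[field]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  tbl <- tibble::tibble(
    variant_id = as.character(pick("variant_id")),
    chrom = as.character(pick("chrom", NA_character_)),
    pos = as.integer(pick("pos", NA_integer_)),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    other_allele = toupper(as.character(pick("other_allele"))),
    eaf = as.numeric(pick("eaf", NA_real_)),
    beta = as.numeric(pick("beta")),
    se = as.numeric(pick("se")),
    pval = as.numeric(pick("pval")),
    n = as.integer(pick("n", NA_integer_)),
    trait = trait,
    source = source
  )
  validate_sumstats(tbl, context = path)
}

#' Validate summary-statistic records
#'
#' Enforces the per-record invariants, dropping (never altering) offending
#' rows and reporting how many were dropped and why.  Exposed so that tables
#' built in code go through the same gate as tables read from disk.
#'
#' @param tbl Tibble with the standard summary-statistic columns.
#' @param context Label used in messages (e.g. the file path).
#' @return The tibble restricted to valid rows, input order preserved.
#' @export
validate_sumstats <- function(tbl, context = "summary statistics") {
  snp_alleles <- c("A", "C", "G", "T")
  ok <- !is.na(tbl$variant_id) & nzchar(tbl$variant_id) &
    tbl$effect_allele %in% snp_alleles &
    tbl$other_allele %in% snp_alleles &
    tbl$effect_allele != tbl$other_allele &
    is.finite(tbl$beta) &
    is.finite(tbl$se) & tbl$se > 0 &
    is.finite(tbl$pval) & tbl$pval > 0 & tbl$pval <= 1 &
    (is.na(tbl$eaf) | (tbl$eaf >= 0 & tbl$eaf <= 1)) &
    (is.na(tbl$n) | tbl$n > 0)
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(tbl$variant_id)
  n_bad <- sum(!ok)
  n_dup <- sum(dup & ok)
  if (n_bad > 0L) {
    inform(paste0(context, ": dropped ", n_bad,
                  " row(s) failing record invariants"))
  }
  if (n_dup > 0L) {
    inform(paste0(context, ": dropped ", n_dup,
                  " row(s) with duplicated variant_id"))
  }
  out <- tbl[ok & !dup, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort(paste0(context, ": no valid summary-statistic rows"),
          class = "mrpipe_empty_input")
  }
  out
}

#' Write a summary-statistics table
#'
#' Writes the standard tab-delimited layout (header plus one row per record).
#' `read_sumstats()` on the written file recovers the table exactly.
#'
#' @param tbl Non-empty summary-statistics tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(tbl, path) {
  if (nrow(tbl) == 0L) {
    abort("refusing to write an empty summary-statistics table",
          class = "mrpipe_empty_input")
  }
  cols <- intersect(c(SUMSTAT_COLS, "trait", "source"), names(tbl))
  readr::write_tsv(tbl[, cols], path, progress = FALSE)
  invisible(path)
}

#' Build a pairwise LD table
#'
#' An LD table stores r-squared between variant pairs; lookup is symmetric
#' and an absent pair means r-squared is unknown.  Pairs are stored once
#' under a canonical ordering.
#'
#' @param id1,id2 Character vectors of variant ids.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return A tibble with columns `id1`, `id2`, `r2` (`id1 < id2`).
#' @export
#' @examples
#' ld <- ld_table(c("rs1", "rs2"), c("rs2", "rs3"), c(0.2, 0.03))
#' ld_lookup(ld, "rs2", "rs1")  # symmetric: 0.2
ld_table <- function(id1 = character(), id2 = character(), r2 = numeric()) {
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    abort("r2 values must lie in [0, 1]", class = "mrpipe_validation_error")
  }
  if (any(id1 == id2)) {
    abort("LD table may not pair a variant with itself (r2 is implicitly 1)",
          class = "mrpipe_validation_error")
  }
  a <- pmin(id1, id2)
  b <- pmax(id1, id2)
  tbl <- tibble::tibble(id1 = a, id2 = b, r2 = r2)
  key <- paste(tbl$id1, tbl$id2)
  if (anyDuplicated(key)) {
    split_r2 <- split(tbl$r2, key)
    conflict <- vapply(split_r2, function(x) length(unique(x)) > 1L, logical(1))
    if (any(conflict)) {
      abort(paste0("conflicting r2 for pair(s): ",
                   paste(names(split_r2)[conflict], collapse = ", ")),
            class = "mrpipe_validation_error")
    }
    tbl <- tbl[!duplicated(key), , drop = FALSE]
  }
  tbl
}

#' Read a pairwise LD table
#'
#' Expects three columns (`id1`, `id2`, `r2`), tab-delimited, with or without
#' a header row.
#'
#' @param path Path to the LD file.
#' @return An LD tibble as produced by [ld_table()].
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) abort(paste0("LD file not found: ", path))
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][3])
  ))
  raw <- readr::read_tsv(path, col_names = c("id1", "id2", "r2"),
                         skip = if (has_header) 1L else 0L,
                         col_types = "ccd", progress = FALSE,
                         show_col_types = FALSE)
  ld_table(raw$id1, raw$id2, raw$r2)
}

#' Write a pairwise LD table
#'
#' @param ld LD tibble from [ld_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  readr::write_tsv(ld, path, progress = FALSE)
  invisible(path)
}

#' Look up pairwise r-squared
#'
#' Symmetric lookup: `ld_lookup(ld, a, b) == ld_lookup(ld, b, a)`.  A variant
#' with itself returns 1; an absent pair returns `NA` (r-squared unknown).
#'
#' @param ld LD tibble from [ld_table()] / [read_ld_table()], or `NULL`
#'   (no LD information: every lookup returns `NA`).
#' @param a,b Character vectors of variant ids (recycled to equal length).
#' @return Numeric vector of r-squared values.
#' @export
ld_lookup <- function(ld, a, b) {
  k <- pmax(length(a), length(b))
  a <- rep_len(a, k)
  b <- rep_len(b, k)
  out <- ifelse(a == b, 1, NA_real_)
  if (!is.null(ld) && nrow(ld) > 0L) {
    key <- paste(pmin(a, b), pmax(a, b))
    idx <- match(key, paste(ld$id1, ld$id2))
    hit <- !is.na(idx) & a != b
    out[hit] <- ld$r2[idx[hit]]
  }
  out
}
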