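test_that("read_sumstats reads a consortium-style table and propagates labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tA1\tA2\tFreq1\tb\tse\tp\tN",
    "rs1\ta\tg\t0.3\t0.05\t0.008\t1e-10\t100000",
    "rs2\tC\tT\t0.4\t-0.04\t0.007\t2e-9\t100000",
    "rs3\tG\tA\t0.5\t0.03\t0.006\t5e-8\t100000"
  ), path)
  tbl <- quiet(read_sumstats(path, trait = "WHRadjBMI", source = "GIANT"))
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(tbl$effect_allele, c("A", "C", "G"))  # uppercased
  expect_true(all(tbl$trait == "WHRadjBMI" & tbl$source == "GIANT"))
  expect_true(all(is.na(tbl$chrom)))  # unmapped optional field
})

test_that("rows violating record invariants are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tA1\tA2\tb\tse\tp",
    "rs1\tA\tG\t0.05\t0\t1e-10",    # se = 0
    "rs2\tA\tA\t0.04\t0.01\t1e-9",  # identical alleles
    "rs3\tA\tG\t0.04\t0.01\t0",     # p = 0
    "rs4\tA\tG\t0.04\t0.01\t1e-9",
    "rs4\tA\tG\t0.04\t0.01\t1e-9"   # duplicate id
  ), path)
  expect_message(tbl <- read_sumstats(path), "dropped 3 row")
  expect_equal(tbl$variant_id, "rs4")
  # values of surviving rows are untouched
  expect_equal(tbl$beta, 0.04)
})

test_that("a missing required mapped column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tb\tse", "rs1\tA\tG\t0.1\t0.01"), path)
  expect_error(read_sumstats(path), class = "mrpipe_config_error")
  expect_error(read_sumstats(path), "'p'")
})

test_that("write/read round-trip is the identity on a simulated table", {
  sim <- simulate_two_sample(sim_scenario(n_snps = 50, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(sim$exposure, path)
  expect_equal(length(readLines(path)), 51L)  # header + 50 rows
  back <- quiet(read_sumstats(path, trait = sim$exposure$trait[1],
                              source = sim$exposure$source[1],
                              column_map = identity_map()))
  expect_equal(as.data.frame(back), as.data.frame(sim$exposure))
})

test_that("writing an empty table errors", {
  expect_error(write_sumstats(tibble::tibble(), tempfile()),
               class = "mrpipe_empty_input")
})

test_that("LD lookup is symmetric and absent pairs are unknown", {
  ld <- ld_table(c("a", "b"), c("b", "c"), c(0.2, 0.03))
  expect_equal(ld_lookup(ld, "b", "a"), 0.2)
  expect_equal(ld_lookup(ld, "a", "b"), 0.2)
  expect_equal(ld_lookup(ld, "b", "c"), 0.03)
  expect_true(is.na(ld_lookup(ld, "a", "c")))
  expect_equal(ld_lookup(ld, "a", "a"), 1)  # self r2 implicit
})

test_that("LD validation rejects out-of-range and conflicting entries", {
  expect_error(ld_table("a", "b", 1.5), class = "mrpipe_validation_error")
  expect_error(ld_table(c("a", "b"), c("b", "a"), c(0.2, 0.3)),
               class = "mrpipe_validation_error")
  # consistent duplicates collapse
  expect_equal(nrow(ld_table(c("a", "b"), c("b", "a"), c(0.2, 0.2))), 1L)
})

test_that("LD lookup agrees with a direct scan on a random 100-pair table", {
  withr::with_seed(42, {
    ids <- sprintf("rs%03d", 1:60)
    pairs <- t(utils::combn(ids, 2))
    pick <- sample(nrow(pairs), 100)
    r2 <- runif(100)
  })
  ld <- ld_table(pairs[pick, 1], pairs[pick, 2], r2)
  scan <- function(a, b) {
    hit <- (ld$id1 == a & ld$id2 == b) | (ld$id1 == b & ld$id2 == a)
    if (any(hit)) ld$r2[hit] else NA_real_
  }
  for (i in sample(100, 25)) {
    a <- pairs[pick[i], 1]; b <- pairs[pick[i], 2]
    expect_equal(ld_lookup(ld, a, b), scan(a, b))
    expect_equal(ld_lookup(ld, b, a), scan(a, b))
  }
})

test_that("read_ld_table round-trips and tolerates a header", {
  ld <- ld_table(c("rs1", "rs2"), c("rs2", "rs3"), c(0.9, 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_table(ld, path)
  expect_equal(as.data.frame(read_ld_table(path)), as.data.frame(ld))
  # headerless variant
  writeLines(c("rs1\trs2\t0.9", "rs2\trs3\t0.1"), path)
  expect_equal(as.data.frame(read_ld_table(path)), as.data.frame(ld))
})

test_that("results table renders one row per pair with all four blocks", {
  res <- tibble::tibble(
    exposure = "WHRadjBMI", outcome = "birth_weight", analysis = "main",
    estimator = c("IVW", "weighted_median", "mr_egger"),
    n_snps = 25L,
    beta = c(0.16789, 0.175, 0.153), se = 0.038,
    ci_low = c(0.0934, 0.108, -0.157), ci_high = c(0.2423, 0.241, 0.464),
    pval = c(7.1e-5, 2.5e-7, 0.332),
    intercept = c(NA, NA, 0), intercept_se = c(NA, NA, 0.005),
    intercept_ci_low = c(NA, NA, -0.011), intercept_ci_high = c(NA, NA, 0.012),
    intercept_pval = c(NA, NA, 0.972)
  )
  wide <- format_results(res)
  expect_equal(nrow(wide), 1L)
  expect_equal(wide$ivw_beta_ci, "0.168 (0.0934 to 0.242)")
  expect_equal(wide$ivw_pval, "7.1e-05")
  # intercept of exactly zero renders as plain 0
  expect_equal(wide$egger_intercept_ci, "0 (-0.011 to 0.012)")
  # a group missing an estimator is an error
  expect_error(format_results(res[1:2, ]), class = "mrpipe_incomplete_group")
})

test_that("written results reparse to the point estimates at 3 s.f.", {
  fx <- make_worked_fixture()
  res <- quiet(mr_pair(fx$exposure, fx$outcome, ld = fx$ld, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  first_num <- function(s) as.numeric(sub(" .*", "", s))
  expect_equal(first_num(wide$ivw_beta_ci),
               signif(res$beta[res$estimator == "IVW"], 3))
  expect_equal(first_num(wide$egger_beta_ci),
               signif(res$beta[res$estimator == "mr_egger"], 3))
  expect_equal(first_num(wide$egger_intercept_ci),
               signif(res$intercept[res$estimator == "mr_egger"], 3))
  # JSON mirror holds the unrounded values
  js <- jsonlite::fromJSON(sub("\\.tsv$", ".json", path))
  expect_equal(js$beta, res$beta)
})
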