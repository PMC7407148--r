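# A small two-polarity assay used across the pipeline tests: two analytes,
# each quantified against its class internal standard (single primary ion per
# standard so that area ratios equal amount ratios by construction).
make_assay <- function() {
  std <- internal_standards()
  std <- std[std$id %in% c("IS_LPC_14:0-d42", "IS_PI_34:1-d31"), ]
  std$products_mz <- lapply(seq_len(nrow(std)), function(i) {
    std$products_mz[[i]][which.min(abs(std$products_mz[[i]] -
      (adduct_mz(monoisotopic_mass(std$formula[i], std$n_deuterium[i]),
                 std$primary_adduct[i]))))]
  })
  analytes <- data.frame(
    name = c("LPC_(16:0)", "PI_(38:4)"),
    mz_list = c("496.3398", "885.5499"),
    polarity = c("pos", "neg"),
    expected_rt = c(0.9, 2.5))
  build_target_list(std, analytes, rt_tolerance = 0.1)
}

is_amounts <- c("IS_LPC_14:0-d42" = 5, "IS_PI_34:1-d31" = 5)

test_that("the quantitation chain recovers configured concentrations", {
  tl <- make_assay()
  scans <- list(
    s1 = simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 2,
                                    "PI_(38:4)" = 3), run_length = 3.5),
    s2 = simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 1,
                                    "PI_(38:4)" = 0.5), run_length = 3.5),
    b1 = simulate_scan_series(tl, is_amounts, run_length = 3.5))
  samples <- data.frame(sample = c("s1", "s2", "b1"),
                        kind = c("sample", "sample", "blank"),
                        tissue_mass = c(10, 20, NA),
                        group = c("g1", "g2", NA))
  res <- quantify_samples(scans, tl, samples)
  expect_s3_class(res, "quant_result")
  val <- function(s, a) res$concentration[res$sample == s & res$analyte == a]
  expect_equal(val("s1", "LPC_(16:0)"), 2 / 10, tolerance = 0.01)
  expect_equal(val("s1", "PI_(38:4)"), 3 / 10, tolerance = 0.01)
  expect_equal(val("s2", "LPC_(16:0)"), 1 / 20, tolerance = 0.01)
  expect_equal(val("s2", "PI_(38:4)"), 0.5 / 20, tolerance = 0.01)
  expect_true(all(res$unit[res$sample != "b1"] == "uM/mg"))
  expect_false(any(res$censored[res$sample != "b1"]))
})

test_that("the drift and blank rules censor exactly the violations", {
  tl <- make_assay()
  scans <- list(
    s1 = simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 2,
                                    "PI_(38:4)" = 0.2), run_length = 3.5),
    s2 = simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 2,
                                    "PI_(38:4)" = 3), run_length = 3.5,
                              rt_shift = c("LPC_(16:0)" = 0.15)),
    b1 = simulate_scan_series(tl, c(is_amounts, "PI_(38:4)" = 0.5),
                              run_length = 3.5))
  samples <- data.frame(sample = c("s1", "s2", "b1"),
                        kind = c("sample", "sample", "blank"),
                        tissue_mass = c(10, 10, NA))
  res <- quantify_samples(scans, tl, samples)
  rule <- function(s, a) res$censor_rule[res$sample == s & res$analyte == a]
  # blank ratio 0.1 -> threshold 0.3; s1's PI ratio 0.04 falls below it
  expect_equal(rule("s1", "PI_(38:4)"), "blank")
  expect_equal(res$concentration[res$sample == "s1" &
                                   res$analyte == "PI_(38:4)"], 0)
  # s2's shifted LPC apex is excluded by the drift rule
  expect_equal(rule("s2", "LPC_(16:0)"), "rt_drift")
  # nothing else is censored
  expect_equal(sum(res$censored[res$sample %in% c("s1", "s2")]), 2L)
  expect_gt(res$concentration[res$sample == "s2" & res$analyte == "PI_(38:4)"],
            0)
})

test_that("a run without blanks warns and skips the blank rule", {
  tl <- make_assay()
  scans <- list(s1 = simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 2,
                                                "PI_(38:4)" = 1),
                                          run_length = 3.5))
  samples <- data.frame(sample = "s1", kind = "sample", tissue_mass = 10)
  expect_warning(res <- quantify_samples(scans, tl, samples), "no blank")
  expect_false(any(res$censored))
})

test_that("a missing internal standard fails that sample's class only", {
  tl <- make_assay()
  scans <- list(
    s1 = simulate_scan_series(tl, c("IS_LPC_14:0-d42" = 5, "LPC_(16:0)" = 2,
                                    "PI_(38:4)" = 1), run_length = 3.5))
  samples <- data.frame(sample = "s1", kind = "sample", tissue_mass = 10)
  res <- suppressWarnings(quantify_samples(scans, tl, samples))
  expect_equal(res$censor_rule[res$analyte == "PI_(38:4)"], "is_missing")
  expect_true(is.na(res$concentration[res$analyte == "PI_(38:4)"]))
  expect_gt(res$concentration[res$analyte == "LPC_(16:0)"], 0)
})

test_that("input validation fails fast", {
  tl <- make_assay()
  expect_error(quantify_samples(list(), tl, data.frame()),
               "missing column")
  expect_error(quantify_samples(list(), tl,
                                data.frame(sample = character(0),
                                           kind = character(0))),
               "empty sample sheet")
  expect_error(quantify_samples(list(), tl,
                                data.frame(sample = "s1", kind = "sample")),
               "no scan data")
})

test_that("the file-based orchestration writes results and provenance", {
  dir <- tempfile("run")
  dir.create(dir)
  tl <- make_assay()
  sc <- simulate_scan_series(tl, c(is_amounts, "LPC_(16:0)" = 2,
                                   "PI_(38:4)" = 1), run_length = 3.5)
  scb <- simulate_scan_series(tl, is_amounts, run_length = 3.5)
  write.table(sc, file.path(dir, "s1.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(scb, file.path(dir, "b1.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.csv(data.frame(sample = c("s1", "b1"), kind = c("sample", "blank"),
                       tissue_mass = c(10, NA), group = c("g1", NA),
                       scan_file = c("s1.tsv", "b1.tsv")),
            file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(data.frame(name = c("LPC_(16:0)", "PI_(38:4)"),
                       mz_list = c("496.3398", "885.5499"),
                       polarity = c("pos", "neg"),
                       expected_rt = c(0.9, 2.5)),
            file.path(dir, "analytes.csv"), row.names = FALSE)
  out <- file.path(dir, "quant.tsv")
  res <- suppressMessages(run_quantify(list(
    sample_sheet = file.path(dir, "samples.csv"),
    analytes_csv = file.path(dir, "analytes.csv"),
    out_tsv = out)))
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".provenance.json")))
  prov <- jsonlite::read_json(paste0(out, ".provenance.json"))
  expect_equal(prov$package, "lipidscreen")
  back <- read.delim(out)
  expect_equal(nrow(back), nrow(res))

  expect_error(suppressMessages(run_quantify(list(
    sample_sheet = file.path(dir, "nope.csv"),
    analytes_csv = file.path(dir, "analytes.csv")))), "unreadable")
})

test_that("the screen orchestration reports the study summary and survives permutation", {
  out_json <- tempfile(fileext = ".json")
  r <- suppressMessages(run_screen(list(out_json = out_json)))
  expect_equal(r$summary$n_flagged, 100L)
  expect_equal(r$summary$n_increasing, 35L)
  expect_equal(r$summary$n_decreasing, 65L)
  js <- jsonlite::read_json(out_json)
  expect_equal(js$n_flagged, 100L)

  # shuffling the dose labels destroys most of the signal
  set.seed(123)
  long <- liver_lipid_table_long()
  for (l in unique(long$lipid)) {
    i <- which(long$lipid == l)
    long$dose[i] <- sample(long$dose[i])
  }
  rp <- suppressMessages(run_screen(data = long))
  expect_lt(rp$summary$n_flagged, 50L)

  expect_error(suppressMessages(
    run_screen(data = data.frame(lipid = "a", dose = 1, mean = 1))),
    "at least 3 dose groups")
})
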