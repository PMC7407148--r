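make_scans <- function(times, mz, intensity, polarity = "pos") {
  as_scan_series(data.frame(scan_time_min = times, polarity = polarity,
                            mz = mz, intensity = intensity))
}

test_that("EIC extraction sums matching centroids per scan, zeros elsewhere", {
  sc <- make_scans(c(1.0, 1.1, 1.2), c(500.0, 500.0, 600.0), c(10, 20, 5))
  tr <- extract_eic(sc, 500.0, "pos")
  expect_equal(tr$time, c(1.0, 1.1, 1.2))
  expect_equal(tr$intensity, c(10, 20, 0))

  # product m/z absent from every scan -> all-zero trace over all scan times
  tr0 <- extract_eic(sc, 900.0, "pos")
  expect_equal(tr0$intensity, c(0, 0, 0))

  # two products summed into one trace
  sc2 <- make_scans(c(1, 1, 2, 2), c(500, 510, 500, 510), c(3, 4, 5, 6))
  tr2 <- extract_eic(sc2, c(500, 510), "pos")
  expect_equal(tr2$intensity, c(7, 11))

  # polarity filtering: neg target sees nothing in pos scans
  expect_equal(nrow(extract_eic(sc, 500, "neg")), 0L)
  expect_error(extract_eic(sc, numeric(0), "pos"), "empty target")

  # ppm window: 500.004 is within 10 ppm of 500, 500.02 is not
  sc3 <- make_scans(c(1, 1), c(500.004, 500.02), c(8, 9))
  expect_equal(extract_eic(sc3, 500, "pos", tol_ppm = 10)$intensity, 8)
})

test_that("two co-eluting adduct products reproduce the generated sum", {
  tl <- build_target_list(analytes = data.frame(
    name = "A", mz_list = "400.1;422.1", polarity = "pos", expected_rt = 2))
  sc <- simulate_scan_series(tl, c(A = 2), peak_sigma = 0.05,
                             run_length = 4)
  tr <- extract_eic(sc, c(400.1, 422.1), "pos")
  h <- 2 * 1000                         # amount x response, per product
  expected <- 2 * h * exp(-((tr$time - 2)^2) / (2 * 0.05^2))
  nz <- expected > 1e-3
  expect_equal(tr$intensity[nz], expected[nz], tolerance = 1e-9)
})

test_that("peak integration recovers a Gaussian area within 2%", {
  tl <- build_target_list(analytes = data.frame(
    name = "A", mz_list = "400.1", polarity = "pos", expected_rt = 2))
  sc <- simulate_scan_series(tl, c(A = 1), peak_sigma = 0.05, run_length = 4)
  tr <- extract_eic(sc, 400.1, "pos")
  pk <- integrate_peak(tr, expected_rt = 2)
  expect_true(pk$found)
  expect_equal(pk$apex_rt, 2, tolerance = 0.01)
  expect_equal(pk$area, gaussian_area(1000, 0.05), tolerance = 0.02)
})

test_that("apex drift beyond the retention-time tolerance yields Not Found", {
  tl <- build_target_list(analytes = data.frame(
    name = "A", mz_list = "400.1", polarity = "pos", expected_rt = 2))
  sc <- simulate_scan_series(tl, c(A = 1), rt_shift = 0.15, run_length = 4)
  tr <- extract_eic(sc, 400.1, "pos")
  pk <- integrate_peak(tr, expected_rt = 2)
  expect_false(pk$found)
  expect_equal(pk$area, 0)
  expect_equal(pk$status, "rt_drift")

  # drift within tolerance still integrates
  sc2 <- simulate_scan_series(tl, c(A = 1), rt_shift = 0.08, run_length = 4)
  pk2 <- integrate_peak(extract_eic(sc2, 400.1, "pos"), expected_rt = 2)
  expect_true(pk2$found)

  # flat-zero trace
  flat <- structure(data.frame(time = seq(0, 4, 0.01), intensity = 0),
                    class = c("eic_trace", "data.frame"))
  pk3 <- integrate_peak(flat, expected_rt = 2)
  expect_false(pk3$found)
  expect_equal(pk3$status, "not_found")
})

test_that("areas and ratios are exactly linear in peak amplitude", {
  tl <- build_target_list(analytes = data.frame(
    name = c("A", "IS"), mz_list = c("400.1", "450.1"),
    polarity = "pos", expected_rt = c(2, 2)))
  area_of <- function(amount) {
    sc <- simulate_scan_series(tl, c(A = amount, IS = 5), run_length = 4)
    a <- integrate_peak(extract_eic(sc, 400.1, "pos"), 2)
    s <- integrate_peak(extract_eic(sc, 450.1, "pos"), 2)
    c(area = a$area, ratio = area_ratio(a, s))
  }
  one <- area_of(1)
  two <- area_of(2)
  expect_equal(two[["area"]] / one[["area"]], 2, tolerance = 1e-9)
  expect_equal(two[["ratio"]] / one[["ratio"]], 2, tolerance = 1e-9)
})

test_that("area ratios follow the definition and flag failed standards", {
  ok <- structure(list(area = 10, apex_rt = 2, found = TRUE, status = "ok"),
                  class = "peak_area")
  std <- structure(list(area = 20, apex_rt = 2, found = TRUE, status = "ok"),
                   class = "peak_area")
  gone <- structure(list(area = 0, apex_rt = NA, found = FALSE,
                         status = "not_found"), class = "peak_area")
  expect_equal(area_ratio(ok, std), 0.5)
  expect_equal(area_ratio(gone, std), 0)
  expect_error(area_ratio(ok, gone), "internal standard missing")
})

test_that("blank correction censors below three times the blank level", {
  bc <- blank_correct(c(2.9, 3.1, 0.5), blank_values = c(1.0, 1.0))
  expect_equal(bc$values, c(0, 3.1, 0))
  expect_equal(bc$censored, c(TRUE, FALSE, TRUE))
  expect_equal(bc$threshold, 3)

  # all-zero blanks: threshold 0, nothing censored
  bc0 <- blank_correct(c(0.1, 5), blank_values = c(0, 0))
  expect_equal(bc0$values, c(0.1, 5))
  expect_false(any(bc0$censored))

  # no blanks: rule skipped with a warning
  expect_warning(bcn <- blank_correct(c(1, 2), numeric(0)), "skipped")
  expect_equal(bcn$values, c(1, 2))

  # "max" statistic is more conservative than the mean
  bcm <- blank_correct(c(4), blank_values = c(1, 2), stat = "max")
  expect_true(bcm$censored)
})

test_that("blank correction is idempotent and censoring is monotone", {
  set.seed(7)
  for (rep in 1:20) {
    v <- runif(12, 0, 10)
    b <- runif(3, 0, 2)
    once <- blank_correct(v, b)
    twice <- blank_correct(once$values, b)
    expect_identical(twice$values, once$values)
    # raising the blank level never un-censors a value
    higher <- blank_correct(v, b * 1.5)
    expect_true(all(higher$censored >= once$censored))
  }
})

test_that("concentration conversion handles tissue and fluid samples", {
  expect_equal(as.numeric(to_concentration(1, 5, fluid_volume = 50)), 5)
  expect_equal(attr(to_concentration(1, 5, fluid_volume = 50), "unit"), "uM")
  tis <- to_concentration(1, 5, tissue_mass = 10)
  expect_equal(as.numeric(tis), 0.5)
  expect_equal(attr(tis, "unit"), "uM/mg")
  expect_equal(as.numeric(to_concentration(0, 5, tissue_mass = 10)), 0)
  expect_error(to_concentration(1, 5), "tissue_mass")
  expect_error(to_concentration(1, 5, tissue_mass = 0), "positive")
  expect_error(to_concentration(1, 5, tissue_mass = 1, fluid_volume = 1),
               "not both")
})

test_that("the scan TSV dialect and mzML both round-trip scan data", {
  sc <- make_scans(c(1.0, 1.1), c(500, 500), c(10, 20))
  tsv <- tempfile(fileext = ".tsv")
  write.table(sc, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  rt <- read_scans_tsv(tsv)
  expect_s3_class(rt, "scan_series")
  expect_equal(rt$intensity, c(10, 20))

  expect_error(as_scan_series(data.frame(scan_time_min = 1, polarity = "x",
                                         mz = 500, intensity = 1)),
               "polarity")

  skip_if_not_installed("mzR")
  mzml <- tempfile(fileext = ".mzML")
  write_tiny_mzml(mzml, list(
    list(rt = 1.0, polarity = "pos", mz = c(239.1983, 400.1),
         intensity = c(1000, 50)),
    list(rt = 1.004, polarity = "neg", mz = 302.4557, intensity = 777)))
  sc2 <- suppressWarnings(read_scans_mzml(mzml))
  expect_equal(nrow(sc2), 3L)
  expect_equal(sort(unique(sc2$polarity)), c("neg", "pos"))
  expect_equal(sc2$intensity[sc2$polarity == "neg"], 777)
  tr <- extract_eic(sc2, 239.1983, "pos")
  expect_equal(tr$intensity, 1000)
})
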