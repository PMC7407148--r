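## Synthetic study data: per-animal concentration matrices with configurable
## dose trends (emulating the four-diet design, n = 8-9 per group), synthetic
## polarity-switching scan series with Gaussian chromatographic peaks, and the
## packaged transcription of the printed liver-lipid table.

.liver_table_md5 <- "5f46b55d36bca3b5183fd16a8010d577"

#' Simulate per-animal lipid concentration matrices
#'
#' Each lipid follows a linear dose trend with additive Gaussian within-group
#' noise truncated at zero (group SDs in the printed study table are often
#' comparable to the means, so negative draws are clipped); not-detected
#' censoring replaces a value with NA at the configured probability.
#'
#' @param specs data.frame with one row per lipid: \code{lipid},
#'   \code{intercept}, \code{slope} (per percent beef tallow), and either a
#'   single \code{noise_sd} column or per-group columns
#'   \code{noise_sd_1} ... \code{noise_sd_k}; optional \code{censor_prob}
#'   (default 0).
#' @param doses Dose per group; default the study's beef-tallow percentages.
#' @param n_per_group Animals per group (default 9).
#' @param seed RNG seed; outputs are bit-identical under the same seed.
#' @param noise "gaussian" (default) or "lognormal" (matching mean and sd on
#'   the natural scale).
#' @return List: \code{values} (samples x lipids matrix, NA = not detected)
#'   and \code{samples} (data.frame with \code{sample}, \code{group},
#'   \code{dose}).
#' @export
simulate_concentrations <- function(specs, doses = c(3.6, 6.3, 9.0, 11.7),
                                    n_per_group = 9, seed = NULL,
                                    noise = c("gaussian", "lognormal")) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(specs), n_per_group >= 2,
            all(c("lipid", "intercept", "slope") %in% names(specs)))
  if (!is.null(seed)) set.seed(seed)
  k <- length(doses)
  sd_cols <- paste0("noise_sd_", seq_len(k))
  per_group_sd <- all(sd_cols %in% names(specs))
  if (!per_group_sd && !"noise_sd" %in% names(specs)) {
    stop("specs need 'noise_sd' or per-group 'noise_sd_1..k' columns",
         call. = FALSE)
  }
  censor <- if ("censor_prob" %in% names(specs)) specs$censor_prob else
    rep(0, nrow(specs))
  stopifnot(all(censor >= 0 & censor <= 1))
  samples <- data.frame(
    sample = sprintf("g%d_a%d", rep(seq_len(k), each = n_per_group),
                     rep(seq_len(n_per_group), k)),
    group = rep(seq_len(k), each = n_per_group),
    dose = rep(doses, each = n_per_group),
    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow(samples), nrow(specs),
                 dimnames = list(samples$sample, specs$lipid))
  for (j in seq_len(nrow(specs))) {
    mu <- specs$intercept[j] + specs$slope[j] * samples$dose
    sds <- if (per_group_sd) {
      as.numeric(specs[j, sd_cols])[samples$group]
    } else {
      rep(specs$noise_sd[j], nrow(samples))
    }
    v <- if (noise == "gaussian") {
      pmax(0, mu + stats::rnorm(nrow(samples), 0, sds))
    } else {
      pos <- mu > 0 & sds > 0
      out <- pmax(0, mu)
      if (any(pos)) {
        s2 <- log(1 + (sds[pos] / mu[pos])^2)
        out[pos] <- stats::rlnorm(sum(pos), log(mu[pos]) - s2 / 2, sqrt(s2))
      }
      out
    }
    nd <- stats::runif(nrow(samples)) < censor[j]
    v[nd] <- NA_real_
    vals[, j] <- v
  }
  list(values = vals, samples = samples)
}

#' Simulate one polarity-switching scan series
#'
#' Emulates a centroided high-resolution acquisition: positive- and
#' negative-mode scans alternate on a fixed interval; each analyte contributes
#' a Gaussian elution profile at each of its product m/z values, with peak
#' height proportional to its amount; an optional uniform noise floor is added
#' at every target m/z. A blank injection is simply a series whose amounts are
#' the contamination level.
#'
#' @param targets An \code{mz_target_list}; every id present in
#'   \code{amounts} contributes peaks.
#' @param amounts Named numeric vector: amount per target id (arbitrary
#'   concentration units; peak height = amount x \code{response}).
#' @param seed RNG seed for the noise floor.
#' @param rt_shift Named numeric vector of per-id retention-time shifts in
#'   minutes (for drift scenarios), or a single value applied to all.
#' @param peak_sigma Chromatographic peak sigma in minutes.
#' @param response Instrument response factor (height per amount unit).
#' @param noise_floor Upper bound of uniform noise added at each target m/z in
#'   every scan (0 = noiseless).
#' @param run_length Run length in minutes.
#' @param scan_interval_s Scan interval per polarity in seconds (default 0.25,
#'   i.e. a 4 Hz instrument alternating modes).
#' @return A \code{scan_series}.
#' @export
simulate_scan_series <- function(targets, amounts, seed = NULL, rt_shift = 0,
                                 peak_sigma = 0.05, response = 1000,
                                 noise_floor = 0, run_length = 10,
                                 scan_interval_s = 0.25) {
  stopifnot(inherits(targets, "mz_target_list"), peak_sigma > 0,
            scan_interval_s > 0, run_length > 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- intersect(unique(targets$id), names(amounts))
  if (length(ids) == 0L) stop("no target ids in 'amounts'", call. = FALSE)
  dt <- scan_interval_s / 60
  t_pos <- seq(0, run_length, by = dt)
  t_neg <- t_pos + dt / 2           # alternating polarity
  if (length(rt_shift) == 1L && is.null(names(rt_shift))) {
    rt_shift <- stats::setNames(rep(rt_shift, length(ids)), ids)
  }
  rows <- list()
  for (id in ids) {
    tg <- targets[targets$id == id, , drop = FALSE]
    times <- if (tg$polarity[1] == "pos") t_pos else t_neg
    shift <- if (id %in% names(rt_shift)) rt_shift[[id]] else 0
    apex <- tg$expected_rt[1] + shift
    h <- amounts[[id]] * response
    prof <- h * exp(-((times - apex)^2) / (2 * peak_sigma^2))
    keep <- prof > h * 1e-6 | noise_floor > 0
    for (p in tg$mz) {
      intens <- prof[keep]
      if (noise_floor > 0) {
        intens <- intens + stats::runif(sum(keep), 0, noise_floor)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scan_time_min = times[keep], polarity = tg$polarity[1],
        mz = p, intensity = intens)
    }
  }
  as_scan_series(do.call(rbind, rows))
}

#' The packaged liver-lipid study table
#'
#' Returns the transcription of the printed per-lipid results of the
#' four-diet beef-tallow dose-response study: per diet group the mean and
#' standard deviation of the liver concentration (nM/mg, n = 8-9 animals;
#' ND = not detected, encoded NA), plus the printed trendline slope,
#' intercept and R-squared (kept verbatim as strings to preserve the printed
#' precision), the printed slope-significance star, successive-change label
#' and the printed three-criterion biomarker highlight.
#'
#' @return data.frame with 472 rows and an attribute \code{doses}
#'   (percent beef tallow per diet group).
#' @export
liver_lipid_table <- function() {
  path <- system.file("extdata", "liver_lipid_study.csv",
                      package = "lipidscreen", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .liver_table_md5)) {
    stop("packaged study table is corrupted (checksum mismatch)",
         call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c(paste0("mean_", 1:4), paste0("sd_", 1:4))) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))  # "" (ND) -> NA
  }
  d$printed_sig <- as.logical(d$printed_sig)
  d$printed_flag <- as.logical(d$printed_flag)
  attr(d, "doses") <- c(3.6, 6.3, 9.0, 11.7)
  attr(d, "unit") <- "nM/mg"
  d
}

#' Long-format view of the packaged study table
#'
#' Reshapes [liver_lipid_table()] to one row per lipid x diet group with columns
#' \code{lipid}, \code{dose}, \code{mean}, \code{sd}, ready for
#' [lipid_screen()].
#'
#' @return Long data.frame (472 lipids x 4 groups).
#' @export
liver_lipid_table_long <- function() {
  d <- liver_lipid_table()
  doses <- attr(d, "doses")
  out <- do.call(rbind, lapply(1:4, function(g) {
    data.frame(lipid = d$lipid, dose = doses[g],
               mean = d[[paste0("mean_", g)]],
               sd = d[[paste0("sd_", g)]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Trend generator specs taken from the packaged study table
#'
#' Builds [simulate_concentrations()] specs whose trend lines are the printed
#' fits and whose per-group noise SDs are the printed group SDs, so simulated
#' cohorts share the study's mean/SD structure.
#'
#' @param lipids Lipid names to include (default: all rows with a printed
#'   trendline and four observed groups).
#' @return specs data.frame for [simulate_concentrations()].
#' @export
trend_specs_from_fixture <- function(lipids = NULL) {
  d <- liver_lipid_table()
  full <- stats::complete.cases(d[, paste0("mean_", 1:4)]) &
    nzchar(d$printed_slope)
  if (is.null(lipids)) lipids <- d$lipid[full]
  d <- d[match(lipids, d$lipid), , drop = FALSE]
  if (anyNA(d$lipid)) stop("unknown lipid name(s)", call. = FALSE)
  data.frame(lipid = d$lipid,
             intercept = as.numeric(d$printed_intercept),
             slope = as.numeric(d$printed_slope),
             noise_sd_1 = d$sd_1, noise_sd_2 = d$sd_2,
             noise_sd_3 = d$sd_3, noise_sd_4 = d$sd_4,
             censor_prob = 0, stringsAsFactors = FALSE)
}
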