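## Extracted ion chromatograms: trace construction, peak integration with the
## retention-time drift rule, blank correction and internal-standard
## semi-quantitation.

#' Read centroided scan data from the TSV dialect
#'
#' One row per centroid per scan: columns \code{scan_time_min},
#' \code{polarity} ("pos"/"neg"), \code{mz}, \code{intensity}.
#'
#' @param path TSV file path.
#' @return data.frame of class \code{"scan_series"}.
#' @export
read_scans_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_scan_series(d)
}

#' Validate and class a scan table
#'
#' @param d data.frame with columns \code{scan_time_min}, \code{polarity},
#'   \code{mz}, \code{intensity}.
#' @return The validated data.frame, classed \code{"scan_series"}.
#' @export
as_scan_series <- function(d) {
  need <- c("scan_time_min", "polarity", "mz", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("scan table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(d$polarity %in% c("pos", "neg"))) {
    stop("scan polarity must be 'pos' or 'neg'", call. = FALSE)
  }
  if (any(d$intensity < 0)) stop("negative intensities", call. = FALSE)
  d <- d[order(d$scan_time_min, d$mz), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("scan_series", "data.frame")
  d
}

#' Read centroided scans from an mzML file
#'
#' Thin wrapper over \pkg{mzR}; converts an mzML acquisition (centroid mode)
#' into the package's long scan table. Scan polarity is taken from the mzML
#' header (1 = positive, 0 = negative).
#'
#' @param path mzML file path.
#' @return data.frame of class \code{"scan_series"}.
#' @export
read_scans_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  rows <- lapply(seq_len(nrow(hd)), function(i) {
    p <- pk[[i]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(scan_time_min = hd$retentionTime[i] / 60,
               polarity = ifelse(hd$polarity[i] > 0, "pos", "neg"),
               mz = p[, 1], intensity = p[, 2])
  })
  as_scan_series(do.call(rbind, rows))
}

#' Extract an ion chromatogram
#'
#' For every scan of the matching polarity, sums the intensity of all
#' centroids within \code{tol_ppm} of any target product m/z ("all reasonably
#' expected ions" combined into a single trace). The trace covers every scan
#' time of that polarity, with zeros where nothing matched.
#'
#' @param scans A \code{scan_series}.
#' @param mz Numeric vector of product m/z values (non-empty).
#' @param polarity "pos" or "neg".
#' @param tol_ppm Extraction half-window in parts per million (default 10,
#'   appropriate for Orbitrap-class resolution).
#' @return data.frame (class \code{"eic_trace"}) with columns \code{time},
#'   \code{intensity}.
#' @export
extract_eic <- function(scans, mz, polarity, tol_ppm = 10) {
  stopifnot(inherits(scans, "scan_series"), tol_ppm > 0)
  if (length(mz) == 0L) stop("empty target list", call. = FALSE)
  stopifnot(polarity %in% c("pos", "neg"))
  sel <- scans$polarity == polarity
  times <- sort(unique(scans$scan_time_min[sel]))
  total <- numeric(length(times))
  sub <- scans[sel, , drop = FALSE]
  scan_idx <- match(sub$scan_time_min, times)
  for (p in mz) {
    hit <- abs(sub$mz - p) <= p * tol_ppm * 1e-6
    if (!any(hit)) next
    agg <- rowsum(sub$intensity[hit], scan_idx[hit])
    i <- as.integer(rownames(agg))
    total[i] <- total[i] + agg[, 1]
  }
  out <- data.frame(time = times, intensity = total)
  class(out) <- c("eic_trace", "data.frame")
  out
}

## trapezoidal rule over (x, y)
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Integrate an EIC peak at its expected retention time
#'
#' Locates the trace apex within \code{expected_rt +/- window}. Analytes whose
#' apex drifts by more than \code{rt_tolerance} from the expected retention
#' time are excluded as Not Found (zero area) rather than integrated at the
#' wrong position. Peak bounds are the nearest flanking local minima, capped
#' at \code{max_halfwidth} from the apex; the area is the trapezoidal integral
#' between them.
#'
#' @param trace An \code{eic_trace} from [extract_eic()].
#' @param expected_rt Expected retention time in minutes.
#' @param rt_tolerance Maximum tolerated apex drift in minutes (default 0.1).
#' @param window Half-width of the apex search window (minutes, >=
#'   \code{rt_tolerance}).
#' @param max_halfwidth Cap on integration bounds either side of the apex.
#' @return List of class \code{"peak_area"}: \code{area} (intensity-minutes),
#'   \code{apex_rt} (NA when absent), \code{found}, and \code{status} (one of
#'   "ok", "rt_drift", "not_found").
#' @export
integrate_peak <- function(trace, expected_rt, rt_tolerance = 0.1,
                           window = 0.5, max_halfwidth = 0.2) {
  stopifnot(inherits(trace, "data.frame"), nrow(trace) > 0,
            window >= rt_tolerance)
  res <- function(area, apex, found, status) {
    structure(list(area = area, apex_rt = apex, found = found,
                   status = status), class = "peak_area")
  }
  in_win <- abs(trace$time - expected_rt) <= window
  if (!any(in_win) || max(trace$intensity[in_win]) <= 0) {
    return(res(0, NA_real_, FALSE, "not_found"))
  }
  cand <- which(in_win)
  apex <- cand[which.max(trace$intensity[cand])]
  apex_rt <- trace$time[apex]
  if (abs(apex_rt - expected_rt) > rt_tolerance) {
    return(res(0, apex_rt, FALSE, "rt_drift"))
  }
  ## walk outward while the trace is non-increasing (descending through
  ## plateaus); stop at a rise (the valley before a neighbouring peak) or at
  ## the half-width cap
  lo <- apex
  while (lo > 1L &&
         trace$time[lo - 1L] >= apex_rt - max_halfwidth &&
         trace$intensity[lo - 1L] <= trace$intensity[lo]) {
    lo <- lo - 1L
  }
  hi <- apex
  n <- nrow(trace)
  while (hi < n &&
         trace$time[hi + 1L] <= apex_rt + max_halfwidth &&
         trace$intensity[hi + 1L] <= trace$intensity[hi]) {
    hi <- hi + 1L
  }
  res(.trapz(trace$time[lo:hi], trace$intensity[lo:hi]), apex_rt, TRUE, "ok")
}

#' Analyte / internal-standard area ratio
#'
#' @param analyte,standard \code{peak_area} objects for the same injection.
#' @return The dimensionless area ratio; 0 when the analyte was not found.
#'   A missing or zero-area internal standard is a sample-level quantitation
#'   failure and errors.
#' @export
area_ratio <- function(analyte, standard) {
  stopifnot(inherits(analyte, "peak_area"), inherits(standard, "peak_area"))
  if (!standard$found || standard$area <= 0) {
    stop("internal standard missing or empty in this sample; ",
         "analyte class cannot be quantified", call. = FALSE)
  }
  if (!analyte$found) return(0)
  analyte$area / standard$area
}

#' Blank correction of area ratios
#'
#' Values below \code{factor} times the blank level are indistinguishable from
#' carry-over/background and are censored to zero ("Not Found"). The blank
#' level is the mean of the blank-injection ratios by default (max available
#' as a conservative alternative).
#'
#' @param values Numeric vector of per-sample area ratios for one analyte.
#' @param blank_values Ratios of the same analyte in blank injections.
#' @param factor Censoring multiple of the blank level (default 3).
#' @param stat "mean" (default) or "max" of the blanks.
#' @return List with \code{values} (censored entries set to 0) and logical
#'   \code{censored}. With no blanks the rule is skipped with a warning.
#' @export
blank_correct <- function(values, blank_values, factor = 3,
                          stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(is.numeric(values), factor > 0)
  if (length(blank_values) == 0L || all(is.na(blank_values))) {
    warning("no blank samples: blank correction skipped", call. = FALSE)
    return(list(values = values, censored = rep(FALSE, length(values)),
                threshold = NA_real_))
  }
  level <- switch(stat, mean = mean(blank_values, na.rm = TRUE),
                  max = max(blank_values, na.rm = TRUE))
  threshold <- factor * level
  censored <- !is.na(values) & values < threshold
  values[censored] <- 0
  list(values = values, censored = censored, threshold = threshold)
}

#' Area ratio to concentration
#'
#' Single-point semi-quantitation: the area ratio times the spiked
#' internal-standard concentration gives the analyte concentration; tissue
#' results are further divided by the extracted tissue mass (amount per mg),
#' fluid results stay molar.
#'
#' @param ratio Area ratio(s).
#' @param is_concentration Internal-standard working concentration in uM
#'   (default 5, the spiked working solution).
#' @param tissue_mass Tissue amount in mg (tissue samples).
#' @param fluid_volume Fluid volume in uL (fluid samples). Exactly one of
#'   \code{tissue_mass}/\code{fluid_volume} must be given.
#' @return Numeric concentration(s) with a \code{"unit"} attribute
#'   ("uM/mg" for tissue, "uM" for fluids).
#' @export
to_concentration <- function(ratio, is_concentration = 5, tissue_mass = NULL,
                             fluid_volume = NULL) {
  stopifnot(is.numeric(ratio), all(ratio >= 0 | is.na(ratio)),
            is_concentration > 0)
  if (!is.null(tissue_mass) && !is.null(fluid_volume)) {
    stop("give either tissue_mass or fluid_volume, not both", call. = FALSE)
  }
  if (!is.null(tissue_mass)) {
    if (!is.numeric(tissue_mass) || any(tissue_mass <= 0)) {
      stop("tissue_mass must be positive (mg)", call. = FALSE)
    }
    return(structure(ratio * is_concentration / tissue_mass, unit = "uM/mg"))
  }
  if (!is.null(fluid_volume)) {
    if (!is.numeric(fluid_volume) || any(fluid_volume <= 0)) {
      stop("fluid_volume must be positive (uL)", call. = FALSE)
    }
    return(structure(ratio * is_concentration, unit = "uM"))
  }
  stop("sample needs a tissue_mass (mg) or fluid_volume (uL)", call. = FALSE)
}
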