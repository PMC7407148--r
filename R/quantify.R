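## Sample-set quantitation: run every EIC target through integration, apply
## the retention-time and blank rules, and convert to concentrations.

#' Quantify a set of injections against an EIC target list
#'
#' Runs the full semi-quantitation chain for each sample: per-target EIC
#' extraction and peak integration (with the retention-time drift exclusion),
#' analyte/internal-standard area ratios, 3x-blank censoring across the
#' sample set, and conversion to concentrations via the spiked
#' internal-standard amount and the tissue mass (or fluid volume).
#'
#' @param scans Named list of \code{scan_series}, one per sample in
#'   \code{samples$sample}.
#' @param targets An \code{mz_target_list} from [build_target_list()]
#'   containing the analytes and their internal standards.
#' @param samples Sample sheet: data.frame with columns \code{sample},
#'   \code{kind} ("sample", "blank" or "qc"), \code{group} (optional), and
#'   \code{tissue_mass} (mg) or \code{fluid_volume} (uL) for kind "sample".
#' @param analyte_is Named character vector mapping each analyte id in
#'   \code{targets} to its internal-standard id. Defaults to resolving
#'   analyte names as shorthand lipid names via [internal_standard_for()].
#' @param tol_ppm EIC extraction tolerance (ppm).
#' @param rt_tolerance Retention-time drift tolerance (minutes).
#' @param blank_factor Blank censoring multiple (default 3).
#' @param blank_stat Blank level statistic, "mean" or "max".
#' @param is_concentration Internal-standard working concentration (uM).
#' @return data.frame of class \code{"quant_result"}, one row per sample x
#'   analyte: \code{area}, \code{apex_rt}, \code{area_ratio},
#'   \code{concentration}, \code{censored}, \code{censor_rule}
#'   ("rt_drift", "blank", "nd" or ""), \code{unit}.
#' @export
quantify_samples <- function(scans, targets, samples, analyte_is = NULL,
                             tol_ppm = 10, rt_tolerance = 0.1,
                             blank_factor = 3, blank_stat = "mean",
                             is_concentration = 5) {
  stopifnot(inherits(targets, "mz_target_list"))
  need <- c("sample", "kind")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("empty sample sheet", call. = FALSE)
  absent <- setdiff(samples$sample, names(scans))
  if (length(absent)) {
    stop("no scan data for sample(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  analyte_ids <- unique(targets$id[targets$kind == "analyte"])
  standard_ids <- unique(targets$id[targets$kind == "standard"])
  if (length(analyte_ids) == 0L) stop("no analytes in target list",
                                      call. = FALSE)
  if (is.null(analyte_is)) {
    analyte_is <- stats::setNames(internal_standard_for(analyte_ids),
                                  analyte_ids)
  }
  miss_is <- setdiff(analyte_ids, names(analyte_is))
  if (length(miss_is)) {
    stop("no internal standard mapped for analyte(s): ",
         paste(miss_is, collapse = ", "), call. = FALSE)
  }
  miss_std <- setdiff(unique(analyte_is[analyte_ids]), standard_ids)
  if (length(miss_std)) {
    stop("mapped internal standard(s) not in target list: ",
         paste(miss_std, collapse = ", "), call. = FALSE)
  }

  ## integrate every target in every sample
  peaks <- list()
  for (s in samples$sample) {
    ss <- scans[[s]]
    for (id in c(standard_ids, analyte_ids)) {
      tg <- targets[targets$id == id, , drop = FALSE]
      trace <- extract_eic(ss, tg$mz, tg$polarity[1], tol_ppm = tol_ppm)
      peaks[[paste(s, id, sep = "\r")]] <-
        integrate_peak(trace, tg$expected_rt[1],
                       rt_tolerance = tg$rt_tolerance[1])
    }
  }
  pk <- function(s, id) peaks[[paste(s, id, sep = "\r")]]

  ## area ratios per sample x analyte
  grid <- expand.grid(sample = samples$sample, analyte = analyte_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$area <- NA_real_
  grid$apex_rt <- NA_real_
  grid$area_ratio <- NA_real_
  grid$censor_rule <- ""
  for (i in seq_len(nrow(grid))) {
    a <- pk(grid$sample[i], grid$analyte[i])
    std <- pk(grid$sample[i], analyte_is[[grid$analyte[i]]])
    grid$area[i] <- a$area
    grid$apex_rt[i] <- a$apex_rt
    if (!std$found || std$area <= 0) {
      grid$censor_rule[i] <- "is_missing"
      next
    }
    grid$area_ratio[i] <- area_ratio(a, std)
    if (!a$found) grid$censor_rule[i] <- a$status  # rt_drift or not_found
  }
  grid$censor_rule[grid$censor_rule == "not_found"] <- "nd"

  ## blank correction on area ratios, per analyte across the sample set
  blanks <- samples$sample[samples$kind == "blank"]
  if (length(blanks) == 0L) {
    warning("no blank samples: blank correction skipped", call. = FALSE)
  }
  for (id in analyte_ids) {
    rows <- which(grid$analyte == id & grid$sample %in%
                    samples$sample[samples$kind != "blank"])
    brow <- which(grid$analyte == id & grid$sample %in% blanks)
    if (length(brow) == 0L) next
    bc <- suppressWarnings(
      blank_correct(grid$area_ratio[rows], grid$area_ratio[brow],
                    factor = blank_factor, stat = blank_stat))
    newly <- bc$censored & grid$censor_rule[rows] == ""
    grid$area_ratio[rows] <- bc$values
    grid$censor_rule[rows][newly] <- "blank"
  }
  grid$censored <- grid$censor_rule != ""

  ## concentrations for study samples
  grid$concentration <- NA_real_
  grid$unit <- NA_character_
  for (i in seq_len(nrow(samples))) {
    if (samples$kind[i] != "sample") next
    rows <- which(grid$sample == samples$sample[i])
    tm <- if ("tissue_mass" %in% names(samples)) samples$tissue_mass[i] else NA
    fv <- if ("fluid_volume" %in% names(samples)) samples$fluid_volume[i] else NA
    conc <- if (!is.na(tm)) {
      to_concentration(grid$area_ratio[rows], is_concentration,
                       tissue_mass = tm)
    } else if (!is.na(fv)) {
      to_concentration(grid$area_ratio[rows], is_concentration,
                       fluid_volume = fv)
    } else {
      stop("sample '", samples$sample[i],
           "' has neither tissue_mass nor fluid_volume", call. = FALSE)
    }
    grid$concentration[rows] <- as.numeric(conc)
    grid$unit[rows] <- attr(conc, "unit")
  }
  grid$concentration[grid$censored] <- 0
  grid$concentration[grid$censor_rule == "is_missing"] <- NA_real_

  if ("group" %in% names(samples)) {
    grid$group <- samples$group[match(grid$sample, samples$sample)]
  }
  class(grid) <- c("quant_result", "data.frame")
  grid
}
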