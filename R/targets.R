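## EIC target lists: every ion (adduct x isotopologue) to be summed into one
## extracted ion chromatogram per analyte or internal standard.

#' Packaged internal-standard definitions
#'
#' Reads the internal-standard sheet: elemental formula, deuterium count,
#' measured adducts, primary ionisation mode and expected retention time,
#' together with the explicit list of ionisation products used on the
#' instrument and the designated primary (quantitation) ion.
#'
#' @param path CSV path; defaults to the packaged sheet.
#' @return data.frame with list-columns \code{adducts} and \code{products_mz}.
#' @export
internal_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "internal_standards.csv",
                        package = "lipidscreen", mustWork = TRUE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "formula", "n_deuterium", "adducts", "polarity",
            "expected_rt")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("standards sheet is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d$adducts <- strsplit(d$adducts, ";", fixed = TRUE)
  if ("products_mz" %in% names(d)) {
    d$products_mz <- lapply(strsplit(d$products_mz, ";", fixed = TRUE),
                            as.numeric)
  }
  d
}

#' Ionisation products computed from a standard's formula
#'
#' For one labelled standard, computes the m/z of every expected ion: each
#' listed adduct with a deuterium-loss isotopologue series. Heavily labelled
#' standards (>= 30 deuteriums) carry a visible label-count distribution and
#' get a three-ion series per adduct; lightly labelled standards a single ion.
#'
#' @param formula Elemental formula of the unlabelled molecule.
#' @param n_deuterium Deuterium substitutions of the label.
#' @param adducts Character vector of adduct labels.
#' @param depth Isotopologue series length per adduct; default by label count.
#' @return data.frame with columns \code{adduct}, \code{n_down}, \code{mz},
#'   \code{polarity}.
#' @examples
#' standard_products("C34H67NO3", 31,
#'                   c("[M+H]+", "[M+H-H2O]+", "[M+Na]+", "[M+K]+"))
#' @export
standard_products <- function(formula, n_deuterium, adducts,
                              depth = if (n_deuterium >= 30) 3L else 1L) {
  M <- monoisotopic_mass(formula, n_deuterium)
  out <- lapply(adducts, function(a) {
    mz <- isotopologue_series(adduct_mz(M, a), depth - 1L)
    data.frame(adduct = a, n_down = seq_along(mz) - 1L, mz = mz,
               polarity = adduct_polarity(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the EIC target list
#'
#' Combines internal standards and analytes into one table of EIC targets:
#' per id, all ionisation-product m/z values (adducts plus isotopologues for
#' labelled standards), polarity, expected retention time and retention-time
#' tolerance. Standards use their explicit packaged product lists when
#' present, otherwise products computed from the elemental formula; analyte
#' ions are supplied directly in the analytes sheet (the endogenous lipids'
#' formulas are not modelled).
#'
#' @param standards data.frame from [internal_standards()], or a CSV path.
#' @param analytes Optional analyte sheet: data.frame or CSV path with columns
#'   \code{name}, \code{mz_list} (semicolon-separated), \code{polarity},
#'   \code{expected_rt}.
#' @param rt_tolerance Allowed retention-time drift in minutes (default 0.1).
#' @param mz_range Instrument scan range; targets outside it are an error.
#' @return data.frame of class \code{"mz_target_list"}: one row per ion with
#'   columns \code{id}, \code{kind} (standard/analyte), \code{mz},
#'   \code{polarity}, \code{expected_rt}, \code{rt_tolerance}.
#' @export
build_target_list <- function(standards = internal_standards(),
                              analytes = NULL, rt_tolerance = 0.1,
                              mz_range = c(100, 1800)) {
  if (is.character(standards)) standards <- internal_standards(standards)
  rows <- list()
  for (i in seq_len(nrow(standards))) {
    mz <- if (!is.null(standards$products_mz) &&
              length(standards$products_mz[[i]]) > 0 &&
              !anyNA(standards$products_mz[[i]])) {
      standards$products_mz[[i]]
    } else {
      standard_products(standards$formula[i], standards$n_deuterium[i],
                        standards$adducts[[i]])$mz
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = standards$id[i], kind = "standard", mz = mz,
      polarity = standards$polarity[i], expected_rt = standards$expected_rt[i],
      stringsAsFactors = FALSE)
  }
  if (!is.null(analytes)) {
    if (is.character(analytes)) {
      analytes <- utils::read.csv(analytes, stringsAsFactors = FALSE)
    }
    need <- c("name", "mz_list", "polarity", "expected_rt")
    miss <- setdiff(need, names(analytes))
    if (length(miss)) {
      stop("analytes sheet is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(analytes))) {
      mz <- as.numeric(strsplit(as.character(analytes$mz_list[i]), ";",
                                fixed = TRUE)[[1]])
      if (length(mz) == 0L || anyNA(mz)) {
        stop("analyte '", analytes$name[i], "' has no usable m/z products",
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = analytes$name[i], kind = "analyte", mz = mz,
        polarity = analytes$polarity[i], expected_rt = analytes$expected_rt[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rt_tolerance <- rt_tolerance
  if (!all(out$polarity %in% c("pos", "neg"))) {
    stop("target polarity must be 'pos' or 'neg'", call. = FALSE)
  }
  bad <- out$mz < mz_range[1] | out$mz > mz_range[2]
  if (any(bad)) {
    stop("target m/z outside scan range [", mz_range[1], ", ", mz_range[2],
         "]: ", paste(unique(out$id[bad]), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("mz_target_list", "data.frame")
  out
}
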