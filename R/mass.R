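## Monoisotopic mass arithmetic for deuterium-labelled lipid standards.
## Atomic masses are pinned so that computed ion m/z values are bit-stable.

.atomic_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  D  = 2.0141017780,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.9637064864
)

## mass gained when one H position carries a deuterium
.delta_DH <- .atomic_masses[["D"]] - .atomic_masses[["H"]]

## charge-carrier deltas, proton-mass (electron-corrected) convention;
## singly charged ions only
.adduct_deltas <- c(
  "[M+H]+"      = 1.007276,
  "[M+H-H2O]+"  = 1.007276 - 18.010565,
  "[M+NH4]+"    = 18.033823,
  "[M+Na]+"     = 22.989218,
  "[M+K]+"      = 38.963158,
  "[M-H]-"      = -1.007276
)

.adduct_polarity <- c(
  "[M+H]+" = "pos", "[M+H-H2O]+" = "pos", "[M+NH4]+" = "pos",
  "[M+Na]+" = "pos", "[M+K]+" = "pos", "[M-H]-" = "neg"
)

#' Parse an elemental formula string
#'
#' Turns a Hill-style formula such as \code{"C42H82NO8P"} into a named count
#' vector. Only the elements commonly found in lipids (and their salt adducts)
#' are supported: C, H, D, N, O, P, S, Na, K.
#'
#' @param formula A single formula string. An empty string is the empty
#'   formula (mass zero).
#' @return Named integer vector of element counts.
#' @examples
#' parse_elemental_formula("C11H21NO4")
#' @export
parse_elemental_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(integer(0))
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!nzchar(paste(tokens, collapse = "")) ||
      nchar(paste(tokens, collapse = "")) != nchar(formula)) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  els <- gsub("[0-9]", "", tokens)
  ns <- vapply(tokens, function(t) {
    n <- gsub("[^0-9]", "", t)
    if (nzchar(n)) as.integer(n) else 1L
  }, integer(1))
  bad <- setdiff(els, names(.atomic_masses))
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(ns, factor(els, levels = unique(els)), sum)
  storage.mode(counts) <- "integer"
  counts[counts > 0]
}

#' Monoisotopic mass of a (possibly deuterated) formula
#'
#' Sum of pinned monoisotopic atomic masses, plus \code{n_deuterium} times the
#' D-H mass difference for stable-isotope-labelled standards. Deuterium counts
#' express H positions substituted by D and may not exceed the H count of the
#' unlabelled formula.
#'
#' @param formula Formula string (see [parse_elemental_formula()]) or a named
#'   count vector.
#' @param n_deuterium Number of H positions carrying deuterium.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C11H21NO4")                   # butyryl-carnitine
#' monoisotopic_mass("C11H21NO4", n_deuterium = 7)  # its d7 label
#' @export
monoisotopic_mass <- function(formula, n_deuterium = 0) {
  counts <- if (is.character(formula)) parse_elemental_formula(formula) else formula
  stopifnot(is.numeric(n_deuterium), length(n_deuterium) == 1L, n_deuterium >= 0)
  if (length(counts) == 0L) {
    if (n_deuterium > 0) stop("cannot deuterate an empty formula", call. = FALSE)
    return(0)
  }
  if (is.null(names(counts)) || any(!names(counts) %in% names(.atomic_masses))) {
    bad <- setdiff(names(counts), names(.atomic_masses))
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element counts", call. = FALSE)
  nH <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  if (n_deuterium > nH) {
    stop("n_deuterium (", n_deuterium, ") exceeds H count (", nH, ")",
         call. = FALSE)
  }
  sum(counts * .atomic_masses[names(counts)]) + n_deuterium * .delta_DH
}

#' Supported adduct labels
#'
#' @return Character vector of the ionisation products the package knows:
#'   protonated, protonated with water loss, ammoniated, sodiated, potasiated
#'   and deprotonated, all singly charged.
#' @export
adduct_labels <- function() names(.adduct_deltas)

#' m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (positive).
#' @param adduct Adduct label, one of [adduct_labels()]. Vectorised.
#' @return m/z in Da (singly charged).
#' @examples
#' adduct_mz(monoisotopic_mass("C11H21NO4", 7), "[M+H]+")  # 239.1983
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  bad <- setdiff(adduct, names(.adduct_deltas))
  if (length(bad)) {
    stop("unknown adduct label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  neutral_mass + unname(.adduct_deltas[adduct])
}

#' Polarity of an adduct
#'
#' @param adduct Adduct label(s).
#' @return "pos" or "neg" for each label.
#' @export
adduct_polarity <- function(adduct) {
  bad <- setdiff(adduct, names(.adduct_polarity))
  if (length(bad)) {
    stop("unknown adduct label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(.adduct_polarity[adduct])
}

#' Deuterium-loss isotopologue series
#'
#' Labelled standards are synthesised with a distribution of label counts: the
#' full-label ion is accompanied by ions with one, two, ... fewer deuteriums,
#' each lighter by the D-H mass difference (~1.006277 Da). This returns the
#' descending series starting at the full-label m/z.
#'
#' @param base_mz m/z of the full-label ion.
#' @param n_down How many label losses to include (0 = the base ion only).
#' @return Numeric vector \code{base_mz - (0:n_down) * (m_D - m_H)}.
#' @examples
#' isotopologue_series(422.5560, 2)
#' @export
isotopologue_series <- function(base_mz, n_down) {
  stopifnot(is.numeric(base_mz), length(base_mz) == 1L,
            is.numeric(n_down), length(n_down) == 1L, n_down >= 0)
  base_mz - (0:n_down) * .delta_DH
}
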