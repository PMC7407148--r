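## Shorthand lipid nomenclature: Class_(C:D) with optional -OH / -2COOH
## suffixes, a C-prefixed acyl-carbon count for acyl-carnitines, and the
## one-off plasmalogen dialect PC_C18(plas)-18:1.

.lipid_classes <- c("Carn", "Cer", "CL", "DG", "GM1", "Hex-Cer", "LPC", "LPE",
                    "LPI", "LPS", "Lyso_CL", "MG", "PA", "PC", "PE", "PG",
                    "PI", "PS", "S", "SM", "TG", "FA")

#' Lipid class abbreviations known to the parser
#' @return Character vector of class codes (Carn, Cer, CL, ... TG, FA).
#' @export
lipid_classes <- function() .lipid_classes

#' Parse shorthand lipid names
#'
#' Parses names of the form \code{Class_(C:D)} where C is the summed
#' fatty-acyl carbon count and D the number of double bonds, e.g.
#' \code{"Cer_(42:1)"}. Acyl-carnitines prefix the (acyl-chain only) carbon
#' count with a literal C and zero-pad it, e.g. \code{"Carn_(C03:0)"};
#' the carnitine backbone is not counted. Modifier suffixes \code{-OH}
#' (hydroxylated) and \code{-2COOH} (dicarboxylic) are captured, as is the
#' single plasmalogen dialect \code{PC_C18(plas)-18:1} (class PC, 36 carbons,
#' 1 double bond).
#'
#' @param name Character vector of shorthand names.
#' @return A data.frame of class \code{"lipid_species"} with one row per name:
#'   \code{class_code}, \code{total_carbons}, \code{double_bonds}, logical
#'   modifier columns \code{oh}, \code{dicarboxylic}, \code{plasmalogen}, and
#'   \code{raw_name}. Field widths of the carbon/double-bond tokens are kept
#'   so [format_lipid_name()] round-trips the original spelling.
#' @examples
#' parse_lipid_name(c("Cer_(42:1)", "Carn_(C03:0-2COOH)", "CL_(66:02)"))
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  out <- lapply(name, .parse_one_lipid)
  res <- do.call(rbind, out)
  class(res) <- c("lipid_species", "data.frame")
  res
}

.parse_one_lipid <- function(nm) {
  row <- function(cls, carb, db, oh = FALSE, dicarb = FALSE, plas = FALSE,
                  cw = 0L, dw = 0L) {
    data.frame(class_code = cls, total_carbons = as.integer(carb),
               double_bonds = as.integer(db), oh = oh, dicarboxylic = dicarb,
               plasmalogen = plas, raw_name = nm,
               carbons_width = as.integer(cw), db_width = as.integer(dw),
               stringsAsFactors = FALSE)
  }
  nm1 <- trimws(nm)
  ## plasmalogen dialect: PC_C18(plas)-18:1
  m <- regexec("^([A-Za-z-]+)_C([0-9]+)\\(plas\\)-([0-9]+):([0-9]+)$", nm1)
  g <- regmatches(nm1, m)[[1]]
  if (length(g) == 5L) {
    cls <- g[2]
    if (!cls %in% .lipid_classes) {
      stop("unknown lipid class '", cls, "' in '", nm, "'", call. = FALSE)
    }
    return(row(cls, as.integer(g[3]) + as.integer(g[4]), as.integer(g[5]),
               plas = TRUE))
  }
  ## general dialect: Class_(C:D[-OH|-2COOH]) with optional carnitine C prefix
  m <- regexec("^(.+)_\\((C?)([0-9]+):([0-9]+)(-OH|-2COOH)?\\)$", nm1)
  g <- regmatches(nm1, m)[[1]]
  if (length(g) == 0L) {
    stop("malformed lipid name: '", nm, "'", call. = FALSE)
  }
  cls <- g[2]
  if (!cls %in% .lipid_classes) {
    stop("unknown lipid class '", cls, "' in '", nm, "'", call. = FALSE)
  }
  has_prefix <- nzchar(g[3])
  if (has_prefix && cls != "Carn") {
    stop("C-prefixed carbon count is reserved for acyl-carnitines: '",
         nm, "'", call. = FALSE)
  }
  if (cls == "Carn" && !has_prefix) {
    stop("acyl-carnitine names carry a C-prefixed chain length: '",
         nm, "'", call. = FALSE)
  }
  mod <- g[6]
  row(cls, g[4], g[5],
      oh = identical(mod, "-OH"), dicarb = identical(mod, "-2COOH"),
      cw = nchar(g[4]), dw = nchar(g[5]))
}

#' Canonical shorthand spelling of parsed lipid species
#'
#' Inverse of [parse_lipid_name()]: zero padding of the carbon and double-bond
#' tokens is reproduced, so \code{format_lipid_name(parse_lipid_name(x))}
#' equals \code{x} for every name in the packaged liver-lipid table.
#'
#' @param x A \code{lipid_species} data.frame.
#' @return Character vector of canonical names.
#' @export
format_lipid_name <- function(x) {
  stopifnot(inherits(x, "lipid_species"))
  vapply(seq_len(nrow(x)), function(i) {
    if (x$plasmalogen[i]) {
      ## single-dialect form: ether carbon block fixed at 18 carbons
      return(sprintf("%s_C18(plas)-%d:%d", x$class_code[i],
                     x$total_carbons[i] - 18L, x$double_bonds[i]))
    }
    mod <- if (x$oh[i]) "-OH" else if (x$dicarboxylic[i]) "-2COOH" else ""
    carb <- formatC(x$total_carbons[i], width = max(1L, x$carbons_width[i]),
                    flag = "0")
    db <- formatC(x$double_bonds[i], width = max(1L, x$db_width[i]), flag = "0")
    pre <- if (x$class_code[i] == "Carn") "C" else ""
    sprintf("%s_(%s%s:%s%s)", x$class_code[i], pre, carb, db, mod)
  }, character(1))
}

#' Odd- or even-chain classification
#'
#' A lipid is classed as odd-chain when its summed fatty-acyl carbon count is
#' odd: an odd total implies at least one odd-chain fatty acyl, the standard
#' proxy when only summed compositions are known.
#'
#' @param x A \code{lipid_species} data.frame, or an integer vector of total
#'   carbon counts.
#' @return Character vector, "odd" or "even" per species.
#' @examples
#' chain_parity(parse_lipid_name(c("Cer_(33:1)", "TG_(52:3)")))
#' @export
chain_parity <- function(x) {
  carbons <- if (inherits(x, "lipid_species")) x$total_carbons else x
  stopifnot(is.numeric(carbons), all(carbons >= 0))
  ifelse(carbons %% 2 == 1, "odd", "even")
}

#' Analyte-class to internal-standard mapping
#'
#' Loads the packaged table of lipid classes, their measured adducts,
#' ionisation mode and assigned internal standard (one row per class;
#' acyl-carnitines list two standards, resolved by chain length in
#' [internal_standard_for()]).
#'
#' @param path CSV path; defaults to the packaged mapping.
#' @return data.frame of class \code{"class_is_map"}.
#' @export
class_is_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_internal_standards.csv",
                        package = "lipidscreen", mustWork = TRUE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_code", "adducts", "ionisation_mode", "internal_standard")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("class map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(m) <- c("class_is_map", "data.frame")
  m
}

#' Internal standard assigned to a lipid species
#'
#' Resolves each species' class to its semi-quantitation internal standard.
#' Acyl-carnitines are split by acyl chain length: chains of
#' \code{carnitine_cutoff} carbons or fewer use the short-chain d7 butyryl
#' standard, longer chains the d3 palmitoyl standard (polarity match between
#' analyte and standard hydrophobicity).
#'
#' @param species A \code{lipid_species} data.frame (or character names,
#'   parsed on the fly).
#' @param map A \code{class_is_map}; defaults to the packaged mapping.
#' @param carnitine_cutoff Acyl-carbon cutoff separating the two carnitine
#'   standards (default 8).
#' @return Character vector of internal-standard ids.
#' @examples
#' internal_standard_for(parse_lipid_name(c("Cer_(42:1)", "Carn_(C04:0)")))
#' @export
internal_standard_for <- function(species, map = class_is_map(),
                                  carnitine_cutoff = 8) {
  if (is.character(species)) species <- parse_lipid_name(species)
  stopifnot(inherits(species, "lipid_species"))
  idx <- match(species$class_code, map$class_code)
  if (anyNA(idx)) {
    stop("no internal standard configured for class(es): ",
         paste(unique(species$class_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- character(nrow(species))
  for (i in seq_len(nrow(species))) {
    ids <- strsplit(map$internal_standard[idx[i]], ";", fixed = TRUE)[[1]]
    out[i] <- if (length(ids) == 1L) {
      ids
    } else if (species$total_carbons[i] <= carnitine_cutoff) {
      ids[1]
    } else {
      ids[2]
    }
  }
  out
}
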