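## Relative compositions (Mol%) and the closure artifact: real changes in one
## part of a closed composition induce spurious opposite trends in the others.

#' Relative composition (Mol%)
#'
#' Closes each sample row to 100: entry = 100 * value / row total. Expressing
#' lipid data this way normalises to the sample's total fat but interconnects
#' the components, which is what produces the closure artifact.
#'
#' @param concentrations Numeric matrix or data.frame, samples in rows,
#'   lipids in columns, non-negative.
#' @return Matrix of the same shape whose rows each sum to 100.
#' @examples
#' mol_percent(rbind(a = c(2, 2), b = c(1, 3)))
#' @export
mol_percent <- function(concentrations) {
  m <- as.matrix(concentrations)
  if (any(m < 0, na.rm = TRUE)) stop("negative concentrations", call. = FALSE)
  totals <- rowSums(m, na.rm = TRUE)
  zero <- which(totals <= 0)
  if (length(zero)) {
    nm <- rownames(m)[zero]
    if (is.null(nm)) nm <- zero
    stop("all-zero sample row(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  100 * sweep(m, 1, totals, "/")
}

#' Odd/even chain totals per sample
#'
#' @param concentrations Samples x lipids matrix (columns named by lipid, or
#'   supply \code{parity}).
#' @param parity Optional "odd"/"even" per column; by default derived from the
#'   column names via [parse_lipid_name()] and [chain_parity()].
#' @return data.frame with \code{sample}, \code{total_odd}, \code{total_even},
#'   \code{total_all} (NA values treated as absent, i.e. 0).
#' @export
aggregate_parity <- function(concentrations, parity = NULL) {
  m <- as.matrix(concentrations)
  if (is.null(parity)) {
    if (is.null(colnames(m))) {
      stop("need lipid column names or an explicit parity vector",
           call. = FALSE)
    }
    parity <- chain_parity(parse_lipid_name(colnames(m)))
  }
  stopifnot(length(parity) == ncol(m), all(parity %in% c("odd", "even")))
  odd <- rowSums(m[, parity == "odd", drop = FALSE], na.rm = TRUE)
  even <- rowSums(m[, parity == "even", drop = FALSE], na.rm = TRUE)
  data.frame(sample = if (is.null(rownames(m))) seq_len(nrow(m)) else
               rownames(m),
             total_odd = odd, total_even = even, total_all = odd + even,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Absolute vs. Mol% dose trends of the parity totals
#'
#' Fits the dose trend of the odd-chain, even-chain and combined totals in
#' absolute concentration space, and of the odd/even shares in Mol% space
#' (two-part closure over odd + even, computed per sample and then averaged
#' per group). Because the two Mol% parts sum to 100 in every sample, their
#' fitted slopes are exactly equal and opposite with identical R-squared and
#' p: an apparent Mol% rise in one part can be entirely an artifact of a real
#' fall in the other.
#'
#' @param totals Per-sample parity totals: data.frame with columns
#'   \code{total_odd}, \code{total_even} and a \code{dose} per sample (e.g.
#'   [aggregate_parity()] output joined to the sample sheet).
#' @return Object of class \code{"artifact_report"}: group-level series and
#'   \code{trend_fit}s for absolute odd/even/all and Mol% odd/even.
#' @export
artifact_report <- function(totals) {
  need <- c("dose", "total_odd", "total_even")
  miss <- setdiff(need, names(totals))
  if (length(miss)) {
    stop("totals need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  doses <- sort(unique(totals$dose))
  if (length(doses) < 3L) stop("need >= 3 dose groups", call. = FALSE)
  two_part <- totals$total_odd + totals$total_even
  if (any(two_part <= 0)) stop("sample with zero total lipid", call. = FALSE)
  molpct_odd <- 100 * totals$total_odd / two_part
  gmean <- function(v) {
    vapply(doses, function(d) mean(v[totals$dose == d]), numeric(1))
  }
  series <- data.frame(
    dose = doses,
    abs_odd = gmean(totals$total_odd),
    abs_even = gmean(totals$total_even),
    abs_all = gmean(totals$total_odd + totals$total_even),
    molpct_odd = gmean(molpct_odd),
    molpct_even = gmean(100 - molpct_odd)
  )
  fits <- list(
    absolute = list(odd = fit_trend(doses, series$abs_odd),
                    even = fit_trend(doses, series$abs_even),
                    all = fit_trend(doses, series$abs_all)),
    molpct = list(odd = fit_trend(doses, series$molpct_odd),
                  even = fit_trend(doses, series$molpct_even))
  )
  structure(list(series = series, fits = fits, doses = doses),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  line <- function(name, f) {
    cat(sprintf("  %-12s slope %9.4g +/- %.4g   R^2 %.3f   p %.4g\n",
                name, f$slope, f$slope_se, f$r2, f$p_value))
  }
  cat("Absolute concentration trends:\n")
  line("odd", x$fits$absolute$odd)
  line("even", x$fits$absolute$even)
  line("odd + even", x$fits$absolute$all)
  cat("Mol% trends (two-part closure):\n")
  line("odd", x$fits$molpct$odd)
  line("even", x$fits$molpct$even)
  invisible(x)
}
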