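# Independent oracles used across tests.

# two-sided Student-t tail by numerical integration of the density
# (independent of the distribution-function route used by the package)
t_tail_oracle <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-10)$value
}

# half a unit in the last printed digit of a numeric string
# ("2.6" -> 0.05; "97500" -> 50; "581" -> 0.5)
printed_ulp <- function(s) {
  s <- sub("^-", "", s)
  if (grepl(".", s, fixed = TRUE)) {
    10^(-nchar(sub("^[^.]*\\.", "", s))) / 2
  } else {
    10^attr(regexpr("0*$", s), "match.length") / 2
  }
}

# closed-form area of a Gaussian elution profile
gaussian_area <- function(height, sigma) height * sigma * sqrt(2 * pi)

study_doses <- c(3.6, 6.3, 9.0, 11.7)
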