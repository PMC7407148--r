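## Dose-response trend fitting and the three-criterion biomarker screen:
## per lipid, ordinary least squares of the four diet-group mean
## concentrations on the dietary beef-tallow percentage, slope significance by
## a two-sided t test (df = n_groups - 2), and a strict monotonicity check.

#' Per-group summary statistics
#'
#' @param values Numeric vector of per-animal values.
#' @param groups Group label per value.
#' @param doses Named numeric vector mapping group label to dose.
#' @return data.frame with \code{group}, \code{dose}, \code{mean}, \code{sd}
#'   (n-1 denominator; 0 with a warning for singleton groups) and \code{n}.
#'   Missing values (ND) are dropped from the statistics.
#' @export
group_stats <- function(values, groups, doses) {
  stopifnot(length(values) == length(groups))
  gl <- names(doses)
  if (is.null(gl)) {
    gl <- sort(unique(groups))
    names(doses) <- gl
  }
  out <- lapply(gl, function(g) {
    v <- values[groups == g]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(data.frame(group = g, dose = doses[[g]], mean = NA_real_,
                        sd = NA_real_, n = 0L, stringsAsFactors = FALSE))
    }
    s <- if (length(v) == 1L) {
      warning("group '", g, "' has a single observation; sd set to 0",
              call. = FALSE)
      0
    } else {
      stats::sd(v)
    }
    data.frame(group = g, dose = doses[[g]], mean = mean(v), sd = s,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit a linear dose trend to group means
#'
#' Ordinary least squares of mean concentration on dose. The slope standard
#' error comes from the residual variance at \code{df = n - 2}; significance
#' is the two-sided t tail of slope/SE. With all means equal the degenerate
#' convention slope 0, R-squared 0, p 1 applies.
#'
#' @param doses Numeric dose per group (not all equal).
#' @param means Group mean concentrations; NA pairs are dropped.
#' @return Object of class \code{"trend_fit"}: \code{slope},
#'   \code{intercept}, \code{slope_se}, \code{r2}, \code{t_stat},
#'   \code{p_value}, \code{df}, \code{n}.
#' @examples
#' fit_trend(c(3.6, 6.3, 9.0, 11.7), c(2.29, 1.68, 1.48, 1.27))
#' @export
fit_trend <- function(doses, means) {
  stopifnot(length(doses) == length(means))
  keep <- !is.na(doses) & !is.na(means)
  x <- doses[keep]
  y <- means[keep]
  if (length(x) < 3L) {
    stop("need at least 3 dose groups to fit a trend", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("doses are all equal", call. = FALSE)
  n <- length(x)
  if (stats::var(y) == 0) {
    fit <- structure(list(slope = 0, intercept = y[1], slope_se = NA_real_,
                          r2 = 0, t_stat = 0, p_value = 1,
                          df = n - 2L, n = n), class = "trend_fit")
    return(fit)
  }
  m <- stats::lm(y ~ x)
  ## 3-point fits can be exactly collinear (zero residual); the t statistic is
  ## then infinite and summary.lm warns about the perfect fit
  sm <- suppressWarnings(summary(m))
  structure(list(slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r2 = sm$r.squared,
                 t_stat = sm$coefficients[2, 3],
                 p_value = sm$coefficients[2, 4],
                 df = m$df.residual, n = n),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("linear trend: y = %.4gx %s %.4g\n", x$slope,
              ifelse(x$intercept < 0, "-", "+"), abs(x$intercept)))
  cat(sprintf("  slope SE %.4g, R^2 %.3f, t(%d) = %.3f, p = %.4g\n",
              x$slope_se, x$r2, x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' Two-sided slope significance
#'
#' Tail probability of Student's t at |slope/SE| with the given residual
#' degrees of freedom (2 when four group means are fitted).
#'
#' @param slope,slope_se Slope estimate and its standard error (> 0).
#' @param df Residual degrees of freedom (>= 1).
#' @return Two-sided p-value.
#' @examples
#' slope_p_value(-41.0, 5.71, 2)  # 0.0189
#' @export
slope_p_value <- function(slope, slope_se, df) {
  stopifnot(slope_se > 0, df >= 1)
  2 * stats::pt(-abs(slope / slope_se), df)
}

#' Successive change across ordered groups
#'
#' Strict monotonicity of the supplied means: "increasing" when every
#' consecutive pair rises, "decreasing" when every pair falls, otherwise
#' "none". Ties break monotonicity; a missing mean makes its comparisons
#' undefined, hence "none".
#'
#' @param means Numeric vector (length >= 2) in group order.
#' @return "increasing", "decreasing" or "none".
#' @export
successive_change <- function(means) {
  stopifnot(length(means) >= 2L)
  if (anyNA(means)) return("none")
  d <- diff(means)
  if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "none"
}

#' Three-criterion biomarker call
#'
#' A lipid is called a dose-response biomarker when its trend slope is
#' significant (p below \code{alpha}), the fit is strong (R-squared strictly
#' above \code{r2_min}) and the group means change successively in one
#' direction.
#'
#' @param fit A \code{trend_fit}.
#' @param change Output of [successive_change()] for the same lipid.
#' @param r2_min R-squared threshold (strict; default 0.75).
#' @param alpha Slope significance level (default 0.05).
#' @return List of class \code{"biomarker_call"}: \code{direction},
#'   \code{passes} and \code{reasons} (the criteria that failed).
#' @export
flag_biomarker <- function(fit, change, r2_min = 0.75, alpha = 0.05) {
  stopifnot(inherits(fit, "trend_fit"),
            change %in% c("increasing", "decreasing", "none"))
  reasons <- character(0)
  if (!(fit$p_value < alpha)) reasons <- c(reasons, "slope_not_significant")
  if (!(fit$r2 > r2_min)) reasons <- c(reasons, "r2_below_threshold")
  if (change == "none") reasons <- c(reasons, "not_successive")
  structure(list(direction = change, passes = length(reasons) == 0L,
                 reasons = reasons), class = "biomarker_call")
}

#' Dose-response biomarker screen
#'
#' The package's central fit: for every lipid, ordinary least squares of the
#' group mean concentrations on dose, slope significance at
#' \code{df = n_groups - 2}, strict successive-change classification over the
#' complete group sequence, and the three-criterion biomarker call
#' (p < alpha, R-squared > r2_min, successive change).
#'
#' @param data Long-format data.frame. Either per-group means (columns
#'   \code{lipid}, \code{dose}, \code{mean}, optional \code{sd}, \code{n}) or
#'   per-sample values (columns \code{lipid}, \code{dose}, \code{value}),
#'   which are first aggregated to group means.
#' @param r2_min,alpha Screen thresholds (defaults 0.75 and 0.05).
#' @return Object of class \code{"lipid_screen"} with a per-lipid results
#'   table (slope, intercept, slope SE, R-squared, t, p, direction, flagged),
#'   the dose levels, thresholds and summary counts. Lipids observed in fewer
#'   than 3 dose groups are excluded from fitting and listed in
#'   \code{$excluded}.
#' @examples
#' scr <- lipid_screen(liver_lipid_table_long())
#' summary(scr)
#' @export
lipid_screen <- function(data, r2_min = 0.75, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!all(c("lipid", "dose") %in% names(data))) {
    stop("data needs 'lipid' and 'dose' columns", call. = FALSE)
  }
  if ("value" %in% names(data) && !"mean" %in% names(data)) {
    agg <- stats::aggregate(value ~ lipid + dose, data = data, FUN = mean,
                            na.action = stats::na.omit)
    names(agg)[names(agg) == "value"] <- "mean"
    data <- agg
  }
  if (!"mean" %in% names(data)) {
    stop("data needs a 'mean' or 'value' column", call. = FALSE)
  }
  doses <- sort(unique(data$dose))
  if (length(doses) < 3L) {
    stop("need at least 3 dose groups to screen", call. = FALSE)
  }
  lipids <- unique(data$lipid)
  rows <- vector("list", length(lipids))
  excluded <- character(0)
  for (i in seq_along(lipids)) {
    sub <- data[data$lipid == lipids[i], , drop = FALSE]
    means <- sub$mean[match(doses, sub$dose)]
    n_obs <- sum(!is.na(means))
    if (n_obs < 3L) {
      excluded <- c(excluded, lipids[i])
      next
    }
    fit <- fit_trend(doses, means)
    change <- successive_change(means)
    call <- flag_biomarker(fit, change, r2_min = r2_min, alpha = alpha)
    rows[[i]] <- data.frame(
      lipid = lipids[i], n_groups = n_obs, slope = fit$slope,
      intercept = fit$intercept, slope_se = fit$slope_se, r2 = fit$r2,
      t_stat = fit$t_stat, p_value = fit$p_value, direction = change,
      flagged = call$passes, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  structure(list(
    table = tab, excluded = excluded, doses = doses,
    r2_min = r2_min, alpha = alpha,
    n_tested = nrow(tab),
    n_flagged = sum(tab$flagged),
    n_increasing = sum(tab$flagged & tab$direction == "increasing"),
    n_decreasing = sum(tab$flagged & tab$direction == "decreasing"),
    data = data
  ), class = "lipid_screen")
}

#' @export
print.lipid_screen <- function(x, ...) {
  cat("Dose-response lipid biomarker screen\n")
  cat(sprintf("  doses: %s\n", paste(x$doses, collapse = ", ")))
  cat(sprintf("  thresholds: p < %g, R^2 > %g, successive change\n",
              x$alpha, x$r2_min))
  cat(sprintf("  %d lipids tested (%d excluded, < 3 groups observed)\n",
              x$n_tested, length(x$excluded)))
  cat(sprintf("  %d flagged: %d increasing, %d decreasing\n",
              x$n_flagged, x$n_increasing, x$n_decreasing))
  invisible(x)
}

#' @export
summary.lipid_screen <- function(object, ...) {
  structure(list(
    counts = c(n_tested = object$n_tested, n_flagged = object$n_flagged,
               n_increasing = object$n_increasing,
               n_decreasing = object$n_decreasing,
               n_excluded = length(object$excluded)),
    flagged = object$table[object$table$flagged, , drop = FALSE],
    thresholds = c(r2_min = object$r2_min, alpha = object$alpha)
  ), class = "summary.lipid_screen")
}

#' @export
print.summary.lipid_screen <- function(x, ...) {
  cat("Screen summary\n")
  print(x$counts)
  cat("\nFlagged lipids (head):\n")
  print(utils::head(x$flagged[, c("lipid", "slope", "r2", "p_value",
                                  "direction")], 10))
  invisible(x)
}

#' @export
coef.lipid_screen <- function(object, ...) {
  m <- as.matrix(object$table[, c("intercept", "slope")])
  rownames(m) <- object$table$lipid
  m
}

#' @export
predict.lipid_screen <- function(object, newdata = NULL, ...) {
  doses <- if (is.null(newdata)) object$doses else newdata
  cf <- coef(object)
  out <- cf[, "intercept"] + outer(cf[, "slope"], doses)
  colnames(out) <- doses
  out
}

#' @export
residuals.lipid_screen <- function(object, ...) {
  fitted <- predict(object)
  obs <- matrix(NA_real_, nrow(fitted), length(object$doses),
                dimnames = dimnames(fitted))
  for (i in seq_len(nrow(object$data))) {
    l <- object$data$lipid[i]
    if (!l %in% rownames(obs)) next
    obs[l, as.character(object$data$dose[i])] <- object$data$mean[i]
  }
  obs - fitted
}

#' @export
plot.lipid_screen <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$r2, -log10(pmax(tab$p_value, 1e-12)),
                 pch = ifelse(tab$flagged, 19, 1),
                 col = ifelse(tab$flagged,
                              ifelse(tab$direction == "increasing",
                                     "firebrick", "navy"), "grey50"),
                 xlab = expression(R^2),
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(v = x$r2_min, h = -log10(x$alpha), lty = 3)
  invisible(x)
}

#' Two-group comparison statistics
#'
#' Percent difference of means, per-group coefficients of variation, Welch's
#' two-sided t test and the conventional significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param values_a,values_b Numeric vectors (n >= 2 each).
#' @return List: \code{percent_difference} (of mean_a relative to mean_b),
#'   \code{cv_a}, \code{cv_b} (percent), \code{p_value}, \code{stars}.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  ma <- mean(values_a)
  mb <- mean(values_b)
  pd <- if (mb == 0) {
    warning("zero reference mean: percent difference undefined",
            call. = FALSE)
    NA_real_
  } else {
    100 * (ma - mb) / mb
  }
  p <- if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (ma == mb) 1 else 0
  } else {
    stats::t.test(values_a, values_b)$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(percent_difference = pd,
       cv_a = 100 * stats::sd(values_a) / ma,
       cv_b = 100 * stats::sd(values_b) / mb,
       p_value = p, stars = stars)
}
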