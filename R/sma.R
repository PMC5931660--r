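#' Standardized major axis line fit
#'
#' Fits the SMA (reduced major axis) line to a bivariate trait
#' relationship: \code{slope = sign(cor(x, y)) * sd(y)/sd(x)} and
#' \code{intercept = mean(y) - slope * mean(x)}, computed on the analysis
#' scale. With \code{log10 = TRUE} (the convention for allometric trait
#' scaling) both axes are log10-transformed first. The slope confidence
#' interval uses the standard F-based formula
#' \code{slope * (sqrt(B + 1) +/- sqrt(B))} with
#' \code{B = F(1-alpha; 1, n-2) (1 - r^2)/(n - 2)}, and the correlation
#' p-value comes from the usual t test.
#'
#' Note the SMA pathology: for uncorrelated data with equal SDs the
#' estimator returns |slope| near 1 regardless of the absence of any
#' relationship — which is why group comparisons are gated behind
#' [sma_prefilter()].
#'
#' @param x,y numeric vectors (strictly positive when \code{log10}).
#' @param log10 log10-transform both axes before fitting (default FALSE;
#'   group comparison routines set it).
#' @param alpha level for the slope confidence interval.
#' @return Object of class \code{"sma_fit"}: list with \code{n},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{slope_ci}, \code{log10}, and first/second moments of the
#'   analysis-scale data.
#' @export
#' @examples
#' f <- sma_fit(1:10, 2 * (1:10))
#' c(f$slope, f$r_squared)
sma_fit <- function(x, y, log10 = FALSE, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("SMA fit needs at least 3 complete observations", call. = FALSE)
  if (log10) {
    if (any(x <= 0) || any(y <= 0))
      stop("log10 scale requires strictly positive values", call. = FALSE)
    x <- log10(x); y <- log10(y)
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx < 1e-12 || sy < 1e-12)
    stop("degenerate SMA fit: zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- sign(r + (r == 0)) * sy / sx  # sign(0) treated as +
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  pval <- 2 * stats::pt(-abs(tstat), n - 2)
  structure(list(n = n, slope = slope, intercept = intercept,
                 r_squared = r^2, p_value = pval,
                 slope_ci = sort(ci), log10 = log10,
                 mean_x = mean(x), mean_y = mean(y),
                 var_x = sx^2, var_y = sy^2, cov_xy = stats::cov(x, y)),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf(
    "SMA fit (n = %d%s): slope %.4g [%.4g, %.4g], intercept %.4g, R2 = %.3f (p = %.3g)\n",
    x$n, if (x$log10) ", log10 axes" else "", x$slope, x$slope_ci[1],
    x$slope_ci[2], x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Correlation prefilter for SMA comparisons
#'
#' SMA lines are only fitted and compared for relationships showing at
#' least moderate correlation: R-squared strictly greater than 0.1 and
#' correlation-test p strictly below 0.1. Boundary values fail.
#'
#' @param x,y numeric vectors (log10-transformed first when
#'   \code{log10 = TRUE}).
#' @param log10 apply log10 before testing.
#' @return logical.
#' @export
sma_prefilter <- function(x, y, log10 = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(FALSE)
  if (log10) {
    if (any(x <= 0) || any(y <= 0)) return(FALSE)
    x <- log10(x); y <- log10(y)
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(FALSE)
  ct <- stats::cor.test(x, y)
  unname(ct$estimate^2 > 0.1 & ct$p.value < 0.1)
}

# Profile log-likelihood criterion for the common SMA slope: at slope b,
# the correlation between residual scores (y - b x) and axis scores
# (y + b x) within each group measures departure; the common slope
# minimises -sum n_i log(1 - r_i(b)^2), which is also the LR statistic
# against group-specific slopes (each group's own SMA slope zeroes its
# residual-axis correlation).
sma_resid_axis_r2 <- function(stats_i, b) {
  # corr(y - b x, y + b x) from second moments
  num <- stats_i$var_y - b^2 * stats_i$var_x
  den <- sqrt((stats_i$var_y - 2 * b * stats_i$cov_xy + b^2 * stats_i$var_x) *
                (stats_i$var_y + 2 * b * stats_i$cov_xy + b^2 * stats_i$var_x))
  (num / den)^2
}

sma_common_slope_objective <- function(fits, b) {
  sum(vapply(fits, function(f)
    f$n * log(pmax(1 - sma_resid_axis_r2(f, b), 1e-12)), numeric(1)))
}

# Iteratively locate the common slope: golden-section search on log|b|
# within a bracket spanning the group slopes.
sma_common_slope <- function(fits, tol = 1e-10, maxiter = 100) {
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  sgn <- sign(mean(sign(slopes)) + 0.5)  # dominant sign, + on tie
  lo <- min(abs(slopes)) / 10
  hi <- max(abs(slopes)) * 10
  opt <- stats::optimize(function(lb)
    -sma_common_slope_objective(fits, sgn * exp(lb)),
    lower = log(lo), upper = log(hi), tol = tol)
  sgn * exp(opt$minimum)
}

#' Multi-group SMA comparison: common slope, elevation and shift tests
#'
#' Implements the hierarchical SMA testing routine for two or more
#' groups on a (log10-scaled) trait pair:
#' \enumerate{
#'   \item Groups failing the correlation prefilter (R2 > 0.1, p < 0.1)
#'     are dropped with a note; comparisons never run on them.
#'   \item Common-slope test: likelihood ratio based on the
#'     residual-versus-axis correlation at the iterated common-slope
#'     estimate, referred to chi-squared with (groups - 1) df.
#'   \item Only if a common slope is not rejected (at \code{alpha}):
#'     elevation test (Wald test on group mean residuals \code{y - b x}
#'     at the common slope, accounting for slope uncertainty) and
#'     shift-along-axis test (Wald test on group mean axis scores
#'     \code{y + b x}). Otherwise both are reported \code{NA}.
#' }
#'
#' @param data data.frame containing the variables and a group column.
#' @param x_name,y_name column names of the trait pair.
#' @param group_name column name of the grouping factor (e.g. leaf
#'   habit).
#' @param log10 log10-transform both axes (default TRUE, the trait
#'   scaling convention).
#' @param alpha gatekeeping significance level (default 0.05).
#' @return Object of class \code{"sma_comparison"}: list with
#'   \code{fits} (per-group [sma_fit()]s), \code{excluded} (groups
#'   failing the prefilter), \code{common_slope}, \code{common_slope_stat},
#'   \code{common_slope_df}, \code{common_slope_p},
#'   \code{slopes_common} (logical), \code{elevation_stat},
#'   \code{elevation_p}, \code{shift_stat}, \code{shift_p},
#'   \code{prefilter_passed}, and the test metadata.
#' @export
sma_compare_groups <- function(data, x_name, y_name, group_name,
                               log10 = TRUE, alpha = 0.05) {
  assert_columns(data, c(x_name, y_name, group_name), "SMA data")
  groups <- split(data, data[[group_name]], drop = TRUE)
  passed <- vapply(groups, function(d)
    sma_prefilter(d[[x_name]], d[[y_name]], log10 = log10), logical(1))
  excluded <- names(groups)[!passed]
  groups <- groups[passed]

  out <- list(x_name = x_name, y_name = y_name, group_name = group_name,
              log10 = log10, alpha = alpha, excluded = excluded,
              prefilter_passed = length(groups) >= 2)
  if (!out$prefilter_passed) {
    out <- c(out, list(fits = NULL, common_slope = NA_real_,
                       common_slope_stat = NA_real_, common_slope_df = NA,
                       common_slope_p = NA_real_, slopes_common = NA,
                       elevation_stat = NA_real_, elevation_p = NA_real_,
                       shift_stat = NA_real_, shift_p = NA_real_))
    class(out) <- "sma_comparison"
    return(out)
  }

  fits <- lapply(groups, function(d)
    sma_fit(d[[x_name]], d[[y_name]], log10 = log10))
  b_hat <- sma_common_slope(fits)
  lr <- -sma_common_slope_objective(fits, b_hat)
  df <- length(fits) - 1L
  p_slope <- stats::pchisq(lr, df, lower.tail = FALSE)
  slopes_common <- p_slope >= alpha

  elev <- shift <- list(stat = NA_real_, p = NA_real_)
  if (slopes_common) {
    # Curvature of the profile criterion gives the common-slope variance.
    h <- 1e-4 * abs(b_hat)
    f0 <- -sma_common_slope_objective(fits, b_hat)
    fp <- -sma_common_slope_objective(fits, b_hat + h)
    fm <- -sma_common_slope_objective(fits, b_hat - h)
    curv <- (fp + fm - 2 * f0) / h^2
    var_b <- if (is.finite(curv) && curv > 0) 2 / curv else 0
    score_stats <- function(sgn_x) {
      # group means/variances of y + sgn_x * b x from the stored moments
      m <- vapply(fits, function(f) f$mean_y + sgn_x * b_hat * f$mean_x,
                  numeric(1))
      v <- vapply(fits, function(f)
        (f$var_y + 2 * sgn_x * b_hat * f$cov_xy + b_hat^2 * f$var_x) / f$n +
          (sgn_x * f$mean_x)^2 * var_b, numeric(1))
      w <- 1 / v
      grand <- sum(w * m) / sum(w)
      list(stat = sum(w * (m - grand)^2),
           p = stats::pchisq(sum(w * (m - grand)^2), df, lower.tail = FALSE))
    }
    elev <- score_stats(-1)   # residual scores y - b x
    shift <- score_stats(+1)  # axis scores y + b x
  }

  out <- c(out, list(fits = fits, common_slope = b_hat,
                     common_slope_stat = lr, common_slope_df = df,
                     common_slope_p = p_slope, slopes_common = slopes_common,
                     elevation_stat = elev$stat, elevation_p = elev$p,
                     shift_stat = shift$stat, shift_p = shift$p))
  class(out) <- "sma_comparison"
  out
}

#' @export
print.sma_comparison <- function(x, ...) {
  cat(sprintf("SMA comparison: %s ~ %s by %s%s\n", x$y_name, x$x_name,
              x$group_name, if (x$log10) " (log10 axes)" else ""))
  if (length(x$excluded))
    cat("  excluded by prefilter:", paste(x$excluded, collapse = ", "), "\n")
  if (!x$prefilter_passed) {
    cat("  fewer than 2 groups pass the R2/p prefilter: no comparison\n")
    return(invisible(x))
  }
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat(sprintf("  %-12s n = %3d  slope %.3f  R2 = %.2f (p = %.3g)\n",
                g, f$n, f$slope, f$r_squared, f$p_value))
  }
  cat(sprintf("  common-slope test: LR = %.3f, df = %d, p = %.4g -> %s\n",
              x$common_slope_stat, x$common_slope_df, x$common_slope_p,
              if (x$slopes_common) "common slope retained" else "slopes differ"))
  if (x$slopes_common) {
    cat(sprintf("  common slope %.3f; elevation p = %.4g; shift p = %.4g\n",
                x$common_slope, x$elevation_p, x$shift_p))
  } else {
    cat("  elevation/shift tests not applicable under differing slopes\n")
  }
  invisible(x)
}

#' Graded significance code for a p-value
#'
#' The conventional figure annotation: \code{"+"} for p < 0.1,
#' \code{"*"} < 0.05, \code{"**"} < 0.01, \code{"***"} < 0.001, empty
#' otherwise.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_code <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else if (pi < 0.1) "+" else ""
  }, character(1))
}
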