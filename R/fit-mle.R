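#' Fit a single light-response curve by least squares
#'
#' Estimates the four NRH parameters for one individual's A/q curve by
#' Gaussian maximum likelihood (nonlinear least squares,
#' Levenberg-Marquardt via \pkg{minpack.lm}), with data-driven starting
#' values and a small multi-start grid as fallback. Parameters are
#' constrained to their physiological boxes: a_max in (0, 100], phi in
#' (0, 0.125], theta in (0, 1], r_d in [0, 10].
#'
#' A curve that cannot support a fit (fewer than 5 distinct irradiance
#' levels, missing low/high light coverage, a flat response, or
#' non-convergence after multi-start) yields a failure object carrying a
#' diagnostic message rather than an error, so batch fitting never halts.
#'
#' @param observations data.frame with columns \code{ppfd} and
#'   \code{a_net} (one individual's curve).
#' @return An object of class \code{"nrh_fit"}: list with \code{ok},
#'   \code{params} (an [nrh_params()] object when \code{ok}),
#'   \code{se} (approximate standard errors), \code{sigma} (residual SD),
#'   \code{rss}, \code{gradient_norm} (norm of the RSS gradient at the
#'   optimum), \code{n}, and \code{message}.
#' @export
#' @examples
#' p <- nrh_params(10, 0.06, 0.8, 1)
#' q <- c(0, 20, 50, 100, 200, 300, 500, 800, 1000, 1300)
#' fit <- fit_curve_mle(data.frame(ppfd = q, a_net = nrh_predict(p, q)))
#' unlist(fit$params)
fit_curve_mle <- function(observations) {
  assert_columns(observations, c("ppfd", "a_net"), "curve data")
  obs <- observations[is.finite(observations$ppfd) & is.finite(observations$a_net), ]
  n <- nrow(obs)
  fail <- function(msg) structure(
    list(ok = FALSE, params = NULL, se = NULL, sigma = NA_real_, rss = NA_real_,
         gradient_norm = NA_real_, n = n, message = msg),
    class = "nrh_fit")

  lv <- unique(obs$ppfd)
  if (length(lv) < 5) return(fail("fewer than 5 distinct PPFD levels"))
  if (!any(lv <= 50) || !any(lv >= 800))
    return(fail("curve lacks low (<=50) or saturating (>=800) light coverage"))
  if (stats::sd(obs$a_net) < 1e-8) return(fail("flat response (no variance in a_net)"))

  # Starting values from curve geometry.
  rd0 <- if (any(obs$ppfd == 0)) max(0, -mean(obs$a_net[obs$ppfd == 0])) else
    max(0, -min(obs$a_net))
  amax0 <- min(max(max(obs$a_net) + rd0, 0.5), 90)
  low <- obs[obs$ppfd > 0 & obs$ppfd <= 110, ]
  phi0 <- if (nrow(low) >= 2)
    stats::coef(stats::lm(a_net ~ ppfd, data = low))[["ppfd"]] else 0.05
  phi0 <- min(max(phi0, 0.005), 0.12)

  lower <- c(a_max = 1e-3, phi = 1e-4, theta = 1e-3, r_d = 0)
  upper <- c(a_max = 100, phi = 0.125, theta = 1, r_d = 10)
  starts <- rbind(
    c(amax0, phi0, 0.7, rd0),
    as.matrix(expand.grid(a_max = c(amax0, 2 * amax0),
                          phi = c(0.03, 0.06, 0.09),
                          theta = c(0.3, 0.6, 0.9),
                          r_d = c(max(rd0, 0.2)))))
  colnames(starts) <- names(lower)

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[k, ], lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        a_net ~ nrh_gross(ppfd, a_max, phi, theta) - r_d,
        data = obs, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    if (k == 1 && !is.null(best)) break  # geometry-based start usually suffices
  }
  if (is.null(best)) return(fail("non-convergence after multi-start"))

  cf <- stats::coef(best$fit)
  grad <- rss_gradient(cf, obs)
  # Project the gradient onto the feasible directions at active bounds.
  at_lo <- cf <= lower + 1e-7
  at_hi <- cf >= upper - 1e-7
  gproj <- grad
  gproj[at_lo & grad > 0] <- 0
  gproj[at_hi & grad < 0] <- 0
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e)
    rep(NA_real_, 4))
  structure(list(
    ok = TRUE,
    params = nrh_params(cf[["a_max"]], cf[["phi"]], cf[["theta"]], cf[["r_d"]]),
    se = se, sigma = sqrt(best$rss / max(n - 4, 1)), rss = best$rss,
    gradient_norm = sqrt(sum(gproj^2)), n = n, message = "converged"),
    class = "nrh_fit")
}

# Central-difference gradient of the residual sum of squares.
rss_gradient <- function(par, obs, h = 1e-6) {
  f <- function(p) {
    pr <- nrh_gross(obs$ppfd, p[["a_max"]], p[["phi"]], p[["theta"]]) - p[["r_d"]]
    sum((obs$a_net - pr)^2)
  }
  vapply(seq_along(par), function(i) {
    hp <- hm <- par
    step <- h * max(abs(par[i]), 1e-3)
    hp[i] <- par[i] + step
    hm[i] <- par[i] - step
    (f(hp) - f(hm)) / (2 * step)
  }, numeric(1))
}

#' @export
print.nrh_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("NRH curve fit (n = %d, sigma = %.3g):\n", x$n, x$sigma))
    print(x$params)
  } else {
    cat("NRH curve fit FAILED:", x$message, "\n")
  }
  invisible(x)
}

#' Fit every individual's curve in a light-curve table
#'
#' Applies [fit_curve_mle()] to each individual and collects the results
#' in a tidy table; individuals whose fit fails are retained with
#' \code{ok = FALSE} and the failure reason.
#'
#' @param curves data.frame with columns \code{individual_id},
#'   \code{species_code}, \code{ppfd}, \code{a_net} and optionally
#'   \code{e_trans}.
#' @return data.frame, one row per individual: identifiers, \code{ok},
#'   estimates \code{a_max}, \code{phi}, \code{theta}, \code{r_d},
#'   derived \code{lcp}, residual \code{sigma}, \code{n_obs},
#'   \code{e_trans_sat} (mean transpiration at the highest irradiance, if
#'   present) and \code{message}.
#' @export
fit_curves <- function(curves) {
  assert_columns(curves, c("individual_id", "species_code", "ppfd", "a_net"),
                 "light-curve table")
  ids <- unique(curves$individual_id)
  rows <- lapply(ids, function(id) {
    sub <- curves[curves$individual_id == id, ]
    fit <- fit_curve_mle(sub)
    e_sat <- NA_real_
    if ("e_trans" %in% names(sub)) {
      top <- sub$ppfd == max(sub$ppfd)
      e_sat <- mean(sub$e_trans[top])
    }
    if (fit$ok) {
      p <- fit$params
      data.frame(individual_id = id, species_code = sub$species_code[1],
                 ok = TRUE, a_max = p$a_max, phi = p$phi, theta = p$theta,
                 r_d = p$r_d,
                 lcp = if (p$r_d < p$a_max) lcp_of(p) else NA_real_,
                 sigma = fit$sigma, n_obs = fit$n, e_trans_sat = e_sat,
                 message = fit$message, stringsAsFactors = FALSE)
    } else {
      data.frame(individual_id = id, species_code = sub$species_code[1],
                 ok = FALSE, a_max = NA_real_, phi = NA_real_,
                 theta = NA_real_, r_d = NA_real_, lcp = NA_real_,
                 sigma = NA_real_, n_obs = fit$n, e_trans_sat = e_sat,
                 message = fit$message, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
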