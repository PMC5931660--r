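#' Non-rectangular hyperbola parameter set
#'
#' Bundles the four parameters of the non-rectangular hyperbola (NRH)
#' photosynthetic light-response model and validates them against their
#' physiological bounds.
#'
#' The NRH models net CO2 assimilation \eqn{A_{net}} as a function of
#' irradiance \eqn{q} (PPFD): the gross rate \eqn{A} is the lower root of
#' \deqn{\theta A^2 - (\phi q + A_{max}) A + \phi q A_{max} = 0,}
#' and \eqn{A_{net} = A - R_d}.
#'
#' @param a_max light-saturated gross photosynthetic rate
#'   (umol CO2 m-2 s-1), > 0.
#' @param phi apparent quantum yield (mol CO2 mol-1 photons),
#'   in (0, 0.125]; 0.125 is the theoretical maximum for C3 leaves.
#' @param theta convexity of the curve, dimensionless, in (0, 1].
#'   As \code{theta} approaches 0 the NRH degenerates to a rectangular
#'   hyperbola; at 1 it is a Blackman response.
#' @param r_d daytime dark respiration rate (umol CO2 m-2 s-1), >= 0.
#'
#' @return An object of class \code{"nrh_params"}: a named list with the
#'   four parameters.
#' @seealso [nrh_predict()], [lcp_of()]
#' @export
#' @examples
#' p <- nrh_params(a_max = 10, phi = 0.06, theta = 0.8, r_d = 1)
#' nrh_predict(p, c(0, 100, 1300))
nrh_params <- function(a_max, phi, theta, r_d) {
  stopifnot(is.numeric(a_max), is.numeric(phi), is.numeric(theta), is.numeric(r_d))
  if (!is.finite(a_max) || a_max <= 0)
    stop("a_max must be finite and > 0", call. = FALSE)
  if (!is.finite(phi) || phi <= 0 || phi > 0.125)
    stop("phi must be in (0, 0.125]", call. = FALSE)
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop("theta must be in [0, 1]", call. = FALSE)
  if (!is.finite(r_d) || r_d < 0)
    stop("r_d must be >= 0", call. = FALSE)
  structure(list(a_max = a_max, phi = phi, theta = theta, r_d = r_d),
            class = "nrh_params")
}

#' @export
print.nrh_params <- function(x, ...) {
  cat("Non-rectangular hyperbola parameters:\n")
  cat(sprintf("  a_max = %.4g  phi = %.4g  theta = %.4g  r_d = %.4g\n",
              x$a_max, x$phi, x$theta, x$r_d))
  if (x$r_d < x$a_max)
    cat(sprintf("  LCP   = %.4g umol photons m-2 s-1\n", lcp_of(x)))
  invisible(x)
}

# Gross assimilation: lower root of theta*A^2 - (phi*q + a_max)*A + phi*q*a_max = 0,
# written in the rationalised form 2*phi*q*a_max / (b + sqrt(b^2 - 4*theta*phi*q*a_max))
# which is numerically stable and continuous through theta -> 0
# (the discriminant is >= (phi*q - a_max)^2 >= 0 for theta <= 1).
nrh_gross <- function(q, a_max, phi, theta) {
  b <- phi * q + a_max
  disc <- pmax(b^2 - 4 * theta * phi * q * a_max, 0)
  2 * phi * q * a_max / (b + sqrt(disc))
}

#' Predict net assimilation from NRH parameters
#'
#' Evaluates the non-rectangular hyperbola at the given irradiance(s):
#' the gross rate is the lower root of the defining quadratic, and the
#' dark respiration rate is subtracted. The implementation uses the
#' rationalised root formula, which is continuous in \code{theta}
#' including the \code{theta == 0} rectangular-hyperbola limit
#' \eqn{\phi q A_{max} / (\phi q + A_{max})}.
#'
#' @param params an [nrh_params()] object (or coercible named list).
#' @param ppfd numeric vector of irradiances
#'   (umol photons m-2 s-1), all >= 0.
#' @return Numeric vector of net assimilation rates (umol CO2 m-2 s-1).
#' @export
#' @examples
#' p <- nrh_params(10, 0.06, 0.8, 1)
#' nrh_predict(p, 0)     # = -r_d
#' nrh_predict(p, 1e6)   # ~ a_max - r_d
nrh_predict <- function(params, ppfd) {
  params <- as_nrh_params(params)
  if (!is.numeric(ppfd) || any(!is.finite(ppfd)) || any(ppfd < 0))
    stop("ppfd must be finite and >= 0", call. = FALSE)
  nrh_gross(ppfd, params$a_max, params$phi, params$theta) - params$r_d
}

as_nrh_params <- function(x) {
  if (inherits(x, "nrh_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    need <- c("a_max", "phi", "theta", "r_d")
    if (!all(need %in% names(x)))
      stop("parameters must carry names a_max, phi, theta, r_d", call. = FALSE)
    return(nrh_params(x$a_max, x$phi, x$theta, x$r_d))
  }
  stop("cannot interpret parameters", call. = FALSE)
}

#' Light compensation point of an NRH curve
#'
#' The light compensation point (LCP) is the irradiance at which net
#' assimilation crosses zero (the x-axis intercept of the light-response
#' curve). For the NRH it has the closed form
#' \deqn{q^* = \frac{R_d (A_{max} - \theta R_d)}{\phi (A_{max} - R_d)},}
#' obtained by setting the gross rate equal to \eqn{R_d} in the defining
#' quadratic.
#'
#' @param params an [nrh_params()] object.
#' @return The LCP (umol photons m-2 s-1). If \code{r_d == 0} the curve
#'   passes through the origin and the LCP is 0.
#' @export
#' @examples
#' lcp_of(nrh_params(10, 0.06, 0.8, 1))
lcp_of <- function(params) {
  params <- as_nrh_params(params)
  if (params$r_d >= params$a_max)
    stop("no light compensation point: r_d >= a_max (curve never reaches zero)",
         call. = FALSE)
  if (params$r_d == 0) return(0)
  params$r_d * (params$a_max - params$theta * params$r_d) /
    (params$phi * (params$a_max - params$r_d))
}
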