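#' Restricted cubic spline basis (Royston-Parmar parameterization)
#'
#' Truncated-power restricted cubic spline basis used for the log cumulative
#' excess hazard on the log-time scale.  With knots \eqn{k_1 < \dots < k_K}
#' the basis has `K - 1` columns (no intercept): \eqn{v_1 = x} and, for
#' \eqn{j = 2, \dots, K-1},
#' \deqn{v_j = (x - k_j)_+^3 - \lambda_j (x - k_1)_+^3
#'             - (1 - \lambda_j)(x - k_K)_+^3,\quad
#'       \lambda_j = \frac{k_K - k_j}{k_K - k_1}.}
#' The resulting spline has continuous value, first and second derivative at
#' every knot and is linear outside the boundary knots.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing numeric vector of at least 2 knots.
#' @return Matrix `length(x)` by `length(knots) - 1`.
#' @export
rcs_basis <- function(x, knots) {
  .check_knots(knots)
  K <- length(knots)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- x
  if (K > 2L) {
    k1 <- knots[1L]; kK <- knots[K]
    p1 <- pmax(x - k1, 0)^3
    pK <- pmax(x - kK, 0)^3
    for (j in 2:(K - 1L)) {
      lam <- (kK - knots[j]) / (kK - k1)
      out[, j] <- pmax(x - knots[j], 0)^3 - lam * p1 - (1 - lam) * pK
    }
  }
  out
}

#' Derivative of the restricted cubic spline basis
#'
#' Elementwise derivative of [rcs_basis()] with respect to `x`; needed to turn
#' the fitted log cumulative excess hazard into an excess hazard rate via
#' \eqn{\lambda(t) = \exp(\eta)\, s'(\ln t)/t}.
#'
#' @inheritParams rcs_basis
#' @return Matrix of the same shape as [rcs_basis()].
#' @export
rcs_deriv <- function(x, knots) {
  .check_knots(knots)
  K <- length(knots)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- 1
  if (K > 2L) {
    k1 <- knots[1L]; kK <- knots[K]
    p1 <- 3 * pmax(x - k1, 0)^2
    pK <- 3 * pmax(x - kK, 0)^2
    for (j in 2:(K - 1L)) {
      lam <- (kK - knots[j]) / (kK - k1)
      out[, j] <- 3 * pmax(x - knots[j], 0)^2 - lam * p1 - (1 - lam) * pK
    }
  }
  out
}

.check_knots <- function(knots) {
  if (length(knots) < 2L) stop("at least 2 knots are required")
  if (anyNA(knots) || any(!is.finite(knots))) stop("knots must be finite")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  invisible(knots)
}

#' Evaluate a restricted cubic spline function
#'
#' @param x evaluation points.
#' @param knots knot vector.
#' @param gamma coefficients of length `length(knots)`, the first element
#'   being the intercept.
#' @return Numeric vector `gamma[1] + rcs_basis(x, knots) %*% gamma[-1]`.
#' @export
rcs_eval <- function(x, knots, gamma) {
  if (length(gamma) != length(knots))
    stop("`gamma` must have one coefficient per knot (intercept included)")
  drop(gamma[1L] + rcs_basis(x, knots) %*% gamma[-1L])
}

#' Default knot placement on log event times
#'
#' Boundary knots at the minimum and maximum of the uncensored log event
#' times; `K - 2` internal knots at equally spaced centiles (empirical
#' quantiles with linear interpolation, `type = 7`).  E.g. `K = 6` places
#' internal knots at the 20/40/60/80th centiles.
#'
#' @param log_times numeric vector of log event times (uncensored only).
#' @param K number of knots, at least 2.
#' @return Strictly increasing knot vector of length `K`.
#' @export
default_knots <- function(log_times, K) {
  if (K < 2L) stop("at least 2 knots are required")
  log_times <- log_times[is.finite(log_times)]
  if (length(unique(log_times)) < K)
    stop("fewer than K distinct event times; use fewer knots")
  kn <- unname(stats::quantile(log_times, probs = seq(0, 1, length.out = K),
                               type = 7))
  if (any(diff(kn) <= 0))
    stop("tied centiles make knots non-distinct; use fewer knots")
  kn
}
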