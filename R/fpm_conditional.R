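#' Conditional flexible parametric relative survival model
#'
#' Maximum likelihood fit of an excess hazard model on the log cumulative
#' excess hazard scale,
#' \deqn{\ln \Lambda(t|X_i) = s(\ln t | k_0, \gamma) + X_i\beta
#'       + \textstyle\sum_c x_{ic}\, s_c(\ln t | k_c, \theta_c),}
#' with per-subject log-likelihood
#' \eqn{d_i \ln[h^*(t_i|X_i) + \lambda(t_i|X_i)] - \Lambda(t_i|X_i)}.
#' The baseline uses a restricted cubic spline of log time with `knots` knots;
#' time-dependent effects (`tvc`) add covariate-specific splines of log time
#' without constant terms.  Fitted excess hazards may be negative; only the
#' total hazard at event rows must stay positive (steps violating this are
#' rejected during optimization).
#'
#' @param cohort an `rs_cohort`.
#' @param table an `rs_ratetable` supplying `h*`.
#' @param x covariates: a RHS-only formula evaluated in `cohort` (intercept
#'   dropped), or a numeric matrix with one row per subject, or `NULL`.
#' @param tvc covariates given time-dependent effects: a formula/matrix as in
#'   `x` (typically a subset of its columns).
#' @param knots number of baseline knots (default 6) or an explicit vector of
#'   knots on the log-time scale.
#' @param tvc_knots knots per time-dependent effect (count or vector).
#' @param start optional starting values.
#' @param control passed to [stats::optim()].
#' @return An object of class `rs_fit_conditional` with components
#'   `coefficients`, `vcov` (inverse observed information), `loglik`,
#'   `converged`, `knots`, and the design information used by
#'   [regression_standardize()].  Non-convergence is flagged, not an error.
#' @export
fit_conditional <- function(cohort, table, x = NULL, tvc = NULL, knots = 6,
                            tvc_knots = 4, start = NULL, control = list()) {
  cohort <- as_cohort(cohort)
  if (sum(cohort$dead) < 1) stop("at least one event is required")
  X <- .as_design_matrix(x, cohort)
  TVC <- .as_design_matrix(tvc, cohort)
  lt_ev <- log(cohort$time[cohort$dead == 1])
  k0 <- if (length(knots) == 1L) default_knots(lt_ev, knots) else sort(knots)
  tvk <- NULL
  if (!is.null(TVC)) {
    tvk <- lapply(seq_len(ncol(TVC)), function(c)
      if (length(tvc_knots) > 1L) sort(tvc_knots)
      else default_knots(lt_ev, tvc_knots))
    names(tvk) <- colnames(TVC)
  }
  spec <- list(knots = k0, xnames = colnames(X), tvc_knots = tvk)

  n <- nrow(cohort)
  die <- which(cohort$dead == 1)
  scheds <- .cohort_scheds(cohort, table)
  hstar <- vapply(die, function(i)
    .sched_hazard(scheds[[i]], cohort$time[i]), 0)
  dd <- .eta_design(log(cohort$time[die]), spec,
                    if (!is.null(X)) X[die, , drop = FALSE],
                    if (!is.null(TVC)) TVC[die, , drop = FALSE])
  cd <- .eta_design(log(cohort$time), spec, X, TVC)
  dsn <- list(ev = list(B = dd$B, D = dd$D, t = cohort$time[die],
                        w = rep(1, length(die)), offset = hstar, id = die),
              cum = list(B = cd$B, w = rep(1, n), id = seq_len(n)))
  if (is.null(start)) start <- .fpm_start(cohort, scheds, spec)
  fit <- .fpm_fit(dsn, start, control)
  pn <- .spec_parnames(spec)
  if (!is.null(fit$vcov)) dimnames(fit$vcov) <- list(pn, pn)
  structure(list(coefficients = stats::setNames(fit$par, pn),
                 vcov = fit$vcov, loglik = -fit$value,
                 converged = fit$converged, knots = k0, spec = spec,
                 X = X, TVC = TVC, n = n, n_events = length(die),
                 w_a = cohort$w_a, call = match.call()),
            class = "rs_fit_conditional")
}

.as_design_matrix <- function(x, cohort) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "formula")) {
    mm <- stats::model.matrix(x, data = cohort)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    return(mm)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

#' Restricted cubic spline design columns for a covariate
#'
#' Convenience wrapper placing `K` knots at equally spaced centiles of `x`
#' (boundaries at min/max) and returning the `K - 1` basis columns, for use
#' as a non-linear covariate effect (e.g. age splines).
#'
#' @param x covariate values.
#' @param K number of knots.
#' @param knots optional explicit knots overriding `K`.
#' @return Basis matrix with `K - 1` named columns.
#' @export
rcs_mat <- function(x, K = 4, knots = NULL) {
  if (is.null(knots)) knots <- default_knots(x, K)
  b <- rcs_basis(x, knots)
  colnames(b) <- paste0("rcs", seq_len(ncol(b)))
  attr(b, "knots") <- knots
  b
}

#' @export
print.rs_fit_conditional <- function(x, ...) {
  cat("Conditional flexible parametric relative survival model\n")
  cat("  subjects:", x$n, " events:", x$n_events,
      " knots:", length(x$knots), "\n")
  cat("  log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.rs_fit_conditional <- function(object, ...) object$coefficients

#' @export
vcov.rs_fit_conditional <- function(object, ...) object$vcov

#' @export
logLik.rs_fit_conditional <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

## eta(t) for every subject at one time, given parameters (internal)
.cond_eta <- function(fit, theta, t) {
  d <- .eta_design(rep(log(t), fit$n), fit$spec, fit$X, fit$TVC)
  list(eta = drop(d$B %*% theta), sp = drop(d$D %*% theta))
}

#' Regression standardization of a conditional model
#'
#' Averages the model-based individual relative survival predictions,
#' \eqn{\hat R_m(t) = \sum_i w_i \hat R(t|X_i) / \sum_i w_i}, and forms the
#' marginal excess hazard by the ratio
#' \eqn{\hat\lambda_m(t) = \sum_i w_i \hat R \hat\lambda / \sum_i w_i \hat R}.
#' Confidence intervals use the delta method on the
#' \eqn{\log(-\log)} scale (survival) and log scale (hazard) with numeric
#' gradients.
#'
#' @param fit an `rs_fit_conditional`.
#' @param times evaluation times.
#' @param w_a optional standardization weights (default: cohort weights used
#'   at fit time).
#' @param conf_level confidence level.
#' @return Data frame with `time`, `rel_surv`, `lower`, `upper`,
#'   `excess_haz`, `haz_lower`, `haz_upper`.
#' @export
regression_standardize <- function(fit, times, w_a = NULL,
                                   conf_level = 0.95) {
  stopifnot(inherits(fit, "rs_fit_conditional"))
  if (!fit$converged)
    warning("standardizing a fit flagged as non-converged", call. = FALSE)
  if (any(log(times) < fit$knots[1]))
    warning("times before the first knot: spline extrapolation", call. = FALSE)
  if (is.null(w_a)) w_a <- fit$w_a
  w <- w_a / sum(w_a)
  theta <- fit$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(times, function(tt) {
    Rm_fun <- function(th) {
      e <- .cond_eta(fit, th, tt)
      sum(w * exp(-exp(e$eta)))
    }
    lm_fun <- function(th) {
      e <- .cond_eta(fit, th, tt)
      R <- exp(-exp(e$eta))
      lam <- exp(e$eta) * e$sp / tt
      sum(w * R * lam) / sum(w * R)
    }
    Rm <- Rm_fun(theta)
    lam <- lm_fun(theta)
    if (is.null(fit$vcov)) return(c(Rm, NA, NA, lam, NA, NA))
    gR <- .num_jac(function(th) log(-log(Rm_fun(th))), theta)
    seR <- sqrt(drop(gR %*% fit$vcov %*% t(gR)))
    ci <- exp(-exp(log(-log(Rm)) + c(1, -1) * z * seR))
    if (is.finite(lam) && lam > 0) {
      gl <- .num_jac(function(th) log(lm_fun(th)), theta)
      sel <- sqrt(drop(gl %*% fit$vcov %*% t(gl)))
      cil <- exp(log(lam) + c(-1, 1) * z * sel)
    } else cil <- c(NA_real_, NA_real_)
    c(Rm, ci, lam, cil)
  })
  out <- do.call(rbind, out)
  data.frame(time = times, rel_surv = out[, 1], lower = out[, 2],
             upper = out[, 3], excess_haz = out[, 4], haz_lower = out[, 5],
             haz_upper = out[, 6])
}

#' Predicted conditional relative survival
#'
#' @param object an `rs_fit_conditional`.
#' @param times evaluation times.
#' @param ... unused.
#' @return Matrix of \eqn{\hat R(t|X_i)}, subjects in rows, times in columns.
#' @export
predict.rs_fit_conditional <- function(object, times, ...) {
  sapply(times, function(tt) {
    e <- .cond_eta(object, object$coefficients, tt)
    exp(-exp(e$eta))
  })
}
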