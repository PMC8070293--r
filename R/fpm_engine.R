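## Shared likelihood engine for the flexible parametric excess hazard models.
##
## Both the conditional model and the weighted marginal model maximize a
## likelihood whose event term is  w_e * ln(offset + lambda(t_e))  and whose
## cumulative term is a weighted sum of increments of Lambda(t) = exp(eta(t)),
## with  eta(t) = s(ln t | k0, gamma) + X beta + sum_c x_c s_c(ln t | k_c).
## The design is pre-computed once; each objective evaluation is a handful of
## matrix-vector products.

## eta design matrices at log-times `lt` for covariate rows X / TVC.
## Returns B (eta = B theta) and D (d eta / d ln t = D theta).
.eta_design <- function(lt, spec, X = NULL, TVC = NULL) {
  n <- length(lt)
  B <- cbind(1, rcs_basis(lt, spec$knots))
  D <- cbind(0, rcs_deriv(lt, spec$knots))
  if (!is.null(spec$xnames) && length(spec$xnames)) {
    X <- matrix(X, n, length(spec$xnames))
    B <- cbind(B, X)
    D <- cbind(D, matrix(0, n, ncol(X)))
  }
  if (!is.null(spec$tvc_knots) && length(spec$tvc_knots)) {
    TVC <- matrix(TVC, n, length(spec$tvc_knots))
    for (c in seq_along(spec$tvc_knots)) {
      kc <- spec$tvc_knots[[c]]
      B <- cbind(B, TVC[, c] * rcs_basis(lt, kc))
      D <- cbind(D, TVC[, c] * rcs_deriv(lt, kc))
    }
  }
  list(B = B, D = D)
}

.spec_npar <- function(spec) {
  length(spec$knots) + length(spec$xnames) +
    sum(vapply(spec$tvc_knots, function(k) length(k) - 1L, 0L))
}

.spec_parnames <- function(spec) {
  nm <- c("gamma0", paste0("gamma", seq_len(length(spec$knots) - 1L)))
  nm <- c(nm, spec$xnames)
  if (length(spec$tvc_knots))
    for (c in seq_along(spec$tvc_knots))
      nm <- c(nm, paste0(names(spec$tvc_knots)[c], ":lnt",
                         seq_len(length(spec$tvc_knots[[c]]) - 1L)))
  nm
}

## Negative log-likelihood.  dsn carries:
##   ev : list(B, D, t, w, offset, id)   -- event rows
##   cum: list(B, w, id)                 -- signed-coefficient rows; the
##        cumulative term is sum(w * exp(B theta)).  Interval increments are
##        encoded as +w rows at stops and -w rows at starts; the quadrature
##        engine adds Gauss-Legendre node rows (integration by parts turns
##        int w lambda du into endpoint terms minus int w h* Lambda du).
.fpm_nll <- function(theta, dsn) {
  ev <- dsn$ev
  lam <- .ev_lambda(theta, ev)
  tot <- ev$offset + lam
  if (any(tot <= 0)) return(1e10 + sum(pmax(-tot, 0)))
  nll <- -sum(ev$w * log(tot))
  nll + sum(dsn$cum$w * exp(drop(dsn$cum$B %*% theta)))
}

.ev_lambda <- function(theta, ev) {
  eta <- drop(ev$B %*% theta)
  sp <- drop(ev$D %*% theta)
  exp(eta) * sp / ev$t
}

.fpm_grad <- function(theta, dsn) {
  ev <- dsn$ev
  eta <- drop(ev$B %*% theta)
  sp <- drop(ev$D %*% theta)
  lam <- exp(eta) * sp / ev$t
  tot <- ev$offset + lam
  if (any(tot <= 0)) return(rep(0, length(theta)))
  # d lambda / d theta = lam * B + exp(eta)/t * D
  wfac <- ev$w / tot
  g <- -(crossprod(ev$B, wfac * lam) + crossprod(ev$D, wfac * exp(eta) / ev$t))
  cum <- dsn$cum
  drop(g) + drop(crossprod(cum$B, cum$w * exp(drop(cum$B %*% theta))))
}

## Per-subject scores of the LOG-likelihood at theta (n_id x p), for the
## cluster-robust sandwich with clusters = subjects.
.fpm_scores <- function(theta, dsn, n_id) {
  p <- length(theta)
  S <- matrix(0, n_id, p)
  add <- function(S, G, id, sign = 1) {
    agg <- rowsum(G, id)
    rows <- as.integer(rownames(agg))
    S[rows, ] <- S[rows, ] + sign * agg
    S
  }
  ev <- dsn$ev
  eta <- drop(ev$B %*% theta)
  sp <- drop(ev$D %*% theta)
  lam <- exp(eta) * sp / ev$t
  tot <- ev$offset + lam
  wfac <- ev$w / tot
  Gev <- wfac * lam * ev$B + wfac * exp(eta) / ev$t * ev$D
  S <- add(S, Gev, ev$id)
  cum <- dsn$cum
  Gc <- cum$w * exp(drop(cum$B %*% theta)) * cum$B
  add(S, Gc, cum$id, sign = -1)
}

## Analytic Hessian of the negative log-likelihood.  With per-row basis b,
## derivative-basis d, e = exp(eta)/t:  dlam = lam b + e d  and
## d2lam = lam b b' + e (b d' + d b'); the cumulative term contributes
## w Lambda b b' per row (Gauss-Legendre node rows contribute w d2lam).
.fpm_hess <- function(theta, dsn) {
  ev <- dsn$ev
  eta <- drop(ev$B %*% theta)
  sp <- drop(ev$D %*% theta)
  e <- exp(eta) / ev$t
  lam <- e * sp
  tot <- ev$offset + lam
  dL <- lam * ev$B + e * ev$D
  H <- crossprod(sqrt(ev$w) / tot * dL) -
    crossprod(ev$B, (ev$w * lam / tot) * ev$B) -
    crossprod(ev$B, (ev$w * e / tot) * ev$D) -
    crossprod(ev$D, (ev$w * e / tot) * ev$B)
  cum <- dsn$cum
  Lc <- exp(drop(cum$B %*% theta))
  H <- H + crossprod(cum$B, (cum$w * Lc) * cum$B)
  (H + t(H)) / 2
}

## BFGS driver.  Returns MLE, -loglik, convergence flag, observed information.
.fpm_fit <- function(dsn, start, control = list()) {
  ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)
  opt <- stats::optim(start, .fpm_nll, .fpm_grad, dsn = dsn,
                      method = "BFGS", control = ctrl)
  gr <- .fpm_grad(opt$par, dsn)
  hess <- try(.fpm_hess(opt$par, dsn), silent = TRUE)
  conv <- opt$convergence == 0 && all(is.finite(gr)) &&
    max(abs(gr)) < 1e-3 * (1 + abs(opt$value)) && !inherits(hess, "try-error")
  vcov <- NULL
  if (!inherits(hess, "try-error")) {
    vcov <- try(solve(hess), silent = TRUE)
    if (inherits(vcov, "try-error") || any(!is.finite(vcov)) ||
        any(diag(vcov) < 0)) {
      vcov <- NULL; conv <- FALSE
    } else vcov <- (vcov + t(vcov)) / 2
  } else hess <- NULL
  list(par = opt$par, value = opt$value, converged = conv,
       gradient = gr, hessian = hess, vcov = vcov)
}

## Starting values: least-squares fit of the baseline spline to the log of a
## crude weighted cumulative excess hazard (Pohar-Perme-type jumps at event
## times minus a coarsely integrated expected-hazard term, reusing the
## already-built subject schedules); extra covariate/TVC coefficients start
## at zero.
.fpm_start <- function(cohort, scheds, spec, w_a = NULL, grid = 0.25) {
  p <- .spec_npar(spec)
  start <- numeric(p)
  K <- length(spec$knots)
  ev <- sort(unique(cohort$time[cohort$dead == 1]))
  ok <- FALSE
  res <- try({
    rs <- .riskset_sums(cohort, scheds, ev, w_a)
    cumj <- cumsum(rs$jn / rs$den)
    br <- seq(0, max(cohort$time), by = grid)
    if (br[length(br)] < max(cohort$time)) br <- c(br, max(cohort$time))
    mids <- (br[-1] + br[-length(br)]) / 2
    ri <- .riskset_sums(cohort, scheds, mids, w_a, jumps = FALSE)
    f <- ifelse(ri$den > 0, ri$num / ri$den, 0)
    cumint <- stats::approx(c(0, br[-1]), c(0, cumsum(f * diff(br))),
                            xout = ev, rule = 2)$y
    chz <- pmax(cumj - cumint, 1e-5)
    Bm <- cbind(1, rcs_basis(log(ev), spec$knots))
    cf <- stats::lm.fit(Bm, log(chz))$coefficients
    if (all(is.finite(cf))) { start[seq_len(K)] <- cf; ok <- TRUE }
  }, silent = TRUE)
  if (!ok) {
    # fallback: exponential excess hazard 0.1
    start[1] <- log(0.1); start[2] <- 1
  }
  start
}

## central-difference jacobian of a vector-valued function
.num_jac <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
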