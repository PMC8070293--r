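## Shared machinery: the expected-hazard integral
##   I(t) = int_0^t  [ sum_j w_j(u) Y_j(u) h*_j(u) ] / [ sum_j w_j(u) Y_j(u) ] du
## evaluated by the midpoint rule on a subdivision at the grid step and at all
## event/censoring times.  Rates change only at yearly band boundaries, so a
## daily default step is conservative.
.expected_integral <- function(cohort, scheds, w_a, grid, horizon) {
  br <- sort(unique(c(seq(0, horizon, by = grid),
                      cohort$time[cohort$time <= horizon], horizon)))
  mids <- (br[-1] + br[-length(br)]) / 2
  rs <- .riskset_sums(cohort, scheds, mids, w_a, jumps = FALSE)
  f <- ifelse(rs$den > 0, rs$num / rs$den, 0)
  list(breaks = br, f = f, cum = c(0, cumsum(f * diff(br))))
}

.integral_at <- function(ig, t) {
  i <- findInterval(t, ig$breaks, all.inside = TRUE)
  ig$cum[i] + ig$f[i] * (t - ig$breaks[i])
}

.new_rs_curve <- function(event_times, jumps, var_jumps, ig, conf_level,
                          horizon) {
  structure(list(event_times = event_times, cum_jump = cumsum(jumps),
                 cum_var = cumsum(var_jumps), integral = ig,
                 conf_level = conf_level, horizon = horizon),
            class = "rs_curve")
}

#' Evaluate an estimated relative survival curve
#'
#' @param curve an `rs_curve` (or age-standardized `rs_stdcurve`).
#' @param times evaluation times.
#' @return Data frame with the cumulative excess hazard (where defined), its
#'   standard error, relative survival and confidence limits.
#' @export
curve_at <- function(curve, times) UseMethod("curve_at")

#' @export
curve_at.rs_curve <- function(curve, times) {
  if (any(times > curve$horizon + 1e-12))
    warning("curve truncated at ", format(curve$horizon),
            "; later times use the value there", call. = FALSE)
  times <- pmin(times, curve$horizon)
  nj <- findInterval(times + 1e-12, curve$event_times)
  jump <- c(0, curve$cum_jump)[nj + 1L]
  v <- c(0, curve$cum_var)[nj + 1L]
  ch <- jump - .integral_at(curve$integral, times)
  z <- stats::qnorm(1 - (1 - curve$conf_level) / 2)
  se <- sqrt(v)
  lo <- hi <- rep(NA_real_, length(times))
  pos <- which(ch > 0 & se > 0)
  # CI on the log cumulative excess hazard scale
  lo[pos] <- exp(-exp(log(ch[pos]) + z * se[pos] / ch[pos]))
  hi[pos] <- exp(-exp(log(ch[pos]) - z * se[pos] / ch[pos]))
  data.frame(time = times, cumhaz = ch, se_cumhaz = se,
             rel_surv = exp(-ch), lower = lo, upper = hi)
}

#' @export
print.rs_curve <- function(x, ...) {
  cat("Non-parametric marginal relative survival curve\n")
  cat("  events:", length(x$event_times), " horizon:", format(x$horizon), "\n")
  print(curve_at(x, pretty(c(0, x$horizon))[-1]), row.names = FALSE)
  invisible(x)
}

#' Pohar Perme estimator of marginal relative survival
#'
#' Non-parametric estimator of the marginal cumulative excess hazard
#' \deqn{\hat\Lambda_E(t) = \sum_{s \le t}
#'   \frac{\sum_i w_i(s)\, dN_i(s)}{\sum_i w_i(s) Y_i(s)}
#'   - \int_0^t \frac{\sum_i w_i(u) Y_i(u) h^*_i(u)}{\sum_i w_i(u) Y_i(u)} du}
#' with time-dependent weights \eqn{w_i(u) = w^a_i / S^*_i(u)}; relative
#' survival is \eqn{\exp(-\hat\Lambda_E)}.  The integral is evaluated by the
#' midpoint rule after subdividing follow-up at the `grid` step and at all
#' event/censoring times.  The variance cumulates
#' \eqn{\sum_i w_i(s)^2 dN_i(s) / [\sum_i w_i(s) Y_i(s)]^2} and confidence
#' intervals are formed on the log cumulative excess hazard scale.
#'
#' @param cohort an `rs_cohort`.
#' @param table an `rs_ratetable`.
#' @param w_a optional standardization weights overriding the cohort's `w_a`.
#' @param grid integration step in years for the expected-hazard term.
#' @param max_time horizon; defaults to the largest observed time.
#' @param conf_level confidence level.
#' @return An `rs_curve`; evaluate it with [curve_at()].
#' @export
pohar_perme <- function(cohort, table, w_a = NULL, grid = 1 / 365,
                        max_time = NULL, conf_level = 0.95) {
  cohort <- as_cohort(cohort)
  if (is.null(w_a)) w_a <- cohort$w_a
  horizon <- max(cohort$time)
  if (!is.null(max_time)) {
    if (max_time > horizon)
      warning("empty risk set after ", format(horizon),
              "; curve truncated there", call. = FALSE)
    horizon <- min(max_time, horizon)
  }
  scheds <- .cohort_scheds(cohort, table, horizon + 1)
  ev <- sort(unique(cohort$time[cohort$dead == 1 & cohort$time <= horizon]))
  if (length(ev)) {
    rs <- .riskset_sums(cohort, scheds, ev, w_a)
    jumps <- rs$jn / rs$den
    vjump <- rs$js / rs$den^2
  } else jumps <- vjump <- numeric(0)
  ig <- .expected_integral(cohort, scheds, w_a, grid, horizon)
  .new_rs_curve(ev, jumps, vjump, ig, conf_level, horizon)
}

#' Piecewise (Poisson) marginal excess hazard estimator
#'
#' Semi-parametric mirror of the marginal model: follow-up is split at every
#' distinct event time and within each interval a constant marginal excess
#' hazard atom is estimated by numerically maximizing the weighted Poisson
#' likelihood restricted to that interval (weights \eqn{w_i(s_k)} at the event
#' time, risk set at the event time).  Cumulating the atoms and subtracting
#' the same weighted expected-hazard integral as [pohar_perme()] reproduces
#' the Pohar Perme estimator exactly when no covariates are modelled; with
#' all expected rates zero the atoms are the Nelson-Aalen increments.
#'
#' @inheritParams pohar_perme
#' @return An `rs_curve`.
#' @export
piecewise_marginal <- function(cohort, table, w_a = NULL, grid = 1 / 365,
                               max_time = NULL, conf_level = 0.95) {
  cohort <- as_cohort(cohort)
  if (is.null(w_a)) w_a <- cohort$w_a
  horizon <- max(cohort$time)
  if (!is.null(max_time)) horizon <- min(max_time, horizon)
  scheds <- .cohort_scheds(cohort, table, horizon + 1)
  ev <- sort(unique(cohort$time[cohort$dead == 1 & cohort$time <= horizon]))
  jumps <- vjump <- numeric(length(ev))
  if (length(ev)) {
    rs <- .riskset_sums(cohort, scheds, ev, w_a)
    for (k in seq_along(ev)) {
      wd <- rs$jn[k]
      wy <- rs$den[k]
      # weighted Poisson log-likelihood for the hazard atom a = exp(xi),
      # maximized numerically then polished by two Newton steps on the score
      negll <- function(xi) -(wd * xi - exp(xi) * wy)
      xi <- stats::optimize(negll, interval = c(-40, 10), tol = 1e-10)$minimum
      for (it in 1:2) xi <- xi + (wd - exp(xi) * wy) / (exp(xi) * wy)
      jumps[k] <- exp(xi)
      vjump[k] <- rs$js[k] / wy^2
    }
  }
  ig <- .expected_integral(cohort, scheds, w_a, grid, horizon)
  .new_rs_curve(ev, jumps, vjump, ig, conf_level, horizon)
}

#' Age-standardized Pohar Perme estimator
#'
#' Externally age-standardized marginal relative survival.  In `"stratified"`
#' mode the estimator is run separately within each reference age group and
#' the group curves are averaged with the reference proportions
#' (variance combined on the survival scale assuming independent strata).  In
#' `"individual"` mode a single estimate is computed with individual
#' standardization weights \eqn{w^a_i = p^R_i / p^a_i}.
#'
#' @inheritParams pohar_perme
#' @param ref an [ref_dist()] reference age distribution.
#' @param mode `"stratified"` or `"individual"`.
#' @return `"individual"`: an `rs_curve`.  `"stratified"`: an `rs_stdcurve`,
#'   also evaluated with [curve_at()].
#' @export
pohar_perme_agestd <- function(cohort, table, ref,
                               mode = c("stratified", "individual"),
                               grid = 1 / 365, max_time = NULL,
                               conf_level = 0.95) {
  mode <- match.arg(mode)
  cohort <- as_cohort(cohort)
  if (mode == "individual") {
    w_a <- standardization_weights(cohort, ref)
    return(pohar_perme(cohort, table, w_a = w_a, grid = grid,
                       max_time = max_time, conf_level = conf_level))
  }
  g <- .ref_group(ref, cohort$age_dx)
  used <- which(ref$props > 0)
  empty <- used[!(used %in% unique(g))]
  if (length(empty))
    stop("reference group(s) ", paste(ref$labels[empty], collapse = ", "),
         " have positive weight but no subjects")
  curves <- lapply(used, function(gg)
    pohar_perme(cohort[g == gg, , drop = FALSE], table, grid = grid,
                max_time = max_time, conf_level = conf_level))
  structure(list(curves = curves, props = ref$props[used],
                 conf_level = conf_level,
                 horizon = min(vapply(curves, `[[`, 0, "horizon"))),
            class = "rs_stdcurve")
}

#' @export
curve_at.rs_stdcurve <- function(curve, times) {
  parts <- lapply(curve$curves, curve_at, times = times)
  R <- sapply(parts, `[[`, "rel_surv")
  # delta method on the survival scale: Var(R_g) = R_g^2 Var(Lambda_g)
  Vs <- sapply(parts, function(p) p$rel_surv^2 * p$se_cumhaz^2)
  R <- matrix(R, nrow = length(times)); Vs <- matrix(Vs, nrow = length(times))
  rel <- drop(R %*% curve$props)
  se <- sqrt(drop(Vs %*% curve$props^2))
  z <- stats::qnorm(1 - (1 - curve$conf_level) / 2)
  data.frame(time = times, rel_surv = rel, se = se,
             lower = pmax(rel - z * se, 0), upper = pmin(rel + z * se, 1))
}
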