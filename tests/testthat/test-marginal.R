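test_that("with zero expected rates the marginal model is the conditional one", {
  ch <- sim_fixture(1, n = 300, seed = 3)
  fm <- fit_marginal(ch, zero_table(), split_width = 0.2)
  fc <- fit_conditional(ch, zero_table())
  # all weights 1 and hbar* = 0: Eq-identical likelihoods, same optimum
  expect_equal(fm$loglik, fc$loglik, tolerance = 1e-8)
  expect_equal(unname(coef(fm)), unname(coef(fc)), tolerance = 1e-6)
})

test_that("cluster-robust sandwich uses subjects, not rows", {
  ch <- sim_fixture(1, n = 250, seed = 31)
  tb <- synthetic_ratetable()
  fit <- fit_marginal(ch, tb)
  V <- vcov(fit, "robust")
  expect_true(isSymmetric(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  # rebuild the internal design and check the sandwich against its pieces
  prep <- marsurv:::.prep_marginal(ch, tb, width = 0.2)
  spec <- list(knots = fit$knots, xnames = NULL, tvc_knots = NULL)
  s <- prep$split
  ed <- marsurv:::.eta_design(log(prep$ev$t), spec)
  bs <- marsurv:::.eta_design(log(s$stop), spec)
  pos <- which(s$start > 0)
  ba <- marsurv:::.eta_design(log(s$start[pos]), spec)
  dsn <- list(ev = list(B = ed$B, D = ed$D, t = prep$ev$t, w = prep$ev$w,
                        offset = prep$ev$hbar, id = prep$ev$idx),
              cum = list(B = rbind(bs$B, ba$B), w = c(s$w, -s$w[pos]),
                         id = c(s$idx, s$idx[pos])))
  th <- unname(coef(fit))
  A <- marsurv:::.fpm_hess(th, dsn)
  S <- marsurv:::.fpm_scores(th, dsn, nrow(ch))
  V_manual <- solve(A) %*% crossprod(S) %*% solve(A)
  expect_equal(unname(V), unname((V_manual + t(V_manual)) / 2),
               tolerance = 1e-6)
  # clustering on rows instead of subjects gives a different (wrong) variance
  dsn_rows <- dsn
  n_ev <- length(dsn$ev$id)
  dsn_rows$ev$id <- seq_len(n_ev)
  dsn_rows$cum$id <- n_ev + seq_along(dsn$cum$id)
  B_rows <- crossprod(marsurv:::.fpm_scores(th, dsn_rows,
                                            n_ev + length(dsn$cum$id)))
  V_rows <- solve(A) %*% B_rows %*% solve(A)
  expect_gt(max(abs(V_rows - V_manual)) / max(abs(V_manual)), 0.01)
})

test_that("per-subject scores sum to the total gradient", {
  ch <- sim_fixture(2, n = 150, seed = 37)
  tb <- synthetic_ratetable()
  prep <- marsurv:::.prep_marginal(ch, tb, width = 0.25)
  spec <- list(knots = default_knots(log(prep$ev$t), 5), xnames = NULL,
               tvc_knots = NULL)
  s <- prep$split
  ed <- marsurv:::.eta_design(log(prep$ev$t), spec)
  bs <- marsurv:::.eta_design(log(s$stop), spec)
  pos <- which(s$start > 0)
  ba <- marsurv:::.eta_design(log(s$start[pos]), spec)
  dsn <- list(ev = list(B = ed$B, D = ed$D, t = prep$ev$t, w = prep$ev$w,
                        offset = prep$ev$hbar, id = prep$ev$idx),
              cum = list(B = rbind(bs$B, ba$B), w = c(s$w, -s$w[pos]),
                         id = c(s$idx, s$idx[pos])))
  th <- marsurv:::.fpm_start(ch, prep$scheds, spec)
  g_num <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (marsurv:::.fpm_nll(tp, dsn) - marsurv:::.fpm_nll(tm, dsn)) / (2 * h)
  }, 0)
  expect_equal(marsurv:::.fpm_grad(th, dsn), g_num, tolerance = 1e-4)
  S <- marsurv:::.fpm_scores(th, dsn, nrow(ch))
  expect_equal(colSums(S), -marsurv:::.fpm_grad(th, dsn), tolerance = 1e-8)
})

test_that("predictions follow the closed form and hazard matches the slope", {
  ch <- sim_fixture(1, n = 400, seed = 41)
  tb <- synthetic_ratetable()
  fit <- fit_marginal(ch, tb)
  pr <- suppressWarnings(predict(fit, c(1, 4, 8)))
  eta <- rcs_eval(log(c(1, 4, 8)), fit$knots, unname(coef(fit)))
  expect_equal(pr$rel_surv, exp(-exp(eta)), tolerance = 1e-12)
  # lambda = -d ln R / dt by central differences
  h <- 1e-5
  for (t0 in c(1, 4, 8)) {
    Rm <- function(t) exp(-exp(rcs_eval(log(t), fit$knots,
                                        unname(coef(fit)))))
    num <- -(log(Rm(t0 + h)) - log(Rm(t0 - h))) / (2 * h)
    expect_equal(pr$excess_haz[pr$time == t0], num, tolerance = 1e-4)
  }
  expect_true(all(pr$lower <= pr$rel_surv & pr$rel_surv <= pr$upper))
})

test_that("standardizing to the observed age distribution changes nothing", {
  ch <- sim_fixture(2, n = 300, seed = 43)
  tb <- synthetic_ratetable()
  br <- c(0, 55, 65, 75, Inf)
  obs <- as.vector(table(cut(ch$age_dx, br, right = FALSE))) / nrow(ch)
  f1 <- fit_marginal(ch, tb)
  f2 <- fit_marginal(ch, tb, ref = ref_dist(br, obs))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("group contrasts: self-difference is zero, null EMRR covers one", {
  tb <- synthetic_ratetable(sexes = c("male", "female"), sex_ratio = 1.4)
  set.seed(47)
  cover <- logical(20)
  for (r in 1:20) {
    scn <- sim_scenario(2, n = 250)
    ch <- simulate_cohort(scn, tb)
    ch$group <- sample(c("A", "B"), nrow(ch), replace = TRUE)
    fit <- fit_marginal(ch, tb, knots = 4, group = "group")
    if (!fit$converged) next
    cc <- contrast(fit)
    cover[r] <- cc$lower <= 1 && 1 <= cc$upper
    if (r == 1) {
      sd0 <- contrast(fit, type = "survival_difference", times = c(1, 5),
                      levels = c("A", "A"))
      expect_equal(sd0$estimate, c(0, 0))
      expect_error(contrast(fit, levels = c("A", "C")), "unknown group")
    }
  }
  expect_gte(sum(cover), 16)   # 95% CI should cover the null ~19/20 times
})

test_that("a genuine group effect is detected and standardized per group", {
  # group B has substantially higher excess hazard via older ages plus a
  # direct label-linked effect: build it by thinning survivors
  set.seed(53)
  tb <- synthetic_ratetable()
  scn <- sim_scenario(2, n = 900)
  ch <- simulate_cohort(scn, tb)
  ch$group <- "A"
  chB <- simulate_cohort(sim_scenario(2, n = 900), tb)
  # accelerate group B's cancer deaths: halve their survival times when dead
  chB$time <- ifelse(chB$dead == 1, chB$time * 0.55, chB$time)
  chB$group <- "B"; chB$id <- chB$id + 1000
  both <- as_cohort(rbind(ch, chB))
  br <- c(0, 55, 65, 75, Inf)
  pA <- as.vector(table(cut(ch$age_dx, br, right = FALSE))) / nrow(ch)
  fit <- fit_marginal(both, tb, group = "group", ref = ref_dist(br, pA))
  expect_true(fit$converged)
  cc <- contrast(fit, levels = c("B", "A"))
  expect_gt(cc$estimate, 1.2)
  expect_gt(cc$lower, 1)
  sd <- contrast(fit, type = "survival_difference", times = 5,
                 levels = c("B", "A"))
  expect_lt(sd$estimate, 0)
  expect_true(sd$lower <= sd$estimate & sd$estimate <= sd$upper)
})

test_that("time-dependent group effects yield time-varying rate ratios", {
  set.seed(59)
  tb <- synthetic_ratetable()
  ch <- simulate_cohort(sim_scenario(2, n = 800), tb)
  ch$group <- sample(c("A", "B"), nrow(ch), replace = TRUE)
  f0 <- fit_marginal(ch, tb, knots = 4, group = "group")
  f1 <- fit_marginal(ch, tb, knots = 4, group = "group", group_tvc = TRUE,
                     tvc_knots = 4)
  expect_true(f1$converged)
  expect_gte(f1$loglik, f0$loglik - 1e-6)   # 3 extra parameters
  expect_equal(length(coef(f1)), length(coef(f0)) + 3)
  cc <- contrast(f1, type = "emrr", times = c(1, 3, 6))
  expect_equal(nrow(cc), 3)
  expect_true(all(cc$estimate > 0))
})

test_that("sweep over widths and knots reproduces direct fits", {
  ch <- sim_fixture(2, n = 250, seed = 61)
  tb <- synthetic_ratetable()
  sw <- sensitivity_sweep(ch, tb, widths = 0.5, knot_counts = 4, times = 5)
  direct <- fit_marginal(ch, tb, knots = 4, split_width = 0.5)
  expect_equal(sw$rel_surv, suppressWarnings(predict(direct, 5))$rel_surv,
               tolerance = 1e-12)
})

test_that("event weight at the exact event time is the default, flaggable", {
  ch <- sim_fixture(1, n = 200, seed = 67)
  tb <- synthetic_ratetable()
  f1 <- fit_marginal(ch, tb)
  f2 <- fit_marginal(ch, tb, event_weight = "midpoint")
  expect_false(isTRUE(all.equal(coef(f1), coef(f2))))
  expect_equal(coef(f1), coef(f2), tolerance = 0.05)  # close, not identical
})
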