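test_that("cohort validation catches malformed inputs", {
  base <- data.frame(id = 1:2, time = c(1, 2), dead = c(0, 1), age_dx = 60,
                     sex = "male", year_dx = 2009)
  expect_s3_class(as_cohort(base), "rs_cohort")
  expect_error(as_cohort(base[-1]), "id")
  expect_error(as_cohort(transform(base, time = c(0, 2))), "> 0")
  expect_error(as_cohort(transform(base, dead = c(2, 1))), "0 or 1")
  expect_error(as_cohort(transform(base, id = c(1, 1))), "unique")
  expect_error(as_cohort(transform(base, w_a = c(-1, 1))), "positive")
})

test_that("time splitting partitions follow-up exactly", {
  ch <- as_cohort(data.frame(id = 1:3, time = c(0.5, 0.2, 1.14),
                             dead = c(1, 1, 0), age_dx = 60, sex = "male",
                             year_dx = 2009))
  sp <- split_time(ch, width = 0.2)
  s1 <- sp[sp$id == 1, ]
  expect_equal(s1$stop, c(0.2, 0.4, 0.5))
  expect_equal(s1$mid, c(0.1, 0.3, 0.45))
  expect_equal(s1$event, c(0, 0, 1))
  expect_equal(sum(sp$id == 2), 1)              # t exactly one width
  # width >= max(t): one row per subject
  expect_equal(nrow(split_time(ch, width = 5)), 3)
  expect_error(split_time(ch, width = 0), "positive")

  set.seed(3)
  ch2 <- random_cohort(50)
  sp2 <- split_time(ch2, width = 0.37)
  persub <- tapply(sp2$stop - sp2$start, sp2$id, sum)
  expect_equal(as.numeric(persub[as.character(ch2$id)]), ch2$time,
               tolerance = 1e-12)
  expect_equal(sum(sp2$event), sum(ch2$dead))
  expect_true(all(sp2$stop > sp2$start))
})

test_that("standardization weights are reference over observed proportions", {
  ch <- as_cohort(data.frame(id = 1:4, time = 1, dead = 1,
                             age_dx = c(40, 42, 70, 72), sex = "male",
                             year_dx = 2009))
  # reference equal to observed: all weights 1
  ref_eq <- ref_dist(c(0, 50, Inf), c(0.5, 0.5))
  expect_equal(standardization_weights(ch, ref_eq), rep(1, 4))
  # observed (0.5, 0.5), reference (0.25, 0.75) -> weights (0.5, 1.5)
  ref2 <- ref_dist(c(0, 50, Inf), c(0.25, 0.75))
  expect_equal(standardization_weights(ch, ref2), c(0.5, 0.5, 1.5, 1.5))
  # empty observed group with positive reference weight
  ref3 <- ref_dist(c(0, 50, 60, Inf), c(0.25, 0.5, 0.25))
  expect_error(standardization_weights(ch, ref3), "no observed subjects")
})

test_that("group-wise weights standardize each group to the same reference", {
  # two comparison groups with different age mixes
  ch <- as_cohort(data.frame(id = 1:6, time = 1, dead = 1,
                             age_dx = c(40, 40, 70, 40, 70, 70),
                             sex = "m", year_dx = 2009,
                             group = rep(c("A", "B"), each = 3)))
  ref <- ref_dist(c(0, 50, Inf), c(0.5, 0.5))
  w <- standardization_weights(ch, ref, by = "group")
  # group A observes (2/3, 1/3): weights (0.75, 1.5); B the reverse
  expect_equal(w, c(0.75, 0.75, 1.5, 1.5, 0.75, 0.75))
  # and within each group the weighted age distribution matches the reference
  for (g in c("A", "B")) {
    sel <- ch$group == g
    p_young <- sum(w[sel][ch$age_dx[sel] < 50]) / sum(w[sel])
    expect_equal(p_young, 0.5)
  }
})

test_that("mean expected hazard is the weighted risk-set average", {
  tb <- const_table(0.02)
  # two at risk with hand-set rates via different tables: use per-age rates
  r <- array(0.01, c(2, 1, 1)); r[2, , 1] <- 0.03
  tb2 <- rate_table(r, 60:61, 2009, "m")
  ch <- as_cohort(data.frame(id = 1:2, time = c(2, 2), dead = c(1, 0),
                             age_dx = c(60, 61), sex = "m", year_dx = 2009))
  # at t=0.5 rates are 0.01 and 0.03, S* nearly equal -> mean close to 0.02
  expect_equal(mean_expected_hazard(ch, tb2, 0.5), 0.02, tolerance = 5e-3)
  # hand-set combined weights 3 and 1: close to (3*0.01 + 1*0.03)/4 = 0.015
  ch$w_a <- c(3, 1)
  m <- mean_expected_hazard(ch, tb2, 0.5)
  w <- c(3, 1) * exp(c(0.01, 0.03) * 0.5)
  expect_equal(m, sum(w * c(0.01, 0.03)) / sum(w), tolerance = 1e-12)
  expect_equal(m, 0.015, tolerance = 1e-2)
  # single subject at risk: its own rate (attained age 61 by t=1.5)
  expect_equal(mean_expected_hazard(ch[1, ], tb2, 1.5),
               suppressWarnings(expected_hazard(tb2, 60, 2009, "m", 1.5)))
  expect_error(mean_expected_hazard(ch, tb2, 2.5), "empty risk set")
})

test_that("mean expected hazard is bounded and vanishes with zero rates", {
  set.seed(5)
  ch <- random_cohort(30)
  tb <- synthetic_ratetable(a = 1e-3, b = 0.08,
                            sexes = c("male", "female"), sex_ratio = 1.4)
  tt <- c(0.5, 2, 4)
  hb <- mean_expected_hazard(ch, tb, tt)
  for (j in seq_along(tt)) {
    atrisk <- which(ch$time >= tt[j])
    hi <- vapply(atrisk, function(i) suppressWarnings(
      expected_hazard(tb, ch$age_dx[i], ch$year_dx[i], ch$sex[i], tt[j])), 0)
    expect_gte(hb[j], min(hi)); expect_lte(hb[j], max(hi))
  }
  expect_equal(mean_expected_hazard(ch, zero_table(), tt), rep(0, 3),
               tolerance = 1e-10)
})

test_that("reference distributions are validated", {
  expect_error(ref_dist(c(0, 50, Inf), c(0.6, 0.6)), "sum to 1")
  expect_error(ref_dist(c(0, 50, Inf), 1), "one entry per age group")
  expect_error(ref_dist(c(50, 0, Inf), c(0.5, 0.5)), "increasing")
})
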