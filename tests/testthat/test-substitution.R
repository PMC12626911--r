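fit_small_cohort <- function(n = 300, seed = 17) {
  data <- generate_cohort(generator_config(n = n, seed = seed))$data
  list(data = data, fit = fit_outcome_model(data))
}

test_that("zero reallocation gives exactly zero change with a degenerate CI", {
  f <- fit_small_cohort()
  s <- substitution_effect(f$fit, donor = "SB", recipient = "MVPA",
                           minutes = 0)
  expect_equal(s$delta, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(0, 0))
})

test_that("the effect equals the difference of two model predictions", {
  f <- fit_small_cohort()
  ref <- f$fit$center
  s <- substitution_effect(f$fit, donor = "SLP", recipient = "MVPA",
                           minutes = 20)
  brute <- predict_outcome(f$fit, reallocate(ref, "SLP", "MVPA", 20)) -
    predict_outcome(f$fit, ref)
  expect_equal(s$delta, brute, tolerance = 1e-12)
  # and is invariant to the pivot parameterization
  f2 <- fit_outcome_model(f$data, pivot_order = c("LPA", "MVPA", "SLP", "SB"))
  s2 <- substitution_effect(f2, reference = ref, donor = "SLP",
                            recipient = "MVPA", minutes = 20)
  expect_equal(s$delta, s2$delta, tolerance = 1e-9)
})

test_that("reallocation cannot overdraw the donor and reports the limit", {
  f <- fit_small_cohort()
  expect_error(substitution_effect(f$fit, donor = "MVPA", recipient = "SB",
                                   minutes = 2000), "available")
  expect_error(reallocate(f$fit$center, "SB", "SB", 10), "differ")
})

test_that("two half reallocations through the midpoint compose exactly", {
  f <- fit_small_cohort()
  ref <- f$fit$center
  t <- 24
  direct <- substitution_effect(f$fit, ref, "SB", "MVPA", t)$delta
  mid <- reallocate(ref, "SB", "MVPA", t / 2)
  twostep <- substitution_effect(f$fit, ref, "SB", "MVPA", t / 2)$delta +
    substitution_effect(f$fit, mid, "SB", "MVPA", t / 2)$delta
  expect_equal(direct, twostep, tolerance = 1e-9)
})

test_that("opposite reallocations are antisymmetric to first order", {
  f <- fit_small_cohort()
  for (pair in list(c("SB", "MVPA"), c("SLP", "LPA"), c("SLP", "MVPA"))) {
    ab <- substitution_effect(f$fit, donor = pair[1], recipient = pair[2],
                              minutes = 0.01)$delta
    ba <- substitution_effect(f$fit, donor = pair[2], recipient = pair[1],
                              minutes = 0.01)$delta
    expect_equal(ab / ba, -1, tolerance = 0.01)
  }
  # opposite signs at finite t in a model with nonzero effect
  ab <- substitution_effect(f$fit, donor = "SB", recipient = "MVPA",
                            minutes = 1)$delta
  ba <- substitution_effect(f$fit, donor = "MVPA", recipient = "SB",
                            minutes = 1)$delta
  expect_lt(ab * ba, 0)
})

test_that("displacing the smallest part moves the prediction more than augmenting it", {
  # MVPA is by far the smallest behavior, so the log-ratio geometry makes
  # MVPA-donor reallocations larger in magnitude than MVPA-recipient ones
  f <- fit_small_cohort()
  for (other in c("SLP", "SB", "LPA")) {
    lose <- substitution_effect(f$fit, donor = "MVPA", recipient = other,
                                minutes = 15)$delta
    gain <- substitution_effect(f$fit, donor = other, recipient = "MVPA",
                                minutes = 15)$delta
    expect_gt(abs(lose), abs(gain))
    expect_gt(lose, 0)  # losing MVPA raises the predicted score
    expect_lt(gain, 0)
  }
})

test_that("the substitution table enumerates all 12 ordered pairs once", {
  f <- fit_small_cohort()
  tab <- substitution_table(f$fit, minutes = 15)
  expect_equal(nrow(tab), 12)
  expect_equal(anyDuplicated(tab[, c("donor", "recipient")]), 0)
  expect_true(all(tab$donor != tab$recipient))
  expect_equal(unique(tab$donor), ap_behaviors)  # grouped canonically
  expect_true(all(tab$ci_low <= tab$delta & tab$delta <= tab$ci_high))
})

test_that("dose-response curves shrink to zero, flatten for MVPA gains, and truncate", {
  f <- fit_small_cohort()
  expect_message(
    curves <- dose_response_curves(f$fit,
                                   grid = c(0.01, seq(5, 60, by = 5))),
    "truncated")
  sbm <- curves[curves$donor == "SB" & curves$recipient == "MVPA", ]
  expect_lt(abs(sbm$delta[1]), 0.01)  # continuity at t -> 0
  # diminishing marginal effect as MVPA grows
  inc <- abs(diff(sbm$delta[-1]))
  expect_true(all(diff(inc) < 0))
  # MVPA-donor curves stop before the 40-min reserve runs out
  mv <- curves[curves$donor == "MVPA", ]
  expect_lt(max(mv$minutes), unname(f$fit$center["MVPA"]))
  expect_true(all(curves$ci_low <= curves$delta &
                  curves$delta <= curves$ci_high))
})

test_that("bootstrap intervals are seeded, degenerate without noise, and near the delta method", {
  nl <- noiseless_cohort(n = 150)
  ci0 <- bootstrap_ci(nl$data, "SB", "MVPA", 15, B = 100, seed = 1)
  expect_lt(diff(ci0), 1e-6)  # interpolated fit: no resampling variance

  f <- fit_small_cohort(n = 986, seed = 99)
  ci1 <- bootstrap_ci(f$data, "SB", "MVPA", 15, B = 300, seed = 7)
  ci2 <- bootstrap_ci(f$data, "SB", "MVPA", 15, B = 300, seed = 7)
  expect_equal(unclass(ci1), unclass(ci2))
  expect_error(bootstrap_ci(f$data, "SB", "MVPA", 15, B = 50), "at least 100")

  sd_ <- substitution_effect(f$fit, donor = "SB", recipient = "MVPA",
                             minutes = 15, ci_method = "delta")
  sb_ <- substitution_effect(f$fit, donor = "SB", recipient = "MVPA",
                             minutes = 15, ci_method = "bootstrap",
                             data = f$data, B = 1000, seed = 3)
  w_delta <- sd_$ci_high - sd_$ci_low
  w_boot <- sb_$ci_high - sb_$ci_low
  expect_lt(abs(w_boot - w_delta) / w_delta, 0.15)
  expect_true(sb_$ci_low <= sd_$delta && sd_$delta <= sb_$ci_high)
})

test_that("penalized-spline fit nests the linear model on linear data", {
  cfg <- generator_config(n = 600, seed = 55)
  data <- generate_cohort(cfg)$data
  lin <- fit_outcome_model(data)
  g <- spline_dose_response(data)
  expect_true(g$deviance_explained >= lin$r_squared - 1e-8)
  expect_lt(abs(g$deviance_explained - lin$r_squared), 0.02)
  # on a low-noise linear cohort the smooth curves match the linear ones
  lo <- generate_cohort(generator_config(n = 600, seed = 56,
                                         noise_sd = 0.5))$data
  lin2 <- fit_outcome_model(lo)
  g2 <- spline_dose_response(lo, pairs = data.frame(donor = "SB",
                                                    recipient = "MVPA"),
                             grid = seq(5, 15, 5))
  lc <- dose_response_curves(lin2, reference = g2$reference,
                             pairs = data.frame(donor = "SB",
                                                recipient = "MVPA"),
                             grid = seq(5, 15, 5))
  expect_lt(max(abs(g2$curves$delta - lc$delta)), 0.2)
})

test_that("pure-noise covariates barely move the GCV deviance explained", {
  cfg <- generator_config(n = 986, seed = 77)
  data <- generate_cohort(cfg)$data
  g0 <- spline_dose_response(data)
  set.seed(123)
  data$noise1 <- rnorm(nrow(data))
  data$noise2 <- rnorm(nrow(data))
  g1 <- spline_dose_response(data, covariates = c("gender", "age",
                                                  "residence", "noise1",
                                                  "noise2"))
  expect_lt(abs(g1$deviance_explained - g0$deviance_explained), 0.03)
})
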