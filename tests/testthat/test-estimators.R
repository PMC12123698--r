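## Independent brute-force evaluation of the weight formulas, written as
## plain loops over subjects so it shares no code with the package versions.
brute_tnr_weights <- function(cohort, t, h) {
  n <- cohort$n
  num <- numeric(n)
  for (i in seq_len(n)) {
    b <- cohort$biopsies[cohort$biopsies$id == i, ]
    for (k in seq_len(nrow(b))) {
      if (b$result[k] == 0) {
        u <- (b$time[k] - t) / h
        if (abs(u) <= 1) num[i] <- num[i] + 0.75 * (1 - u^2) / h
      }
    }
  }
  elig <- cohort$last_obs > t
  w <- num / mean(num[elig])
  w[!elig] <- 0
  w
}

brute_tpr_weights <- function(cohort, s, tau, h) {
  n <- cohort$n
  num <- numeric(n)
  for (i in seq_len(n)) {
    b <- cohort$biopsies[cohort$biopsies$id == i, ]
    times <- c(0, b$time)
    res <- c(0, b$result)
    for (k in seq_len(nrow(b)) + 1) {
      if (res[k] == 1 && res[k - 1] == 0) {
        u <- (times[k] - s - tau) / h
        v <- (times[k - 1] - s) / h
        if (abs(u) <= 1 && abs(v) <= 1) {
          num[i] <- num[i] + 0.75^2 * (1 - u^2) * (1 - v^2) / h^2
        }
      }
    }
  }
  num / mean(num)
}

test_that("TNR weights renormalize the eligible subset to mean one", {
  ## two eligible subjects; only the first has a negative biopsy at t
  coh <- toy_cohort(list(c(50, 90), c(90)), list(c(0, 0), c(0)))
  w <- tnr_weights(coh, 50, 5, warn_boundary = FALSE)
  expect_equal(w, c(2, 0))
  ## no biopsy in [t - h, t + h]
  expect_error(tnr_weights(coh, 70, 5, warn_boundary = FALSE),
               class = "noSupportError")
  ## ineligible subjects (last biopsy before t) are zeroed out
  coh2 <- toy_cohort(list(c(50, 90), c(50)), list(c(0, 0), c(0)))
  w2 <- tnr_weights(coh2, 50, 5, warn_boundary = FALSE)
  expect_equal(w2[2], 0)
  expect_equal(mean(w2[coh2$last_obs > 50]), 1)
})

test_that("TNR weights match a brute-force evaluation of the formula", {
  coh <- toy_cohort(
    list(c(20, 45, 62), c(38, 55), c(47, 70, 95), c(52), c(30, 58, 80)),
    list(c(0, 0, 0), c(0, 1), c(0, 0, 0), c(0), c(0, 0, 1)))
  for (t in c(45, 55, 70)) {
    expect_equal(tnr_weights(coh, t, 10, warn_boundary = FALSE),
                 brute_tnr_weights(coh, t, 10), tolerance = 1e-12)
  }
})

test_that("pair weights concentrate on adjacent negative-positive pairs", {
  ## single-support case: one subject holds the whole mass
  coh <- toy_cohort(list(c(30, 55), c(40, 70), c(90)),
                    list(c(0, 1), c(0, 0), c(0)))
  w <- tpr_weights(coh, 30, 25, 12)
  expect_equal(w, c(3, 0, 0))   # n / (number of contributing subjects)
  ## negative-only subjects never contribute
  expect_equal(w[2], 0)
  expect_error(tpr_weights(coh, 90, 25, 12), class = "noSupportError")
})

test_that("pair weights match a brute-force evaluation of the formula", {
  coh <- toy_cohort(
    list(c(28, 52), c(33, 58), c(40, 66, 90), c(25, 49), c(70), c(18, 44)),
    list(c(0, 1), c(0, 1), c(0, 0, 0), c(0, 0), c(1), c(0, 1)))
  for (s in c(30, 44)) {
    expect_equal(tpr_weights(coh, s, 24, 12),
                 brute_tpr_weights(coh, s, 24, 12), tolerance = 1e-12)
  }
})

test_that("weight systems average to one on simulated cohorts", {
  coh <- cached_cohort(300, seed = 5)
  bw <- bandwidths(48, coh$n)
  for (s in c(24, 48, 72)) {
    wp <- tryCatch(tpr_weights(coh, s, 24, bw$h_tilde),
                   noSupportError = function(e) NULL)
    if (!is.null(wp)) expect_equal(mean(wp), 1, tolerance = 1e-10)
    wn <- tryCatch(tnr_weights(coh, s + 24, bw$h, warn_boundary = FALSE),
                   noSupportError = function(e) NULL)
    if (!is.null(wn)) {
      expect_equal(mean(wn[coh$last_obs > s + 24]), 1, tolerance = 1e-10)
      expect_true(all(wn >= 0))
    }
  }
})

test_that("trivial rules give exact TPR and TNR values", {
  coh <- cached_cohort(300, seed = 5)
  bw <- bandwidths(48, coh$n)
  expect_equal(estimate_tpr(coh, +1, 48, 24, bw$h_tilde), 1)
  expect_equal(estimate_tpr(coh, -1, 48, 24, bw$h_tilde), 0)
  expect_equal(suppressWarnings(estimate_tnr(coh, -1, 48, 24, bw$h)), 1)
  expect_equal(suppressWarnings(estimate_tnr(coh, +1, 48, 24, bw$h)), 0)
})

test_that("complementary rules have rates summing to one", {
  coh <- cached_cohort(300, seed = 5)
  bw <- bandwidths(48, coh$n)
  rule <- reference_rule()
  anti <- function(Z) -rule_decide(rule, Z)
  for (s in c(24, 48)) {
    expect_equal(estimate_tpr(coh, rule, s, 24, bw$h_tilde) +
                   estimate_tpr(coh, anti, s, 24, bw$h_tilde), 1,
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(
      estimate_tnr(coh, rule, s, 24, bw$h) +
        estimate_tnr(coh, anti, s, 24, bw$h)), 1, tolerance = 1e-10)
  }
})

test_that("kernel TPR/TNR track the oracle when tau sits inside the gap support", {
  ## with T_gap = 12 the window (s, s + 24] is interior to the pair-gap
  ## distribution, so the estimators should be close to the truth
  cfg <- scenario_config(1, T_gap = 12)
  coh <- cached_cohort(2000, seed = 42, config = cfg)
  bw <- bandwidths(48, coh$n)
  rule <- reference_rule()
  for (s in c(24, 48)) {
    orc <- oracle_performance(coh, rule, s, 24)
    expect_lt(abs(estimate_tpr(coh, rule, s, 24, bw$h_tilde) - orc$tpr), 0.05)
    expect_lt(abs(suppressWarnings(
      estimate_tnr(coh, rule, s, 24, bw$h)) - orc$tnr), 0.05)
  }
})

test_that("conditional progression probability has the exact degenerate limits", {
  ## all pairs negative-negative near (s, s + tau): clipped zero under
  ## every method (no event is ever bracketed)
  coh <- toy_cohort(rep(list(c(48, 72)), 10), rep(list(c(0, 0)), 10))
  expect_equal(estimate_rho(coh, 48, 24, 10, method = "ll"), 1e-6)
  expect_equal(estimate_rho(coh, 48, 24, 10, method = "nw"), 1e-6)
  expect_equal(estimate_rho(coh, 48, 24), 1e-6)
  ## equal negative-positive and negative-negative mass: one half
  coh2 <- toy_cohort(rep(list(c(48, 72)), 4),
                     list(c(0, 1), c(0, 0), c(0, 1), c(0, 0)))
  expect_equal(estimate_rho(coh2, 48, 24, 10, method = "ll"), 0.5)
  expect_equal(estimate_rho(coh2, 48, 24, 10, method = "nw"), 0.5)
  expect_error(estimate_rho(coh2, 130, 24, 5, method = "ll"),
               class = "noSupportError")
})

test_that("rho estimates approach the Monte-Carlo truth", {
  cfg <- scenario_config(1, T_gap = 12)
  coh <- cached_cohort(2000, seed = 42, config = cfg)
  bw <- bandwidths(48, coh$n)
  tt <- mc_event_times(2e5, cfg)
  for (s in c(48, 72)) {
    truth <- sum(tt > s & tt <= s + 24) / sum(tt > s)
    expect_lt(abs(estimate_rho(coh, s, 24) - truth), 0.05)
    expect_lt(abs(estimate_rho(coh, s, 24, bw$h_tilde, method = "ll") - truth),
              0.05)
  }
})

test_that("the bracket-likelihood survival fit tracks the sampler's survival", {
  coh <- cached_cohort(2000, seed = 42, config = scenario_config(1, T_gap = 12))
  S <- tailoras:::pch_survival(coh, 24)
  tt <- mc_event_times(2e5, scenario_config(1, T_gap = 12))
  for (t0 in c(36, 60, 84, 108)) {
    expect_lt(abs(S(t0) - mean(tt > t0)), 0.04)
  }
  expect_equal(S(0), 1)
  expect_true(all(diff(S(seq(12, 150, by = 6))) <= 1e-12))
})

test_that("cost-benefit weight transforms rho exactly", {
  expect_equal(xi_from_rho(0.2, 4), 1)
  expect_equal(xi_from_rho(0.5, 2), 0.5)
  rhos <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(xi_from_rho(rhos, 3)) < 0))   # monotone to 0 as rho -> 1
  expect_lt(xi_from_rho(1 - 1e-6, 1), 1e-5)
  expect_error(xi_from_rho(0, 2), "rho")
  expect_error(xi_from_rho(1.2, 2), "rho")
})

test_that("weighted-benefits value combines landmarks as a plain average", {
  coh <- cached_cohort(300, seed = 5)
  bw <- bandwidths(48, coh$n)
  ## constant rules under fixed xi: exact endpoints
  expect_equal(suppressWarnings(
    estimate_value(coh, +1, c(24, 48), tradeoff_fixed(0.7), 24, bw)), 1)
  expect_equal(suppressWarnings(
    estimate_value(coh, -1, c(24, 48), tradeoff_fixed(0.7), 24, bw)), 0.7)
  ## hand-composed average for a nontrivial rule
  rule <- reference_rule()
  expected <- mean(vapply(c(24, 48), function(s)
    estimate_tpr(coh, rule, s, 24, bw$h_tilde) +
      0.7 * suppressWarnings(estimate_tnr(coh, rule, s, 24, bw$h)),
    numeric(1)))
  expect_equal(suppressWarnings(
    estimate_value(coh, rule, c(24, 48), tradeoff_fixed(0.7), 24, bw)),
    expected)
})

test_that("unsupported landmarks are dropped with a warning and reduce J", {
  coh <- toy_cohort(
    list(c(28, 52), c(33, 58), c(40, 66), c(25, 49, 80), c(30, 61, 85)),
    list(c(0, 1), c(0, 1), c(0, 0), c(0, 0, 0), c(0, 0, 0)),
    config = scenario_config(landmarks = c(30, 120)))
  bw <- list(h = 10, h_tilde = 12)
  ## landmark 120 has no support at all; value falls back to landmark 30
  expect_warning(
    v <- estimate_value(coh, +1, c(30, 120), tradeoff_fixed(1), 24, bw),
    "unsupported")
  expect_equal(v, 1)
  expect_error(
    suppressWarnings(estimate_value(coh, +1, c(120), tradeoff_fixed(1), 24, bw)),
    class = "noSupportError")
})
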