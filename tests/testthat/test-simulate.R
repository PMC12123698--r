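cfg1 <- scenario_config(1)

test_that("event-time transform hits its closed-form anchors", {
  cfg <- cfg1
  a0 <- matrix(0.3, 1, 4)
  a1 <- matrix(-0.2, 1, 4)
  ## zero exponential draw collapses the bracket: T = entry offset exactly
  expect_equal(tailoras:::event_time_from_exp(0, a0, a1, cfg), 12)
  ## strictly increasing in the exponential draw when gamma > 0
  tt <- tailoras:::event_time_from_exp(c(0.1, 0.5, 1, 3), a0[rep(1, 4), , drop = FALSE],
                                       a1[rep(1, 4), , drop = FALSE], cfg)
  expect_true(all(diff(tt) > 0))
})

test_that("latent trajectories are linear in log time", {
  cfg <- cfg1
  lat <- list(a0 = matrix(c(0.5, 1, -2, 0), 1, 4),
              a1 = matrix(c(0.2, 0, 0.3, -1), 1, 4))
  expect_equal(covariate_value(lat, 1, cfg$nu, cfg), 0.5)  # log(t/nu) = 0
  expect_equal(covariate_value(lat, 2, 7, cfg), 1)         # flat trajectory
  expect_error(covariate_value(lat, 1, -3, cfg), "positive")
})

test_that("measurement noise has the configured variance", {
  cfg <- cfg1
  lat <- list(a0 = matrix(0, 1e5, 4), a1 = matrix(0, 1e5, 4))
  set.seed(11)
  x <- covariate_value(lat, 2, 40, cfg, with_noise = TRUE)
  v <- var(x)
  se <- 0.1 * sqrt(2 / (1e5 - 1))    # SE of a normal sample variance
  expect_lt(abs(v - 0.1), 3 * se)
})

test_that("biopsy schedules respect the gap bounds and stopping rule", {
  cfg <- scenario_config(1, T_gap = 24)
  set.seed(21)
  gaps <- c()
  for (i in 1:500) {
    sch <- draw_biopsy_schedule(cfg)
    expect_gte(sch[1], 12)
    expect_lte(sch[1], 72)
    g <- diff(sch)
    expect_true(all(g >= 24 & g <= 72))
    ## stopping rule: scheduling continued while last + T_gap <= horizon
    expect_gt(sch[length(sch)] + 24, 150)
    gaps <- c(gaps, g)
  }
  ## wide gap: at most two biopsies can be scheduled
  cfg80 <- scenario_config(1, T_gap = 80)
  for (i in 1:50) expect_lte(length(draw_biopsy_schedule(cfg80)), 2)
})

test_that("consecutive gaps are uniform on [T_gap, 3 T_gap]", {
  cfg <- scenario_config(1, T_gap = 24)
  set.seed(31)
  gaps <- unlist(replicate(10000, diff(draw_biopsy_schedule(cfg)),
                           simplify = FALSE))
  ks <- suppressWarnings(ks.test(gaps, "punif", 24, 72))
  expect_gt(ks$p.value, 0.01)
})

test_that("observation walk applies censoring, missingness and dropout", {
  cfg <- cfg1
  ## progression at 50 detected at 55; later biopsies unobserved
  o <- assemble_observed(50, 100, c(30, 55, 80), cfg)
  expect_equal(o$times, c(30, 55))
  expect_equal(o$results, c(0L, 1L))
  expect_true(o$dropped_out)
  ## censoring before the detecting biopsy truncates the sequence
  o <- assemble_observed(50, 40, c(30, 55, 80), cfg)
  expect_equal(o$times, 30)
  expect_equal(o$results, 0L)
  expect_false(o$dropped_out)
  ## a missed appointment skips that biopsy; adjacency re-links around it
  o <- assemble_observed(50, Inf, c(30, 55, 80), cfg,
                         miss = c(FALSE, TRUE, FALSE))
  expect_equal(o$times, c(30, 80))
  expect_equal(o$results, c(0L, 1L))
  ## without dropout the walk continues past positives (current-status mode)
  o <- assemble_observed(50, Inf, c(30, 55, 80), cfg, dropout = FALSE)
  expect_equal(o$results, c(0L, 1L, 1L))
})

test_that("cohorts are reproducible and satisfy the observation invariants", {
  cfg <- scenario_config(1, T_gap = 24)
  a <- simulate_cohort(500, cfg, seed = 7)
  b <- simulate_cohort(500, cfg, seed = 7)
  expect_identical(a$biopsies, b$biopsies)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
  ## at most one positive per subject, positioned last
  by_id <- split(a$biopsies, a$biopsies$id)
  for (s in by_id) {
    expect_true(all(diff(s$time) > 0))
    expect_lte(sum(s$result), 1L)
    if (any(s$result == 1L)) expect_equal(s$result[nrow(s)], 1L)
  }
  ## no biopsy beyond min(C, detection time); results match the truth
  tr <- a$truth
  m <- merge(a$biopsies, tr, by = "id")
  expect_true(all(m$time < m$C))
  expect_identical(m$result, as.integer(m$T <= m$time))
  ## truth aligns one-to-one with subjects
  expect_identical(tr$id, seq_len(a$n))
})

test_that("with no censoring or missingness the bracketing pair is observed", {
  cfg <- scenario_config(1, T_gap = 24)
  coh <- simulate_cohort(300, cfg, seed = 13, censoring = FALSE)
  pr <- coh$pairs
  np <- pr[pr$res_prev == 0L & pr$res_curr == 1L, ]
  tr <- coh$truth
  detected <- tr$T <= sapply(split(coh$biopsies$time, coh$biopsies$id), max)[
    as.character(tr$id)]
  detected[is.na(detected)] <- FALSE
  ## every subject whose event occurred before the last scheduled biopsy has
  ## exactly one negative-positive pair, and it brackets T
  expect_setequal(np$id, tr$id[detected])
  m <- merge(np, tr, by = "id")
  expect_true(all(m$t_prev < m$T & m$T <= m$t_curr))
})

test_that("marginal survival of simulated event times matches the implied hazard", {
  ## Oracle: numerically integrate the hazard implied by the generator,
  ## lambda(t) = (shape / nu) exp(eta0) ((t - 12) / nu)^(gamma - 1), and
  ## compare with empirical survival from the inverse-transform sampler.
  cfg <- cfg1
  avals <- list(c(0.3, 0.1, -0.4, 0.2), c(-0.1, -0.1, -0.1, -0.1),
                c(0.5, -0.8, 0.6, 0))
  a1v <- c(-0.1, 0.05, -0.2, 0.1)
  for (a0v in avals) {
    a0 <- matrix(a0v, 1, 4)
    a1 <- matrix(a1v, 1, 4)
    gam <- tailoras:::latent_gamma(a1, cfg)
    eta0 <- tailoras:::latent_eta0(a0, cfg)
    set.seed(101)
    n <- 1e5
    tt <- tailoras:::event_time_from_exp(rexp(n), a0[rep(1, n), , drop = FALSE],
                                         a1[rep(1, n), , drop = FALSE], cfg)
    for (t0 in c(30, 60, 100)) {
      cumhaz <- integrate(function(u)
        (cfg$nu_shape / cfg$nu) * exp(eta0) * ((u - 12) / cfg$nu)^(gam - 1),
        12, t0, rel.tol = 1e-10)$value
      s_true <- exp(-cumhaz)
      s_emp <- mean(tt > t0)
      se <- sqrt(s_true * (1 - s_true) / n)
      expect_lt(abs(s_emp - s_true), 3 * se + 1e-12)
    }
  }
})

test_that("cohort-level event frequency is self-consistent with the sampler", {
  coh <- cached_cohort(2000, seed = 77)
  p_emp <- mean(coh$truth$T <= 150)
  tt <- mc_event_times(1e6)
  p_mc <- mean(tt <= 150)
  se <- sqrt(p_mc * (1 - p_mc) * (1 / 2000 + 1 / 1e6))
  expect_lt(abs(p_emp - p_mc), 3 * se)
})

test_that("degenerate configurations are rejected after bounded resampling", {
  ## shape forced negative with certainty: slopes huge and negative
  cfg <- scenario_config(1, slope_mean = c(-0.1, 10),
                         slope_cov = matrix(c(1e-8, 0, 0, 1e-8), 2, 2))
  expect_error(simulate_cohort(5, cfg, seed = 1), "degenerate")
})
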