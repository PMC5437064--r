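test_that("MSD matches hand evaluation and is time-reversal symmetric", {
  # y = (0, 1, 2) um: MSD(1) = 1, MSD(2) = 4
  m <- compute_msd(c(0, 1, 2), n_max = 2, dt = 0.05)
  expect_equal(m$msd_um2, c(1, 4))
  expect_equal(m$interval_s, c(0.05, 0.10))
  expect_equal(m$n_pairs, c(2L, 1L))

  flat <- compute_msd(rep(2.5, 50), n_max = 10, dt = 0.05)
  expect_true(all(flat$msd_um2 == 0))

  set.seed(5)
  y <- cumsum(rnorm(80))
  expect_equal(compute_msd(y, 10, 0.05)$msd_um2,
               compute_msd(rev(y), 10, 0.05)$msd_um2)

  expect_error(compute_msd(1:5, n_max = 10), "at least 11")
})

test_that("MSD equals the brute-force double loop on random trajectories", {
  set.seed(17)
  for (i in 1:100) {
    y <- cumsum(rnorm(sample(15:60, 1)))
    n_max <- sample(2:8, 1)
    expect_equal(compute_msd(y, n_max, 0.05)$msd_um2, brute_msd(y, n_max),
                 tolerance = 1e-12)
  }
})

test_that("D estimation inverts an exact MSD line and flags flat curves", {
  msd <- tibble::tibble(lag = 1:10, interval_s = (1:10) * 0.05,
                        msd_um2 = 2 * 0.5 * (1:10) * 0.05, n_pairs = 100L)
  est <- estimate_D(msd)
  expect_equal(est$D_um2_s, 0.5, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_false(est$clamped)

  # noise offset goes into the intercept, not D
  msd$msd_um2 <- msd$msd_um2 + 0.02
  est2 <- estimate_D(msd)
  expect_equal(est2$D_um2_s, 0.5, tolerance = 1e-12)
  expect_equal(est2$intercept, 0.02, tolerance = 1e-12)
  # through-origin option
  est0 <- estimate_D(msd, intercept = FALSE)
  expect_gt(est0$D_um2_s, 0.5)

  flat <- tibble::tibble(lag = 1:5, interval_s = (1:5) * 0.05,
                         msd_um2 = rep(0.3, 5), n_pairs = 50L)
  ef <- estimate_D(flat)
  expect_equal(ef$D_um2_s, 0)
  expect_error(estimate_D(flat, n_max = 9), "available")
})

test_that("D estimator bias is < 5% noise-free and slope bias < 10% with noise", {
  p <- experiment_preset("yPCNA_homoduplex")
  D_hat <- vapply(1:200, function(s) {
    tr <- simulate_trajectory(p, 0.1, 2000, 6.5, seed = s,
                              loc_noise_sd_um = 0)
    estimate_D(compute_msd(tr, 10))$D_um2_s
  }, numeric(1))
  expect_lt(abs(mean(D_hat) - 0.1) / 0.1, 0.05)

  with_noise <- vapply(1:100, function(s) {
    tr <- simulate_trajectory(p, 0.1, 2000, 6.5, seed = s,
                              loc_noise_sd_um = 0.05)
    est <- estimate_D(compute_msd(tr, 10))
    c(est$D_um2_s, est$intercept)
  }, numeric(2))
  expect_lt(abs(mean(with_noise[1, ]) - 0.1) / 0.1, 0.10)
  expect_gt(mean(with_noise[2, ]), 0) # intercept absorbs the offset
})

test_that("salt slope is exact on exact linear means and 0 on constant D", {
  flat <- tibble::tibble(conc_mM = rep(c(50, 75, 100), each = 5),
                         D_um2_s = 0.4)
  expect_warning(s0 <- salt_slope(flat), "fewer than")
  expect_equal(s0$slope_um2_s_mM, 0, tolerance = 1e-12)

  lin <- tibble::tibble(conc_mM = rep(c(50, 75, 100), each = 5))
  lin$D_um2_s <- 0.2 + 0.1 * (lin$conc_mM - 50)
  expect_warning(s1 <- salt_slope(lin), "fewer than")
  expect_equal(s1$slope_um2_s_mM, 0.1, tolerance = 1e-10)

  expect_error(salt_slope(tibble::tibble(conc_mM = 50, D_um2_s = 1)),
               "2 distinct")
})

test_that("behavior classifier matches hand labels on a golden fixture set", {
  site <- 21.3
  ramp <- function(from, to, n = 100) seq(from, to, length.out = n)
  cases <- list(
    list(y = rep(site - 10, 100), label = "no_encounter"),   # parked far away
    list(y = ramp(site - 3, site + 3), label = "bypass"),    # monotone up
    list(y = ramp(site + 3, site - 3), label = "bypass"),    # monotone down
    list(y = c(ramp(site - 3, site - 0.5, 50),
               ramp(site - 0.5, site - 3, 50)), label = "blocked"),
    list(y = c(ramp(site + 3, site + 0.5, 50),
               ramp(site + 0.5, site + 3, 50)), label = "blocked"),
    list(y = rep(site, 100), label = "captured"),            # pinned
    list(y = rep(site + 1.0, 100), label = "captured"),      # pinned in zone
    # wanders out of the zone on one side only, large excursions
    list(y = c(ramp(site, site - 4, 50), ramp(site - 4, site, 50)),
         label = "blocked"),
    # crossing with a dip is still a bypass
    list(y = c(ramp(site - 3, site + 2, 60), ramp(site + 2, site + 3, 40)),
         label = "bypass"),
    list(y = rep(site - 1.51, 100), label = "no_encounter"), # just outside
    # stationary but outside the zone: small sd does not mean captured
    list(y = rep(site - 2, 100) + rnorm(100, 0, 0.05), label = "no_encounter"),
    # enters from above and retreats
    list(y = c(ramp(site + 2, site + 1.2, 30), ramp(site + 1.2, site + 2, 70)),
         label = "blocked")
  )
  set.seed(12)
  for (i in seq_along(cases)) {
    got <- classify_behavior(cases[[i]]$y, site)$label
    expect_equal(got, cases[[i]]$label, info = paste("case", i))
  }
})

test_that("classification precedence prefers captured over bypass/blocked", {
  site <- 21.3
  # loaded at the site, essentially stationary: captured even though it
  # grazes the zone the whole time
  y <- site + rnorm(200, 0, 0.05)
  expect_equal(classify_behavior(y, site)$label, "captured")
})

test_that("survival MLE equals the closed-form exponential estimators", {
  # all dwells equal T, uncensored: t_half = T ln 2 exactly
  fitT <- fit_survival(rep(8, 20), B = 100, seed = 1)
  expect_equal(fitT$t_half_s, 8 * log(2), tolerance = 1e-12)

  # uncensored MLE = ln 2 x sample mean to machine precision
  d <- simulate_dwell_times(15, 200, Inf, seed = 3)
  fit <- fit_survival(d, B = 100, seed = 1)
  expect_equal(fit$t_half_s, log(2) * mean(d$dwell_s), tolerance = 1e-12)

  # censored: total time on test / events, exactly
  dc <- simulate_dwell_times(100, 200, t_obs = 60, seed = 4)
  fc <- fit_survival(dc, B = 100, seed = 1)
  expect_equal(fc$t_half_s,
               log(2) * sum(dc$dwell_s) / sum(!dc$censored),
               tolerance = 1e-12)
  expect_gt(fc$n_censored, 0)
  expect_true(fc$ci_lo <= fc$t_half_s && fc$t_half_s <= fc$ci_hi)

  all_cens <- tibble::tibble(dwell_s = rep(5, 10), censored = TRUE)
  expect_error(fit_survival(all_cens), "censored")
  few <- tibble::tibble(dwell_s = c(1, 2, 3, 50), censored = c(rep(FALSE, 3), TRUE))
  expect_error(fit_survival(few), "at least 5")
})

test_that("censored MLE agrees with survreg's exponential fit", {
  skip_if_not_installed("survival")
  d <- simulate_dwell_times(30, 150, t_obs = 40, seed = 5)
  ours <- fit_survival(d, B = 100, seed = 1)
  sr <- survival::survreg(
    survival::Surv(d$dwell_s, !d$censored) ~ 1, dist = "exponential")
  expect_equal(ours$mean_s, exp(unname(coef(sr))), tolerance = 1e-6)
})

test_that("least-squares survival fit approximates the MLE on clean data", {
  d <- simulate_dwell_times(20, 500, Inf, seed = 6)
  mle <- fit_survival(d, B = 100, seed = 1)
  ls <- fit_survival(d, method = "ls", B = 100, seed = 1)
  expect_lt(abs(ls$t_half_s - mle$t_half_s) / mle$t_half_s, 0.15)
})
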