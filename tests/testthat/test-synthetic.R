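test_that("identical preset and seed give bit-identical generator output", {
  p <- experiment_preset("yPCNA_flap")
  expect_identical(simulate_binding_positions(p, 500, seed = 3),
                   simulate_binding_positions(p, 500, seed = 3))
  expect_identical(simulate_trajectory(p, 0.2, 300, 5, seed = 3),
                   simulate_trajectory(p, 0.2, 300, 5, seed = 3))
  expect_identical(simulate_dwell_times(21, 63, 300, seed = 3),
                   simulate_dwell_times(21, 63, 300, seed = 3))
  pos <- tibble::tibble(frame = 0L, x_px = 12.2, y_px = 9.1)
  expect_identical(render_frames(pos, c(20L, 20L), seed = 3),
                   render_frames(pos, c(20L, 20L), seed = 3))
})

test_that("pure-background preset is uniform over the substrate", {
  x <- simulate_binding_positions(experiment_preset("yPCNA_homoduplex"),
                                  n = 1e4, seed = 1)
  expect_true(all(x$position_kb >= 0 & x$position_kb <= 48.502))
  ks <- suppressWarnings(
    stats::ks.test(x$position_kb, "punif", 0, 48.502))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate site component (sd 0, no jitter) collapses to the site", {
  p <- experiment_preset("yPCNA_flap")
  p$mixture <- tibble::tibble(
    component = c("site1", "background"),
    center_kb = c(21.3, NA), sd_kb = c(0, NA), weight = c(1, 0)
  )
  x <- simulate_binding_positions(p, 200, seed = 2)
  expect_true(all(x$position_kb == 21.3))
})

test_that("empirical site fraction matches the mixture weight (3 binomial SDs)", {
  p <- experiment_preset("yPCNA_flap")
  w <- p$mixture$weight[p$mixture$component == "site1"]
  n <- 1e5
  x <- simulate_binding_positions(p, n, seed = 5)
  frac <- mean(x$component == "site1")
  expect_lt(abs(frac - w), 3 * sqrt(w * (1 - w) / n))
})

test_that("all-zero mixture weights are a configuration error", {
  p <- experiment_preset("yPCNA_homoduplex")
  p$mixture$weight <- 0
  expect_error(simulate_binding_positions(p, 10, 1), "positive weights")
})

test_that("trajectories respect D = 0, tether ends, and site interactions", {
  p <- experiment_preset("yPCNA_homoduplex")
  flat <- simulate_trajectory(p, 0, 100, 5, seed = 1, loc_noise_sd_um = 0)
  expect_true(all(flat$y_um == 5))
  expect_error(simulate_trajectory(p, -1, 100, 5), ">= 0")
  expect_error(simulate_trajectory(p, 1, 100, 20), "within")

  # reflecting tether ends: never outside [0, 13] even at large D, with noise
  hot <- simulate_trajectory(p, 5, 3000, 6.5, seed = 2)
  expect_true(all(hot$y_um >= 0 & hot$y_um <= 13))

  # reflecting site: a walker starting below the site never crosses it
  site_um <- 21.3 * 13 / 48.502
  for (s in 1:5) {
    tr <- simulate_trajectory(p, 0.5, 1000, site_um - 2, seed = s,
                              site_interaction = "reflecting",
                              site_um = site_um)
    expect_true(all(tr$y_um <= site_um))
  }

  # trapping pins the molecule at the site (localization noise only)
  trap <- simulate_trajectory(p, 0.5, 500, site_um, seed = 3,
                              site_interaction = "trapping",
                              site_um = site_um)
  expect_lt(sd(trap$y_um), 0.05)
  expect_lt(abs(mean(trap$y_um) - site_um), 0.01)
})

test_that("fitted D from the generator's own output recovers the input D", {
  p <- experiment_preset("yPCNA_homoduplex")
  D <- vapply(1:50, function(s) {
    tr <- simulate_trajectory(p, 0.1, 2000, 6.5, seed = s,
                              loc_noise_sd_um = 0)
    estimate_D(compute_msd(tr, n_max = 10))$D_um2_s
  }, numeric(1))
  se <- sd(D) / sqrt(length(D))
  expect_lt(abs(mean(D) - 0.1), 3 * se + 0.005)
})

test_that("dwell-time draws have the exponential mean and censor correctly", {
  d <- simulate_dwell_times(10, 1e5, Inf, seed = 1)
  expect_false(any(d$censored))
  expect_lt(abs(mean(d$dwell_s) - 10 / log(2)) / (10 / log(2)), 0.01)

  cens <- simulate_dwell_times(1e9, 50, t_obs = 30, seed = 1)
  expect_true(all(cens$censored))
  expect_true(all(cens$dwell_s == 30))

  expect_error(simulate_dwell_times(-1, 10), "> 0")
  expect_error(simulate_dwell_times(10, 0), ">= 1")
})

test_that("rendered frames have the right background, centroid, and photon count", {
  opt <- curtain_optics(background = 10)
  blank <- render_frames(tibble::tibble(frame = integer(), x_px = double(),
                                        y_px = double()),
                         dims = c(32L, 32L), n_frames = 4, optics = opt,
                         seed = 9)
  # mean equals background within Poisson error of the pooled pixels
  n_px <- 32 * 32 * 4
  expect_lt(abs(mean(blank) - 10), 3 * sqrt(10 / n_px) + 0.5)

  # sub-pixel emitter, zero noise: intensity-weighted centroid is exact
  st <- render_single_emitter(10.30, 7.60, noise = FALSE, background = 0)
  f <- st[, , 1]
  expect_lt(abs(sum(col(f) * f) / sum(f) - 10.30), 0.01)
  expect_lt(abs(sum(row(f) * f) / sum(f) - 7.60), 0.01)

  # Poisson conservation: ROI sum over background ~ photons per frame
  stn <- render_single_emitter(16.4, 12.6, seed = 4, photons = 1000)
  roi <- stn[6:19, 10:23, 1]
  signal <- sum(roi) - 10 * length(roi)
  expect_lt(abs(signal - 1000), 3 * sqrt(1000 + 10 * length(roi)))

  expect_error(render_frames(tibble::tibble(frame = 0L, x_px = 1, y_px = 1),
                             optics = curtain_optics(photon_rate = 0)),
               "photon rate")
})

test_that("TIFF stacks round-trip through disk unchanged", {
  skip_if_not_installed("tiff")
  st <- render_single_emitter(12.3, 9.7, seed = 2)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(st))
  expect_equal(as.vector(back), as.vector(st))
})

test_that("behavior fixtures carry the preset's exact category counts", {
  p <- experiment_preset("yPCNA_flap_dynamics")
  fx <- make_behavior_fixture(p, seed = 1)
  expect_equal(unname(table(fx$true_label[!duplicated(fx$molecule)])["blocked"]),
               36L)
  expect_equal(length(unique(fx$molecule)), 40L)
  expect_identical(make_behavior_fixture(p, seed = 1),
                   make_behavior_fixture(p, seed = 1))
})

test_that("salt-series generator encodes the linear D(c) model", {
  p <- experiment_preset("yPCNA_salt_series")
  traj <- simulate_salt_series(p, seed = 1, n_molecules = 2, n_frames = 50)
  byc <- unique(traj[, c("conc_mM", "D_true")])
  expect_equal(byc$D_true,
               0.3 + 0.25 * (byc$conc_mM - 50))
})
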