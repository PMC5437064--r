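#' Simulate binding positions from a preset's mixture model
#'
#' Positions are i.i.d. draws from the preset's binding mixture: each site
#' component is the site center plus uniform anchor jitter plus a Gaussian
#' residual (so that the component's total sd equals the preset value), and
#' the background component is uniform over the substrate. Draws falling
#' outside `[0, genome_kb]` are redrawn from the same component.
#'
#' @param preset An [experiment_preset()] of kind `binding`.
#' @param n Number of molecules (default: the preset's sample size).
#' @param seed Integer seed; identical preset + seed gives identical output.
#' @return A tibble with columns `molecule`, `position_kb`, `component`,
#'   `substrate`, `flowcell` and `on_dna` (a ready-made binding set).
#' @examples
#' simulate_binding_positions(experiment_preset("LacI_siteA"), n = 100, seed = 1)
#' @export
simulate_binding_positions <- function(preset, n = preset$n_default, seed = 1) {
  stopifnot(inherits(preset, "experiment_preset"))
  mix <- preset$mixture
  if (is.null(mix) || sum(mix$weight) <= 0) {
    stop("preset has no binding mixture with positive weights", call. = FALSE)
  }
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  geom <- preset$geometry
  set.seed(seed)
  comp <- sample(mix$component, n, replace = TRUE, prob = mix$weight)
  pos <- numeric(n)
  draw <- function(idx) {
    out <- numeric(length(idx))
    for (cname in unique(comp[idx])) {
      sel <- idx[comp[idx] == cname]
      row <- mix[mix$component == cname, ]
      if (cname == "background") {
        out[match(sel, idx)] <- stats::runif(length(sel), 0, geom$genome_kb)
      } else {
        p <- site_component_pars(row$sd_kb, geom)
        out[match(sel, idx)] <- row$center_kb +
          stats::runif(length(sel), -p$jitter_kb / 2, p$jitter_kb / 2) +
          (if (p$resid_sd > 0) stats::rnorm(length(sel), 0, p$resid_sd) else 0)
      }
    }
    out
  }
  todo <- seq_len(n)
  while (length(todo) > 0) {
    pos[todo] <- draw(todo)
    todo <- todo[pos[todo] < 0 | pos[todo] > geom$genome_kb]
  }
  tibble::tibble(
    molecule = seq_len(n), position_kb = pos, component = comp,
    substrate = preset$name, flowcell = 1L + (seq_len(n) - 1L) %% 3L,
    on_dna = TRUE
  )
}

# Fold x into [lo, hi] by reflection (triangle wave). Degenerate intervals
# collapse to lo.
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(x)))
  r <- (x - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

#' Simulate a 1D sliding trajectory on a tethered DNA molecule
#'
#' Discrete Brownian walk along the DNA axis with per-step displacements
#' Normal(0, 2 D dt), reflecting at the tether ends. An optional interaction
#' site either reflects the walker (steps across the site are reflected back,
#' so the walker stays on its starting side) or traps it (position pinned at
#' the site). Independent Gaussian localization noise is added to every
#' frame; positions always remain within `[0, tether_um]`.
#'
#' @param preset An [experiment_preset()] supplying geometry and optics.
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param n_frames Number of frames (>= 2).
#' @param start_um Starting position along the DNA, um from the barrier.
#' @param seed Integer seed.
#' @param site_interaction One of `"none"`, `"reflecting"`, `"trapping"`
#'   (default: the preset's setting).
#' @param site_um Interaction-site position in um (default: the preset's
#'   `site_kb` mapped through the geometry).
#' @param loc_noise_sd_um Localization noise sd in um (default from the
#'   preset's optics; set 0 for noise-free paths).
#' @return A tibble with columns `frame` (0-based), `t_s`, `y_um`, and
#'   attributes `frame_interval_s`, `tether_um`, `censored_start`,
#'   `censored_end`.
#' @export
simulate_trajectory <- function(preset, D, n_frames, start_um, seed = 1,
                                site_interaction = NULL, site_um = NULL,
                                loc_noise_sd_um = NULL) {
  stopifnot(inherits(preset, "experiment_preset"))
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  geom <- preset$geometry
  dt <- preset$optics$frame_interval_s
  L <- geom$tether_um
  if (start_um < 0 || start_um > L) {
    stop("start_um must lie within [0, tether length]", call. = FALSE)
  }
  site_interaction <- site_interaction %||% preset$site_interaction
  site_um <- site_um %||%
    (if (!is.na(preset$site_kb)) preset$site_kb * geom$um_per_kb else NA_real_)
  loc_noise_sd_um <- loc_noise_sd_um %||% preset$optics$loc_noise_sd_um
  set.seed(seed)
  if (identical(site_interaction, "trapping")) {
    y <- rep(site_um, n_frames)
    lo <- 0; hi <- L
  } else {
    steps <- if (D > 0) stats::rnorm(n_frames - 1, 0, sqrt(2 * D * dt)) else
      rep(0, n_frames - 1)
    raw <- start_um + cumsum(c(0, steps))
    if (identical(site_interaction, "reflecting") && !is.na(site_um)) {
      if (start_um <= site_um) { lo <- 0; hi <- site_um }
      else { lo <- site_um; hi <- L }
    } else {
      lo <- 0; hi <- L
    }
    y <- reflect_into(raw, lo, hi)
  }
  if (loc_noise_sd_um > 0) {
    y <- reflect_into(y + stats::rnorm(n_frames, 0, loc_noise_sd_um), lo, hi)
  }
  out <- tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    t_s = (seq_len(n_frames) - 1L) * dt,
    y_um = y
  )
  attr(out, "frame_interval_s") <- dt
  attr(out, "tether_um") <- L
  attr(out, "censored_start") <- TRUE
  attr(out, "censored_end") <- TRUE
  out
}

#' Simulate dwell times with observation-window censoring
#'
#' Dwell times are exponential with half-life `t_half` (mean
#' `t_half / ln 2`); dwells exceeding the observation window `t_obs` are
#' returned censored at `t_obs`.
#'
#' @param t_half Half-life in seconds (> 0).
#' @param n Number of molecules (>= 1).
#' @param t_obs Observation window in seconds (finite or `Inf`).
#' @param seed Integer seed.
#' @return A tibble with columns `molecule`, `dwell_s`, `censored`.
#' @examples
#' simulate_dwell_times(21, n = 63, t_obs = 300, seed = 1)
#' @export
simulate_dwell_times <- function(t_half, n, t_obs = Inf, seed = 1) {
  if (t_half <= 0) stop("t_half must be > 0", call. = FALSE)
  if (t_obs <= 0) stop("t_obs must be > 0 (or Inf)", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  t <- stats::rexp(n, rate = log(2) / t_half)
  cens <- t > t_obs
  tibble::tibble(
    molecule = seq_len(n),
    dwell_s = ifelse(cens, t_obs, t),
    censored = cens
  )
}

#' Simulate dwell times from a dwell preset
#'
#' @param preset An [experiment_preset()] of kind `dwell`.
#' @param n Sample size (default: the preset's measured N).
#' @param seed Integer seed.
#' @return See [simulate_dwell_times()].
#' @export
simulate_dwell_preset <- function(preset, n = NULL, seed = 1) {
  stopifnot(inherits(preset, "experiment_preset"))
  if (is.null(preset$dwell)) stop("preset has no dwell parameters", call. = FALSE)
  n <- n %||% preset$dwell$n
  simulate_dwell_times(preset$dwell$t_half_s, n, preset$dwell$t_obs_s, seed)
}

#' Simulate the salt-series diffusion experiment
#'
#' Simulates `n_molecules` trajectories at each NaCl concentration of the
#' preset's linear salt model `D(c) = D0 + slope (c - c0)`.
#'
#' @param preset An [experiment_preset()] of kind `salt`
#'   (e.g. `"yPCNA_salt_series"`).
#' @param seed Integer seed (per-molecule seeds are derived from it).
#' @param n_molecules,n_frames Override the preset's per-concentration
#'   molecule count and trajectory length.
#' @return A tibble of trajectories with columns `conc_mM`, `molecule`,
#'   `frame`, `t_s`, `y_um` and attribute `frame_interval_s`.
#' @export
simulate_salt_series <- function(preset = experiment_preset("yPCNA_salt_series"),
                                 seed = 1, n_molecules = NULL, n_frames = NULL) {
  dyn <- preset$dynamics
  if (is.null(dyn$concentrations_mM)) {
    stop("preset has no salt series", call. = FALSE)
  }
  n_molecules <- n_molecules %||% dyn$n_molecules
  n_frames <- n_frames %||% dyn$n_frames
  L <- preset$geometry$tether_um
  rows <- purrr::map_dfr(seq_along(dyn$concentrations_mM), function(ci) {
    conc <- dyn$concentrations_mM[ci]
    D <- dyn$d0_um2_s + dyn$salt_slope_um2_s_mM * (conc - dyn$c0_mM)
    purrr::map_dfr(seq_len(n_molecules), function(m) {
      tr <- simulate_trajectory(
        preset, D = D, n_frames = n_frames, start_um = L / 2,
        seed = derive_seed(seed, sprintf("salt_%d_%d", ci, m)),
        site_interaction = "none"
      )
      dplyr::mutate(tr, conc_mM = conc, molecule = m, D_true = D,
                    .before = 1)
    })
  })
  attr(rows, "frame_interval_s") <- preset$optics$frame_interval_s
  rows
}

# Deterministic idealized encounter paths used by the behavior fixtures.
# All paths are expressed in kb and carry iid localization noise only (no
# cumulative Brownian term), so their classification is unambiguous.
behavior_fixture_path <- function(label, site_kb, n_frames, noise_sd_kb, seed) {
  set.seed(seed)
  half <- n_frames %/% 2
  base <- switch(
    label,
    # approach from 3 kb below, turn around 0.2 kb short of the site
    blocked = c(seq(site_kb - 3, site_kb - 0.2, length.out = half),
                seq(site_kb - 0.2, site_kb - 3,
                    length.out = n_frames - half)),
    # loaded at the site and pinned there
    captured = rep(site_kb, n_frames),
    # steady crossing from 3 kb below to 3 kb above
    bypass = seq(site_kb - 3, site_kb + 3, length.out = n_frames),
    # parked far from the site
    no_encounter = rep(site_kb - 10, n_frames),
    stop("unknown behavior label '", label, "'", call. = FALSE)
  )
  base + stats::rnorm(n_frames, 0, noise_sd_kb)
}

#' Deterministic behavior-classification fixture set
#'
#' Generates idealized encounter trajectories with *exact* category counts
#' taken from the preset (e.g. 36 blocked / 2 captured / 2 bypass for the
#' 5'-flap experiment), so downstream classification percentages are
#' deterministic. Paths are prescribed shapes (approach-and-reverse for
#' blocked, pinned for captured, steady crossing for bypass) plus independent
#' localization noise.
#'
#' @param preset An [experiment_preset()] of kind `behavior`.
#' @param n_frames Frames per trajectory.
#' @param noise_sd_kb Localization noise sd in kb.
#' @param seed Integer seed.
#' @return A tibble with columns `molecule`, `true_label`, `frame`,
#'   `position_kb` plus attributes `site_kb` and `frame_interval_s`.
#' @export
make_behavior_fixture <- function(preset, n_frames = 200, noise_sd_kb = 0.05,
                                  seed = 1) {
  stopifnot(inherits(preset, "experiment_preset"))
  counts <- preset$behavior_counts
  if (is.null(counts)) stop("preset has no behavior counts", call. = FALSE)
  labels <- rep(names(counts), counts)
  out <- purrr::map_dfr(seq_along(labels), function(i) {
    tibble::tibble(
      molecule = i, true_label = labels[i],
      frame = seq_len(n_frames) - 1L,
      position_kb = behavior_fixture_path(
        labels[i], preset$site_kb, n_frames, noise_sd_kb,
        derive_seed(seed, sprintf("behavior_%d", i))
      )
    )
  })
  attr(out, "site_kb") <- preset$site_kb
  attr(out, "frame_interval_s") <- preset$optics$frame_interval_s
  out
}

#' Write trajectories to CSV
#'
#' @param traj Trajectory tibble (long format, one row per frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}
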