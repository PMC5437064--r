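#' Default DNA-curtain geometry
#'
#' Double-tethered curtain geometry: the 48.502-kb substrate spans 13 um
#' between the chromium barrier and pedestal (~80% extension relative to
#' B-form DNA). Binding histograms assume every molecule is anchored at the
#' barrier center, while the true anchor is uniform across the ~1-1.5 um
#' barrier width; this anchor jitter is the dominant source of histogram
#' broadening and is reproduced by the generator.
#'
#' @param genome_kb Substrate length in kb.
#' @param tether_um Barrier-to-pedestal separation in um.
#' @param extension Fractional extension relative to B-form contour length.
#' @param barrier_width_um Chromium barrier width (anchor jitter is uniform
#'   over this width).
#' @param pixel_um Image pixel size in um (60x objective, EMCCD).
#' @return A list of geometry parameters, including the derived
#'   `um_per_kb` scale.
#' @export
curtain_geometry <- function(genome_kb = 48.502, tether_um = 13,
                             extension = 0.8, barrier_width_um = 1.25,
                             pixel_um = 0.267) {
  list(
    genome_kb = genome_kb, tether_um = tether_um, extension = extension,
    barrier_width_um = barrier_width_um, pixel_um = pixel_um,
    um_per_kb = tether_um / genome_kb
  )
}

#' Default imaging parameters
#'
#' @param psf_sigma_px PSF standard deviation in pixels (symmetric Gaussian).
#' @param frame_interval_s Frame interval in seconds (50 ms exposure).
#' @param photon_rate Detected photons per second per emitter.
#' @param background Mean background level, photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param loc_noise_sd_um Localization noise SD applied to simulated
#'   trajectories, in um (30 nm, typical for quantum-dot tracking).
#' @return A list of optics parameters.
#' @export
curtain_optics <- function(psf_sigma_px = 1.1, frame_interval_s = 0.05,
                           photon_rate = 2e4, background = 10,
                           read_noise_sd = 2, loc_noise_sd_um = 0.03) {
  list(
    psf_sigma_px = psf_sigma_px, frame_interval_s = frame_interval_s,
    photon_rate = photon_rate, background = background,
    read_noise_sd = read_noise_sd, loc_noise_sd_um = loc_noise_sd_um
  )
}

# Decompose a site component's total positional sd (kb) into a uniform
# anchor-jitter part plus a Gaussian residual. If the printed total sd is
# below the sd implied by the full barrier width, the jitter width is shrunk
# to match the total.
site_component_pars <- function(total_sd_kb, geometry) {
  jitter_kb <- geometry$barrier_width_um / geometry$um_per_kb
  jitter_sd <- jitter_kb / sqrt(12)
  if (total_sd_kb <= 0) {
    return(list(jitter_kb = 0, resid_sd = 0))
  }
  if (total_sd_kb < jitter_sd) {
    list(jitter_kb = total_sd_kb * sqrt(12), resid_sd = 0)
  } else {
    list(jitter_kb = jitter_kb, resid_sd = sqrt(total_sd_kb^2 - jitter_sd^2))
  }
}

# P(site component falls inside [lo, hi]) for a component that is
# center + Uniform(-j/2, j/2) + Normal(0, s).
site_capture_fraction <- function(center_kb, total_sd_kb, lo_kb, hi_kb,
                                  geometry = curtain_geometry()) {
  p <- site_component_pars(total_sd_kb, geometry)
  j <- p$jitter_kb
  s <- p$resid_sd
  if (j < 1e-9 && s < 1e-9) {
    return(as.numeric(center_kb >= lo_kb && center_kb < hi_kb))
  }
  if (j < 1e-9) {
    return(stats::pnorm(hi_kb, center_kb, s) - stats::pnorm(lo_kb, center_kb, s))
  }
  if (s < 1e-9) {
    lo_u <- max(lo_kb, center_kb - j / 2)
    hi_u <- min(hi_kb, center_kb + j / 2)
    return(max(0, hi_u - lo_u) / j)
  }
  f <- function(u) {
    (stats::pnorm(hi_kb, center_kb + u, s) -
       stats::pnorm(lo_kb, center_kb + u, s)) / j
  }
  stats::integrate(f, -j / 2, j / 2, rel.tol = 1e-9)$value
}

# Solve the site-component weight that yields a given expected fold
# enrichment in the target window against a pure-background reference.
weight_for_fold <- function(fold, center_kb, total_sd_kb,
                            window_kb = c(18.8, 23.8),
                            geometry = curtain_geometry()) {
  u <- diff(window_kb) / geometry$genome_kb
  q <- site_capture_fraction(center_kb, total_sd_kb, window_kb[1],
                             window_kb[2], geometry)
  w <- u * (fold - 1) / (q - u)
  if (w < 0 || w > 1) stop("fold not achievable with this component",
                           call. = FALSE)
  w
}

new_preset <- function(name, kind, mixture = NULL, dynamics = NULL,
                       dwell = NULL, behavior_counts = NULL,
                       site_interaction = "none", site_kb = NA_real_,
                       n_default = NA_integer_,
                       geometry = curtain_geometry(),
                       optics = curtain_optics(), substrate = NULL) {
  if (!is.null(mixture)) {
    tot <- sum(mixture$weight)
    if (any(mixture$weight < 0) || abs(tot - 1) > 1e-8) {
      stop("mixture weights must be >= 0 and sum to 1", call. = FALSE)
    }
  }
  structure(
    list(
      name = name, kind = kind, mixture = mixture, dynamics = dynamics,
      dwell = dwell, behavior_counts = behavior_counts,
      site_interaction = site_interaction, site_kb = site_kb,
      n_default = n_default, geometry = geometry, optics = optics,
      substrate = substrate %||% build_lambda_map()
    ),
    class = "experiment_preset"
  )
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat("<experiment_preset> ", x$name, " (", x$kind, ")\n", sep = "")
  if (!is.null(x$mixture)) print(x$mixture)
  if (!is.null(x$dwell)) {
    cat("  dwell t1/2 =", x$dwell$t_half_s, "s, n =", x$dwell$n,
        ", t_obs =", x$dwell$t_obs_s, "s\n")
  }
  if (!is.null(x$dynamics)) {
    cat("  D0 =", x$dynamics$d0_um2_s, "um^2/s\n")
  }
  invisible(x)
}

binding_mixture <- function(sites, background_weight) {
  dplyr::bind_rows(
    sites,
    tibble::tibble(component = "background", center_kb = NA_real_,
                   sd_kb = NA_real_, weight = background_weight)
  )
}

#' Named experiment presets
#'
#' Returns a preset encoding one measured experimental condition: site
#' centers and histogram widths, dwell half-lives and sample sizes, diffusion
#' coefficients and the salt series, and the exact behavior-category counts
#' used for classification fixtures. Available presets:
#'
#' * `LacI_siteA` / `LacI_siteB` / `LacI_siteC`: Lac repressor bound at one
#'   operator cassette (centers 21.7 / 34.0 / 46.0 kb, total sds 1.0 / 1.5 /
#'   2.3 kb, N = 558 / 538 / 467), 92% site-specific binding.
#' * `LacI_siteBC`: double-operator substrate (34.0 +- 2.0 and 46.2 +- 2.2 kb,
#'   N = 525) with equal occupancy.
#' * `dig_flap_end`: anti-digoxigenin labeling of a 5'-flap at site A plus
#'   the free DNA end (22 +- 0.8 and 47.5 +- 2.0 kb, N = 225).
#' * `yPCNA_flap` / `yPCNA_cag13` / `yPCNA_homoduplex`: clamp loading on the
#'   5'-ssDNA flap (21.2 +- 1.4 kb), the (CAG)13 repeat, or homoduplex DNA.
#'   Site weights are derived from the measured 2.7x and 1.5x target-window
#'   enrichments over homoduplex.
#' * `LacI_IPTG_siteB` / `LacI_IPTG_siteC` / `LacI_noIPTG`: dwell-time
#'   presets (half-lives 21, 22 and 327 s; n = 63, 56, 49).
#' * `yPCNA_salt_series`: 1D diffusion at three NaCl levels with
#'   D(c) = D0 + 0.25 (c - c0) um^2/s, 30 molecules per level.
#' * `yPCNA_flap_dynamics` / `yPCNA_cag13_dynamics` /
#'   `yPCNA_homoduplex_dynamics`: behavior-classification fixtures with exact
#'   category counts (flap: 36 blocked / 2 captured / 2 bypass of 40;
#'   (CAG)13: 23 / 11 / 2 of 36; homoduplex: 1 / 1 / 38 of 40).
#'
#' @param name Preset name (see above).
#' @return An `experiment_preset` object.
#' @examples
#' experiment_preset("yPCNA_flap")
#' @export
experiment_preset <- function(name) {
  geometry <- curtain_geometry()
  site_mix <- function(centers, sds, weights, n) {
    new_preset(name, "binding", n_default = n, mixture = binding_mixture(
      tibble::tibble(component = paste0("site", seq_along(centers)),
                     center_kb = centers, sd_kb = sds, weight = weights),
      background_weight = 1 - sum(weights)
    ))
  }
  dwell_preset <- function(t_half, n, t_obs) {
    new_preset(name, "dwell",
               dwell = list(t_half_s = t_half, n = n, t_obs_s = t_obs))
  }
  fold_weight <- function(fold, center, sd) {
    weight_for_fold(fold, center, sd, window_kb = c(18.8, 23.8), geometry)
  }
  switch(
    name,
    LacI_siteA = site_mix(21.7, 1.0, 0.92, 558L),
    LacI_siteB = site_mix(34.0, 1.5, 0.92, 538L),
    LacI_siteC = site_mix(46.0, 2.3, 0.92, 467L),
    LacI_siteBC = site_mix(c(34.0, 46.2), c(2.0, 2.2), c(0.46, 0.46), 525L),
    dig_flap_end = site_mix(c(22.0, 47.5), c(0.8, 2.0), c(0.45, 0.45), 225L),
    yPCNA_flap = {
      w <- fold_weight(2.7, 21.2, 1.4)
      p <- site_mix(21.2, 1.4, w, 500L)
      p$site_kb <- 21.3
      p
    },
    yPCNA_cag13 = {
      w <- fold_weight(1.5, 21.3, 1.4)
      p <- site_mix(21.3, 1.4, w, 500L)
      p$site_kb <- 21.3
      p
    },
    yPCNA_homoduplex = new_preset(
      name, "binding", n_default = 500L,
      mixture = binding_mixture(
        tibble::tibble(component = character(), center_kb = double(),
                       sd_kb = double(), weight = double()),
        background_weight = 1
      )
    ),
    LacI_IPTG_siteB = dwell_preset(21, 63L, 300),
    LacI_IPTG_siteC = dwell_preset(22, 56L, 300),
    LacI_noIPTG = dwell_preset(327, 49L, 1800),
    yPCNA_salt_series = new_preset(
      name, "salt",
      dynamics = list(
        d0_um2_s = 0.3, c0_mM = 50, salt_slope_um2_s_mM = 0.25,
        concentrations_mM = c(50, 51, 52), n_molecules = 30L,
        n_frames = 1200L
      )
    ),
    yPCNA_flap_dynamics = new_preset(
      name, "behavior", site_kb = 21.3, site_interaction = "reflecting",
      dynamics = list(d0_um2_s = 0.3),
      behavior_counts = c(blocked = 36L, captured = 2L, bypass = 2L)
    ),
    yPCNA_cag13_dynamics = new_preset(
      name, "behavior", site_kb = 21.3, site_interaction = "trapping",
      dynamics = list(d0_um2_s = 0.3),
      behavior_counts = c(blocked = 23L, captured = 11L, bypass = 2L)
    ),
    yPCNA_homoduplex_dynamics = new_preset(
      name, "behavior", site_kb = 21.3, site_interaction = "none",
      dynamics = list(d0_um2_s = 0.3),
      behavior_counts = c(blocked = 1L, captured = 1L, bypass = 38L)
    ),
    stop("unknown preset '", name, "'; see list_presets()", call. = FALSE)
  )
}

#' List the available experiment presets
#'
#' @return A character vector of preset names accepted by
#'   [experiment_preset()].
#' @export
list_presets <- function() {
  c("LacI_siteA", "LacI_siteB", "LacI_siteC", "LacI_siteBC", "dig_flap_end",
    "yPCNA_flap", "yPCNA_cag13", "yPCNA_homoduplex",
    "LacI_IPTG_siteB", "LacI_IPTG_siteC", "LacI_noIPTG",
    "yPCNA_salt_series", "yPCNA_flap_dynamics", "yPCNA_cag13_dynamics",
    "yPCNA_homoduplex_dynamics")
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' One master seed drives a named sequence of stage seeds so pipeline stages
#' can be re-run in isolation. The derivation is a fixed affine hash of the
#' master seed and the stage label, reduced modulo a 31-bit prime.
#'
#' @param seed Master seed (integer).
#' @param stage Stage label (character) or index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483629
  h <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_len(nchar(stage))) else as.numeric(stage)
  as.integer((((as.numeric(seed) %% m) * 48271) %% m + (h * 7919) %% m) %% m + 1)
}
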