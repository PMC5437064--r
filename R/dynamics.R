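#' Mean squared displacement of a 1D trajectory
#'
#' For each interval `n = 1..n_max`, computes the time-averaged MSD over all
#' `N - n` overlapping displacement pairs:
#' `MSD(n dt) = 1/(N-n) * sum_i (y_{i+n} - y_i)^2`.
#'
#' @param traj A trajectory tibble with a `y_um` column (and optional
#'   `frame_interval_s` attribute), or a numeric position vector.
#' @param n_max Largest interval in frames (default 10); the trajectory must
#'   have at least `n_max + 1` frames.
#' @param dt Frame interval in seconds (default: the `frame_interval_s`
#'   attribute, else 0.05).
#' @param position_col Position column name when `traj` is a data frame.
#' @return An `msd_curve` tibble: `lag` (frames), `interval_s`, `msd_um2`,
#'   `n_pairs`; attributes `n_frames` and `frame_interval_s`.
#' @examples
#' tr <- simulate_trajectory(experiment_preset("yPCNA_homoduplex"), 0.1, 500, 6, 1,
#'                           loc_noise_sd_um = 0)
#' compute_msd(tr)
#' @export
compute_msd <- function(traj, n_max = 10, dt = NULL, position_col = "y_um") {
  y <- if (is.numeric(traj) && is.null(dim(traj))) traj else traj[[position_col]]
  dt <- dt %||% attr(traj, "frame_interval_s") %||% 0.05
  N <- length(y)
  if (N <= n_max) {
    stop("trajectory has ", N, " frames; MSD up to lag ", n_max,
         " needs at least ", n_max + 1, call. = FALSE)
  }
  msd <- vapply(seq_len(n_max), function(n) {
    d <- y[(n + 1):N] - y[1:(N - n)]
    mean(d^2)
  }, numeric(1))
  out <- tibble::tibble(
    lag = seq_len(n_max),
    interval_s = seq_len(n_max) * dt,
    msd_um2 = msd,
    n_pairs = N - seq_len(n_max)
  )
  class(out) <- c("msd_curve", class(out))
  attr(out, "n_frames") <- N
  attr(out, "frame_interval_s") <- dt
  out
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Fits an ordinary least-squares line to the first `n_max` MSD points and
#' reports `D = slope / 2` (1D diffusion, `MSD = 2 D dt`). The default fit
#' has a free intercept, which absorbs the static localization-noise offset;
#' a through-origin fit is available with `intercept = FALSE`. Negative
#' fitted slopes are reported as `D = 0` with `clamped = TRUE`.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_max Number of leading intervals used (default: all available,
#'   itself capped at 10 by [compute_msd()]).
#' @param intercept Fit a free intercept (default `TRUE`).
#' @return A `diffusion_estimate`: one-row tibble with `D_um2_s`, `slope`,
#'   `intercept`, `se_slope`, `n_max`, `clamped`.
#' @export
estimate_D <- function(msd, n_max = NULL, intercept = TRUE) {
  n_max <- n_max %||% nrow(msd)
  if (n_max > nrow(msd)) {
    stop("n_max exceeds the ", nrow(msd), " available MSD intervals",
         call. = FALSE)
  }
  if (n_max < 2) stop("need at least 2 MSD points", call. = FALSE)
  d <- msd[seq_len(n_max), ]
  fit <- if (intercept) {
    stats::lm(msd_um2 ~ interval_s, data = d)
  } else {
    stats::lm(msd_um2 ~ interval_s - 1, data = d)
  }
  # exact synthetic curves fit perfectly; the SE caveat is expected there
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["interval_s", "Estimate"]
  se <- co["interval_s", "Std. Error"]
  icpt <- if (intercept) co["(Intercept)", "Estimate"] else 0
  clamped <- slope < 0
  out <- tibble::tibble(
    D_um2_s = max(slope, 0) / 2, slope = slope, intercept = icpt,
    se_slope = se, n_max = as.integer(n_max), clamped = clamped
  )
  class(out) <- c("diffusion_estimate", class(out))
  out
}

#' Per-molecule diffusion coefficients for a set of trajectories
#'
#' Maps [compute_msd()] + [estimate_D()] over molecules in a long trajectory
#' table.
#'
#' @param traj Long tibble with columns identifying the molecule (see
#'   `id_cols`), plus `y_um`.
#' @param id_cols Grouping columns (default `molecule`, plus `conc_mM` when
#'   present).
#' @param n_max MSD intervals used in the fit.
#' @param dt Frame interval (default from attribute).
#' @param intercept Passed to [estimate_D()].
#' @return A tibble with one row per molecule: the id columns plus the
#'   [estimate_D()] fields.
#' @export
estimate_D_by_molecule <- function(traj, id_cols = NULL, n_max = 10,
                                   dt = NULL, intercept = TRUE) {
  id_cols <- id_cols %||% intersect(c("conc_mM", "molecule"), names(traj))
  dt <- dt %||% attr(traj, "frame_interval_s") %||% 0.05
  traj |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::group_modify(function(df, key) {
      estimate_D(compute_msd(df$y_um, n_max = n_max, dt = dt),
                 intercept = intercept)
    }) |>
    dplyr::ungroup()
}

#' Salt dependence of the diffusion coefficient
#'
#' Fits a weighted least-squares line to mean diffusion coefficient versus
#' NaCl concentration (weights `1/SE^2` of each concentration's mean, or
#' unweighted if any SE is unavailable). The slope distinguishes sliding
#' (weak dependence) from hopping (strong dependence).
#'
#' @param estimates Tibble with columns `conc_mM` and `D_um2_s`, one row per
#'   molecule (e.g. from [estimate_D_by_molecule()]).
#' @param min_molecules Warn when any concentration has fewer molecules.
#' @return A one-row tibble: `slope_um2_s_mM`, `se_slope`, `intercept`,
#'   `n_concentrations`; attribute `means` holds the per-concentration table.
#' @export
salt_slope <- function(estimates, min_molecules = 30) {
  means <- estimates |>
    dplyr::group_by(.data$conc_mM) |>
    dplyr::summarise(
      mean_D = mean(.data$D_um2_s),
      se_D = stats::sd(.data$D_um2_s) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
  if (nrow(means) < 2) {
    stop("need at least 2 distinct salt concentrations", call. = FALSE)
  }
  if (any(means$n < min_molecules)) {
    warning("fewer than ", min_molecules, " molecules at some concentration")
  }
  w <- if (any(!is.finite(means$se_D)) || any(means$se_D <= 0)) NULL else
    1 / means$se_D^2
  fit <- stats::lm(mean_D ~ conc_mM, data = means, weights = w)
  co <- suppressWarnings(summary(fit)$coefficients)
  out <- tibble::tibble(
    slope_um2_s_mM = co["conc_mM", "Estimate"],
    se_slope = co["conc_mM", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    n_concentrations = nrow(means)
  )
  attr(out, "means") <- means
  out
}

#' Classify a trajectory's behavior at an interaction site
#'
#' Labels, in precedence order:
#' * `captured`: loaded within `tol_kb` of the site and positionally
#'   stationary (overall sd below `stationary_sd_kb`);
#' * `bypass`: visits both flanks beyond the tolerance zone, i.e. crosses
#'   the site in either direction;
#' * `blocked`: enters the tolerance zone, reverses, and never crosses;
#' * `no_encounter`: never reaches the tolerance zone.
#'
#' @param traj Trajectory tibble with a `position_kb` column, or numeric
#'   vector of positions in kb.
#' @param site_kb Site coordinate, kb from cosL.
#' @param tol_kb Tolerance zone half-width (default 1.5 kb).
#' @param stationary_sd_kb Positional-sd threshold for `captured`
#'   (default 0.25 kb).
#' @return A one-row tibble: `label`, `site_kb`, `approach`
#'   (`"below"`/`"above"`/`"at"`, by first position).
#' @export
classify_behavior <- function(traj, site_kb, tol_kb = 1.5,
                              stationary_sd_kb = 0.25) {
  y <- if (is.numeric(traj) && is.null(dim(traj))) traj else traj$position_kb
  if (length(y) < 2) stop("need at least 2 frames", call. = FALSE)
  lo_flank <- y < site_kb - tol_kb
  hi_flank <- y > site_kb + tol_kb
  in_zone <- !lo_flank & !hi_flank
  # visiting both flanks implies a pass through the zone in some direction
  crossed <- any(lo_flank) && any(hi_flank)
  label <- if (abs(y[1] - site_kb) <= tol_kb &&
               stats::sd(y) < stationary_sd_kb) {
    "captured"
  } else if (crossed) {
    "bypass"
  } else if (any(in_zone)) {
    "blocked"
  } else {
    "no_encounter"
  }
  approach <- if (abs(y[1] - site_kb) <= tol_kb) "at" else
    if (y[1] < site_kb) "below" else "above"
  tibble::tibble(label = label, site_kb = site_kb, approach = approach)
}

#' Classify every molecule in a long trajectory table
#'
#' @param traj Long tibble with `molecule` and `position_kb` columns.
#' @param site_kb Site coordinate (default: the table's `site_kb` attribute).
#' @inheritParams classify_behavior
#' @return A tibble with one row per molecule (`molecule`, `label`,
#'   `site_kb`, `approach`).
#' @export
classify_behavior_by_molecule <- function(traj, site_kb = NULL, tol_kb = 1.5,
                                          stationary_sd_kb = 0.25) {
  site_kb <- site_kb %||% attr(traj, "site_kb")
  if (is.null(site_kb)) stop("site_kb is required", call. = FALSE)
  traj |>
    dplyr::group_by(.data$molecule) |>
    dplyr::group_modify(function(df, key) {
      classify_behavior(df$position_kb, site_kb, tol_kb, stationary_sd_kb)
    }) |>
    dplyr::ungroup()
}

#' Fit an exponential dwell-time (survival) model with right-censoring
#'
#' Maximum-likelihood exponential fit: the rate is events divided by total
#' observed time (censored spans included), equivalently the total-time-on-
#' test estimator, and the half-life is `ln 2` times the fitted mean. The
#' 95% CI is a percentile bootstrap over molecules. A least-squares fit to
#' the empirical survival curve is available with `method = "ls"`.
#'
#' @param dwells Tibble with columns `dwell_s` and `censored` (logical), or
#'   a numeric vector of uncensored dwell times.
#' @param method `"mle"` (default) or `"ls"` (regression of log survival on
#'   time through the origin, uncensored records only).
#' @param B Bootstrap resamples for the CI.
#' @param seed Bootstrap seed.
#' @param min_events Minimum uncensored events required (default 5).
#' @return A `survival_fit`: one-row tibble with `t_half_s`, `mean_s`,
#'   `rate_per_s`, `ci_lo`, `ci_hi`, `n`, `n_events`, `n_censored`,
#'   `method`.
#' @examples
#' d <- simulate_dwell_times(21, 63, t_obs = 300, seed = 1)
#' fit_survival(d)
#' @export
fit_survival <- function(dwells, method = c("mle", "ls"), B = 1000, seed = 1,
                         min_events = 5) {
  method <- match.arg(method)
  if (is.numeric(dwells) && is.null(dim(dwells))) {
    dwells <- tibble::tibble(dwell_s = dwells, censored = FALSE)
  }
  t <- dwells$dwell_s
  cens <- dwells$censored
  n_events <- sum(!cens)
  if (n_events == 0) {
    stop("all observations are censored; no estimate possible", call. = FALSE)
  }
  if (n_events < min_events) {
    stop("need at least ", min_events, " uncensored events", call. = FALSE)
  }
  point <- function(tt, cc) {
    if (method == "mle") {
      sum(tt) / sum(!cc) # total time on test / events
    } else {
      tu <- sort(tt[!cc])
      s <- 1 - seq_along(tu) / (length(tu) + 1) # empirical survival
      fit <- stats::lm(log(s) ~ tu - 1)
      -1 / unname(stats::coef(fit)[1])
    }
  }
  mean_s <- point(t, cens)
  set.seed(seed)
  boots <- vapply(seq_len(B), function(i) {
    idx <- sample.int(length(t), replace = TRUE)
    if (sum(!cens[idx]) == 0) return(NA_real_)
    point(t[idx], cens[idx])
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  out <- tibble::tibble(
    t_half_s = log(2) * mean_s, mean_s = mean_s, rate_per_s = 1 / mean_s,
    ci_lo = log(2) * ci[1], ci_hi = log(2) * ci[2],
    n = length(t), n_events = n_events, n_censored = sum(cens),
    method = method
  )
  class(out) <- c("survival_fit", class(out))
  out
}

#' @describeIn fit_survival One-row parameter table of a survival fit.
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble::tibble(term = "t_half_s", estimate = x$t_half_s,
                 conf.low = x$ci_lo, conf.high = x$ci_hi)
}

#' @describeIn fit_survival One-row fit summary.
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("n", "n_events", "n_censored", "method")])
}

#' Empirical survival curve with the fitted exponential
#'
#' @param object A `survival_fit`.
#' @param dwells The dwell sample the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_survival <- function(object, dwells, ...) {
  tt <- sort(dwells$dwell_s[!dwells$censored])
  df <- tibble::tibble(t = tt, s = 1 - seq_along(tt) / (length(tt) + 1))
  grid <- tibble::tibble(t = seq(0, max(tt), length.out = 200))
  grid$s <- exp(-grid$t / object$mean_s)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::labs(x = "dwell time (s)", y = "survival fraction") +
    ggplot2::theme_minimal()
}

#' MSD curve plot with the fitted line
#'
#' @param object An `msd_curve`.
#' @param estimate Optional `diffusion_estimate` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, estimate = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$interval_s, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta * t ~ "(s)"),
                  y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_abline(slope = estimate$slope,
                                  intercept = estimate$intercept,
                                  color = "red")
  }
  p
}
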