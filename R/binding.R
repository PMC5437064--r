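#' Convert positions along the DNA from micrometers to kilobases
#'
#' Positions are measured from the chromium barrier (the anchor is assumed at
#' the barrier center); the conversion uses the curtain scale
#' `tether_um / genome_kb` (default 13/48.502 ~ 0.268 um/kb). Positions
#' mapping beyond the substrate end plus `tol_kb` are flagged off-DNA.
#'
#' @param df A data frame with a position column in um, or a numeric vector.
#' @param geometry Geometry list, see [curtain_geometry()].
#' @param position_col Name of the um position column (default `y_um`).
#' @param tol_kb Overhang tolerance before flagging off-DNA.
#' @return The data frame with added `position_kb` and `on_dna` columns
#'   (or a numeric vector if `df` is a vector).
#' @examples
#' map_to_kb(tibble::tibble(y_um = c(0, 13, 5.683)))
#' @export
map_to_kb <- function(df, geometry = curtain_geometry(),
                      position_col = "y_um", tol_kb = 2) {
  if (is.numeric(df) && is.null(dim(df))) {
    if (any(df < 0)) stop("positions must be >= 0", call. = FALSE)
    return(df / geometry$um_per_kb)
  }
  pos <- df[[position_col]]
  if (any(pos < 0)) stop("positions must be >= 0", call. = FALSE)
  kb <- pos / geometry$um_per_kb
  dplyr::mutate(df, position_kb = kb,
                on_dna = kb <= geometry$genome_kb + tol_kb)
}

gaussian_sum <- function(x, centers, sds, amps, offset) {
  y <- rep(offset, length(x))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * sds[i]^2))
  }
  y
}

#' Fit Gaussian peaks to a binding-position distribution
#'
#' Bins positions into a 1-kb histogram (the field's standard presentation)
#' and fits one or two Gaussians plus a constant background by least squares.
#' A raw-sample maximum-likelihood fit (no binning) is available with
#' `method = "mle"`.
#'
#' @param binding A binding-set tibble with a `position_kb` column (rows with
#'   `on_dna = FALSE` are dropped if the column exists), or a numeric vector
#'   of positions in kb.
#' @param n_components 1 or 2 Gaussian components.
#' @param window Optional `c(lo, hi)` kb range restricting the fit.
#' @param bin_kb Histogram bin width (default 1 kb).
#' @param method `"binned"` (least squares on the histogram, default) or
#'   `"mle"` (Gaussian mixture on raw positions via mclust).
#' @return A `peak_fit` object; see [tidy.peak_fit()] for the component
#'   table (centers, sds, weights).
#' @examples
#' x <- simulate_binding_positions(experiment_preset("LacI_siteA"), 500, 1)
#' fit_peaks(x, 1)
#' @export
fit_peaks <- function(binding, n_components = 1, window = NULL, bin_kb = 1,
                      method = c("binned", "mle")) {
  method <- match.arg(method)
  pos <- if (is.numeric(binding)) binding else {
    b <- tibble::as_tibble(binding)
    if ("on_dna" %in% names(b)) b <- b[b$on_dna, ]
    b$position_kb
  }
  if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
  n <- length(pos)
  if (n < 2) stop("need at least 2 positions to fit", call. = FALSE)
  if (stats::sd(pos) < 1e-12) {
    comps <- tibble::tibble(component = 1L, center_kb = mean(pos), sd_kb = 0,
                            weight = 1)
    return(new_peak_fit(comps, n, method, converged = FALSE,
                        note = "degenerate zero-variance sample"))
  }
  if (method == "mle") {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      stop("method = 'mle' requires the mclust package", call. = FALSE)
    }
    fit <- mclust::Mclust(pos, G = n_components, modelNames = "V",
                          verbose = FALSE)
    comps <- tibble::tibble(
      component = seq_len(n_components),
      center_kb = as.numeric(fit$parameters$mean),
      sd_kb = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
      weight = as.numeric(fit$parameters$pro)
    )
    return(new_peak_fit(dplyr::arrange(comps, .data$center_kb), n, method,
                        converged = TRUE, loglik = fit$loglik))
  }
  # bins aligned so centers fall on multiples of bin_kb
  lo <- round(min(pos) / bin_kb) * bin_kb - 1.5 * bin_kb
  hi <- round(max(pos) / bin_kb) * bin_kb + 1.5 * bin_kb
  breaks <- seq(lo - bin_kb / 2, hi + bin_kb / 2, by = bin_kb)
  h <- graphics::hist(pos, breaks = breaks, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  # starts: histogram modes
  if (n_components == 1) {
    m0 <- sum(mids * counts) / sum(counts)
    s0 <- sqrt(sum(counts * (mids - m0)^2) / sum(counts))
    start <- c(m1 = m0, s1 = max(s0 / 2, bin_kb / 2), a1 = max(counts), b = 0)
    lower <- c(lo, bin_kb / 10, 0, 0)
    upper <- c(hi, hi - lo, Inf, Inf)
    fn <- function(p) counts - gaussian_sum(mids, p[1], p[2], p[3], p[4])
  } else if (n_components == 2) {
    ord <- order(counts, decreasing = TRUE)
    peak1 <- mids[ord[1]]
    far <- ord[abs(mids[ord] - peak1) > 3 * bin_kb]
    peak2 <- if (length(far) > 0) mids[far[1]] else peak1 + 5 * bin_kb
    start <- c(m1 = min(peak1, peak2), s1 = 1.5, a1 = max(counts),
               m2 = max(peak1, peak2), s2 = 1.5, a2 = max(counts) / 2, b = 0)
    lower <- c(lo, bin_kb / 10, 0, lo, bin_kb / 10, 0, 0)
    upper <- c(hi, hi - lo, Inf, hi, hi - lo, Inf, Inf)
    fn <- function(p) counts - gaussian_sum(mids, p[c(1, 4)], p[c(2, 5)],
                                            p[c(3, 6)], p[7])
  } else {
    stop("n_components must be 1 or 2", call. = FALSE)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  if (n_components == 1) {
    comps <- tibble::tibble(component = 1L, center_kb = p[["m1"]],
                            sd_kb = p[["s1"]], amplitude = p[["a1"]])
  } else {
    comps <- tibble::tibble(
      component = 1:2, center_kb = c(p[["m1"]], p[["m2"]]),
      sd_kb = c(p[["s1"]], p[["s2"]]), amplitude = c(p[["a1"]], p[["a2"]])
    )
  }
  area <- comps$amplitude * comps$sd_kb * sqrt(2 * pi)
  comps$weight <- area / sum(area)
  comps <- dplyr::arrange(comps, .data$center_kb)
  new_peak_fit(comps, n, method, converged = !(fit$info %in% c(0, 5)),
               background = p[["b"]], rss = sum(fit$fvec^2),
               histogram = tibble::tibble(mid_kb = mids, count = counts))
}

new_peak_fit <- function(components, n, method, converged, background = NA,
                         rss = NA, loglik = NA, note = NULL, histogram = NULL) {
  structure(
    list(components = components, n = n, method = method,
         converged = converged, background = background, rss = rss,
         loglik = loglik, note = note, histogram = histogram),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("<peak_fit> ", nrow(x$components), " component(s), n = ", x$n,
      ", method = ", x$method, "\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  center %.1f kb, sd %.1f kb, weight %.2f\n",
                x$components$center_kb[i], x$components$sd_kb[i],
                x$components$weight[i]))
  }
  invisible(x)
}

#' @describeIn fit_peaks Component table of a peak fit: one row per Gaussian
#'   with `center_kb`, `sd_kb`, `weight`.
#' @param x A `peak_fit`.
#' @param ... Unused.
#' @method tidy peak_fit
#' @export
tidy.peak_fit <- function(x, ...) x$components

#' @describeIn fit_peaks One-row fit summary (`n`, `method`, `converged`,
#'   `rss`).
#' @method glance peak_fit
#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method, converged = x$converged,
                 n_components = nrow(x$components), rss = x$rss)
}

#' Histogram plus fitted peaks
#'
#' @param object A `peak_fit` from the binned method.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_fit
#' @export
autoplot.peak_fit <- function(object, ...) {
  if (is.null(object$histogram)) {
    stop("autoplot is available for binned fits only", call. = FALSE)
  }
  h <- object$histogram
  grid <- tibble::tibble(x = seq(min(h$mid_kb), max(h$mid_kb), length.out = 400))
  grid$y <- gaussian_sum(grid$x, object$components$center_kb,
                         object$components$sd_kb,
                         object$components$amplitude, object$background)
  ggplot2::ggplot(h, ggplot2::aes(.data$mid_kb, .data$count)) +
    ggplot2::geom_col(fill = "grey70", width = diff(h$mid_kb[1:2]) * 0.95) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$y),
                       color = "red") +
    ggplot2::labs(x = "position (kb from cosL)", y = "molecules") +
    ggplot2::theme_minimal()
}

#' Bootstrap a statistic with replacement
#'
#' @param sample A numeric vector (non-empty).
#' @param statistic A function reducing a numeric vector to one number
#'   (default `mean`).
#' @param B Number of resamples (>= 100; fewer triggers a warning).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return A one-row tibble: `point` (statistic on the original sample),
#'   `sd` (bootstrap SD), `ci_lo`, `ci_hi`, `B`.
#' @examples
#' bootstrap_stat(rnorm(100), mean, B = 1000, seed = 1)
#' @export
bootstrap_stat <- function(sample, statistic = mean, B = 1000, seed = 1,
                           conf = 0.95) {
  if (length(sample) == 0) stop("sample must be non-empty", call. = FALSE)
  if (B < 100) warning("B < 100 gives unreliable bootstrap errors")
  set.seed(seed)
  stats_b <- vapply(seq_len(B), function(i) {
    statistic(sample[sample.int(length(sample), replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(point = statistic(sample), sd = stats::sd(stats_b),
                 ci_lo = ci[1], ci_hi = ci[2], B = as.integer(B))
}

#' Default eight-window layout for enrichment analysis
#'
#' Eight contiguous 5-kb windows spanning 3.8-43.8 kb, positioned so the
#' target window is centered on the site-A cassette (21.3 kb); window 4
#' covers 18.8-23.8 kb.
#'
#' @param center_kb Target-window center (default 21.3, the site-A cassette).
#' @param width_kb Window width (default 5).
#' @param n_windows Number of windows (default 8).
#' @param target_index Which window holds the modification (default 4).
#' @return A tibble with `window`, `start_kb`, `end_kb`, `is_target`.
#' @export
default_window_layout <- function(center_kb = 21.3, width_kb = 5,
                                  n_windows = 8, target_index = 4) {
  start1 <- center_kb - width_kb / 2 - (target_index - 1) * width_kb
  tibble::tibble(
    window = seq_len(n_windows),
    start_kb = start1 + (seq_len(n_windows) - 1) * width_kb,
    end_kb = start1 + seq_len(n_windows) * width_kb,
    is_target = seq_len(n_windows) == target_index
  )
}

count_in_windows <- function(positions_kb, layout) {
  vapply(seq_len(nrow(layout)), function(i) {
    sum(positions_kb >= layout$start_kb[i] & positions_kb < layout$end_kb[i])
  }, numeric(1))
}

#' Windowed fold-enrichment of binding on a modified vs reference substrate
#'
#' Per-substrate window frequencies are window counts normalized by the total
#' molecule count on that substrate; the fold enrichment is the target-window
#' frequency on the modified substrate divided by the same window's frequency
#' on the reference substrate.
#'
#' @param target Binding set (tibble with `position_kb`, or numeric vector)
#'   for the modified substrate.
#' @param reference Binding set for the reference (homoduplex) substrate.
#' @param layout Window layout, see [default_window_layout()].
#' @param target_window Target window id (default: the layout's `is_target`
#'   row).
#' @return An `enrichment_result`: list with `windows` (per-window counts and
#'   normalized frequencies for both sets), `fold`, `target_window`, and the
#'   two totals. `fold` is `NA` (with a note) when the reference window is
#'   empty.
#' @examples
#' a <- simulate_binding_positions(experiment_preset("yPCNA_flap"), 500, 1)
#' b <- simulate_binding_positions(experiment_preset("yPCNA_homoduplex"), 500, 2)
#' window_enrichment(a, b)
#' @export
window_enrichment <- function(target, reference,
                              layout = default_window_layout(),
                              target_window = NULL) {
  getpos <- function(x) {
    if (is.numeric(x)) x else {
      b <- tibble::as_tibble(x)
      if ("on_dna" %in% names(b)) b <- b[b$on_dna, ]
      b$position_kb
    }
  }
  pt <- getpos(target); pr <- getpos(reference)
  if (length(pt) == 0 || length(pr) == 0) {
    stop("both binding sets must be non-empty", call. = FALSE)
  }
  target_window <- target_window %||% layout$window[layout$is_target][1]
  if (!target_window %in% layout$window) {
    stop("target window not in layout", call. = FALSE)
  }
  windows <- dplyr::mutate(
    layout,
    count_target_set = count_in_windows(pt, layout),
    count_reference_set = count_in_windows(pr, layout),
    freq_target_set = .data$count_target_set / length(pt),
    freq_reference_set = .data$count_reference_set / length(pr)
  )
  i <- which(windows$window == target_window)
  note <- NULL
  fold <- if (windows$count_reference_set[i] == 0) {
    note <- "undefined fold: reference count in target window is zero"
    NA_real_
  } else {
    windows$freq_target_set[i] / windows$freq_reference_set[i]
  }
  structure(
    list(windows = windows, fold = fold, target_window = target_window,
         n_target = length(pt), n_reference = length(pr), note = note),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> fold =", round(x$fold, 2), "in window",
      x$target_window, "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  print(x$windows)
  invisible(x)
}

#' @describeIn window_enrichment Per-window tibble of counts and frequencies.
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) x$windows

#' @describeIn window_enrichment One-row summary (`fold`, `target_window`,
#'   totals).
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(fold = x$fold, target_window = x$target_window,
                 n_target = x$n_target, n_reference = x$n_reference)
}

#' Bar plot of per-window normalized frequencies
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$windows, dplyr::all_of(c("freq_target_set", "freq_reference_set")),
    names_to = "set", values_to = "freq"
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$window), .data$freq,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "5-kb window", y = "normalized frequency") +
    ggplot2::theme_minimal()
}

#' Bootstrap error of a windowed fold enrichment
#'
#' Resamples both binding sets with replacement and recomputes the fold,
#' giving the resampling SD and percentile CI of the enrichment estimate.
#'
#' @inheritParams window_enrichment
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @return A one-row tibble: `fold`, `sd`, `ci_lo`, `ci_hi`, `B`.
#' @export
bootstrap_fold <- function(target, reference,
                           layout = default_window_layout(),
                           target_window = NULL, B = 1000, seed = 1) {
  getpos <- function(x) if (is.numeric(x)) x else x$position_kb
  pt <- getpos(target); pr <- getpos(reference)
  point <- window_enrichment(pt, pr, layout, target_window)$fold
  set.seed(seed)
  folds <- vapply(seq_len(B), function(i) {
    window_enrichment(pt[sample.int(length(pt), replace = TRUE)],
                      pr[sample.int(length(pr), replace = TRUE)],
                      layout, target_window)$fold
  }, numeric(1))
  ci <- stats::quantile(folds, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble::tibble(fold = point, sd = stats::sd(folds, na.rm = TRUE),
                 ci_lo = ci[1], ci_hi = ci[2], B = as.integer(B))
}

#' Two-tailed t-test of target-window vs homoduplex-window frequencies
#'
#' Welch's unequal-variance two-sample t-test by default. If both groups are
#' (numerically) zero-variance the t statistic is undefined, and the function
#' falls back to an exact/Monte-Carlo permutation test on the difference of
#' means, reported in `method`.
#'
#' @param target_freqs Normalized target-window frequencies (>= 2 values,
#'   e.g. one per modified substrate).
#' @param reference_freqs Normalized frequencies of the homoduplex windows.
#' @param n_perm Permutation count for the degenerate fallback.
#' @param seed Seed for the Monte-Carlo permutation fallback.
#' @return A one-row tibble: `t`, `df`, `p`, `method`.
#' @export
windows_t_test <- function(target_freqs, reference_freqs, n_perm = 10000,
                           seed = 1) {
  if (length(target_freqs) < 2 || length(reference_freqs) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  v1 <- stats::var(target_freqs); v2 <- stats::var(reference_freqs)
  if (v1 < 1e-24 && v2 < 1e-24) {
    obs <- abs(mean(target_freqs) - mean(reference_freqs))
    pooled <- c(target_freqs, reference_freqs)
    n1 <- length(target_freqs)
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
    p <- (1 + sum(perm >= obs - 1e-15)) / (n_perm + 1)
    return(tibble::tibble(t = NA_real_, df = NA_real_, p = p,
                          method = "permutation (degenerate variance)"))
  }
  ht <- stats::t.test(target_freqs, reference_freqs, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, method = "Welch two-sample t-test")
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's statistic against independence (no continuity correction);
#' degrees of freedom `(r-1)(c-1)`. A note is recorded when any expected
#' cell count falls below 1.
#'
#' @param table A matrix of non-negative integer counts with no all-zero
#'   margin.
#' @return A one-row tibble: `statistic`, `dof`, `p`, `warning` (NA or a
#'   small-expected-count note).
#' @examples
#' chi_squared_table(matrix(c(20, 10, 10, 20), 2))
#' @export
chi_squared_table <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has an all-zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  note <- if (any(expected < 1)) "expected cell count < 1" else NA_character_
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 dof = unname(ht$parameter), p = ht$p.value, warning = note)
}

#' Read/write binding sets as CSV
#'
#' @param binding Binding-set tibble (`substrate`, `flowcell`, `position_kb`,
#'   `on_dna`, ...).
#' @param path CSV path.
#' @return `write_binding_csv`: `path` invisibly; `read_binding_csv`: a
#'   tibble.
#' @export
write_binding_csv <- function(binding, path) {
  readr::write_csv(binding, path)
  invisible(path)
}

#' @rdname write_binding_csv
#' @export
read_binding_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
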