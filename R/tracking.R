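# separable Gaussian blur with edge renormalization ("same" size)
gaussian_blur <- function(frame, sigma) {
  half <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-half:half, 0, sigma)
  conv1 <- function(m) { # along rows of m
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      okr <- src >= 1 & src <= n
      out[okr, ] <- out[okr, ] + k[j] * m[src[okr], ]
      norm[okr] <- norm[okr] + k[j]
    }
    out / norm
  }
  t(conv1(t(conv1(frame))))
}

#' Detect candidate particles in a single frame
#'
#' The frame is first smoothed with a Gaussian matched filter (the PSF
#' sigma), the standard pre-step that suppresses single-pixel shot noise.
#' Candidates are strict local maxima (8-neighborhood) of the smoothed image
#' exceeding its robust background threshold `median + k * MAD`, then
#' non-maximum-suppressed so that no two candidates lie within one PSF radius
#' (2 sigma) of each other (brightest kept).
#'
#' @param frame A 2D numeric image matrix.
#' @param threshold_k Threshold multiplier `k` (default 6).
#' @param psf_sigma_px PSF sigma used for the matched filter and the
#'   suppression radius.
#' @return A tibble with columns `x_px`, `y_px` (integer pixel coordinates)
#'   and `intensity` (raw-frame value), ordered by decreasing intensity.
#' @export
detect_spots <- function(frame, threshold_k = 6, psf_sigma_px = 1.1) {
  if (!is.matrix(frame) || any(dim(frame) < 3) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix of size >= 3x3", call. = FALSE)
  }
  sm <- gaussian_blur(frame, psf_sigma_px)
  thr <- stats::median(sm) + threshold_k * stats::mad(sm)
  ny <- nrow(frame); nx <- ncol(frame)
  core <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & core >= sm[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(x_px = integer(), y_px = integer(),
                          intensity = numeric()))
  }
  cand <- tibble::tibble(
    x_px = idx[, 2] + 1L, y_px = idx[, 1] + 1L,
    intensity = frame[cbind(idx[, 1] + 1L, idx[, 2] + 1L)]
  )
  cand <- dplyr::arrange(cand, dplyr::desc(.data$intensity), .data$y_px,
                         .data$x_px)
  r2 <- (2 * psf_sigma_px)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1)])
    d2 <- (cand$x_px[i] - cand$x_px[prev])^2 + (cand$y_px[i] - cand$y_px[prev])^2
    keep[i] <- all(d2 > r2)
  }
  cand[keep, ]
}

# Pixel-integrated symmetric 2D Gaussian + offset, matching the renderer.
gauss2d_model <- function(par, rows, cols) {
  wx <- stats::pnorm(cols + 0.5, par[["x"]], par[["sigma"]]) -
    stats::pnorm(cols - 0.5, par[["x"]], par[["sigma"]])
  wy <- stats::pnorm(rows + 0.5, par[["y"]], par[["sigma"]]) -
    stats::pnorm(rows - 0.5, par[["y"]], par[["sigma"]])
  par[["offset"]] + par[["amp"]] * as.vector(outer(wy, wx))
}

failed_localization <- function(frame_index, code) {
  tibble::tibble(
    frame = frame_index, x_px = NA_real_, y_px = NA_real_,
    amplitude = NA_real_, sigma_px = NA_real_, offset = NA_real_,
    rss = NA_real_, ok = FALSE, code = code
  )
}

#' Localize one candidate by least-squares 2D Gaussian fitting
#'
#' Fits a symmetric pixel-integrated 2D Gaussian plus constant offset to a
#' square region of interest around the candidate, returning the subpixel
#' center. Fit failures are reported with a failure code, never silently
#' dropped.
#'
#' @param frame A 2D numeric image matrix.
#' @param x_px,y_px Candidate pixel coordinates (e.g. from [detect_spots()]).
#' @param roi_half Half-width of the square ROI in pixels (default 5); the
#'   ROI must lie fully inside the frame.
#' @param frame_index Frame index recorded in the output (0-based).
#' @return A one-row tibble: `frame`, `x_px`, `y_px` (subpixel), `amplitude`
#'   (total photons), `sigma_px`, `offset`, `rss`, `ok`, `code`
#'   (`"ok"`, `"no_signal"` or `"no_convergence"`).
#' @export
fit_gaussian_2d <- function(frame, x_px, y_px, roi_half = 5L,
                            frame_index = 0L) {
  x0 <- round(x_px); y0 <- round(y_px)
  if (x0 - roi_half < 1 || x0 + roi_half > ncol(frame) ||
      y0 - roi_half < 1 || y0 + roi_half > nrow(frame)) {
    stop("ROI extends outside the frame", call. = FALSE)
  }
  rows <- (y0 - roi_half):(y0 + roi_half)
  cols <- (x0 - roi_half):(x0 + roi_half)
  roi <- frame[rows, cols]
  bg <- stats::median(roi)
  peak <- max(roi) - bg
  spread <- stats::mad(roi)
  if (peak <= 0 || peak <= 3 * max(spread, 1e-12)) {
    return(failed_localization(frame_index, "no_signal"))
  }
  z <- as.vector(roi)
  start <- c(x = x_px, y = y_px, amp = peak * 2 * pi * 1.2^2,
             sigma = 1.2, offset = bg)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(par) z - gauss2d_model(par, rows, cols),
      lower = c(min(cols), min(rows), 0, 0.3, -Inf),
      upper = c(max(cols), max(rows), Inf, roi_half, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info %in% c(0, 5)) {
    return(failed_localization(frame_index, "no_convergence"))
  }
  p <- fit$par
  tibble::tibble(
    frame = frame_index, x_px = p[["x"]], y_px = p[["y"]],
    amplitude = p[["amp"]], sigma_px = p[["sigma"]], offset = p[["offset"]],
    rss = sum(fit$fvec^2), ok = TRUE, code = "ok"
  )
}

#' Detect and localize particles in every frame of a stack
#'
#' Runs [detect_spots()] then [fit_gaussian_2d()] frame by frame, keeping
#' candidates whose ROI fits inside the image.
#'
#' @param stack A `frame_stack` array (ny, nx, frames).
#' @param threshold_k Detection threshold multiplier.
#' @param psf_sigma_px PSF sigma for detection suppression.
#' @param roi_half Fit ROI half-width.
#' @return A tibble of localizations (see [fit_gaussian_2d()]); failed fits
#'   are retained with `ok = FALSE`.
#' @export
localize_stack <- function(stack, threshold_k = 6, psf_sigma_px = 1.1,
                           roi_half = 5L) {
  purrr::map_dfr(seq_len(dim(stack)[3]), function(k) {
    frame <- stack[, , k]
    cand <- detect_spots(frame, threshold_k, psf_sigma_px)
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[cand$x_px - roi_half >= 1 & cand$x_px + roi_half <= ncol(frame) &
                   cand$y_px - roi_half >= 1 & cand$y_px + roi_half <= nrow(frame), ]
    purrr::map_dfr(seq_len(nrow(cand)), function(i) {
      fit_gaussian_2d(frame, cand$x_px[i], cand$y_px[i], roi_half,
                      frame_index = k - 1L)
    })
  })
}

#' Link per-frame localizations into trajectories
#'
#' Greedy nearest-neighbor linking: within each frame, candidate-to-track
#' assignments are made in order of increasing displacement (ties broken by
#' lower track id), subject to a per-frame displacement gate that scales with
#' the gap length. Tracks unmatched for more than `max_gap` frames are
#' closed; unmatched detections start new tracks. Each localization belongs
#' to at most one trajectory and gap frames carry no interpolated rows.
#'
#' @param locs Localization tibble with columns `frame`, `x_px`, `y_px`
#'   (rows with `ok = FALSE` are ignored if present).
#' @param max_disp Maximum displacement per elapsed frame, px.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @return The localizations augmented with a `particle` column, sorted by
#'   particle then frame.
#' @export
link_trajectories <- function(locs, max_disp = 5, max_gap = 1) {
  locs <- tibble::as_tibble(locs)
  if ("ok" %in% names(locs)) locs <- locs[locs$ok, ]
  if (nrow(locs) == 0) {
    return(dplyr::mutate(locs, particle = integer()))
  }
  locs <- dplyr::arrange(locs, .data$frame)
  locs$particle <- NA_integer_
  frames <- sort(unique(locs$frame))
  # active track state
  track_id <- integer(0); track_x <- numeric(0); track_y <- numeric(0)
  track_last <- integer(0)
  next_id <- 1L
  for (f in frames) {
    rows <- which(locs$frame == f)
    # retire stale tracks
    live <- track_last >= f - 1L - max_gap
    track_id <- track_id[live]; track_x <- track_x[live]
    track_y <- track_y[live]; track_last <- track_last[live]
    if (length(track_id) > 0 && length(rows) > 0) {
      gap <- f - track_last
      d <- outer(seq_along(rows), seq_along(track_id),
                 function(i, j) sqrt((locs$x_px[rows[i]] - track_x[j])^2 +
                                       (locs$y_px[rows[i]] - track_y[j])^2))
      gate <- matrix(max_disp * gap, nrow = length(rows),
                     ncol = length(track_id), byrow = TRUE)
      cand <- which(d <= gate, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], track_id[cand[, 2]])
        used_det <- logical(length(rows)); used_trk <- logical(length(track_id))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_det[i] || used_trk[j]) next
          used_det[i] <- TRUE; used_trk[j] <- TRUE
          locs$particle[rows[i]] <- track_id[j]
          track_x[j] <- locs$x_px[rows[i]]; track_y[j] <- locs$y_px[rows[i]]
          track_last[j] <- f
        }
      }
    }
    # unmatched detections start new tracks
    new_rows <- rows[is.na(locs$particle[rows])]
    for (i in new_rows) {
      locs$particle[i] <- next_id
      track_id <- c(track_id, next_id)
      track_x <- c(track_x, locs$x_px[i]); track_y <- c(track_y, locs$y_px[i])
      track_last <- c(track_last, f)
      next_id <- next_id + 1L
    }
  }
  dplyr::arrange(locs, .data$particle, .data$frame)
}

#' Full tracking pipeline on an image stack
#'
#' Convenience wrapper: [localize_stack()] then [link_trajectories()].
#'
#' @inheritParams localize_stack
#' @inheritParams link_trajectories
#' @return A trajectory tibble with `particle`, `frame`, `x_px`, `y_px`, ...
#' @export
track_stack <- function(stack, threshold_k = 6, psf_sigma_px = 1.1,
                        roi_half = 5L, max_disp = 5, max_gap = 1) {
  link_trajectories(localize_stack(stack, threshold_k, psf_sigma_px, roi_half),
                    max_disp = max_disp, max_gap = max_gap)
}

#' Extract a kymograph from an image stack
#'
#' Averages a horizontal band of rows (the DNA axis) per frame and stacks the
#' profiles into a position-by-frame array.
#'
#' @param stack A `frame_stack` array (ny, nx, frames).
#' @param row Center row of the DNA molecule.
#' @param halfwidth Rows averaged on each side of `row`.
#' @return A `kymograph` object: matrix of dim (nx, n_frames) with attributes
#'   `pixel_um` and `frame_interval_s` inherited from the stack.
#' @export
extract_kymograph <- function(stack, row, halfwidth = 1L) {
  ny <- dim(stack)[1]
  if (row - halfwidth < 1 || row + halfwidth > ny) {
    stop("kymograph band extends outside the image", call. = FALSE)
  }
  band <- stack[(row - halfwidth):(row + halfwidth), , , drop = FALSE]
  km <- apply(band, c(2, 3), mean)
  structure(km, class = "kymograph",
            pixel_um = attr(stack, "pixel_um"),
            frame_interval_s = attr(stack, "frame_interval_s"))
}

#' Plot a kymograph
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot object (position vs time, intensity fill).
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    frame = seq_len(ncol(object)),
    position_px = seq_len(nrow(object))
  )
  df$intensity <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$position_px,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "position (px)") +
    ggplot2::theme_minimal()
}
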