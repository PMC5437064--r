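#' Render particle positions into a synthetic image stack
#'
#' Each particle is drawn as a symmetric 2D Gaussian point-spread function
#' integrated over the pixel grid (pixel `c` spans `[c - 0.5, c + 0.5)` in
#' pixel coordinates, so integer coordinates are pixel centers). Per frame,
#' the expected image is background plus the summed PSFs; observed counts are
#' Poisson draws plus Gaussian read noise, floored at zero and rounded, as on
#' a 16-bit camera.
#'
#' @param positions A tibble with columns `frame` (0-based), `x_px`, `y_px`
#'   and optionally `photons` (photons per frame for that emitter; default
#'   `photon_rate * frame_interval_s` from `optics`).
#' @param dims Image size `c(ny, nx)` in pixels.
#' @param n_frames Number of frames (default: `max(frame) + 1`, at least 1).
#' @param optics Optics parameter list, see [curtain_optics()].
#' @param seed Integer seed for the noise draws.
#' @param noise If `FALSE`, the noiseless expected images are returned.
#' @return A numeric array of dim `c(ny, nx, n_frames)` with class
#'   `frame_stack` and attributes `pixel_um` (if supplied via `optics`) and
#'   `frame_interval_s`.
#' @export
render_frames <- function(positions, dims = c(32L, 64L), n_frames = NULL,
                          optics = curtain_optics(), seed = 1, noise = TRUE) {
  if (optics$photon_rate <= 0) {
    stop("photon rate must be positive", call. = FALSE)
  }
  positions <- tibble::as_tibble(positions)
  if (nrow(positions) > 0 && !"photons" %in% names(positions)) {
    positions$photons <- optics$photon_rate * optics$frame_interval_s
  }
  n_frames <- n_frames %||% (if (nrow(positions) > 0) max(positions$frame) + 1L else 1L)
  ny <- dims[1]; nx <- dims[2]
  sigma <- optics$psf_sigma_px
  stack <- array(optics$background, dim = c(ny, nx, n_frames))
  half <- ceiling(6 * sigma)
  if (nrow(positions) > 0) {
    for (i in seq_len(nrow(positions))) {
      fr <- positions$frame[i] + 1L
      if (fr < 1 || fr > n_frames) next
      x <- positions$x_px[i]; y <- positions$y_px[i]
      cols <- max(1L, floor(x - half)):min(nx, ceiling(x + half))
      rows <- max(1L, floor(y - half)):min(ny, ceiling(y + half))
      if (length(cols) == 0 || length(rows) == 0) next
      wx <- stats::pnorm(cols + 0.5, x, sigma) - stats::pnorm(cols - 0.5, x, sigma)
      wy <- stats::pnorm(rows + 0.5, y, sigma) - stats::pnorm(rows - 0.5, y, sigma)
      stack[rows, cols, fr] <- stack[rows, cols, fr] +
        positions$photons[i] * outer(wy, wx)
    }
  }
  if (noise) {
    set.seed(seed)
    n <- length(stack)
    stack[] <- pmax(0, round(
      stats::rpois(n, stack) + stats::rnorm(n, 0, optics$read_noise_sd)
    ))
  }
  structure(stack, class = "frame_stack",
            pixel_um = optics$pixel_um %||% NA_real_,
            frame_interval_s = optics$frame_interval_s)
}

#' Convert DNA-axis trajectories to image-plane emitter positions
#'
#' Maps positions along the DNA (um from the barrier) onto the image x axis
#' and assigns each particle its own image row, mimicking separate DNA
#' molecules in a curtain.
#'
#' @param traj Trajectory tibble with columns `molecule` (or `particle`),
#'   `frame`, `y_um`.
#' @param geometry Geometry list, see [curtain_geometry()].
#' @param margin_px Left margin between the barrier and image edge.
#' @param row_spacing_px Rows between adjacent DNA molecules.
#' @param first_row_px Row of the first molecule.
#' @return A tibble with columns `particle`, `frame`, `x_px`, `y_px`.
#' @export
trajectories_to_emitters <- function(traj, geometry = curtain_geometry(),
                                     margin_px = 6, row_spacing_px = 6,
                                     first_row_px = 8) {
  traj <- tibble::as_tibble(traj)
  id_col <- if ("particle" %in% names(traj)) "particle" else "molecule"
  ids <- sort(unique(traj[[id_col]]))
  tibble::tibble(
    particle = match(traj[[id_col]], ids),
    frame = traj$frame,
    x_px = margin_px + traj$y_um / geometry$pixel_um,
    y_px = first_row_px + (match(traj[[id_col]], ids) - 1) * row_spacing_px
  )
}

#' Write an image stack as an uncompressed multi-page 16-bit TIFF
#'
#' @param stack A `frame_stack` array (counts).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k]
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @return A `frame_stack` array of counts.
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) stack[, , k] <- round(frames[[k]] * 65535)
  structure(stack, class = "frame_stack")
}
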