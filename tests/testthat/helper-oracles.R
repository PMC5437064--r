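# Independent oracles and fixture builders shared across tests.

# exhaustive double-strand substring scan, independent of Biostrings
brute_scan <- function(sequence, motif) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  hits <- function(pat) {
    n <- nchar(sequence); k <- nchar(pat)
    found <- integer(0)
    for (i in seq_len(n - k + 1)) {
      if (substr(sequence, i, i + k - 1) == pat) found <- c(found, i - 1L)
    }
    found
  }
  top <- hits(motif)
  bottom <- hits(rc(motif))
  out <- tibble::tibble(
    position = c(top, bottom),
    strand = c(rep("top", length(top)), rep("bottom", length(bottom)))
  )
  out[order(out$position, out$strand), ]
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force double loop over Eq-style overlapping displacements
brute_msd <- function(y, n_max) {
  N <- length(y)
  vapply(seq_len(n_max), function(n) {
    acc <- 0
    for (i in seq_len(N - n)) acc <- acc + (y[i + n] - y[i])^2
    acc / (N - n)
  }, numeric(1))
}

# textbook Welch t statistic
welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# a synthetic lambda-length sequence with BspQI motifs planted at known
# positions/strands and none elsewhere (motif-free random background)
synthetic_lambda_sequence <- function(top_positions, bottom_positions,
                                      length_nt = 48502, seed = 99) {
  motif <- "GCTCTTC"
  rc_motif <- "GAAGAGC"
  s <- random_dna(length_nt, seed)
  # scrub chance occurrences by mutating their middle base until clean
  repeat {
    occ <- c(gregexpr(motif, s, fixed = TRUE)[[1]],
             gregexpr(rc_motif, s, fixed = TRUE)[[1]])
    occ <- occ[occ > 0]
    if (length(occ) == 0) break
    for (i in occ) substr(s, i + 3, i + 3) <- "A"
  }
  plant <- function(s, pat, pos0) {
    substr(s, pos0 + 1, pos0 + nchar(pat)) <- pat
    s
  }
  for (p in top_positions) s <- plant(s, motif, p)
  for (p in bottom_positions) s <- plant(s, rc_motif, p)
  s
}

# a rendered single-emitter frame with defaults suited to SNR ~ 10
render_single_emitter <- function(x, y, seed = 1, noise = TRUE,
                                  background = 10, photons = 1000,
                                  dims = c(24L, 32L)) {
  opt <- curtain_optics(background = background)
  render_frames(
    tibble::tibble(frame = 0L, x_px = x, y_px = y, photons = photons),
    dims = dims, optics = opt, seed = seed, noise = noise
  )
}
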