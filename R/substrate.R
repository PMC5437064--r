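#' Linear genome map of a lambda-phage substrate
#'
#' A `genome_map` describes a linear DNA substrate as a total length plus a
#' feature table. Coordinates are 0-based, half-open `[start_bp, end_bp)`,
#' measured in bp from the *cosL* end. Point landmarks (insertion sites,
#' modification sites) are stored as 1-bp features whose start is the landmark
#' coordinate.
#'
#' @param length_bp Total substrate length in bp.
#' @param features A data frame with columns `name`, `start_bp`, `end_bp`,
#'   `kind` (one of `insertion_site`, `dispensable`, `cassette`,
#'   `recognition_site`, `modification`) and optionally `strand`
#'   (`top`/`bottom`/`NA`, used for strand-resolved recognition sites).
#' @return An object of class `genome_map`.
#' @seealso [build_lambda_map()]
#' @export
genome_map <- function(length_bp, features = NULL) {
  if (is.null(features)) {
    features <- tibble::tibble(
      name = character(), start_bp = integer(), end_bp = integer(),
      kind = character(), strand = character()
    )
  }
  features <- tibble::as_tibble(features)
  if (!"strand" %in% names(features)) features$strand <- NA_character_
  features <- features[, c("name", "start_bp", "end_bp", "kind", "strand")]
  map <- structure(
    list(length_bp = as.integer(length_bp), features = features),
    class = "genome_map"
  )
  validate_genome_map(map)
  map
}

feature_kinds <- c(
  "insertion_site", "dispensable", "cassette", "recognition_site",
  "modification"
)

validate_genome_map <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  if (is.na(map$length_bp) || map$length_bp <= 0) {
    stop("genome_map length_bp must be a positive integer", call. = FALSE)
  }
  ft <- map$features
  if (nrow(ft) == 0) return(invisible(map))
  bad_kind <- setdiff(unique(ft$kind), feature_kinds)
  if (length(bad_kind) > 0) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  oob <- ft$start_bp < 0 | ft$end_bp > map$length_bp | ft$start_bp > ft$end_bp
  if (any(oob)) {
    stop("feature(s) out of range or inverted: ",
         paste(ft$name[oob], collapse = ", "), call. = FALSE)
  }
  # Overlap is checked within a feature kind only: point landmarks legitimately
  # sit inside dispensable segments.
  for (k in unique(ft$kind)) {
    sub <- dplyr::arrange(ft[ft$kind == k & ft$end_bp > ft$start_bp, ],
                          .data$start_bp)
    if (nrow(sub) > 1) {
      ovl <- sub$start_bp[-1] < sub$end_bp[-nrow(sub)]
      if (any(ovl)) {
        stop("overlapping ", k, " features: ",
             paste(sub$name[c(FALSE, ovl) | c(ovl, FALSE)], collapse = ", "),
             call. = FALSE)
      }
    }
  }
  invisible(map)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$length_bp, " bp (", round(x$length_bp / 1000, 1),
      " kb), ", nrow(x$features), " features\n", sep = "")
  if (nrow(x$features) > 0) print(x$features, n = 10)
  invisible(x)
}

#' Build the default lambda substrate map
#'
#' Constructs the 48,502-bp lambda-phage substrate with the three engineered
#' insertion sites A, B and C (centered 21,300, 33,500 and 45,300 bp from
#' *cosL*), a 16-kb dispensable segment between gene products J and N, and a
#' 1.6-kb dispensable segment between Rz and the *cosR* end.
#'
#' @param overrides Optional feature data frame replacing the default feature
#'   set entirely (same columns as [genome_map()]); `length_bp` is kept at the
#'   wild-type 48,502 bp unless also overridden.
#' @param length_bp Substrate length in bp (default wild-type 48502).
#' @return A [genome_map()].
#' @examples
#' map <- build_lambda_map()
#' site_centers(map)
#' @export
build_lambda_map <- function(overrides = NULL, length_bp = 48502L) {
  if (!is.null(overrides)) {
    return(genome_map(length_bp, overrides))
  }
  features <- tibble::tibble(
    name = c("siteA", "siteB", "siteC", "dispensable_J_N", "dispensable_Rz_cosR"),
    start_bp = c(21300L, 33500L, 45300L, 18500L, 46902L),
    end_bp = c(21301L, 33501L, 45301L, 34500L, 48502L),
    kind = c(rep("insertion_site", 3), rep("dispensable", 2)),
    strand = NA_character_
  )
  genome_map(length_bp, features)
}

#' Feature centers of a genome map, in bp
#'
#' @param map A [genome_map()].
#' @param kind Feature kind to report (default `insertion_site`).
#' @return Named integer vector of feature midpoints (floor of the interval
#'   center; for 1-bp landmarks this is the landmark coordinate).
#' @export
site_centers <- function(map, kind = "insertion_site") {
  ft <- map$features[map$features$kind == kind, ]
  stats::setNames(as.integer(floor((ft$start_bp + ft$end_bp - 1) / 2)), ft$name)
}

#' Describe a recombineering cassette
#'
#' @param insert_length_bp Length of the inserted DNA in bp (>= 0).
#' @param replaced_length_bp Length of native sequence replaced, centered on
#'   the target site.
#' @param target_site Name of the insertion-site feature to target.
#' @param marker Antibiotic-marker label carried by the cassette.
#' @param homology_arm_bp Homology arm length flanking the cassette (bp; the
#'   arms anneal outside the replaced interval and do not change the length
#'   arithmetic).
#' @return An object of class `cassette`.
#' @export
cassette <- function(insert_length_bp, replaced_length_bp = 0L,
                     target_site = "siteA", marker = "kanR",
                     homology_arm_bp = 200L) {
  if (homology_arm_bp <= 0) stop("homology_arm_bp must be > 0", call. = FALSE)
  if (insert_length_bp < 0) stop("insert_length_bp must be >= 0", call. = FALSE)
  structure(
    list(
      insert_length_bp = as.integer(insert_length_bp),
      replaced_length_bp = as.integer(replaced_length_bp),
      target_site = target_site, marker = marker,
      homology_arm_bp = as.integer(homology_arm_bp)
    ),
    class = "cassette"
  )
}

# Phage-capsid packaging limits: 78-105% of the wild-type genome.
packaging_limits_bp <- c(38000L, 53000L)

#' Is a substrate length packageable into lambda capsids?
#'
#' Packaging tolerates substrates between 78% and 105% of the wild-type
#' genome length, i.e. 38 to 53 kb.
#'
#' @param length_bp Substrate length in bp.
#' @return Logical vector.
#' @export
is_packageable <- function(length_bp) {
  length_bp >= packaging_limits_bp[1] & length_bp <= packaging_limits_bp[2]
}

#' Insert a recombineering cassette into a substrate map
#'
#' Replaces `replaced_length_bp` of native sequence centered on the target
#' insertion site with the cassette insert, shifting all downstream feature
#' coordinates by the net length change and recording the cassette as a
#' feature. The insertion-site landmark is retained at the center of the new
#' cassette, so a second insertion with swapped insert/replaced lengths
#' restores the original layout.
#'
#' @param map A [genome_map()].
#' @param cas A [cassette()].
#' @return A new [genome_map()] with attribute `packaging_ok = TRUE`.
#' @export
insert_cassette <- function(map, cas) {
  stopifnot(inherits(map, "genome_map"), inherits(cas, "cassette"))
  centers <- site_centers(map)
  if (!cas$target_site %in% names(centers)) {
    stop("target site '", cas$target_site, "' not present in map", call. = FALSE)
  }
  center <- centers[[cas$target_site]]
  half <- cas$replaced_length_bp %/% 2
  repl_start <- center - half
  repl_end <- repl_start + cas$replaced_length_bp
  if (repl_start < 0 || repl_end > map$length_bp) {
    stop("replaced interval extends outside the substrate", call. = FALSE)
  }
  delta <- cas$insert_length_bp - cas$replaced_length_bp
  new_len <- map$length_bp + delta
  if (!is_packageable(new_len)) {
    stop("packaging violation: resulting length ", new_len,
         " bp is outside the 38,000-53,000 bp packageable range", call. = FALSE)
  }

  ft <- map$features
  is_target <- ft$name == cas$target_site
  # previous cassette at this site is consumed by the replacement
  consumed <- !is_target & ft$start_bp >= repl_start & ft$end_bp <= repl_end &
    ft$end_bp > ft$start_bp & ft$kind == "cassette"
  ft <- ft[!consumed, ]
  shift <- function(pos) {
    dplyr::case_when(
      pos <= repl_start ~ pos,
      pos >= repl_end ~ pos + delta,
      TRUE ~ repl_start # positions inside the replaced interval collapse
    )
  }
  ft <- dplyr::mutate(
    ft,
    start_bp = as.integer(shift(.data$start_bp)),
    end_bp = as.integer(shift(.data$end_bp))
  )
  # re-center the target landmark and add the cassette feature
  new_center <- repl_start + cas$insert_length_bp %/% 2
  ft$start_bp[ft$name == cas$target_site] <- as.integer(new_center)
  ft$end_bp[ft$name == cas$target_site] <- as.integer(new_center + 1L)
  if (cas$insert_length_bp > 0) {
    ft <- dplyr::bind_rows(ft, tibble::tibble(
      name = paste0("cassette_", cas$marker, "_", cas$target_site),
      start_bp = as.integer(repl_start),
      end_bp = as.integer(repl_start + cas$insert_length_bp),
      kind = "cassette", strand = NA_character_
    ))
  }
  out <- genome_map(new_len, ft)
  attr(out, "packaging_ok") <- TRUE
  out
}

#' Scan a sequence for a recognition motif on both strands
#'
#' Reports every occurrence of `motif` on the top strand and every occurrence
#' of its reverse complement (reported as a bottom-strand site) with 0-based
#' start positions on the top-strand coordinate system. Overlapping
#' occurrences are all reported. IUPAC ambiguity codes are rejected so site
#' counts are deterministic.
#'
#' @param sequence A nucleotide string over A/C/G/T, or a `Biostrings::DNAString`.
#' @param motif Non-empty nucleotide string over A/C/G/T (e.g. `"GCTCTTC"`
#'   for BspQI).
#' @return A tibble with columns `position` (0-based start of the match on the
#'   top strand) and `strand` (`"top"` or `"bottom"`), sorted by position.
#' @examples
#' scan_recognition_sites("AAGCTCTTCAA", "GCTCTTC")
#' @export
scan_recognition_sites <- function(sequence, motif) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "XString")) {
    sequence <- as.character(sequence)
  }
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (nchar(motif) == 0) stop("motif must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", sequence) || grepl("[^ACGT]", motif)) {
    stop("sequence and motif must contain only A/C/G/T ",
         "(ambiguity codes are rejected)", call. = FALSE)
  }
  subject <- Biostrings::DNAString(sequence)
  top <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(motif))
  bottom <- Biostrings::matchPattern(rc, subject)
  out <- tibble::tibble(
    position = c(BiocGenerics::start(top), BiocGenerics::start(bottom)) - 1L,
    strand = c(rep("top", length(top)), rep("bottom", length(bottom)))
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Read a genome sequence from a FASTA file
#'
#' @param path Path to a (single-record) FASTA file.
#' @return The sequence as an uppercase character string.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path, call. = FALSE)
  toupper(as.character(seqs[[1]]))
}

#' Describe a three-nick nicking cassette
#'
#' The cassette carries three consecutive nickase (Nt.BspQI) recognition
#' sequences separated by 12-13 bp spacers; nicking all three top-strand
#' sites exposes the single-stranded segment between the first and last nick
#' (39 nt in the default design), which is replaced by a synthetic
#' oligonucleotide.
#'
#' @param nick_positions_bp Three strictly increasing top-strand nick
#'   coordinates (bp from *cosL*).
#' @param spacer_bp Spacer lengths between recognition sequences (informative).
#' @param diagnostic_sites Optional tibble of diagnostic restriction sites:
#'   columns `enzyme`, `position`, `abolished_by_insert`.
#' @return An object of class `nicking_cassette` with field `excised_nt`
#'   (last minus first nick).
#' @export
nicking_cassette <- function(nick_positions_bp, spacer_bp = c(12L, 13L),
                             diagnostic_sites = NULL) {
  nick_positions_bp <- as.integer(nick_positions_bp)
  if (length(nick_positions_bp) != 3 || any(diff(nick_positions_bp) <= 0)) {
    stop("nick_positions_bp must be three strictly increasing coordinates",
         call. = FALSE)
  }
  structure(
    list(
      nick_positions_bp = nick_positions_bp,
      spacer_bp = spacer_bp,
      excised_nt = nick_positions_bp[3] - nick_positions_bp[1],
      diagnostic_sites = diagnostic_sites
    ),
    class = "nicking_cassette"
  )
}

#' Default site-A nicking cassette
#'
#' Nicks at 21,300 / 21,319 / 21,339 bp (7-nt recognition sequence plus
#' 12-13 bp spacers), excising 39 nt of the top strand. The diagnostic NcoI
#' pair flanking the cassette cuts at 20,500 / 21,300 / 23,300 bp, yielding
#' the 0.8-kb and 2.0-kb diagnostic fragments; the flap insert abolishes the
#' flap-proximal site at 21,300 bp.
#'
#' @return A [nicking_cassette()].
#' @export
site_a_nicking_cassette <- function() {
  nicking_cassette(
    nick_positions_bp = c(21300L, 21319L, 21339L),
    spacer_bp = c(12L, 13L),
    diagnostic_sites = tibble::tibble(
      enzyme = "NcoI",
      position = c(20500L, 21300L, 23300L),
      abolished_by_insert = c(FALSE, TRUE, FALSE)
    )
  )
}

new_digest_result <- function(fragment_bp, strand) {
  structure(
    tibble::tibble(fragment_bp = as.integer(fragment_bp), strand = strand),
    class = c("digest_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Predict denaturing-gel strand fragments after nicking and oligo insertion
#'
#' Models the alkaline (denaturing) gel readout of a nicked, oligo-replaced
#' substrate. The bottom strand is never nicked and migrates as one
#' full-length fragment. The top strand depends on the insert mode:
#' `mock` (a complementary oligo perfectly replaces the excised segment and
#' is fully re-ligated) gives a single full-length top strand; `flap` and
#' `gap` leave discontinuities at the outer nicks, so the top strand runs as
#' the two fragments flanking the excised segment (the short synthetic oligo
#' itself is below gel resolution and is not reported).
#'
#' @param map A [genome_map()].
#' @param nicks A [nicking_cassette()], or `NULL` for an unnicked substrate.
#' @param insert_mode One of `"mock"`, `"flap"`, `"gap"`.
#' @return A `digest_result` tibble with columns `fragment_bp` and `strand`
#'   (`"top"`/`"bottom"`).
#' @examples
#' predict_strand_fragments(build_lambda_map(), site_a_nicking_cassette(), "flap")
#' @export
predict_strand_fragments <- function(map, nicks = NULL,
                                     insert_mode = c("mock", "flap", "gap")) {
  insert_mode <- match.arg(insert_mode)
  stopifnot(inherits(map, "genome_map"))
  L <- map$length_bp
  if (is.null(nicks)) {
    return(new_digest_result(c(L, L), c("top", "bottom")))
  }
  stopifnot(inherits(nicks, "nicking_cassette"))
  np <- nicks$nick_positions_bp
  if (any(np < 0) || any(np > L)) {
    stop("nick position outside the substrate (0-", L, " bp)", call. = FALSE)
  }
  top <- switch(insert_mode,
    mock = L,
    flap = ,
    gap = c(np[1], L - np[3])
  )
  new_digest_result(c(top, L), c(rep("top", length(top)), "bottom"))
}

#' Digest a duplex substrate at specified cut positions
#'
#' Fragment lengths are the successive differences over the boundary set
#' `{0} + (cuts - abolished) + {length}`. The fragment multiset always sums
#' to the substrate length.
#'
#' @param map A [genome_map()].
#' @param cut_positions Sorted cut coordinates (bp), within the substrate.
#' @param abolished Cut positions rendered uncleavable (e.g. by an inserted
#'   oligonucleotide); must be a subset of `cut_positions`.
#' @return A `digest_result` tibble with columns `fragment_bp`,
#'   `strand = "duplex"`, and per-fragment `start_bp`/`end_bp`.
#' @examples
#' digest_duplex(build_lambda_map(), c(10000, 20000, 30000))
#' @export
digest_duplex <- function(map, cut_positions, abolished = integer()) {
  stopifnot(inherits(map, "genome_map"))
  cut_positions <- as.integer(cut_positions)
  if (anyDuplicated(cut_positions)) {
    stop("duplicate cut positions", call. = FALSE)
  }
  if (is.unsorted(cut_positions)) {
    stop("cut positions must be sorted", call. = FALSE)
  }
  if (length(cut_positions) > 0 &&
      (min(cut_positions) < 0 || max(cut_positions) > map$length_bp)) {
    stop("cut position outside the substrate", call. = FALSE)
  }
  abolished <- as.integer(abolished)
  if (!all(abolished %in% cut_positions)) {
    stop("abolished sites must be a subset of cut positions", call. = FALSE)
  }
  cuts <- setdiff(cut_positions, abolished)
  bounds <- unique(c(0L, cuts, map$length_bp))
  out <- new_digest_result(diff(bounds), "duplex")
  out$start_bp <- bounds[-length(bounds)]
  out$end_bp <- bounds[-1]
  out
}

#' Diagnostic duplex digest of a nicking-cassette substrate
#'
#' Runs [digest_duplex()] with a cassette's diagnostic restriction sites,
#' honoring `abolished_by_insert` flags when the insert is present.
#'
#' @param map A [genome_map()].
#' @param nicks A [nicking_cassette()] with `diagnostic_sites`.
#' @param enzyme Enzyme name to select from the diagnostic table.
#' @param insert_present If `TRUE`, sites flagged `abolished_by_insert` are
#'   not cut.
#' @return A `digest_result` tibble (see [digest_duplex()]).
#' @export
diagnostic_digest <- function(map, nicks = site_a_nicking_cassette(),
                              enzyme = "NcoI", insert_present = TRUE) {
  ds <- nicks$diagnostic_sites
  if (is.null(ds)) stop("cassette has no diagnostic sites", call. = FALSE)
  ds <- ds[ds$enzyme == enzyme, ]
  abol <- if (insert_present) ds$position[ds$abolished_by_insert] else integer()
  digest_duplex(map, sort(ds$position), abolished = abol)
}

#' Write digest fragments to CSV
#'
#' @param digest A `digest_result` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_digest_csv <- function(digest, path) {
  readr::write_csv(digest, path)
  invisible(path)
}

#' Read a feature table from a BED file
#'
#' BED is 0-based, half-open, matching the package's coordinate convention.
#' Column 4 (name) is used as the feature name; the feature `kind` is taken
#' from an optional 5th column when it matches a known kind, else defaults to
#' `"modification"`.
#'
#' @param path Path to a BED file (3+ columns, tab-separated).
#' @return A feature tibble suitable for [genome_map()].
#' @export
read_features_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  kind <- if (ncol(bed) >= 5 && all(bed[[5]] %in% feature_kinds)) {
    bed[[5]]
  } else {
    rep("modification", nrow(bed))
  }
  nm <- if (ncol(bed) >= 4) as.character(bed[[4]]) else paste0("feat", seq_len(nrow(bed)))
  tibble::tibble(
    name = nm,
    start_bp = as.integer(bed[[2]]),
    end_bp = as.integer(bed[[3]]),
    kind = kind,
    strand = NA_character_
  )
}

#' Simulated gel lane of a digest
#'
#' Draws fragment bands at log10(length) positions, mimicking an agarose gel
#' lane.
#'
#' @param object A `digest_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot digest_result
#' @export
autoplot.digest_result <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), kb = .data$fragment_bp / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strand, y = .data$kb)) +
    ggplot2::geom_tile(width = 0.6, height = 0.02, fill = "grey20") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment length (kb)",
                  title = "simulated gel") +
    ggplot2::theme_minimal()
}
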