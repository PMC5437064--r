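test_that("default lambda map has the engineered sites and dispensable segments", {
  map <- build_lambda_map()
  expect_equal(map$length_bp, 48502L)
  expect_equal(site_centers(map),
               c(siteA = 21300L, siteB = 33500L, siteC = 45300L))
  disp <- map$features[map$features$kind == "dispensable", ]
  expect_setequal(disp$end_bp - disp$start_bp, c(16000L, 1600L))

  empty <- build_lambda_map(overrides = data.frame(
    name = character(), start_bp = integer(), end_bp = integer(),
    kind = character()
  ))
  expect_equal(empty$length_bp, 48502L)
  expect_equal(nrow(empty$features), 0L)
})

test_that("genome_map validation names offending features", {
  expect_error(
    genome_map(1000, data.frame(name = "oops", start_bp = 900, end_bp = 1100,
                                kind = "cassette")),
    "oops"
  )
  expect_error(
    genome_map(48502, data.frame(
      name = c("c1", "c2"), start_bp = c(100, 500), end_bp = c(600, 900),
      kind = "cassette"
    )),
    "overlapping"
  )
})

test_that("insert_cassette does the length arithmetic and enforces packaging", {
  map <- build_lambda_map()
  # zero net length change
  same <- insert_cassette(map, cassette(1200, 1200, "siteB"))
  expect_equal(same$length_bp, 48502L)
  expect_true(any(same$features$kind == "cassette"))
  # +500 bp, still packageable
  bigger <- insert_cassette(map, cassette(1500, 1000, "siteB"))
  expect_equal(bigger$length_bp, 49002L)
  expect_true(is_packageable(bigger$length_bp))
  # 12 kb insertion blows the upper packaging bound
  expect_error(insert_cassette(map, cassette(12000, 0, "siteB")),
               "packaging")
  expect_error(insert_cassette(map, cassette(100, 0, "nope")), "not present")
})

test_that("inserting the inverse cassette restores the original layout", {
  map <- build_lambda_map()
  fwd <- insert_cassette(map, cassette(1500, 1000, "siteB", marker = "m"))
  back <- insert_cassette(fwd, cassette(1000, 1500, "siteB", marker = "m"))
  expect_equal(back$length_bp, map$length_bp)
  orig <- dplyr::arrange(map$features, name)
  rest <- dplyr::arrange(
    back$features[back$features$kind != "cassette", ], name)
  # the residual cassette feature aside, coordinates must round-trip exactly
  expect_equal(rest$start_bp, orig$start_bp)
  expect_equal(rest$end_bp, orig$end_bp)
})

test_that("packaging bound is monotone below any passing length", {
  lens <- seq(36000, 55000, by = 500)
  ok <- is_packageable(lens)
  for (i in which(ok)) {
    expect_true(all(ok[lens >= 38000 & lens <= lens[i]]))
  }
  expect_false(is_packageable(37999))
  expect_false(is_packageable(53001))
})

test_that("scan_recognition_sites finds both-strand occurrences at 0-based starts", {
  # 100-nt toy: motif at top position 10, reverse complement at 50
  s <- synthetic_lambda_sequence(top_positions = 10, bottom_positions = 50,
                                 length_nt = 100, seed = 7)
  hits <- scan_recognition_sites(s, "GCTCTTC")
  expect_equal(hits$position, c(10L, 50L))
  expect_equal(hits$strand, c("top", "bottom"))

  expect_equal(nrow(scan_recognition_sites("ACGTACGT", "GGG")), 0L)
  expect_error(scan_recognition_sites("ACGTN", "GG"), "A/C/G/T")
  expect_error(scan_recognition_sites("ACGT", ""), "non-empty")

  # overlapping occurrences are all reported
  ovl <- scan_recognition_sites("AAAAA", "AA")
  expect_equal(sum(ovl$strand == "top"), 4L)
})

test_that("scan agrees with a brute-force double-strand substring scan", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_dna(500, seed = 1000 + i)
    motif <- random_dna(4, seed = 2000 + i)
    got <- scan_recognition_sites(s, motif)
    want <- brute_scan(s, motif)
    expect_equal(got$position, want$position, info = paste("case", i))
    expect_equal(got$strand, want$strand, info = paste("case", i))
  }
})

test_that("a substrate with ten nickase sites is counted both ways", {
  top <- c(2000, 9000, 16000, 21300, 21319, 21339, 30000, 40000)
  bottom <- c(5000, 12000, 25000, 35000, 45000)
  s <- synthetic_lambda_sequence(top, bottom)
  hits <- scan_recognition_sites(s, "GCTCTTC")
  expect_equal(nrow(hits), 13L)                    # both strands
  expect_equal(sum(hits$strand == "top"), 8L)      # nick-relevant strand only
  # ten sites outside the three-nick cassette, the wild-type-like count
  cassette_nicks <- c(21300, 21319, 21339)
  expect_equal(sum(!hits$position %in% cassette_nicks), 10L)
})

test_that("strand fragments: mock is seamless, flap splits the top strand", {
  map <- build_lambda_map()
  nicks <- site_a_nicking_cassette()
  expect_equal(nicks$excised_nt, 39L)

  mock <- predict_strand_fragments(map, nicks, "mock")
  expect_equal(sort(mock$fragment_bp[mock$strand == "top"]), 48502L)
  expect_equal(mock$fragment_bp[mock$strand == "bottom"], 48502L)

  none <- predict_strand_fragments(map, NULL)
  expect_equal(none$fragment_bp, c(48502L, 48502L))

  flap <- predict_strand_fragments(map, nicks, "flap")
  top <- sort(flap$fragment_bp[flap$strand == "top"])
  expect_equal(top, c(21300L, 48502L - 21339L))    # 21300 and 27163 bp
  # conservation: top fragments sum to strand length minus the excised nt
  expect_equal(sum(top), 48502L - 39L)
  expect_equal(flap$fragment_bp[flap$strand == "bottom"], 48502L)

  expect_error(
    predict_strand_fragments(map, nicking_cassette(c(48000, 48500, 48600))),
    "outside"
  )
})

test_that("duplex digest fragments are boundary differences and conserve length", {
  map <- build_lambda_map()
  expect_equal(digest_duplex(map, integer())$fragment_bp, 48502L)
  expect_equal(digest_duplex(map, c(10000, 20000, 30000))$fragment_bp,
               c(10000L, 10000L, 10000L, 18502L))
  expect_error(digest_duplex(map, c(100, 100)), "duplicate")
  expect_error(digest_duplex(map, c(200, 100)), "sorted")
  expect_error(digest_duplex(map, c(100, 50000)), "outside")
  expect_error(digest_duplex(map, c(100, 200), abolished = 300), "subset")

  # abolishing the middle cut merges the two flanking fragments
  full <- digest_duplex(map, c(20500, 21300, 23300))
  expect_true(all(c(800L, 2000L) %in% full$fragment_bp))
  merged <- digest_duplex(map, c(20500, 21300, 23300), abolished = 21300)
  expect_true(2800L %in% merged$fragment_bp)
  expect_false(800L %in% merged$fragment_bp)

  # fragment conservation over random cut sets
  set.seed(11)
  for (i in 1:25) {
    cuts <- sort(sample.int(48501, sample(0:12, 1)))
    d <- digest_duplex(map, cuts)
    expect_identical(sum(d$fragment_bp), 48502L)
  }
})

test_that("BED feature tables round into genome maps", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("lambda\t21300\t21301\tsiteA\tinsertion_site",
               "lambda\t18500\t34500\tdispJ\tdispensable"), bed)
  ft <- read_features_bed(bed)
  map <- genome_map(48502, ft)
  expect_equal(unname(site_centers(map)["siteA"] |> as.integer()), 21300L)
})
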