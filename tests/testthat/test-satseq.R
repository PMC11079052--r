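test_that("gc_content matches direct counts and validates characters", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATTA"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_error(gc_content("ACGX"), "position 4")
  expect_equal(gc_content("ACGN", skip_ambiguous = TRUE), 200 / 3,
               tolerance = 1e-12)
})

test_that("the bundled deer satellite probe is 725 nt at ~55% GC", {
  probes <- satellite_probes()
  deer <- probes[["red_deer_satellite_I_probe"]]
  expect_identical(Biostrings::width(probes)[1], 725L)
  expect_lt(abs(gc_content(deer) - 55), 1)
})

test_that("site scanning handles IUPAC codes, offsets and methylation blocking", {
  expect_identical(find_sites("TACGTA", "HpyCH4IV"), 2L)
  expect_identical(find_sites(methylated_seq("TACGTA", 3), "HpyCH4IV"),
                   integer(0))
  expect_identical(find_sites("AAATTC", "ApoI"), 1L)   # R = A, Y = C
  expect_identical(find_sites("GAATTT", "ApoI"), 1L)   # R = G, Y = T
  expect_identical(find_sites("CAATTC", "ApoI"), integer(0))
  # ApoI ignores methylation entirely
  ms <- methylated_seq("ACGAATTCGT", c(2, 8))
  expect_identical(find_sites(ms, "ApoI"), find_sites("ACGAATTCGT", "ApoI"))
})

test_that("digests cut where expected and respect methylation", {
  d <- digest("AAACGTAAA", "HpyCH4IV")
  expect_identical(d$fragment_lengths, c(3L, 6L))
  dm <- digest(methylated_seq("AAACGTAAA", 4), "HpyCH4IV")
  expect_identical(dm$fragment_lengths, 9L)
  # isoschizomers agree on unmethylated input
  for (seed in 1:5) {
    s <- random_dna(400, seed)
    expect_identical(digest(s, "HpaII")$fragment_lengths,
                     digest(s, "MspI")$fragment_lengths)
  }
})

test_that("fragment lengths always sum to the sequence length", {
  enzymes <- names(restriction_enzymes())
  for (seed in 1:6) {
    s <- random_dna(300, seed)
    cpg <- cpg_positions(s)
    ms <- methylated_seq(s, cpg[seq_along(cpg) %% 2 == 1])
    for (e in enzymes) {
      expect_identical(sum(digest(ms, e)$fragment_lengths), 300L)
      expect_identical(sum(digest(s, e)$fragment_lengths), 300L)
    }
  }
})

test_that("adding methylation never increases blocked-enzyme cuts and never changes ApoI/MspI", {
  for (seed in 1:5) {
    s <- random_dna(500, seed)
    cpg <- cpg_positions(s)
    half <- methylated_seq(s, cpg[seq_along(cpg) %% 2 == 0])
    full <- methylated_seq(s, cpg)
    for (e in c("HpyCH4IV", "HpaII")) {
      n0 <- length(find_sites(s, e))
      n1 <- length(find_sites(half, e))
      n2 <- length(find_sites(full, e))
      expect_lte(n1, n0); expect_lte(n2, n1)
    }
    for (e in c("ApoI", "MspI"))
      expect_identical(find_sites(full, e), find_sites(s, e))
  }
})

test_that("fully methylated arrays resist the methylation-sensitive enzymes", {
  arr <- simulate_satellite_array("TTACGGAACCGGTT", 40, 0, 1, seed = 2)
  expect_identical(digest(arr, "HpyCH4IV")$fragment_lengths,
                   nchar(arr$seq))
  expect_identical(digest(arr, "HpaII")$fragment_lengths, nchar(arr$seq))
  # the insensitive isoschizomer still cuts
  expect_gt(length(find_sites(arr, "MspI")), 0)
})

test_that("palindromic sites give mirror-image cuts on the reverse complement", {
  for (seed in 1:3) {
    s <- random_dna(300, seed)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (e in c("HpyCH4IV", "HpaII")) {
      enz <- restriction_enzymes()[[e]]
      m <- nchar(enz$iupac_site)
      cuts <- find_sites(s, e)
      mirrored <- sort(300L - find_sites(rc, e) - m + 2L * enz$cut_offset)
      expect_identical(cuts, mirrored)
    }
  }
})

test_that("probe matching agrees with the naive scan and handles both strands", {
  seq <- "ACGTACGT"
  expect_identical(count_probe_matches(seq, seq)$count, 1L)
  expect_identical(count_probe_matches(seq, seq)$positions$start, 1L)
  sat <- count_probe_matches("AAAAAA", "AAA", max_mismatches = 3)
  expect_identical(sat$count, 4L)  # every window at saturation
  for (seed in 1:8) {
    s <- random_dna(200, seed)
    p <- random_dna(8, seed + 100)
    for (mm in c(0L, 1L, 2L)) {
      expect_identical(count_probe_matches(s, p, mm, both_strands = TRUE)$count,
                       naive_probe_scan(s, p, mm, both_strands = TRUE))
    }
  }
})

test_that("the FISH oligo hits the satellite probe where the brute scan says", {
  probes <- satellite_probes()
  mouse <- as.character(probes[["mouse_major_satellite_probe"]])
  fish <- as.character(probes[["mouse_major_satellite_fish_probe"]])
  res <- count_probe_matches(mouse, fish, 0, both_strands = TRUE)
  expect_identical(res$count, naive_probe_scan(mouse, fish, 0, TRUE))
  expect_identical(res$count, 1L)  # frozen regression value
})
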