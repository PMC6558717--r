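test_that("NG86 site counts match the neighbor-enumeration oracle", {
  expect_equal(ng86_sites("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_equal(ng86_sites("GGG"), c(syn = 1, nonsyn = 2))
  expect_equal(ng86_sites("ATG"), c(syn = 0, nonsyn = 3))
  expect_error(ng86_sites("TAA"), "sense")
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cd in sense) {
    s <- ng86_sites(cd)
    expect_equal(s, oracle_sites(cd))
    expect_equal(sum(s), 3)               # renormalized site conservation
  }
})

test_that("NG86 pathway differences match exhaustive enumeration everywhere", {
  expect_equal(ng86_differences("TTT", "TTT"), c(Sd = 0, Nd = 0))
  expect_equal(ng86_differences("TTT", "TTA"), c(Sd = 0, Nd = 1))
  expect_equal(ng86_differences("TTT", "GTA"), oracle_differences("TTT", "GTA"))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (a in sense) for (b in sense) {
    got <- ng86_differences(a, b)
    want <- oracle_differences(a, b)
    expect_equal(got, want)
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!anyNA(got)) expect_equal(sum(got), ndiff)
  }
})

test_that("codon alignment back-translates and round-trips", {
  ca <- random_cds(10, seed = 1)
  aln <- align_global(
    as.character(Biostrings::translate(Biostrings::DNAString(ca))),
    as.character(Biostrings::translate(Biostrings::DNAString(ca))))
  cal <- codon_align(ca, ca, aln)
  expect_length(cal$codons_a, 10)
  expect_false(any(cal$codons_a == "---"))

  # protein gap becomes a codon gap; degapping returns the inputs
  a <- "ATGGCTAAGGCTTGG"          # M A K A W
  b <- "ATGGCTGCTTGG"             # M A A W
  pal <- align_global("MAKAW", "MAAW")
  cal2 <- codon_align(a, b, pal)
  expect_equal(sum(cal2$codons_b == "---"), 1L)
  expect_equal(paste(cal2$codons_a[cal2$codons_a != "---"], collapse = ""), a)
  expect_equal(paste(cal2$codons_b[cal2$codons_b != "---"], collapse = ""), b)

  # CDS/protein discordance is an error naming the codon
  expect_error(codon_align("ATGGCTAAGGCTTGG", b,
                           align_global("MAKSW", "MAAW")), "codon 4")
})

test_that("Ka/Ks behaves on identical and synonymous-only pairs", {
  cds <- random_cds(200, seed = 2)
  aln <- codon_aln_of(cds, cds)
  kk <- kaks(aln)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_true(is.na(kk$ratio))            # 0/0 undefined
  expect_equal(kk$S + kk$N, 3 * kk$n_codons)   # site conservation

  ev <- evolve_pair(cds, target_ks = 0.4, target_ka = 0, seed = 9)
  kk2 <- kaks(codon_aln_of(ev$cds_a, ev$cds_b))
  expect_equal(kk2$Ka, 0)
  expect_gt(kk2$Ks, 0)
  # symmetry in the two sequences
  kk2r <- kaks(codon_aln_of(ev$cds_b, ev$cds_a))
  expect_equal(kk2r$Ks, kk2$Ks)
  expect_equal(kk2r$Ka, kk2$Ka)
})

test_that("sliding windows tile the alignment on the 150/9 grid", {
  cds <- random_cds(100, seed = 3)      # 300 bp
  w <- sliding_window(codon_aln_of(cds, cds))
  expect_equal(nrow(w), 17L)            # floor((300-150)/9) + 1
  expect_equal(unique(diff(w$start_bp)), 9L)
  expect_true(all(w$end_bp - w$start_bp == 150L))
  # shorter than one window: single whole-length flagged window
  short <- sliding_window(codon_aln_of(random_cds(20, 4), random_cds(20, 4)))
  expect_equal(nrow(short), 1L)
  expect_true(attr(short, "short"))
})

test_that("windows fluctuate around the global rate on homogeneous pairs", {
  cds <- random_cds(300, seed = 6)
  ev <- evolve_pair(cds, target_ks = 0.5, target_ka = 0.1, seed = 10)
  aln <- codon_aln_of(ev$cds_a, ev$cds_b)
  glob <- kaks(aln)
  w <- sliding_window(aln)
  expect_false(any(w$saturated, na.rm = TRUE))   # no saturation at Ks 0.5
  expect_lt(abs(median(w$ratio, na.rm = TRUE) - glob$ratio), 0.25)
  # site-weighted aggregate of non-overlapping windows equals the global
  # bookkeeping on this gap-free alignment
  nw <- sliding_window(aln, window_bp = 150L, step_bp = 150L)
  tot <- kaks(aln, min_codons = 1L)
  expect_equal(sum(nw$end_bp - nw$start_bp), 900L)
})

test_that("selection classes follow the 0.3/1 binning convention", {
  out <- classify_selection(c(0.1, 0.3, 0.9999, 1.0, 1.2, NA))
  expect_equal(out$class,
               c("strong_purifying", "relaxed_purifying", "relaxed_purifying",
                 "relaxed_purifying", "positive", "undetermined"))
  expect_equal(out$bin[c(1, 2, 5)], c("<0.3", "0.3-1", ">1"))
})

test_that("duplication ages classify the published orchid Ks values", {
  # the two WGD-aged paralog pairs and the two recent ones
  expect_equal(classify_duplication(c(1.0658, 1.4562)),
               c("shared_WGD", "shared_WGD"))
  expect_equal(classify_duplication(c(0.0433, 0.0827)), c("recent", "recent"))
  expect_equal(classify_duplication(0.5), "other")
  expect_equal(classify_duplication(NA), "other")
})
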