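test_that("planted B-BOX2 consensus instance is found at exact coordinates", {
  # C-X3-H-X8-C-X2-D-X5-C-X2-C-X4-H-X3-H embedded in poly-Ala
  inst <- paste0("C", strrep("A", 3), "H", strrep("A", 8), "C",
                 strrep("A", 2), "D", strrep("A", 5), "C", strrep("A", 2),
                 "C", strrep("A", 4), "H", strrep("A", 3), "H")
  prot <- paste0(strrep("A", 20), inst, strrep("A", 15))
  pats <- load_domain_patterns()
  hits <- scan_domain(prot, pats$BBOX2, "p1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 20L)
  expect_equal(hits$end, 20L + nchar(inst))
  expect_equal(hits$matched_anchors, 8L)
})

test_that("poly-Ala protein yields no hits; two planted copies both found", {
  pats <- load_domain_patterns()
  expect_equal(nrow(scan_domain(strrep("A", 200), pats$BBOX2)), 0L)
  inst <- paste0("C", strrep("A", 3), "H", strrep("A", 8), "C",
                 strrep("A", 2), "D", strrep("A", 5), "C", strrep("A", 2),
                 "C", strrep("A", 4), "H", strrep("A", 3), "H")
  prot <- paste0(strrep("A", 10), inst, strrep("A", 30), inst,
                 strrep("A", 10))
  hits <- scan_domain(prot, pats$BBOX2, "p2")
  expect_equal(nrow(hits), 2L)
  expect_true(all(diff(hits$start) > 0))          # N -> C order
  expect_true(hits$end[1] <= hits$start[2])       # non-overlapping
})

test_that("generator proteins give exact planted-domain recovery", {
  fam <- default_family()
  prots <- Biostrings::AAStringSet(unlist(unname(fam$proteins)))
  hits <- scan_domains(prots)
  truth <- fam$truth$domains
  for (gid in names(prots)) {
    h <- hits[hits$protein_id == gid, c("domain", "start", "end")]
    tr <- truth[truth$gene_id == gid, c("domain", "start", "end")]
    h <- h[order(h$start), ]; tr <- tr[order(tr$start), ]
    rownames(h) <- rownames(tr) <- NULL
    expect_equal(h, tr)
  }
})

test_that("architecture codes and the clade rule table are total", {
  hits <- data.frame(
    protein_id = c("x", "x", "x", "y", "y", "z", "w", "w", "q", "q"),
    domain = c("BBOX1", "BBOX2", "CCT", "BBOX1", "CCT", "BBOX1",
               "BBOX1", "BBOX2", "CCT", "BBOX1"),
    start = c(5, 50, 200, 5, 200, 5, 5, 50, 5, 100),
    end = c(45, 90, 243, 45, 243, 45, 45, 90, 48, 140),
    matched_anchors = 6, stringsAsFactors = FALSE)
  arch <- assign_architecture(hits, c("x", "y", "z", "w", "q", "none"))
  rownames(arch) <- arch$protein_id
  expect_equal(arch["x", "clade"], "I/II")   # two B-BOX + CCT
  expect_equal(arch["y", "clade"], "III")    # one B-BOX + CCT
  expect_equal(arch["z", "clade"], "V")      # one B-BOX, no CCT
  expect_equal(arch["w", "clade"], "IV")     # two B-BOX, no CCT
  expect_equal(arch["q", "clade"], "unclassified")  # CCT N-terminal: atypical
  expect_true(arch["q", "atypical"])
  expect_equal(arch["none", "clade"], "unclassified")  # excluded, no B-BOX
  expect_equal(arch["x", "code"], "B1+B2+CCT")
  expect_true(all(arch$clade %in% c("I/II", "III", "IV", "V", "unclassified")))
})

test_that("clade I/II ambiguity resolves by placement, defaults to II", {
  arch <- data.frame(protein_id = c("a", "b", "c"),
                     code = c("B1+B2+CCT", "B1+CCT", "B1+B2+CCT"),
                     n_bbox = c(2, 1, 2), has_cct = TRUE,
                     clade = c("I/II", "III", "I/II"), atypical = FALSE,
                     stringsAsFactors = FALSE)
  out <- classify_clade(arch, c("I", NA, NA))
  expect_equal(out$clade, c("I", "III", "II"))
  expect_equal(out$architecture_only, c(FALSE, FALSE, TRUE))
})

test_that("molecular weight follows the average-mass convention", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 0.01 / 75)
  expect_error(compute_mw(""), "empty")
  expect_error(compute_mw("GXG"), "positions: 2")
  # strict additivity: mw(AB) == mw(A) + mw(B) - water
  set.seed(3)
  for (i in 1:5) {
    a <- paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]], 8, TRUE),
               collapse = "")
    b <- paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]], 6, TRUE),
               collapse = "")
    expect_equal(compute_mw(paste0(a, b)),
                 compute_mw(a) + compute_mw(b) - 18.01524)
  }
})

test_that("isoelectric point zeroes the net charge and is composition-only", {
  set.seed(4)
  for (i in 1:5) {
    s <- paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]], 30, TRUE),
               collapse = "")
    pi <- compute_pi(s)
    expect_lt(abs(net_charge(s, pi)), 1e-2)
    # permutation invariance (same first residue keeps the N-terminal pKa)
    perm <- paste(c(substr(s, 1, 1),
                    sample(strsplit(substr(s, 2, 30), "")[[1]])),
                  collapse = "")
    expect_equal(compute_pi(perm), pi)
  }
  expect_gt(compute_pi(strrep("K", 10)), compute_pi(strrep("D", 10)))
  # frozen oracle value: bisection on the Bjellqvist two-group charge
  # function for glycine (N-term 7.50, C-term 3.55) -> (7.50 + 3.55) / 2
  expect_equal(compute_pi("G"), 5.53, tolerance = 0.051 / 5.5)
})
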