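test_that("Poisson distances follow the closed form", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(distance_matrix(aln)["a", "b"], 0)
  aln2 <- c(a = "AAAAAAAAAA", b = "CAAAAAAAAA")   # p = 0.1
  expect_equal(distance_matrix(aln2)["a", "b"], -log(0.9))
  expect_equal(distance_matrix(aln2, model = "p")["a", "b"], 0.1)
  # gap columns excluded from the shared denominator
  aln3 <- c(a = "-AAAAAAAAA", b = "CCAAAAAAAA")   # 9 shared, 1 mismatch
  expect_equal(distance_matrix(aln3, model = "p")["a", "b"], 1 / 9)
})

test_that("NJ recovers additive matrices exactly (4-8 taxa)", {
  for (n in 4:8) {
    set.seed(n)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- cophenetic(true)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    est <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
    # branch lengths: path lengths reproduce the input matrix
    De <- cophenetic(est)[rownames(D), colnames(D)]
    expect_equal(De, D, tolerance = 1e-8)
  }
})

test_that("NJ is deterministic under taxon permutation and matches ape", {
  set.seed(21)
  n <- 7
  true <- ape::rtree(n)
  D <- cophenetic(true)
  t1 <- nj_tree(D)
  perm <- sample(n)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  # independent cross-check against ape's NJ on a noisy matrix
  Dn <- D + matrix(runif(n * n, 0, 0.01), n, n)
  Dn <- (Dn + t(Dn)) / 2; diag(Dn) <- 0
  expect_equal(as.numeric(ape::dist.topo(nj_tree(Dn), ape::nj(Dn))), 0)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 0.5, b = 1.5, c = 2.5))
})

test_that("bootstrap supports separate clusters and is reproducible", {
  set.seed(31)
  aas <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
  base1 <- sample(aas, 120, TRUE); base2 <- sample(aas, 120, TRUE)
  jitter <- function(x, k) { i <- sample(120, k); x[i] <- sample(aas, k, TRUE); x }
  aln <- vapply(list(jitter(base1, 3), jitter(base1, 3),
                     jitter(base2, 3), jitter(base2, 3)),
                paste, character(1), collapse = "")
  names(aln) <- c("a1", "a2", "b1", "b2")
  tr <- bootstrap_nj(aln, n = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_gte(max(sup, na.rm = TRUE), 95)       # the central split
  tr2 <- bootstrap_nj(aln, n = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_null(bootstrap_nj(aln, n = 0)$node.label)
})

test_that("Fitch reconstruction equals the brute-force minimum", {
  # all leaves identical: zero changes
  tre <- ape::read.tree(text = "((a,b),(c,d));")
  chars <- matrix(1L, 4, 3, dimnames = list(c("a", "b", "c", "d"),
                                            c("has_B1_duplicated", "has_B2",
                                              "has_CCT")))
  expect_equal(fitch_reconstruct(tre, chars)$score, 0)
  # one informative character: single change on the internal edge
  chars[, "has_CCT"] <- c(1L, 1L, 0L, 0L)
  rec <- fitch_reconstruct(tre, chars)
  expect_equal(rec$score, 1)
  expect_equal(oracle_fitch_score(tre, chars), 1)
  # random binary characters on random rooted trees up to 8 leaves
  for (i in 1:6) {
    set.seed(40 + i)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    cm <- matrix(sample(0:1, n * 3, TRUE), n, 3,
                 dimnames = list(tr$tip.label, c("c1", "c2", "c3")))
    expect_equal(fitch_reconstruct(tr, cm)$score, oracle_fitch_score(tr, cm))
  }
})

test_that("Fitch score agrees with phangorn on random data", {
  set.seed(55)
  tr <- ape::rtree(8)
  tr$tip.label <- paste0("t", 1:8)
  cm <- matrix(sample(0:1, 8 * 4, TRUE), 8, 4,
               dimnames = list(tr$tip.label, paste0("c", 1:4)))
  pd <- phangorn::phyDat(cm, type = "USER", levels = c(0, 1))
  expect_equal(fitch_reconstruct(tr, cm)$score,
               phangorn::fitch(tr, pd))
})

test_that("the family-shaped clade tree yields the four trajectory events", {
  tre <- ape::read.tree(text = "(V,(IV,(II,(III,I))));")
  chars <- architecture_characters(
    setNames(c("V", "IV", "II", "III", "I"), c("V", "IV", "II", "III", "I")))
  rec <- fitch_reconstruct(tre, chars)
  ev <- label_events(rec)
  expect_equal(nrow(ev), 4L)
  expect_setequal(ev$event, c("BBOX_duplication", "CCT_gain",
                              "BBOX2_deletion", "BBOX1_duplication"))
  # events in traversal order: the duplication precedes the CCT gain,
  # which precedes the clade III / clade I splits
  expect_equal(ev$event[1], "BBOX_duplication")
  expect_equal(ev$event[2], "CCT_gain")
  # event list exactly explains all parent/child differences
  st <- rec$states
  edges <- ape::reorder.phylo(tre, "cladewise")$edge
  ndiff <- sum(st[edges[, 1], ] != st[edges[, 2], ])
  expect_equal(nrow(ev), ndiff)
})
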