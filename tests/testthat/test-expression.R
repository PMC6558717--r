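test_that("FPKM bins partition [0, Inf) with left-closed boundaries", {
  expect_equal(as.character(bin_fpkm(50)), "high")
  expect_equal(as.character(bin_fpkm(0.5)), "not_expressed")
  expect_equal(as.character(bin_fpkm(6.8)), "mid_low")
  expect_equal(as.character(bin_fpkm(c(0, 1, 17.5, 44.7, 17092))),
               c("not_expressed", "low", "mid_high", "high", "high"))
  expect_error(bin_fpkm(-1), "negative")
  # total on a dense grid: every value gets exactly one label
  expect_false(anyNA(bin_fpkm(seq(0, 100, by = 0.37))))
})

test_that("expression groups follow the A/B/C rules", {
  m <- rbind(allhigh = rep(20, 8), silent = rep(0, 8),
             lowish = rep(3, 8))
  colnames(m) <- paste0("t", 1:8)
  g <- group_genes(m)
  expect_equal(unname(g), c("A", "B", "C"))
  # planted group sizes recovered across seeds
  for (s in c(1, 7, 19)) {
    fp <- make_fpkm(sim_config(seed = s))
    expect_equal(group_genes(fp$matrix), fp$truth)
    expect_equal(unname(table(fp$truth)[c("A", "B", "C")]),
                 unname(sim_config()$fpkm_groups),
                 ignore_attr = TRUE)
  }
})

test_that("Venn regions equal brute-force set algebra", {
  set.seed(12)
  m <- matrix(runif(30 * 4, 0, 3), 30, 4,
              dimnames = list(sprintf("g%02d", 1:30), paste0("t", 1:4)))
  v <- tissue_venn(m, threshold = 1)
  sets <- lapply(paste0("t", 1:4), function(t) rownames(m)[m[, t] >= 1])
  names(sets) <- paste0("t", 1:4)
  # independent region computation via explicit intersect/setdiff
  for (k in 1:4) for (combo in combn(paste0("t", 1:4), k, simplify = FALSE)) {
    inside <- Reduce(intersect, sets[combo])
    outside <- Reduce(union, sets[setdiff(paste0("t", 1:4), combo)],
                      character(0))
    want <- length(setdiff(inside, outside))
    got <- v$regions$count[v$regions$members == paste(combo, collapse = "&")]
    expect_equal(got, want)
  }
  expect_equal(sum(v$regions$count), length(Reduce(union, sets)))
  # all-expressed genes land in the full intersection
  m2 <- matrix(2, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  v2 <- tissue_venn(m2)
  expect_equal(v2$regions$count[v2$regions$members == "x&y&z"], 2L)
  expect_error(tissue_venn(matrix(1, 2, 7,
                                  dimnames = list(c("a", "b"),
                                                  paste0("t", 1:7)))),
               "at most 6")
})

test_that("2^-ddCt fold changes follow the closed form", {
  # treated dCt == control dCt: fold 1, not significant
  r <- relative_expression(c(25, 25, 25), c(20, 20, 20),
                           c(30, 30, 30), c(25, 25, 25))
  expect_equal(r$fold_change, 1)
  expect_equal(r$significance, "ns")
  expect_equal(r$direction, "unchanged")
  # ddCt = -1 exactly: fold 2
  r2 <- relative_expression(c(24, 24, 24), c(20, 20, 20),
                            c(30, 30, 30), c(25, 25, 25))
  expect_equal(r2$fold_change, 2)
  expect_equal(r2$direction, "up")
  # fewer than 2 replicates on either side is an error
  expect_error(relative_expression(24, 20, c(30, 30, 30), c(25, 25, 25)),
               "2 replicates")
  expect_warning(relative_expression(c(24, 24), c(20, 20),
                                     c(30, 30, 30), c(25, 25, 25)),
                 "fewer than 3")
})

test_that("fold estimation is unbiased in log space on simulated tables", {
  set.seed(77)
  errs <- replicate(200, {
    true_fold <- 4
    tt <- 26 - log2(true_fold) + rnorm(3, 0, 0.2)
    tr <- 20 + rnorm(3, 0, 0.2)
    ct <- 26 + rnorm(3, 0, 0.2)
    cr <- 20 + rnorm(3, 0, 0.2)
    log2(relative_expression(tt, tr, ct, cr)$fold_change / true_fold)
  })
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("qPCR tables resolve shared or per-timepoint controls", {
  qp <- make_qpcr(sim_config(seed = 9))
  fc <- qpcr_fold_changes(qp$ct_table)
  m <- merge(fc, qp$truth)
  expect_equal(nrow(m), nrow(qp$truth))
  expect_lt(mean(abs(log2(m$fold_change / m$fold))), 0.5)
  # strongly regulated entries get stars and the right direction
  strong <- m[m$fold >= 100, ]
  expect_true(all(strong$significance == "**"))
  expect_true(all(strong$direction == "up"))
  down <- m[m$fold < 1, ]
  expect_true(all(down$direction == "down"))
  # Ct range validation
  bad <- qp$ct_table; bad$ct_target[1] <- 50
  expect_error(qpcr_fold_changes(bad), "Ct values")
})
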