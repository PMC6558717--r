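.bbx_tissues <- c("root", "root_tips", "stem", "leaf", "speal", "column",
                  "lip", "flower_buds")

#' Read an FPKM expression matrix
#'
#' Genes x tissues TSV with gene IDs in the first column.
#'
#' @param path TSV path.
#' @return Numeric matrix, rownames = genes.
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative FPKM values")
  m
}

#' Bin FPKM values into expression levels
#'
#' Left-closed bins partitioning `[0, Inf)`: `[0,1)` not expressed,
#' `[1,6.8)` low, `[6.8,17.5)` mid-low, `[17.5,44.7)` mid-high,
#' `[44.7,Inf)` high.
#'
#' @param value Numeric vector of FPKM values (>= 0).
#' @return Factor of bin labels.
#' @export
bin_fpkm <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("negative FPKM value")
  cut(value, breaks = c(0, 1, 6.8, 17.5, 44.7, Inf), right = FALSE,
      labels = c("not_expressed", "low", "mid_low", "mid_high", "high"))
}

#' Group genes by tissue expression pattern
#'
#' Formalized A/B/C grouping: group A (modest overall expression in all
#' tissues) when the median FPKM across tissues is at least `a_median`;
#' group B (basically not expressed) when FPKM is below `b_threshold` in
#' at least `b_tissues` of the tissues; group C otherwise (similar lower
#' expression). Thresholds are exposed because the verbal definitions
#' admit more than one formalization.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param a_median Group-A median threshold (default 6.8, the mid-low bin
#'   floor).
#' @param b_threshold,b_tissues Group-B rule: FPKM below `b_threshold`
#'   (default 1) in at least `b_tissues` (default `ncol - 1`) tissues.
#' @return Named character vector of groups (`A`, `B`, `C`).
#' @export
group_genes <- function(matrix, a_median = 6.8, b_threshold = 1,
                        b_tissues = ncol(matrix) - 1L) {
  med <- apply(matrix, 1L, stats::median)
  n_off <- rowSums(matrix < b_threshold)
  grp <- ifelse(med >= a_median, "A",
         ifelse(n_off >= b_tissues, "B", "C"))
  stats::setNames(grp, rownames(matrix))
}

#' Venn region counts of expressed genes across tissues
#'
#' A gene is expressed in a tissue when its FPKM is at least `threshold`.
#' Returns every region of the Venn diagram over the requested tissues
#' (exclusive regions, one per non-empty tissue-subset), whose counts sum
#' to the union size.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param tissues Tissues to intersect (2 to 6; default all columns, capped
#'   by the readability guard).
#' @param threshold Expression threshold in FPKM (default 1).
#' @return List with `sets` (named list of expressed gene IDs per tissue)
#'   and `regions` (data.frame `members` (e.g. `"root&stem"`), `count`).
#' @export
tissue_venn <- function(matrix, tissues = colnames(matrix), threshold = 1) {
  if (length(tissues) > 6L) stop("at most 6 tissues for a readable Venn")
  if (length(tissues) < 1L) stop("need at least one tissue")
  expressed <- matrix[, tissues, drop = FALSE] >= threshold
  sets <- lapply(tissues, function(t) rownames(matrix)[expressed[, t]])
  names(sets) <- tissues
  # membership pattern per gene over the requested tissues
  in_any <- rownames(matrix)[rowSums(expressed) > 0]
  pat <- apply(expressed[in_any, , drop = FALSE], 1L, function(v)
    paste(tissues[v], collapse = "&"))
  combos <- unlist(lapply(seq_along(tissues), function(k)
    utils::combn(tissues, k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(combos)), combos)
  tt <- table(pat)
  counts[names(tt)] <- as.integer(tt)
  list(sets = sets,
       regions = data.frame(members = combos, count = unname(counts),
                            stringsAsFactors = FALSE))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt` is the mean
#' treated dCt minus the mean control dCt, and the fold change is
#' `2^-ddCt`. Significance stars come from a two-sided Welch t-test on
#' the replicate dCt values (`**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise). With fewer than 2 usable replicates on either side the
#' call is an error; incomplete replicate sets (n = 2) are used with a
#' warning.
#'
#' @param treated_ct_target,treated_ct_ref Treated replicate Ct values.
#' @param control_ct_target,control_ct_ref Control replicate Ct values.
#' @return data.frame row: `fold_change`, `ddct`, `p_value`,
#'   `significance`, `direction` (`up`/`down`/`unchanged`).
#' @export
relative_expression <- function(treated_ct_target, treated_ct_ref,
                                control_ct_target, control_ct_ref) {
  dct_t <- treated_ct_target - treated_ct_ref
  dct_c <- control_ct_target - control_ct_ref
  dct_t <- dct_t[!is.na(dct_t)]; dct_c <- dct_c[!is.na(dct_c)]
  if (length(dct_t) < 2L || length(dct_c) < 2L)
    stop("need at least 2 replicates per condition")
  if (length(dct_t) < 3L || length(dct_c) < 3L)
    warning("fewer than 3 replicates; fold change computed on the rest")
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2^(-ddct)
  p <- if (stats::sd(dct_t) == 0 && stats::sd(dct_c) == 0) {
    if (isTRUE(all.equal(mean(dct_t), mean(dct_c)))) 1 else 0
  } else stats::t.test(dct_t, dct_c)$p.value
  data.frame(fold_change = fold, ddct = ddct, p_value = p,
             significance = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns",
             direction = if (abs(ddct) < 1e-12) "unchanged"
                         else if (fold > 1) "up" else "down",
             stringsAsFactors = FALSE)
}

#' Fold changes for a long-format qPCR Ct table
#'
#' Expects columns `gene_id`, `treatment`, `timepoint`, `replicate`,
#' `ct_target`, `ct_ref`, `is_control`. By default all treated groups of
#' a gene share the single untreated control (the untreated sample taken
#' at the first timepoint); `per_timepoint_control = TRUE` matches each
#' timepoint to a control at the same timepoint instead.
#'
#' @param ct_table Long-format data.frame (see above).
#' @param per_timepoint_control Logical (default `FALSE`).
#' @return data.frame with one row per gene x treatment x timepoint, the
#'   [relative_expression()] columns appended.
#' @export
qpcr_fold_changes <- function(ct_table, per_timepoint_control = FALSE) {
  need <- c("gene_id", "treatment", "timepoint", "replicate",
            "ct_target", "ct_ref", "is_control")
  if (!all(need %in% names(ct_table)))
    stop("missing columns: ", paste(setdiff(need, names(ct_table)),
                                    collapse = ", "))
  if (any(ct_table$ct_target <= 0 | ct_table$ct_target >= 45) ||
      any(ct_table$ct_ref <= 0 | ct_table$ct_ref >= 45))
    stop("Ct values must lie in (0, 45)")
  treated <- ct_table[!ct_table$is_control, , drop = FALSE]
  controls <- ct_table[ct_table$is_control, , drop = FALSE]
  keys <- unique(treated[, c("gene_id", "treatment", "timepoint")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    tr <- treated[treated$gene_id == keys$gene_id[k] &
                  treated$treatment == keys$treatment[k] &
                  treated$timepoint == keys$timepoint[k], , drop = FALSE]
    ct <- controls[controls$gene_id == keys$gene_id[k], , drop = FALSE]
    if (per_timepoint_control)
      ct <- ct[ct$timepoint == keys$timepoint[k], , drop = FALSE]
    if (!nrow(ct)) stop("no control replicates for gene ", keys$gene_id[k])
    cbind(keys[k, , drop = FALSE],
          relative_expression(tr$ct_target, tr$ct_ref,
                              ct$ct_target, ct$ct_ref),
          row.names = NULL)
  })
  do.call(rbind, rows)
}
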