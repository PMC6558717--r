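# ---- distances ------------------------------------------------------------

#' Pairwise distance matrix from aligned proteins
#'
#' Poisson-corrected distance `d = -ln(1 - p)` where `p` is the mismatch
#' fraction over columns where both sequences have a residue; `model =
#' "p"` returns the uncorrected p-distance.
#'
#' @param aln Named character vector of equal-length gapped sequences (or
#'   an `AAStringSet`).
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  seqs <- vapply(seq_along(aln), function(i) toupper(as.character(aln[[i]])),
                 character(1))
  names(seqs) <- names(aln)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal lengths)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(shared)) stop("no shared columns between ", names(seqs)[i],
                           " and ", names(seqs)[j])
    p <- mean(mat[i, shared] != mat[j, shared])
    d <- if (model == "poisson") {
      if (p >= 1) stop("p-distance of 1: Poisson correction undefined")
      -log(1 - p)
    } else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

# ---- neighbor joining -----------------------------------------------------

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard NJ agglomeration with the Q criterion. Ties in Q are broken
#' deterministically by the lexicographically smallest label pair, so
#' permuting the input taxa gives the same tree up to relabeling. On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly. Negative branch-length estimates are clamped at 0.
#'
#' @param D Symmetric distance matrix with at least 3 taxa (named).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (n < 3L) stop("need at least 3 taxa")
  newick <- rownames(D)               # growing subtree strings
  labels <- rownames(D)               # cluster labels for tie-breaking
  Dm <- D
  while (nrow(Dm) > 3L) {
    r <- nrow(Dm)
    Rsum <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(Rsum, Rsum, "+")
    diag(Q) <- Inf
    cand <- which(Q - min(Q) < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest sorted label pair
    keys <- apply(cand, 1L, function(ij)
      paste(sort(c(labels[ij[1L]], labels[ij[2L]])), collapse = "\r"))
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- Dm[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    vj <- Dm[i, j] - vi
    vi <- max(0, vi); vj <- max(0, vj)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], vi, newick[j], vj)
    dnew <- (Dm[i, -c(i, j), drop = TRUE] + Dm[j, -c(i, j), drop = TRUE] -
               Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    mlab <- min(labels[i], labels[j])  # merged cluster inherits smaller label
    Dm <- Dm[keep, keep, drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    labels <- c(labels[keep], mlab)
    rownames(Dm) <- colnames(Dm) <- labels
    newick <- c(newick[keep], merged)
  }
  # final three clusters: closed-form three-point branch lengths
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  v1 <- max(0, (d12 + d13 - d23) / 2)
  v2 <- max(0, (d12 + d23 - d13) / 2)
  v3 <- max(0, (d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 newick[1], v1, newick[2], v2, newick[3], v3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates the reference tree's internal nodes with
#' the percentage of replicates containing each bipartition
#' (via [ape::prop.clades()]). Seeded and reproducible.
#'
#' @param aln Named character vector of equal-length gapped sequences.
#' @param n Number of replicates (0 = return the tree without supports).
#' @param seed RNG seed.
#' @param model Distance model passed to [distance_matrix()].
#' @return The NJ tree with `node.label` set to supports in `[0, 100]`
#'   (empty root label), or without labels when `n = 0`.
#' @export
bootstrap_nj <- function(aln, n = 1000L, seed = 1L, model = "poisson") {
  seqs <- vapply(seq_along(aln), function(i) toupper(as.character(aln[[i]])),
                 character(1))
  names(seqs) <- names(aln)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  ref <- nj_tree(distance_matrix(seqs, model = model))
  if (n <= 0L) return(ref)
  L <- ncol(mat)
  set.seed(seed)
  boots <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    bs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    boots[[b]] <- tryCatch(nj_tree(distance_matrix(bs, model = model)),
                           error = function(e) NULL)
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- as.character(round(100 * counts / length(boots)))
  ref$node.label[1L] <- ""   # root of the unrooted representation
  ref
}

# ---- architecture characters & Fitch parsimony ----------------------------

.clade_states <- rbind(
  I   = c(has_B1_duplicated = 1L, has_B2 = 1L, has_CCT = 1L),
  II  = c(0L, 1L, 1L),
  III = c(0L, 0L, 1L),
  IV  = c(0L, 1L, 0L),
  V   = c(0L, 0L, 0L))

#' Binary architecture characters from clade assignments
#'
#' Encodes each protein's domain architecture as three binary characters:
#' `has_B1_duplicated` (the clade-I B-BOX1 duplication), `has_B2` (a
#' second B-BOX domain) and `has_CCT`. Clades map as I = 111, II = 011,
#' III = 001, IV = 010, V = 000.
#'
#' @param clades Named character vector of clades (`I`..`V`).
#' @return Integer matrix, rows = proteins, columns = the 3 characters.
#' @export
architecture_characters <- function(clades) {
  bad <- setdiff(unique(clades), rownames(.clade_states))
  if (length(bad)) stop("unknown clade(s): ", paste(bad, collapse = ", "))
  m <- .clade_states[clades, , drop = FALSE]
  dimnames(m) <- list(names(clades), colnames(.clade_states))
  m
}

#' Fitch parsimony reconstruction of binary characters
#'
#' Two-pass Fitch on a rooted binary tree, one character at a time. The
#' down-pass resolves ambiguous state sets toward the parent state and,
#' at the root, toward `ancestral_state` — the single-B-BOX ancestral
#' polarity (all characters 0) under which the family's domain
#' trajectory is read.
#'
#' @param tree A rooted binary `ape::phylo` tree.
#' @param chars Matrix from [architecture_characters()]; rownames must
#'   cover the tree's tip labels.
#' @param ancestral_state Preferred state on ties (default 0 for every
#'   character).
#' @return List with `states` (matrix over tips then internal nodes, in
#'   `ape` node numbering) and `score` (total parsimony changes).
#' @export
fitch_reconstruct <- function(tree, chars,
                              ancestral_state = rep(0L, ncol(chars))) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  missing_tips <- setdiff(tree$tip.label, rownames(chars))
  if (length(missing_tips))
    stop("characters missing for tips: ", paste(missing_tips, collapse = ", "))
  chars <- chars[tree$tip.label, , drop = FALSE]
  total <- ntip + nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- ntip + 1L
  # internal-node orders: cladewise gives parents before descendants
  preorder_nodes <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L])
  up_order <- rev(preorder_nodes)     # children before parents
  states <- matrix(NA_integer_, total, ncol(chars),
                   dimnames = list(NULL, colnames(chars)))
  score <- 0L
  for (ch in seq_len(ncol(chars))) {
    sets <- vector("list", total)
    for (t in seq_len(ntip)) sets[[t]] <- chars[t, ch]
    for (nd in up_order) {
      kk <- kids[[as.character(nd)]]
      s <- sets[[kk[1L]]]
      for (k in kk[-1L]) {
        inter <- intersect(s, sets[[k]])
        if (length(inter)) s <- inter
        else { s <- union(s, sets[[k]]); score <- score + 1L }
      }
      sets[[nd]] <- s
    }
    # down-pass: parent state if possible, else the ancestral preference
    assign_state <- function(set, parent_state) {
      if (length(set) == 1L) return(set)
      if (!is.null(parent_state) && parent_state %in% set) return(parent_state)
      if (ancestral_state[ch] %in% set) return(ancestral_state[ch])
      min(set)
    }
    states[root, ch] <- assign_state(sets[[root]], NULL)
    for (nd in preorder_nodes) for (k in kids[[as.character(nd)]]) {
      if (k <= ntip) states[k, ch] <- chars[k, ch]
      else states[k, ch] <- assign_state(sets[[k]], states[nd, ch])
    }
  }
  list(states = states, score = score, tree = tree)
}

.event_names <- list(
  has_B2 = c(gain = "BBOX_duplication", loss = "BBOX2_deletion"),
  has_CCT = c(gain = "CCT_gain", loss = "CCT_loss"),
  has_B1_duplicated = c(gain = "BBOX1_duplication", loss = "BBOX1_loss"))

#' Name the domain gain/loss/duplication events on a reconstruction
#'
#' Walks the tree in preorder and maps every parent-to-child character
#' flip to its named event: a second B-BOX appearing is a B-BOX
#' duplication, a second B-BOX lost is a B-BOX2 deletion, CCT appearing
#' is a CCT gain, and the clade-I character appearing is a B-BOX1
#' duplication. Multiple flips on one edge yield multiple events.
#'
#' @param reconstruction Result of [fitch_reconstruct()].
#' @return data.frame with `parent`, `child` (ape node numbers), `child_label`
#'   (tip label where applicable), `character`, `from`, `to`, `event`,
#'   in tree traversal order.
#' @export
label_events <- function(reconstruction) {
  tree <- reconstruction$tree
  st <- reconstruction$states
  ntip <- length(tree$tip.label)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  rows <- list()
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; c_ <- edges[e, 2L]
    for (ch in colnames(st)) {
      if (st[p, ch] != st[c_, ch]) {
        dir <- if (st[c_, ch] > st[p, ch]) "gain" else "loss"
        rows[[length(rows) + 1L]] <- data.frame(
          parent = p, child = c_,
          child_label = if (c_ <= ntip) tree$tip.label[c_] else NA_character_,
          character = ch, from = st[p, ch], to = st[c_, ch],
          event = .event_names[[ch]][[dir]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(parent = integer(0), child = integer(0),
                      child_label = character(0), character = character(0),
                      from = integer(0), to = integer(0), event = character(0),
                      stringsAsFactors = FALSE)
  out
}
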