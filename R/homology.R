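#' Global protein alignment
#'
#' Needleman-Wunsch global alignment with affine gaps, computed by
#' [Biostrings::pairwiseAlignment()] (BLOSUM62, gap open 10, gap extend
#' 0.5 by default). Identity is the fraction of alignment columns (gaps
#' included) carrying identical residues; coverage is the number of
#' substituted (both-residue) columns divided by the shorter sequence
#' length.
#'
#' @param a,b Protein sequences (character or `AAString`).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param id_a,id_b Identifiers carried into the result.
#' @return A list with `id_a`, `id_b`, `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`, `identity`, `coverage`.
#' @export
align_global <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, id_a = "a", id_b = "b") {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("empty sequence in align_global")
  # residues outside the matrix alphabet are treated as X
  clean <- function(s) gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", s)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(clean(a)), Biostrings::AAString(clean(b)),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  ident <- sum(ca[both] == cb[both]) / length(ca)
  list(id_a = id_a, id_b = id_b, aligned_a = al_a, aligned_b = al_b,
       score = Biostrings::score(pa), identity = ident,
       coverage = sum(both) / min(nchar(a), nchar(b)))
}

# all-vs-all alignment stat matrices between two named sets (one
# pairwiseAlignment call per subject; identity over substituted columns,
# coverage relative to the shorter sequence)
.align_all <- function(xs, ys) {
  to_chr <- function(s) vapply(seq_along(s), function(i)
    toupper(as.character(s[[i]])), character(1))
  xs <- to_chr(xs); ys <- to_chr(ys)
  xset <- Biostrings::AAStringSet(xs)
  n <- length(xs); m <- length(ys)
  score <- ident <- cover <- matrix(0, n, m)
  for (j in seq_len(m)) {
    pa <- Biostrings::pairwiseAlignment(
      xset, Biostrings::AAString(ys[j]), substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global")
    nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
    score[, j] <- Biostrings::score(pa)
    ident[, j] <- nm / Biostrings::nchar(pa)
    cover[, j] <- (nm + nmm) / pmin(nchar(xs), nchar(ys[j]))
  }
  list(score = score, identity = ident, coverage = cover)
}

# best hit per query (row of score matrix); ties reject the query (NA)
.best_hit <- function(scores) {
  apply(scores, 1L, function(s) {
    m <- max(s)
    w <- which(s == m)
    if (length(w) != 1L) NA_integer_ else w
  })
}

#' Reciprocal-best-hit orthologs and paralogs
#'
#' Orthologs are reciprocal best hits between the two genomes; paralogs
#' are reciprocal best hits within a genome (self-hits excluded). Every
#' reported pair must pass both the identity and the coverage threshold.
#' Tied best-hit scores reject the query rather than picking arbitrarily.
#' Pairs are stored canonically (lexicographically ordered IDs), so the
#' output is symmetric under swapping genome labels.
#'
#' @param genome_a_proteins,genome_b_proteins Named protein sets (the
#'   family members of each genome). `genome_b_proteins = NULL` searches
#'   paralogs in genome A only.
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.3
#'   and 0.5).
#' @param genome_a,genome_b Genome labels for the output.
#' @return data.frame with `id_a`, `id_b`, `relation`
#'   (`ortholog`/`paralog`), `genome_a`, `genome_b`, `identity`, `score`.
#' @export
find_homologs <- function(genome_a_proteins, genome_b_proteins = NULL,
                          min_identity = 0.3, min_coverage = 0.5,
                          genome_a = "A", genome_b = "B") {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      relation = character(0), genome_a = character(0),
                      genome_b = character(0), identity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  pair_rows <- function(stats, xs_names, ys_names, relation, ga, gb) {
    n <- length(xs_names); m <- length(ys_names)
    score <- stats$score
    ident <- stats$identity
    cover <- stats$coverage
    if (relation == "paralog") diag(score) <- -Inf
    bx <- .best_hit(score)             # best in ys for each x
    by <- .best_hit(t(score))          # best in xs for each y
    rows <- list()
    for (i in seq_len(n)) {
      j <- bx[i]
      if (is.na(j)) next
      if (is.na(by[j]) || by[j] != i) next
      if (relation == "paralog" && i >= j) next  # count each pair once
      if (ident[i, j] < min_identity || cover[i, j] < min_coverage) next
      ids <- sort(c(xs_names[i], ys_names[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ids[1L], id_b = ids[2L], relation = relation,
        genome_a = ga, genome_b = gb, identity = ident[i, j],
        score = score[i, j], stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else empty
  }

  res <- list()
  if (!is.null(genome_b_proteins) && length(genome_b_proteins)) {
    stats <- .align_all(genome_a_proteins, genome_b_proteins)
    res$ortho <- pair_rows(stats, names(genome_a_proteins),
                           names(genome_b_proteins), "ortholog",
                           genome_a, genome_b)
  }
  if (length(genome_a_proteins) > 1L) {
    stats <- .align_all(genome_a_proteins, genome_a_proteins)
    res$para_a <- pair_rows(stats, names(genome_a_proteins),
                            names(genome_a_proteins), "paralog",
                            genome_a, genome_a)
  }
  if (!is.null(genome_b_proteins) && length(genome_b_proteins) > 1L) {
    stats <- .align_all(genome_b_proteins, genome_b_proteins)
    res$para_b <- pair_rows(stats, names(genome_b_proteins),
                            names(genome_b_proteins), "paralog",
                            genome_b, genome_b)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  out
}
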