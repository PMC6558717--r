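#' Load the domain pattern library
#'
#' Reads the versioned anchor-and-spacer pattern table shipped with the
#' package (or a user-supplied one in the same format). Each pattern is an
#' ordered list of anchor residue classes (e.g. `C`, `D/C`) separated by
#' bounded spacer ranges; B-BOX patterns are anchored on the conserved
#' Cys/His zinc-binding scaffold and require every anchor, while the long
#' CCT consensus tolerates anchor mismatches (`min_anchor_frac < 1`).
#'
#' @param path Pattern TSV; defaults to the shipped library.
#' @return A named list of pattern objects with elements `name`, `anchors`
#'   (list of character vectors of allowed residues), `gap_min`, `gap_max`,
#'   `min_anchor_frac`.
#' @export
load_domain_patterns <- function(path = system.file("extdata", "domain_patterns.tsv",
                                                    package = "bbxkit")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    anchors <- strsplit(strsplit(tab$anchors[i], ",")[[1]], "/")
    gaps <- strsplit(tab$gaps[i], ",")[[1]]
    gm <- t(vapply(strsplit(gaps, "-"), function(g) as.integer(g[c(1L, 2L)]),
                   integer(2)))
    stopifnot(length(anchors) == nrow(gm) + 1L, all(gm[, 1L] <= gm[, 2L]),
              all(gm >= 0L))
    structure(list(name = tab$name[i], anchors = anchors,
                   gap_min = gm[, 1L], gap_max = gm[, 2L],
                   min_anchor_frac = tab$min_anchor_frac[i]),
              class = "bbx_domain_pattern")
  })
  names(pats) <- tab$name
  pats
}

# regex for an all-anchors-required pattern (leftmost-greedy matching gives
# the "earliest start, then longest" hit resolution the scanner promises)
.pattern_regex <- function(pat) {
  n <- length(pat$anchors)
  cls <- vapply(pat$anchors, function(a)
    if (length(a) == 1L) a else paste0("[", paste(a, collapse = ""), "]"),
    character(1))
  gaps <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    gaps[i] <- if (pat$gap_min[i] == pat$gap_max[i])
      sprintf(".{%d}", pat$gap_min[i])
    else sprintf(".{%d,%d}", pat$gap_min[i], pat$gap_max[i])
  }
  paste0(cls[1L], paste0(gaps, cls[-1L], collapse = ""))
}

#' Scan one protein with one domain pattern
#'
#' Reports maximal non-overlapping matches scanned N-terminus to
#' C-terminus. A match places every anchor residue class at a spacing
#' within its `[min, max]` range; patterns with `min_anchor_frac < 1`
#' (fixed-spacing consensi such as CCT) accept windows where at least that
#' fraction of anchors match. Overlaps are resolved greedily left to right
#' (earliest start wins, then the longest hit).
#'
#' @param protein Single protein sequence (character or `AAString`).
#' @param pattern A pattern object from [load_domain_patterns()].
#' @param protein_id Identifier used in the output.
#' @return data.frame with columns `protein_id`, `domain`, `start`, `end`
#'   (0-based half-open residue positions) and `matched_anchors`.
#' @export
scan_domain <- function(protein, pattern, protein_id = "protein") {
  aa <- toupper(as.character(protein))
  n_anch <- length(pattern$anchors)
  empty <- data.frame(protein_id = character(0), domain = character(0),
                      start = integer(0), end = integer(0),
                      matched_anchors = integer(0), stringsAsFactors = FALSE)
  if (pattern$min_anchor_frac >= 1) {
    m <- gregexpr(.pattern_regex(pattern), aa, perl = TRUE)[[1]]
    if (m[1L] == -1L) return(empty)
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    return(data.frame(protein_id = protein_id, domain = pattern$name,
                      start = starts, end = starts + lens,
                      matched_anchors = n_anch, stringsAsFactors = FALSE))
  }
  # fixed-spacing threshold scan (CCT-style): slide the rigid template
  stopifnot(all(pattern$gap_min == pattern$gap_max))
  offs <- cumsum(c(0L, pattern$gap_min + 1L))  # anchor offsets in template
  tlen <- offs[n_anch] + 1L
  need <- ceiling(pattern$min_anchor_frac * n_anch)
  L <- nchar(aa)
  if (L < tlen) return(empty)
  chars <- strsplit(aa, "")[[1]]
  starts0 <- 0:(L - tlen)
  nmatch <- integer(length(starts0))
  for (k in seq_len(n_anch)) {
    ok <- chars[starts0 + offs[k] + 1L] %in% pattern$anchors[[k]]
    nmatch <- nmatch + ok
  }
  hit <- which(nmatch >= need)
  if (!length(hit)) return(empty)
  # greedy left-to-right non-overlap (all hits share the template length)
  keep <- integer(0); last_end <- -1L
  for (s in starts0[hit]) {
    if (s >= last_end) { keep <- c(keep, s); last_end <- s + tlen }
  }
  data.frame(protein_id = protein_id, domain = pattern$name,
             start = keep, end = keep + tlen,
             matched_anchors = nmatch[match(keep, starts0)],
             stringsAsFactors = FALSE)
}

#' Scan proteins against the full domain library
#'
#' Runs [scan_domain()] for every pattern on every protein and resolves
#' overlaps across patterns per protein (earliest start wins, then longest,
#' then library order), so hits on one protein never overlap.
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @param patterns Pattern list from [load_domain_patterns()].
#' @return data.frame of resolved hits, ordered by protein then position.
#' @export
scan_domains <- function(proteins, patterns = load_domain_patterns()) {
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  res <- list()
  for (i in seq_along(proteins)) {
    hits <- do.call(rbind, lapply(patterns, function(p)
      scan_domain(proteins[[i]], p, protein_id = ids[i])))
    if (is.null(hits) || nrow(hits) == 0L) next
    prio <- match(hits$domain, names(patterns))
    hits <- hits[order(hits$start, -(hits$end - hits$start), prio), , drop = FALSE]
    keep <- logical(nrow(hits)); last_end <- -1L
    for (j in seq_len(nrow(hits))) {
      if (hits$start[j] >= last_end) { keep[j] <- TRUE; last_end <- hits$end[j] }
    }
    res[[ids[i]]] <- hits[keep, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), domain = character(0),
                      start = integer(0), end = integer(0),
                      matched_anchors = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign domain architectures and clades
#'
#' Maps each protein's resolved domain hits to an architecture code (domain
#' labels in N-to-C order, B-BOX hits numbered B1, B2 by position) and a
#' clade by the family rule table: two B-BOX + CCT is clade I or II
#' (reported as `I/II` pending [classify_clade()]), one B-BOX + CCT is
#' clade III, two B-BOX without CCT clade IV, one B-BOX without CCT clade
#' V. Proteins with no B-BOX hit are excluded from the family
#' (`unclassified`); a CCT N-terminal to every B-BOX is flagged atypical
#' and left unclassified.
#'
#' @param hits data.frame from [scan_domains()].
#' @param protein_ids Optional vector of all scanned proteins, so that
#'   zero-hit proteins appear as `unclassified` rows.
#' @return data.frame with `protein_id`, `code` (e.g. `"B1+B2+CCT"`),
#'   `n_bbox`, `has_cct`, `clade`, `atypical`.
#' @export
assign_architecture <- function(hits, protein_ids = unique(hits$protein_id)) {
  rows <- lapply(protein_ids, function(pid) {
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    is_bbox <- h$domain %in% c("BBOX1", "BBOX2")
    n_bbox <- sum(is_bbox)
    has_cct <- any(h$domain == "CCT")
    labels <- character(nrow(h))
    labels[is_bbox] <- paste0("B", seq_len(n_bbox))
    labels[h$domain == "CCT"] <- "CCT"
    code <- paste(labels, collapse = "+")
    atypical <- FALSE
    if (n_bbox == 0L) {
      clade <- "unclassified"
    } else if (has_cct && n_bbox > 0L &&
               min(h$start[h$domain == "CCT"]) < min(h$start[is_bbox])) {
      clade <- "unclassified"; atypical <- TRUE
    } else if (n_bbox >= 2L && has_cct) {
      clade <- "I/II"
    } else if (n_bbox == 1L && has_cct) {
      clade <- "III"
    } else if (n_bbox >= 2L) {
      clade <- "IV"
    } else {
      clade <- "V"
    }
    data.frame(protein_id = pid, code = code, n_bbox = n_bbox,
               has_cct = has_cct, clade = clade, atypical = atypical,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve the clade I vs II ambiguity
#'
#' Double-B-BOX + CCT architectures occur in both clade I and clade II;
#' the two differ by B-BOX2 sequence divergence, which architecture alone
#' cannot see. When a phylogenetic placement (clade of the nearest
#' reference) is supplied it decides; otherwise clade II is assigned and
#' the call is flagged `architecture_only`.
#'
#' @param arch One row (or data.frame) from [assign_architecture()].
#' @param tree_placement Optional character vector of placements (`"I"` or
#'   `"II"`), recycled; `NA` means no placement.
#' @return The input with final `clade` and a logical `architecture_only`.
#' @export
classify_clade <- function(arch, tree_placement = NA_character_) {
  placement <- rep_len(tree_placement, nrow(arch))
  arch$architecture_only <- FALSE
  amb <- arch$clade == "I/II"
  use <- amb & !is.na(placement)
  arch$clade[use] <- placement[use]
  arch$clade[amb & is.na(placement)] <- "II"
  arch$architecture_only[amb & is.na(placement)] <- TRUE
  arch
}

# ExPASy-style average residue masses (Da); water added once per chain
.aa_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water <- 18.01524

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water, the convention used by
#' the ExPASy ProtParam tool; strictly additive:
#' `mw(paste0(a, b)) == mw(a) + mw(b) - 18.01524`.
#'
#' @param protein Amino-acid sequence (character or `AAString`).
#' @return Molecular weight in daltons.
#' @export
compute_mw <- function(protein) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) stop("empty protein sequence")
  bad <- which(!aa %in% names(.aa_mass))
  if (length(bad))
    stop("ambiguous/unknown residues at positions: ",
         paste(bad, collapse = ", "))
  sum(.aa_mass[aa]) + .water
}

# Bjellqvist (ExPASy) pKa set: side chains, C-terminus, and an N-terminal
# pKa that depends on the first residue
.pka_side <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0,
               Y = 10.0)
.pka_nterm <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.7)
.pka_nterm_default <- 7.5
.pka_cterm <- 3.55

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side
#' chains (D, E, C, Y, H, K, R) with the Bjellqvist/ExPASy pKa set.
#'
#' @param protein Amino-acid sequence.
#' @param pH pH value(s).
#' @return Net charge (vectorized over `pH`).
#' @export
net_charge <- function(protein, pH) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) stop("empty protein sequence")
  comp <- table(aa)
  n_of <- function(r) if (is.na(comp[r])) 0L else as.integer(comp[r])
  pos <- c(if (is.na(.pka_nterm[aa[1L]])) .pka_nterm_default else .pka_nterm[aa[1L]],
           rep(.pka_side["H"], n_of("H")),
           rep(.pka_side["K"], n_of("K")),
           rep(.pka_side["R"], n_of("R")))
  neg <- c(.pka_cterm,
           rep(.pka_side["D"], n_of("D")),
           rep(.pka_side["E"], n_of("E")),
           rep(.pka_side["C"], n_of("C")),
           rep(.pka_side["Y"], n_of("Y")))
  vapply(pH, function(p)
    sum(1 / (1 + 10^(p - pos))) - sum(1 / (1 + 10^(neg - p))), numeric(1))
}

#' Theoretical isoelectric point
#'
#' pH at which [net_charge()] is zero, found by bisection on `[0, 14]` to
#' a tolerance of 1e-4 and reported to 2 decimals. The value depends only
#' on residue composition (permutation-invariant, apart from the identity
#' of the N-terminal residue, which sets the N-terminal pKa).
#'
#' @param protein Amino-acid sequence.
#' @param digits Decimals in the reported value (default 2).
#' @return Isoelectric point in pH units.
#' @export
compute_pi <- function(protein, digits = 2L) {
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, digits)
}

#' Per-protein MW/pI summary
#'
#' @param proteins Named `AAStringSet` or character vector.
#' @return data.frame with `protein_id`, `length`, `mw`, `pi`.
#' @export
protein_stats <- function(proteins) {
  ids <- names(proteins)
  data.frame(protein_id = ids,
             length = vapply(seq_along(proteins), function(i)
               nchar(as.character(proteins[[i]])), integer(1)),
             mw = vapply(seq_along(proteins), function(i)
               compute_mw(proteins[[i]]), numeric(1)),
             pi = vapply(seq_along(proteins), function(i)
               compute_pi(proteins[[i]]), numeric(1)),
             stringsAsFactors = FALSE)
}
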