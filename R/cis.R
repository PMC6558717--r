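#' Load the cis-element motif library
#'
#' Reads the versioned motif table shipped with the package (or a
#' user-supplied table in the same format): one named element per row
#' with an IUPAC consensus and a category (`development`, `hormone`,
#' `stress`).
#'
#' @param path Motif TSV; defaults to the shipped library.
#' @return data.frame with `name`, `consensus`, `category`,
#'   `function_note`.
#' @export
load_motif_library <- function(path = system.file("extdata",
                                                  "cis_element_library.tsv",
                                                  package = "bbxkit")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "consensus", "category") %in% names(tab)),
            all(nchar(tab$consensus) > 0),
            all(tab$category %in% c("development", "hormone", "stress")))
  tab
}

#' Scan a promoter for cis-elements
#'
#' Counts all (possibly overlapping) IUPAC-consensus matches of every
#' library motif in the promoter. With `strands = "both"` (the default)
#' reverse-strand matches are counted on the reverse complement and added.
#' In strict mode (default) an `N` in the promoter never satisfies a
#' non-`N` consensus position; `strict = FALSE` lets promoter ambiguity
#' codes match compatibly. Scanning is case-insensitive; an empty
#' promoter yields an all-zero profile.
#'
#' @param promoter `DNAString`/character; typically from
#'   [extract_promoter()].
#' @param library Motif table from [load_motif_library()].
#' @param strands `"both"` or `"plus"`.
#' @param strict Logical, see above.
#' @param gene_id Identifier for the profile (defaults to the promoter's
#'   `gene_id` attribute).
#' @return A list (class `bbx_promoter_profile`) with `gene_id` and
#'   `counts` (named integer vector over library motifs).
#' @export
scan_promoter <- function(promoter, library = load_motif_library(),
                          strands = c("both", "plus"), strict = TRUE,
                          gene_id = NULL) {
  strands <- match.arg(strands)
  if (is.null(gene_id))
    gene_id <- attr(promoter, "gene_id") %||% "promoter"
  counts <- stats::setNames(integer(nrow(library)), library$name)
  seq <- Biostrings::DNAString(toupper(as.character(promoter)))
  if (length(seq) > 0) {
    fixed <- if (strict) "subject" else FALSE
    rc <- Biostrings::reverseComplement(seq)
    for (k in seq_len(nrow(library))) {
      pat <- library$consensus[k]
      if (nchar(pat) > length(seq)) next
      n <- Biostrings::countPattern(pat, seq, fixed = fixed)
      if (strands == "both")
        n <- n + Biostrings::countPattern(pat, rc, fixed = fixed)
      counts[k] <- n
    }
  }
  structure(list(gene_id = gene_id, counts = counts),
            class = "bbx_promoter_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate promoter profiles into grid, category sums and ratios
#'
#' Builds the per-gene x per-motif count grid, sums counts per category
#' over all genes, and computes each motif's share of its category total
#' (shares within a non-empty category sum to 1).
#'
#' @param profiles List of profiles from [scan_promoter()].
#' @param library The motif library used for scanning.
#' @return List with `grid` (genes x motifs integer matrix),
#'   `category_sums` (named vector), and `ratios` (data.frame `name`,
#'   `category`, `count`, `ratio`).
#' @export
aggregate_profiles <- function(profiles, library = load_motif_library()) {
  if (!length(profiles)) stop("no profiles to aggregate")
  grid <- do.call(rbind, lapply(profiles, function(p) p$counts))
  rownames(grid) <- vapply(profiles, function(p) p$gene_id, character(1))
  motif_tot <- colSums(grid)
  cat_of <- stats::setNames(library$category, library$name)[colnames(grid)]
  category_sums <- tapply(motif_tot, cat_of, sum)
  ratio <- motif_tot / as.numeric(category_sums[cat_of])
  ratio[is.nan(ratio)] <- 0
  list(grid = grid,
       category_sums = category_sums[sort(unique(cat_of))],
       ratios = data.frame(name = colnames(grid), category = unname(cat_of),
                           count = unname(motif_tot), ratio = unname(ratio),
                           stringsAsFactors = FALSE))
}
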