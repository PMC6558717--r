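# ---- codon bookkeeping (standard genetic code, cached per session) --------

.bbx_cache <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.bbx_cache$tables)) return(.bbx_cache$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  sense <- codons[code != "*"]
  aa <- code[sense]
  nt <- c("A", "C", "G", "T")

  # NG86 site counts: per position, the fraction of non-stop single-nt
  # mutations that are synonymous; stop mutations leave the denominator so
  # syn + nonsyn renormalizes to exactly 3 per codon
  syn_sites <- vapply(sense, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      legal <- 0; synl <- 0
      for (alt in setdiff(nt, ch[pos])) {
        mut <- ch; mut[pos] <- alt
        mcd <- paste(mut, collapse = "")
        if (code[mcd] == "*") next
        legal <- legal + 1
        if (code[mcd] == code[cd]) synl <- synl + 1
      }
      if (legal > 0) s <- s + synl / legal
    }
    s
  }, numeric(1))

  # NG86 pathway-averaged difference counts for every sense-codon pair:
  # enumerate all orderings of the differing positions, drop pathways that
  # pass through a stop codon, average per-step synonymy over legal paths
  n <- length(sense)
  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- strsplit(sense[i], "")[[1]]; b <- strsplit(sense[j], "")[[1]]
    dpos <- which(a != b)
    k <- length(dpos)
    pm <- perms[[as.character(k)]]
    tot_s <- 0; tot_n <- 0; legal <- 0
    for (r in seq_len(nrow(pm))) {
      cur <- a; s <- 0; ns <- 0; ok <- TRUE
      for (step in pm[r, ]) {
        nxt <- cur; nxt[dpos[step]] <- b[dpos[step]]
        ccd <- paste(cur, collapse = ""); ncd <- paste(nxt, collapse = "")
        if (code[ncd] == "*") { ok <- FALSE; break }
        if (code[ncd] == code[ccd]) s <- s + 1 else ns <- ns + 1
        cur <- nxt
      }
      if (ok) { legal <- legal + 1; tot_s <- tot_s + s; tot_n <- tot_n + ns }
    }
    if (legal > 0) {
      Sd[i, j] <- tot_s / legal
      Nd[i, j] <- tot_n / legal
    } else {
      Sd[i, j] <- NA_real_; Nd[i, j] <- NA_real_
    }
  }
  .bbx_cache$tables <- list(sense = sense, aa = aa, syn_sites = syn_sites,
                            Sd = Sd, Nd = Nd)
  .bbx_cache$tables
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the nine single-nucleotide mutations of the codon, counts
#' the fraction that are synonymous; mutations creating stop codons are
#' excluded from the per-position denominator, so `syn + nonsyn == 3`
#' exactly after renormalization.
#'
#' @param codon A sense codon of the standard genetic code.
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @export
ng86_sites <- function(codon) {
  tb <- .codon_tables()
  codon <- toupper(codon)
  if (!codon %in% tb$sense) stop("not a sense codon: ", codon)
  s <- tb$syn_sites[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Averages synonymous/nonsynonymous step counts over all minimal
#' mutational pathways between the codons, excluding pathways through
#' stop codons. Identical codons give `(0, 0)`; a pair whose every
#' pathway crosses a stop returns `NA` (the column is skipped upstream).
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(Sd, Nd)`.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  tb <- .codon_tables()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_a %in% tb$sense) stop("not a sense codon: ", codon_a)
  if (!codon_b %in% tb$sense) stop("not a sense codon: ", codon_b)
  if (codon_a == codon_b) return(c(Sd = 0, Nd = 0))
  c(Sd = tb$Sd[codon_a, codon_b], Nd = tb$Nd[codon_a, codon_b])
}

# ---- codon alignment ------------------------------------------------------

.split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  stopifnot(nchar(cds) %% 3 == 0)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

.strip_stop <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  cod <- .split_codons(cds)
  if (length(cod) && !is.na(code[cod[length(cod)]]) &&
      code[cod[length(cod)]] == "*")
    cod <- cod[-length(cod)]
  cod
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Threads the two coding sequences through their aligned proteins: each
#' protein residue becomes its codon, each protein gap a `---` triplet.
#' Trailing stop codons are removed before threading. The degapped codon
#' rows re-concatenate exactly to the input CDS (minus stop).
#'
#' @param cds_a,cds_b Coding sequences (character/`DNAString`), lengths
#'   multiples of 3.
#' @param alignment Protein alignment from [align_global()] on the two
#'   translations.
#' @return A list (`bbx_codon_alignment`) with `codons_a`, `codons_b`
#'   (equal-length codon vectors) and the pair IDs.
#' @export
codon_align <- function(cds_a, cds_b, alignment) {
  code <- Biostrings::GENETIC_CODE
  thread <- function(cds, gapped, which) {
    cod <- .strip_stop(cds)
    res <- character(nchar(gapped))
    chars <- strsplit(gapped, "")[[1]]
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") { res[i] <- "---"; next }
      k <- k + 1L
      if (k > length(cod))
        stop("CDS ", which, " shorter than aligned protein")
      aa <- code[cod[k]]
      if (is.na(aa) || (aa != chars[i] && chars[i] != "X"))
        stop("CDS/protein mismatch in ", which, " at codon ", k, " (",
             cod[k], " -> ", aa, ", aligned residue ", chars[i], ")")
      res[i] <- cod[k]
    }
    if (k != length(cod))
      stop("CDS ", which, " longer than aligned protein")
    res
  }
  structure(list(id_a = alignment$id_a, id_b = alignment$id_b,
                 codons_a = thread(cds_a, alignment$aligned_a, "a"),
                 codons_b = thread(cds_b, alignment$aligned_b, "b")),
            class = "bbx_codon_alignment")
}

# ---- Ka/Ks ----------------------------------------------------------------

.jc_correct <- function(p) {
  # Jukes-Cantor multiple-hit correction; saturated (p >= 3/4) -> NA
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Site counts `S`, `N` are the per-sequence NG86 sums averaged over the
#' two sequences; difference counts `Sd`, `Nd` are pathway-averaged per
#' codon column. `ps = Sd/S` and `pn = Nd/N` are Jukes-Cantor corrected
#' into `Ks` and `Ka`. Gapped or ambiguous codon columns are skipped, as
#' are the (rare) columns whose every mutational pathway crosses a stop.
#' A proportion at or beyond 3/4 saturates: the estimate is `NA` and the
#' result flagged.
#'
#' @param aln A `bbx_codon_alignment` from [codon_align()].
#' @param min_codons Minimum ungapped codon columns (default 10).
#' @return data.frame row: `id_a`, `id_b`, `n_codons`, `S`, `N`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ratio`, `saturated`.
#' @export
kaks <- function(aln, min_codons = 10L) {
  tb <- .codon_tables()
  keep <- aln$codons_a %in% tb$sense & aln$codons_b %in% tb$sense
  ca <- aln$codons_a[keep]; cb <- aln$codons_b[keep]
  if (length(ca) < min_codons)
    stop("fewer than ", min_codons, " comparable codon columns")
  ia <- match(ca, tb$sense); ib <- match(cb, tb$sense)
  sd_col <- ifelse(ia == ib, 0, tb$Sd[cbind(ia, ib)])
  nd_col <- ifelse(ia == ib, 0, tb$Nd[cbind(ia, ib)])
  ok <- !is.na(sd_col)                       # all-stop-pathway columns skipped
  S <- (sum(tb$syn_sites[ia[ok]]) + sum(tb$syn_sites[ib[ok]])) / 2
  N <- 3 * sum(ok) - S
  Sdv <- sum(sd_col[ok]); Ndv <- sum(nd_col[ok])
  ps <- if (S > 0) Sdv / S else NA_real_
  pn <- if (N > 0) Ndv / N else NA_real_
  Ks <- .jc_correct(ps); Ka <- .jc_correct(pn)
  saturated <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  data.frame(id_a = aln$id_a, id_b = aln$id_b, n_codons = sum(ok),
             S = S, N = N, Sd = Sdv, Nd = Ndv, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, ratio = ratio, saturated = saturated,
             stringsAsFactors = FALSE)
}

#' Sliding-window Ka/Ks profile
#'
#' Advances a window of `window_bp` (default 150 bp = 50 codons) in steps
#' of `step_bp` (default 9 bp = 3 codons) over the aligned coordinate
#' system and computes [kaks()] per window with the same skipping rules.
#' An alignment shorter than the window yields a single whole-length
#' window flagged `short`.
#'
#' @param aln A `bbx_codon_alignment`.
#' @param window_bp,step_bp Window and step sizes in bp (multiples of 3).
#' @return data.frame with `start_bp`, `end_bp` (alignment coordinates,
#'   0-based half-open), `Ks`, `Ka`, `ratio`, `saturated`, plus attribute
#'   `short` when the alignment was shorter than one window.
#' @export
sliding_window <- function(aln, window_bp = 150L, step_bp = 9L) {
  stopifnot(window_bp %% 3 == 0, step_bp %% 3 == 0)
  L <- 3L * length(aln$codons_a)
  short <- L < window_bp
  starts <- if (short) 0L else seq(0L, L - window_bp, by = step_bp)
  rows <- lapply(starts, function(s) {
    e <- if (short) L else s + window_bp
    idx <- (s / 3 + 1):(e / 3)
    sub <- structure(list(id_a = aln$id_a, id_b = aln$id_b,
                          codons_a = aln$codons_a[idx],
                          codons_b = aln$codons_b[idx]),
                     class = "bbx_codon_alignment")
    kk <- tryCatch(kaks(sub, min_codons = 1L), error = function(e) NULL)
    if (is.null(kk))
      return(data.frame(start_bp = s, end_bp = e, Ks = NA_real_,
                        Ka = NA_real_, ratio = NA_real_, saturated = NA))
    data.frame(start_bp = s, end_bp = e, Ks = kk$Ks, Ka = kk$Ka,
               ratio = kk$ratio, saturated = kk$saturated)
  })
  out <- do.call(rbind, rows)
  attr(out, "short") <- short
  out
}

#' Selection class from a Ka/Ks ratio
#'
#' Bins follow the family analysis convention: below 0.3 strong purifying,
#' 0.3 to 1 (inclusive of both bounds) relaxed purifying, strictly above 1
#' positive. Undefined ratios are `undetermined`.
#'
#' @param ratio Numeric vector of Ka/Ks ratios (NA allowed).
#' @return data.frame with `ratio`, `class`, `bin`.
#' @export
classify_selection <- function(ratio) {
  cls <- ifelse(is.na(ratio), "undetermined",
         ifelse(ratio < 0.3, "strong_purifying",
         ifelse(ratio <= 1, "relaxed_purifying", "positive")))
  bin <- ifelse(is.na(ratio), NA_character_,
         ifelse(ratio < 0.3, "<0.3",
         ifelse(ratio <= 1, "0.3-1", ">1")))
  data.frame(ratio = ratio, class = cls, bin = bin, stringsAsFactors = FALSE)
}

#' Duplication-age class from Ks
#'
#' Homolog pairs with Ks inside the whole-genome-duplication band
#' (default `[0.8, 1.6]`, covering the shared orchid WGD at Ks near 1)
#' are `shared_WGD`; pairs below `recent_max` (default 0.2) are `recent`
#' duplicates; everything else, including saturated estimates, is
#' `other`.
#'
#' @param Ks Numeric vector (NA = saturated/undefined).
#' @param wgd_range Two-element WGD Ks band.
#' @param recent_max Upper Ks bound for recent duplicates.
#' @return Character vector of classes.
#' @export
classify_duplication <- function(Ks, wgd_range = c(0.8, 1.6),
                                 recent_max = 0.2) {
  ifelse(is.na(Ks), "other",
  ifelse(Ks >= wgd_range[1] & Ks <= wgd_range[2], "shared_WGD",
  ifelse(Ks < recent_max, "recent", "other")))
}

#' Ka/Ks for a table of homolog pairs
#'
#' Convenience wrapper: for each pair, aligns the proteins, back-translates
#' to codons, and runs [kaks()] plus the classifiers (and optionally
#' [sliding_window()]).
#'
#' @param pairs data.frame from [find_homologs()].
#' @param cds Named character vector / `DNAStringSet` of coding sequences.
#' @param proteins Named protein set matching `cds`.
#' @param windows If `TRUE`, also return per-pair window profiles.
#' @return A list with `results` (one row per pair, including selection
#'   and duplication classes) and `windows` (long-format window table or
#'   `NULL`).
#' @export
kaks_pairs <- function(pairs, cds, proteins, windows = FALSE) {
  res <- list(); win <- list()
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs$id_a[k]; ib <- pairs$id_b[k]
    al <- align_global(proteins[[ia]], proteins[[ib]], id_a = ia, id_b = ib)
    ca <- codon_align(cds[[ia]], cds[[ib]], al)
    kk <- kaks(ca)
    kk$relation <- pairs$relation[k]
    kk$selection_class <- classify_selection(kk$ratio)$class
    kk$selection_bin <- classify_selection(kk$ratio)$bin
    kk$duplication_class <- classify_duplication(kk$Ks)
    res[[k]] <- kk
    if (windows) {
      w <- sliding_window(ca)
      w$id_a <- ia; w$id_b <- ib
      win[[k]] <- w
    }
  }
  list(results = do.call(rbind, res),
       windows = if (windows) do.call(rbind, win) else NULL)
}
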