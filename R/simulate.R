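# Seeded generators emulating every input of the family analysis at toy
# scale, with complete ground truth for recovery tests. Backgrounds avoid
# the residues/motifs being planted (rejection sampling / constructive
# avoidance), so plant-and-detect round trips are exact, not statistical.

.AA_BG <- setdiff(c("A", "R", "N", "D", "E", "Q", "G", "I", "L", "K", "M",
                    "F", "P", "S", "T", "W", "Y", "V"), character(0))
# background/linker residues exclude C and H so the Cys/His-anchored B-BOX
# patterns can only ever match at planted positions

.CODONS_OF <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), code)
})

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
.rand_aa <- function(n) sample(.AA_BG, n, TRUE)
.codon_for <- function(aa) {
  cands <- .CODONS_OF[[aa]]
  cands[sample.int(length(cands), 1L)]
}

# ---- domain realizations --------------------------------------------------

# realize a pattern instance as (residue vector); B-BOX2 fixes D/C as D and
# keeps its 5th spacer at >= 5 so the instance cannot also satisfy the
# B-BOX1 scaffold (and vice versa); spacers use background residues only
.realize_domain <- function(name) {
  pats <- load_domain_patterns()
  p <- pats[[name]]
  n <- length(p$anchors)
  gaps <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    lo <- p$gap_min[i]; hi <- p$gap_max[i]
    if (name == "BBOX2" && i == 4L) lo <- max(lo, 5L)
    gaps[i] <- if (lo == hi) lo else sample(lo:hi, 1L)
  }
  anchors <- vapply(seq_len(n), function(i) {
    a <- p$anchors[[i]]
    if (name == "BBOX2" && i == 4L) "D" else a[1L]
  }, character(1))
  out <- anchors[1L]
  for (i in seq_len(n - 1L))
    out <- c(out, .rand_aa(gaps[i]), anchors[i + 1L])
  out
}

.clade_domains <- list(
  I   = c("BBOX1", "BBOX2", "CCT"),
  II  = c("BBOX1", "BBOX2", "CCT"),
  III = c("BBOX1", "CCT"),
  IV  = c("BBOX1", "BBOX2"),
  V   = c("BBOX1"))

# build a protein realizing the clade architecture; returns residues plus
# the 0-based half-open planted coordinates
.build_protein <- function(clade) {
  # generous random leads/linkers/tails keep unrelated family members well
  # below the RBH identity floor (shared domain anchors alone would not)
  doms <- .clade_domains[[clade]]
  lead <- sample(30:60, 1L)
  res <- .rand_aa(lead)
  truth <- data.frame(domain = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  for (d in doms) {
    if (d == "CCT") res <- c(res, .rand_aa(sample(50:90, 1L)))
    else if (nrow(truth)) res <- c(res, .rand_aa(sample(10:30, 1L)))
    inst <- .realize_domain(d)
    truth <- rbind(truth, data.frame(domain = d, start = length(res),
                                     end = length(res) + length(inst),
                                     stringsAsFactors = FALSE))
    res <- c(res, inst)
  }
  res <- c(res, .rand_aa(sample(100:160, 1L)))
  list(residues = res, domains = truth)
}

# single-nucleotide nonsynonymous neighbor of a codon whose new residue
# stays in the background alphabet; NULL when none exists
.nonsyn_neighbor <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  cands <- character(0)
  for (pos in 1:3) for (alt in setdiff(nt, ch[pos])) {
    mut <- ch; mut[pos] <- alt
    mcd <- paste(mut, collapse = "")
    if (code[mcd] != "*" && code[mcd] != code[codon] &&
        code[mcd] %in% .AA_BG)
      cands <- c(cands, mcd)
  }
  if (length(cands)) sample(cands, 1L) else NULL
}

.reverse_translate <- function(residues, stop_codon = "TAA") {
  paste0(paste(vapply(residues, .codon_for, character(1)), collapse = ""),
         stop_codon)
}

# apply synonymous substitution events to a codon vector (rejection moves)
.syn_evolve <- function(codons, n_events) {
  code <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  done <- 0L
  while (done < n_events) {
    ci <- sample.int(length(codons), 1L)
    ch <- strsplit(codons[ci], "")[[1]]
    pos <- sample.int(3L, 1L)
    alt <- sample(setdiff(nt, ch[pos]), 1L)
    mut <- ch; mut[pos] <- alt
    mcd <- paste(mut, collapse = "")
    if (code[mcd] == "*" || code[mcd] != code[codons[ci]]) next
    codons[ci] <- mcd
    done <- done + 1L
  }
  codons
}

# ---- simulation config ----------------------------------------------------

#' Simulation configuration
#'
#' Defaults mirror the cardinalities of the orchid BBX family analysis:
#' a 19-gene and a 16-gene genome (clades I-V in proportions 3/3/6/17/6),
#' 13 ortholog + 2 + 2 paralog pairs, exon counts 1-7 distributed as
#' 8/10/7/6/2/2 genes, 1500 bp promoters, an 8-tissue FPKM matrix with
#' 5/8/6 expression groups, and a 4-treatment x 4-timepoint qPCR design
#' with 3 replicates.
#'
#' @param seed Integer root seed; every generator draws from it.
#' @param n_orthologs Number of cross-genome ortholog pairs.
#' @param n_paralogs_a,n_paralogs_b Within-genome paralog pairs.
#' @param n_extra_a,n_extra_b Additional unpaired genes per genome.
#' @param genome_names Two genome labels.
#' @param ortholog_identity,paralog_identity Target protein identities.
#' @param ortholog_ks Target synonymous divergence of ortholog pairs.
#' @param paralog_ks_a,paralog_ks_b Per-pair paralog Ks targets (first
#'   pair WGD-aged, second recent, by default).
#' @param exon_plan Named integer vector: exon count -> number of genes.
#' @param promoter_len Promoter length in bp.
#' @param fpkm_groups Named vector of planted A/B/C group sizes.
#' @param qpcr_treatments,qpcr_timepoints qPCR design.
#' @param ct_sd Replicate Ct noise standard deviation.
#' @return A `bbx_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_orthologs = 13L,
                       n_paralogs_a = 2L, n_paralogs_b = 2L,
                       n_extra_a = 2L, n_extra_b = 0L,
                       genome_names = c("Do", "Pe"),
                       ortholog_identity = 0.70,
                       paralog_identity = c(0.80, 0.95),
                       ortholog_ks = 1.0,
                       paralog_ks_a = c(1.3, 0.08),
                       paralog_ks_b = c(1.05, 0.05),
                       exon_plan = c(`1` = 8L, `2` = 10L, `3` = 7L,
                                     `4` = 6L, `5` = 2L, `7` = 2L),
                       promoter_len = 1500L,
                       fpkm_groups = c(A = 5L, B = 8L, C = 6L),
                       qpcr_treatments = c("ABA", "SA", "AgNO3", "MeJA"),
                       qpcr_timepoints = c(24L, 48L, 72L, 96L),
                       ct_sd = 0.2) {
  stopifnot(n_orthologs >= 0, n_paralogs_a >= 0, n_paralogs_b >= 0,
            seed == floor(seed))
  n_b_singles <- if (n_paralogs_b > 0) n_paralogs_b + 1L else 0L
  cfg <- list(seed = as.integer(seed), n_orthologs = n_orthologs,
              n_paralogs_a = n_paralogs_a, n_paralogs_b = n_paralogs_b,
              n_extra_a = n_extra_a, n_extra_b = n_extra_b,
              n_genes_a = n_orthologs + 2L * n_paralogs_a + n_extra_a,
              n_genes_b = n_orthologs + n_b_singles + n_extra_b,
              genome_names = genome_names,
              ortholog_identity = ortholog_identity,
              paralog_identity = paralog_identity,
              ortholog_ks = ortholog_ks,
              paralog_ks_a = paralog_ks_a, paralog_ks_b = paralog_ks_b,
              exon_plan = exon_plan, promoter_len = promoter_len,
              fpkm_groups = fpkm_groups,
              qpcr_treatments = qpcr_treatments,
              qpcr_timepoints = qpcr_timepoints, ct_sd = ct_sd)
  class(cfg) <- "bbx_sim_config"
  cfg
}

# clade assignments for units (ortholog pairs) and singletons, recycled
# from family-shaped cycles
.assign_clades <- function(cfg) {
  unit_cycle <- c("IV", "IV", "IV", "IV", "IV", "IV", "IV", "III", "III",
                  "V", "V", "II", "I")
  para_cycle_a <- c("IV", "V")
  extra_cycle_a <- c("II", "I")
  list(units = if (cfg$n_orthologs)
         rep_len(unit_cycle, cfg$n_orthologs) else character(0),
       para_a = if (cfg$n_paralogs_a)
         rep_len(para_cycle_a, cfg$n_paralogs_a) else character(0),
       extra_a = if (cfg$n_extra_a)
         rep_len(extra_cycle_a, cfg$n_extra_a) else character(0),
       para_b_first = "III",
       extra_b = if (cfg$n_extra_b)
         rep_len(c("IV", "V"), cfg$n_extra_b) else character(0))
}

# ---- make_family ----------------------------------------------------------

#' Generate a two-genome synthetic BBX family
#'
#' Builds two toy genomes whose genes realize the configured clade
#' architectures, ortholog/paralog pair structure and exon-count
#' distribution. Domains are planted from the canonical patterns into
#' Cys/His-free backgrounds, so the domain scanner recovers every planted
#' instance at its exact coordinates with no false positives (verified at
#' generation time). Homolog partners are derived by substituting
#' non-domain residues down to the target identity plus seeded synonymous
#' divergence at the target Ks.
#'
#' Deterministic given `config$seed`. With `dir` set, writes per-genome
#' genome FASTA, GFF3, protein and CDS FASTA files plus `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `genomes` (named list of `DNAStringSet` scaffolds),
#'   `gff3` (named list of GFF3 text lines), `proteins`, `cds` (named
#'   lists of named character vectors), and `truth` (gene table, planted
#'   domain coordinates, pair table).
#' @export
make_family <- function(config = sim_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  cl <- .assign_clades(cfg)
  ga <- cfg$genome_names[1L]; gb <- cfg$genome_names[2L]

  genes <- list()   # per gene: genome, name, clade, residues, domains, cds
  pairs <- list()

  new_gene <- function(genome, clade, residues = NULL, domains = NULL,
                       cds = NULL) {
    if (is.null(residues)) {
      bp <- .build_protein(clade)
      residues <- bp$residues; domains <- bp$domains
      cds <- .reverse_translate(residues)
    }
    list(genome = genome, clade = clade, residues = residues,
         domains = domains, cds = cds)
  }
  derive_gene <- function(src, genome, identity, ks) {
    # synonymous divergence at rate ks, then m single-nucleotide
    # nonsynonymous substitutions outside the planted domains; keeps the
    # NG86 Ks of the pair close to the configured target
    m <- round((1 - identity) * length(src$residues))
    cod <- .split_codons(src$cds)
    stop_cd <- cod[length(cod)]
    cod <- cod[-length(cod)]
    S0 <- sum(vapply(cod, function(c) ng86_sites(c)[["syn"]], numeric(1)))
    cod <- .syn_evolve(cod, round(ks * S0))
    protected <- logical(length(cod))
    for (k in seq_len(nrow(src$domains)))
      protected[(src$domains$start[k] + 1L):src$domains$end[k]] <- TRUE
    free <- which(!protected)
    if (m > length(free)) stop("too few mutable positions for target identity")
    done <- 0L
    pool <- sample(free)
    for (p in pool) {
      if (done >= m) break
      nb <- .nonsyn_neighbor(cod[p])
      if (is.null(nb)) next
      cod[p] <- nb
      done <- done + 1L
    }
    if (done < m) stop("could not reach target identity")
    cds <- paste0(paste(cod, collapse = ""), stop_cd)
    res <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cod, collapse = "")),
      no.init.codon = TRUE)), "")[[1]]
    list(genome = genome, clade = src$clade, residues = res,
         domains = src$domains, cds = cds)
  }

  a_genes <- list(); b_genes <- list()
  # ortholog units
  for (u in seq_len(cfg$n_orthologs)) {
    src <- new_gene(ga, cl$units[u])
    a_genes[[length(a_genes) + 1L]] <- src
    b_genes[[length(b_genes) + 1L]] <-
      derive_gene(src, gb, cfg$ortholog_identity, cfg$ortholog_ks)
    pairs[[length(pairs) + 1L]] <- data.frame(
      a_idx = length(a_genes), b_idx = length(b_genes),
      relation = "ortholog", genomes = paste(ga, gb),
      target_identity = cfg$ortholog_identity, target_ks = cfg$ortholog_ks,
      stringsAsFactors = FALSE)
  }
  # A paralog pairs (both members among A singletons)
  for (p in seq_len(cfg$n_paralogs_a)) {
    idv <- rep_len(cfg$paralog_identity, cfg$n_paralogs_a)[p]
    src <- new_gene(ga, cl$para_a[p])
    a_genes[[length(a_genes) + 1L]] <- src
    a_genes[[length(a_genes) + 1L]] <-
      derive_gene(src, ga, idv, rep_len(cfg$paralog_ks_a, cfg$n_paralogs_a)[p])
    pairs[[length(pairs) + 1L]] <- data.frame(
      a_idx = length(a_genes) - 1L, b_idx = length(a_genes),
      relation = "paralog", genomes = paste(ga, ga),
      target_identity = idv,
      target_ks = rep_len(cfg$paralog_ks_a, cfg$n_paralogs_a)[p],
      stringsAsFactors = FALSE)
  }
  # A extras
  for (e in seq_len(cfg$n_extra_a))
    a_genes[[length(a_genes) + 1L]] <- new_gene(ga, cl$extra_a[e])
  # B paralog pairs: first pair = two fresh singletons; further pairs
  # derive a singleton from an ortholog-unit gene (same clade), matching
  # families where a paralog also has a cross-genome ortholog
  a_para_offset <- cfg$n_orthologs  # indices bookkeeping for pair table
  for (p in seq_len(cfg$n_paralogs_b)) {
    idv <- rep_len(cfg$paralog_identity, cfg$n_paralogs_b)[p]
    ksv <- rep_len(cfg$paralog_ks_b, cfg$n_paralogs_b)[p]
    if (p == 1L) {
      src <- new_gene(gb, cl$para_b_first)
      b_genes[[length(b_genes) + 1L]] <- src
      b_genes[[length(b_genes) + 1L]] <- derive_gene(src, gb, idv, ksv)
      pairs[[length(pairs) + 1L]] <- data.frame(
        a_idx = length(b_genes) - 1L, b_idx = length(b_genes),
        relation = "paralog", genomes = paste(gb, gb),
        target_identity = idv, target_ks = ksv, stringsAsFactors = FALSE)
    } else {
      if (cfg$n_orthologs < p - 1L)
        stop("not enough ortholog units to seed B paralogs")
      src <- b_genes[[p - 1L]]      # ortholog-unit gene p-1 of genome B
      b_genes[[length(b_genes) + 1L]] <- derive_gene(src, gb, idv, ksv)
      pairs[[length(pairs) + 1L]] <- data.frame(
        a_idx = p - 1L, b_idx = length(b_genes),
        relation = "paralog", genomes = paste(gb, gb),
        target_identity = idv, target_ks = ksv, stringsAsFactors = FALSE)
    }
  }
  # B extras
  for (e in seq_len(cfg$n_extra_b))
    b_genes[[length(b_genes) + 1L]] <- new_gene(gb, cl$extra_b[e])

  stopifnot(length(a_genes) == cfg$n_genes_a,
            length(b_genes) == cfg$n_genes_b)

  name_of <- function(genome, i) sprintf("%sBBX%02d", genome, i)
  all_genes <- c(lapply(seq_along(a_genes), function(i) {
    g <- a_genes[[i]]; g$gene_id <- name_of(ga, i); g
  }), lapply(seq_along(b_genes), function(i) {
    g <- b_genes[[i]]; g$gene_id <- name_of(gb, i); g
  }))

  # exon counts over the whole family, shuffled
  exon_counts <- rep(as.integer(names(cfg$exon_plan)), cfg$exon_plan)
  n_all <- length(all_genes)
  exon_counts <- if (length(exon_counts) >= n_all)
    sample(exon_counts)[seq_len(n_all)]
  else sample(rep_len(exon_counts, n_all))

  # lay each gene on its own scaffold; alternate strands
  genomes <- list(); gff <- list()
  genomes[[ga]] <- list(); genomes[[gb]] <- list()
  gff[[ga]] <- character(0); gff[[gb]] <- character(0)
  proteins <- list(); cds_out <- list()
  proteins[[ga]] <- character(0); proteins[[gb]] <- character(0)
  cds_out[[ga]] <- character(0); cds_out[[gb]] <- character(0)
  dom_truth <- list(); gene_truth <- list()

  for (gi in seq_along(all_genes)) {
    g <- all_genes[[gi]]
    k <- exon_counts[gi]
    L <- nchar(g$cds)
    strand <- if (gi %% 2L == 0L) "-" else "+"
    # split CDS into k exon segments of >= 3 bp
    cuts <- if (k > 1L) sort(sample(seq(3L, L - 3L, by = 3L), k - 1L)) else integer(0)
    seg_bounds <- c(0L, cuts, L)
    introns <- if (k > 1L) sample(80:300, k - 1L, replace = TRUE) else integer(0)
    region <- ""
    exon_off <- integer(0)   # region-relative starts of exons
    for (s in seq_len(k)) {
      exon_off <- c(exon_off, nchar(region))
      region <- paste0(region,
                       substr(g$cds, seg_bounds[s] + 1L, seg_bounds[s + 1L]))
      if (s < k) region <- paste0(region, .rand_dna(introns[s]))
    }
    exon_len <- diff(seg_bounds)
    rlen <- nchar(region)
    scaf <- sprintf("scaffold_%s_%02d", g$genome, gi)
    if (strand == "+") {
      gstart <- 2000L
      chrom <- paste0(.rand_dna(2000L), region, .rand_dna(500L))
      ex <- cbind(gstart + exon_off, gstart + exon_off + exon_len)
    } else {
      gstart <- 500L
      chrom <- paste0(.rand_dna(500L),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(region))),
                      .rand_dna(2000L))
      ex <- cbind(gstart + rlen - exon_off - exon_len,
                  gstart + rlen - exon_off)
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
    }
    genomes[[g$genome]][[scaf]] <- chrom
    gid <- g$gene_id
    lines <- c(sprintf("%s\tbbxkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       scaf, min(ex[, 1L]) + 1L, max(ex[, 2L]), strand, gid),
               sprintf("%s\tbbxkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       scaf, min(ex[, 1L]) + 1L, max(ex[, 2L]), strand, gid, gid))
    for (r in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\tbbxkit\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                scaf, ex[r, 1L] + 1L, ex[r, 2L], strand, gid, r, gid),
        sprintf("%s\tbbxkit\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.t1.cds%d;Parent=%s.t1",
                scaf, ex[r, 1L] + 1L, ex[r, 2L], strand, gid, r, gid))
    }
    gff[[g$genome]] <- c(gff[[g$genome]], lines)
    prot <- paste(g$residues, collapse = "")
    proteins[[g$genome]][gid] <- prot
    cds_out[[g$genome]][gid] <- g$cds
    dom_truth[[gid]] <- cbind(gene_id = gid, g$domains,
                              stringsAsFactors = FALSE)
    gene_truth[[gid]] <- data.frame(
      gene_id = gid, genome = g$genome, clade = g$clade, seq_id = scaf,
      strand = strand, n_exons = k, protein_len = nchar(prot),
      stringsAsFactors = FALSE)
  }

  # pair table with final gene names
  pair_rows <- lapply(pairs, function(p) {
    gnms <- strsplit(p$genomes, " ")[[1]]
    id1 <- name_of(gnms[1L], p$a_idx); id2 <- name_of(gnms[2L], p$b_idx)
    ids <- sort(c(id1, id2))
    data.frame(id_a = ids[1L], id_b = ids[2L], relation = p$relation,
               target_identity = p$target_identity, target_ks = p$target_ks,
               stringsAsFactors = FALSE)
  })
  truth <- list(genes = do.call(rbind, gene_truth),
                domains = do.call(rbind, dom_truth),
                pairs = do.call(rbind, pair_rows))
  rownames(truth$genes) <- rownames(truth$domains) <- NULL

  genomes <- lapply(genomes, function(g) Biostrings::DNAStringSet(unlist(g)))
  gff <- lapply(gff, function(x)
    c("##gff-version 3", x))

  # generation-time verification: planted domains are recovered exactly
  for (gm in names(proteins)) {
    hits <- scan_domains(Biostrings::AAStringSet(proteins[[gm]]))
    for (gid in names(proteins[[gm]])) {
      h <- hits[hits$protein_id == gid, c("domain", "start", "end")]
      tr <- truth$domains[truth$domains$gene_id == gid,
                          c("domain", "start", "end")]
      rownames(h) <- rownames(tr) <- NULL
      if (!isTRUE(all.equal(h[order(h$start), ], tr[order(tr$start), ],
                            check.attributes = FALSE)))
        stop("internal error: planted domains not recovered for ", gid)
    }
  }

  out <- list(config = cfg, genomes = genomes, gff3 = gff,
              proteins = proteins, cds = cds_out, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (gm in names(genomes)) {
      write_fasta(genomes[[gm]], file.path(dir, paste0(gm, "_genome.fa")))
      writeLines(gff[[gm]], file.path(dir, paste0(gm, ".gff3")))
      write_fasta(proteins[[gm]], file.path(dir, paste0(gm, "_proteins.faa")),
                  alphabet = "protein")
      write_fasta(cds_out[[gm]], file.path(dir, paste0(gm, "_cds.fna")))
    }
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  out
}

# ---- evolve_pair ----------------------------------------------------------

#' Evolve a homolog pair at target Ka and Ks
#'
#' Applies independent Jukes-Cantor-style substitution processes to two
#' descendant lineages of an ancestral coding sequence: Poisson numbers
#' of synonymous and nonsynonymous events (expectation `target/2 x`
#' ancestral site count per lineage) placed by uniform rejection
#' sampling, never passing through stop codons. Realized event counts
#' are returned as ground truth.
#'
#' @param ancestral_cds Stop-free coding sequence (length multiple of 3).
#' @param target_ks,target_ka Expected substitutions per synonymous /
#'   nonsynonymous site between the descendants (0 to 3; beyond is
#'   saturated and an error).
#' @param seed RNG seed.
#' @return List with `cds_a`, `cds_b`, `events` (realized syn/nonsyn
#'   event counts per lineage), `S0`, `N0`.
#' @export
evolve_pair <- function(ancestral_cds, target_ks, target_ka, seed = 1L) {
  if (target_ks > 3 || target_ka > 3)
    stop("targets beyond saturation (max 3)")
  if (target_ks < 0 || target_ka < 0) stop("targets must be >= 0")
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  cod0 <- .split_codons(ancestral_cds)
  if (any(code[cod0] == "*")) stop("ancestral CDS contains a stop codon")
  S0 <- sum(vapply(cod0, function(c) ng86_sites(c)[["syn"]], numeric(1)))
  N0 <- 3 * length(cod0) - S0

  evolve_lineage <- function(codons, n_syn, n_non) {
    todo <- sample(c(rep("s", n_syn), rep("n", n_non)))
    for (kind in todo) {
      repeat {
        ci <- sample.int(length(codons), 1L)
        ch <- strsplit(codons[ci], "")[[1]]
        pos <- sample.int(3L, 1L)
        alt <- sample(setdiff(nt, ch[pos]), 1L)
        mut <- ch; mut[pos] <- alt
        mcd <- paste(mut, collapse = "")
        if (code[mcd] == "*") next
        syn <- code[mcd] == code[codons[ci]]
        if ((kind == "s") == syn) { codons[ci] <- mcd; break }
      }
    }
    codons
  }
  ns_a <- stats::rpois(1L, target_ks * S0 / 2)
  nn_a <- stats::rpois(1L, target_ka * N0 / 2)
  ns_b <- stats::rpois(1L, target_ks * S0 / 2)
  nn_b <- stats::rpois(1L, target_ka * N0 / 2)
  ca <- evolve_lineage(cod0, ns_a, nn_a)
  cb <- evolve_lineage(cod0, ns_b, nn_b)
  list(cds_a = paste(ca, collapse = ""), cds_b = paste(cb, collapse = ""),
       events = c(syn_a = ns_a, nonsyn_a = nn_a,
                  syn_b = ns_b, nonsyn_b = nn_b),
       S0 = S0, N0 = N0)
}

# ---- make_promoters -------------------------------------------------------

# default planted motif totals over the cohort; hormone shares mirror the
# family profile (TGACG-motif 40/138 = 29%, ABRE 32/138 = 23%)
.default_motif_plan <- c(
  "Skn-1-motif" = 98, "GCN4_motif" = 20, "CAT-box" = 15, "CCGTCC-box" = 12,
  "O2-site" = 10, "MRE" = 18, "Box 4" = 25, "circadian" = 8,
  "TGACG-motif" = 40, "ABRE" = 32, "TGA-element" = 14, "AuxRR-core" = 8,
  "GARE-motif" = 7, "P-box" = 7, "TATC-box" = 5, "ERE" = 25,
  "ARE" = 30, "MBS" = 22, "HSE" = 15, "LTR" = 12, "Box-W1" = 10,
  "TC-rich repeats" = 8, "GC-motif" = 6)

.iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                   S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                   D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.realize_consensus <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(ch)
    sample(strsplit(.iupac_expand[[ch]], "")[[1]], 1L), character(1)),
    collapse = "")
}

.count_motifs <- function(seq, library) {
  scan_promoter(seq, library, strands = "both", strict = TRUE)$counts
}

#' Generate promoters with planted cis-elements
#'
#' For each gene, plants the assigned motif instances at non-overlapping
#' plus-strand positions in a random background, then repairs the
#' sequence base by base until the scanned counts (both strands) equal
#' the planted expectation exactly: accidental background or junction
#' matches are re-randomized, never the planted bases. Palindromic
#' consensi count once per strand. The plant-and-verify loop makes
#' recovery exact rather than statistical.
#'
#' @param config A [sim_config()]; promoters are generated for `n_genes`
#'   synthetic gene IDs.
#' @param n_genes Number of promoters (default: family size of `config`).
#' @param motif_plan Named vector of total planted counts per motif
#'   (default mirrors the family cohort profile).
#' @param library Motif library.
#' @return List with `promoters` (named character vector) and `truth`
#'   (data.frame `gene_id`, `motif`, `planted`, `expected_count`).
#' @export
make_promoters <- function(config = sim_config(),
                           n_genes = config$n_genes_a + config$n_genes_b,
                           motif_plan = .default_motif_plan,
                           library = load_motif_library()) {
  set.seed(config$seed + 1L)
  unknown <- setdiff(names(motif_plan), library$name)
  if (length(unknown)) stop("unknown motifs in plan: ",
                            paste(unknown, collapse = ", "))
  L <- config$promoter_len
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  # distribute each motif's total over genes uniformly
  plan <- matrix(0L, n_genes, length(motif_plan),
                 dimnames = list(gene_ids, names(motif_plan)))
  for (m in names(motif_plan)) {
    slots <- table(sample.int(n_genes, motif_plan[[m]], replace = TRUE))
    plan[as.integer(names(slots)), m] <- as.integer(slots)
  }
  is_palindrome <- vapply(library$consensus, function(cs) {
    !grepl("[^ACGT]", cs) &&
      cs == as.character(Biostrings::reverseComplement(Biostrings::DNAString(cs)))
  }, logical(1))
  names(is_palindrome) <- library$name

  # plus-strand intervals [s, e] of all matches of a consensus, both strands
  match_intervals <- function(seq, cs) {
    d <- Biostrings::DNAString(seq)
    plus <- Biostrings::matchPattern(cs, d, fixed = "subject")
    minus <- Biostrings::matchPattern(cs, Biostrings::reverseComplement(d),
                                      fixed = "subject")
    Lc <- nchar(seq)
    rbind(if (length(plus)) cbind(IRanges::start(plus), IRanges::end(plus)),
          if (length(minus)) cbind(Lc - IRanges::end(minus) + 1L,
                                   Lc - IRanges::start(minus) + 1L))
  }

  promoters <- character(n_genes); names(promoters) <- gene_ids
  truth_rows <- list()
  for (g in seq_len(n_genes)) {
    counts_g <- plan[g, ]
    expected <- stats::setNames(integer(nrow(library)), library$name)
    expected[names(counts_g)] <-
      counts_g * ifelse(is_palindrome[names(counts_g)], 2L, 1L)
    widths <- rep(nchar(library$consensus)[match(names(counts_g),
                                                 library$name)], counts_g)
    motifs <- rep(names(counts_g), counts_g)
    if (sum(widths + 4L) > L)
      stop("promoter too short for planted motif load of ", gene_ids[g])

    # choose non-overlapping plant positions (2 bp margins) by rejection
    taken <- rep(FALSE, L)
    pos <- integer(length(motifs))
    for (i in seq_along(motifs)) {
      repeat {
        s <- sample.int(L - widths[i] + 1L, 1L)
        win <- max(1L, s - 2L):min(L, s + widths[i] + 1L)
        if (!any(taken[win])) { taken[win] <- TRUE; pos[i] <- s; break }
      }
    }
    seq <- .rand_dna(L)
    planted <- cbind(pos, pos + widths - 1L)   # occupied intervals
    realize_all <- function(seq) {
      for (i in seq_along(motifs)) {
        cs <- library$consensus[library$name == motifs[i]]
        substr(seq, pos[i], pos[i] + widths[i] - 1L) <- .realize_consensus(cs)
      }
      seq
    }
    seq <- realize_all(seq)
    # targeted repair: re-randomize the free bases of any accidental match
    # (junction- or background-induced); re-realize a planted instance when
    # the accidental match lies wholly inside planted bases
    in_planted <- rep(FALSE, L)
    for (i in seq_along(motifs)) in_planted[pos[i]:(pos[i] + widths[i] - 1L)] <- TRUE
    planted_ok <- FALSE
    for (iter in 1:300) {
      counts <- .count_motifs(seq, library)
      if (all(counts == expected)) { planted_ok <- TRUE; break }
      if (any(counts < expected)) {  # planted instance clobbered: replant
        seq <- realize_all(seq)
        next
      }
      m <- library$name[which(counts > expected)[1L]]
      cs <- library$consensus[library$name == m]
      iv <- match_intervals(seq, cs)
      my_pos <- pos[motifs == m]
      extra <- iv[!(iv[, 1L] %in% my_pos), , drop = FALSE]
      if (!nrow(extra)) { seq <- realize_all(seq); next }
      span <- extra[1L, 1L]:extra[1L, 2L]
      free <- span[!in_planted[span]]
      if (length(free)) {
        for (p in free) substr(seq, p, p) <- .rand_dna(1L)
      } else {
        # re-draw the realization of an overlapping planted instance
        hit <- which(pos <= extra[1L, 2L] & pos + widths - 1L >= extra[1L, 1L])
        for (i in hit) {
          csx <- library$consensus[library$name == motifs[i]]
          substr(seq, pos[i], pos[i] + widths[i] - 1L) <- .realize_consensus(csx)
        }
      }
    }
    if (!planted_ok) stop("could not plant motifs for ", gene_ids[g])
    promoters[g] <- seq
    truth_rows[[g]] <- data.frame(
      gene_id = gene_ids[g], motif = names(counts_g),
      planted = unname(counts_g),
      expected_count = unname(expected[names(counts_g)]),
      stringsAsFactors = FALSE)
  }
  list(promoters = promoters, truth = do.call(rbind, truth_rows))
}

# ---- make_fpkm ------------------------------------------------------------

#' Generate an FPKM matrix with planted expression groups
#'
#' Group A genes draw every tissue from a moderately-to-highly expressed
#' band (log-uniform 8-120 FPKM, median well above the mid-low floor),
#' group B from a basically-unexpressed band (0-0.9, with one tissue
#' allowed up to 3), group C from a uniformly low band (1.2-6.0). The
#' bands guarantee that [group_genes()] with default thresholds recovers
#' the planted sizes for every seed.
#'
#' @param config A [sim_config()].
#' @param tissues Tissue names (default the eight orchid tissues).
#' @return List with `matrix` (genes x tissues) and `truth` (named group
#'   vector).
#' @export
make_fpkm <- function(config = sim_config(), tissues = .bbx_tissues) {
  set.seed(config$seed + 2L)
  sizes <- config$fpkm_groups
  n <- sum(sizes)
  gene_ids <- sprintf("%sBBX%02d", config$genome_names[1L], seq_len(n))
  groups <- sample(rep(names(sizes), sizes))
  m <- matrix(0, n, length(tissues), dimnames = list(gene_ids, tissues))
  for (i in seq_len(n)) {
    m[i, ] <- switch(groups[i],
      A = exp(stats::runif(length(tissues), log(8), log(120))),
      B = { v <- stats::runif(length(tissues), 0, 0.9)
            v[sample.int(length(tissues), 1L)] <- stats::runif(1L, 0, 3)
            v },
      C = stats::runif(length(tissues), 1.2, 6.0))
  }
  list(matrix = round(m, 3), truth = stats::setNames(groups, gene_ids))
}

# ---- make_qpcr ------------------------------------------------------------

#' Generate a qPCR Ct table with planted fold changes
#'
#' Builds a long-format Ct table over genes x treatments x timepoints
#' with three biological replicates. The reference gene is held flat; the
#' target Ct of a treated sample is the control baseline minus
#' `log2(true fold)` plus Gaussian replicate noise, so the 2^-ddCt
#' estimator recovers the planted folds. The control is the shared
#' untreated sample at the first timepoint.
#'
#' @param config A [sim_config()].
#' @param true_folds Optional data.frame `gene_id`, `treatment`,
#'   `timepoint`, `fold`. Default: a small design with folds spanning
#'   down-regulation to a 1700-fold induction.
#' @param n_reps Biological replicates (default 3).
#' @return List with `ct_table` (long format, see
#'   [qpcr_fold_changes()]) and `truth` (= `true_folds`).
#' @export
make_qpcr <- function(config = sim_config(), true_folds = NULL,
                      n_reps = 3L) {
  set.seed(config$seed + 3L)
  ga <- config$genome_names[1L]
  if (is.null(true_folds)) {
    genes <- sprintf("%sBBX%02d", ga, c(9L, 11L, 17L))
    grid <- expand.grid(gene_id = genes,
                        treatment = config$qpcr_treatments,
                        timepoint = config$qpcr_timepoints,
                        stringsAsFactors = FALSE)
    grid$fold <- 1
    grid$fold[grid$gene_id == genes[1L]] <- 0.25            # repressed
    grid$fold[grid$gene_id == genes[2L] & grid$treatment == "ABA"] <- 100
    grid$fold[grid$gene_id == genes[3L] & grid$treatment == "ABA" &
              grid$timepoint == max(config$qpcr_timepoints)] <- 1700
    grid$fold[grid$gene_id == genes[3L] & grid$treatment == "MeJA"] <- 65
    true_folds <- grid
  }
  ref_ct <- 20; base_ct <- 30
  rows <- list()
  for (g in unique(true_folds$gene_id)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, treatment = "control",
      timepoint = min(config$qpcr_timepoints),
      replicate = seq_len(n_reps),
      ct_target = base_ct + stats::rnorm(n_reps, 0, config$ct_sd),
      ct_ref = ref_ct + stats::rnorm(n_reps, 0, config$ct_sd),
      is_control = TRUE, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(true_folds))) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = true_folds$gene_id[r], treatment = true_folds$treatment[r],
      timepoint = true_folds$timepoint[r], replicate = seq_len(n_reps),
      ct_target = base_ct - log2(true_folds$fold[r]) +
        stats::rnorm(n_reps, 0, config$ct_sd),
      ct_ref = ref_ct + stats::rnorm(n_reps, 0, config$ct_sd),
      is_control = FALSE, stringsAsFactors = FALSE)
  }
  list(ct_table = do.call(rbind, rows), truth = true_folds)
}
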