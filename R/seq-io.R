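#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] that enforces the conventions used
#' throughout the package: sequences are upper-cased, record order is
#' preserved, and duplicate identifiers are an error (the offending ID is
#' named). The identifier is the FASTA header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet], named
#'   by record ID, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- if (alphabet == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ID: ", dup[1L])
  names(seqs) <- ids
  # normalize case (lowercase soft-masked bases are common in plant assemblies)
  if (alphabet == "dna") {
    Biostrings::DNAStringSet(toupper(seqs))
  } else {
    Biostrings::AAStringSet(toupper(seqs))
  }
}

#' Write sequences to FASTA
#'
#' @param seqs A named `XStringSet` or named character vector.
#' @param path Output path.
#' @param alphabet Used only when `seqs` is a character vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs)) {
    seqs <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
            else Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Gene models from a GFF3 annotation
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) into a list of gene
#' models, one per gene, using the first mRNA of each gene. Coordinates are
#' converted from GFF3 1-based inclusive to the 0-based half-open convention
#' used everywhere inside the package. CDS segments are assembled in
#' transcription order and minus-strand CDS are reverse-complemented before
#' translation.
#'
#' Each gene model is a list with elements `gene_id`, `seq_id`, `start`,
#' `end` (0-based half-open gene span), `strand`, `exons` and `cds_ranges`
#' (two-column matrices of 0-based half-open intervals sorted by genomic
#' start), `cds` and `protein` (character), and `complete` (`TRUE` when the
#' CDS length is a multiple of 3 and translation is free of internal stops;
#' incomplete models are kept, flagged, and refused by downstream Ka/Ks).
#' A trailing stop codon, if annotated, stays in `cds` but not in `protein`.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome Named `DNAStringSet` containing every referenced scaffold.
#' @return A named list of gene models (class `bbx_gene_models`).
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- md$Parent
  parent1 <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))

  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  models <- list()
  for (g in genes) {
    gid <- ids[g]
    mr <- mrnas[parent1[mrnas] == gid]
    if (!length(mr)) next
    mr <- mr[1L]  # first mRNA per gene
    mid <- ids[mr]
    seq_id <- as.character(GenomicRanges::seqnames(gr)[g])
    if (!seq_id %in% names(genome))
      stop("gene ", gid, " references absent scaffold: ", seq_id)
    strand <- as.character(GenomicRanges::strand(gr)[g])
    if (!strand %in% c("+", "-")) strand <- "+"

    pick <- function(what) {
      idx <- which(type == what & parent1 == mid)
      if (!length(idx)) return(matrix(numeric(0), ncol = 2))
      m <- cbind(GenomicRanges::start(gr)[idx] - 1L, GenomicRanges::end(gr)[idx])
      m[order(m[, 1L]), , drop = FALSE]
    }
    exons <- pick("exon")
    cdsr <- pick("CDS")
    if (nrow(exons) == 0L) exons <- cdsr
    if (nrow(cdsr) == 0L)
      stop("mRNA ", mid, " has no CDS features")

    chrom <- genome[[seq_id]]
    pieces <- apply(cdsr, 1L, function(iv)
      as.character(Biostrings::subseq(chrom, start = iv[1L] + 1L, end = iv[2L])))
    cds <- paste(pieces, collapse = "")
    if (strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))

    complete <- nchar(cds) %% 3L == 0L
    protein <- ""
    if (complete) {
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               if.fuzzy.codon = "solve",
                                               no.init.codon = TRUE))
      aa <- sub("\\*$", "", aa)           # trailing stop stays in cds only
      if (grepl("\\*", aa)) complete <- FALSE
      protein <- gsub("\\*", "", aa)
    }
    models[[gid]] <- structure(list(
      gene_id = gid, seq_id = seq_id,
      start = min(exons[, 1L], cdsr[, 1L]), end = max(exons[, 2L], cdsr[, 2L]),
      strand = strand, exons = exons, cds_ranges = cdsr,
      cds = cds, protein = protein, complete = complete
    ), class = "bbx_gene_model")
  }
  structure(models, class = "bbx_gene_models")
}

#' @export
print.bbx_gene_model <- function(x, ...) {
  cat(sprintf("<gene model> %s %s:[%d,%d) %s  %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$seq_id, x$start, x$end, x$strand,
              nrow(x$exons), nchar(x$cds),
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' Extract the promoter of a gene model
#'
#' Returns up to `length` bp of genomic sequence immediately 5' of the
#' translation start (the ATG of the first CDS segment), on the coding
#' strand. Promoters shorter than `length` because the gene sits near a
#' scaffold edge are returned truncated with attribute `truncated = TRUE`;
#' a gene starting at position 0 yields a zero-length promoter, not an
#' error. The returned sequence never overlaps the CDS start.
#'
#' @param model A gene model from [read_gff3()] or [make_family()].
#' @param genome Named `DNAStringSet`.
#' @param length Promoter length in bp upstream of the ATG (default 1500).
#' @return A `DNAString` with attributes `gene_id` and `truncated`.
#' @export
extract_promoter <- function(model, genome, length = 1500L) {
  if (!model$seq_id %in% names(genome))
    stop("scaffold not in genome: ", model$seq_id)
  chrom <- genome[[model$seq_id]]
  clen <- length(chrom)
  cds_start <- model$cds_ranges[1L, 1L]
  cds_end <- model$cds_ranges[nrow(model$cds_ranges), 2L]
  if (model$strand == "+") {
    from <- max(0L, cds_start - length)
    prom <- if (cds_start > from) Biostrings::subseq(chrom, from + 1L, cds_start)
            else Biostrings::DNAString("")
    truncated <- (cds_start - from) < length
  } else {
    to <- min(clen, cds_end + length)
    prom <- if (to > cds_end) Biostrings::reverseComplement(
              Biostrings::subseq(chrom, cds_end + 1L, to))
            else Biostrings::DNAString("")
    truncated <- (to - cds_end) < length
  }
  attr(prom, "gene_id") <- model$gene_id
  attr(prom, "truncated") <- truncated
  prom
}

#' Exon counts and their histogram
#'
#' @param models A `bbx_gene_models` list.
#' @return A list with `counts` (named integer vector, gene -> exon count)
#'   and `histogram` (table of exon-count frequencies, whose values sum to
#'   the number of models).
#' @export
exon_count_table <- function(models) {
  counts <- vapply(models, function(m) nrow(m$exons), integer(1))
  hist <- if (length(counts)) table(counts) else table(integer(0))
  list(counts = counts, histogram = hist)
}

#' Gene-structure summary table
#'
#' One row per gene with span, strand, exon count and CDS status; the
#' exon-intron structure summary exported by the `structure` pipeline stage.
#'
#' @param models A `bbx_gene_models` list.
#' @return A data.frame.
#' @export
gene_structure_table <- function(models) {
  do.call(rbind, lapply(unname(models), function(m) data.frame(
    gene_id = m$gene_id, seq_id = m$seq_id, start = m$start, end = m$end,
    strand = m$strand, n_exons = nrow(m$exons), cds_bp = nchar(m$cds),
    complete = m$complete, stringsAsFactors = FALSE
  )))
}
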