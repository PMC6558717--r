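test_that("FASTA round trip preserves normalized records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 first record", "acgtACGT", ">s2", "TTTT", "GGGG"), f)
  seqs <- read_fasta(f, "dna")
  expect_equal(names(seqs), c("s1", "s2"))
  expect_equal(as.character(seqs[["s1"]]), "ACGTACGT")  # upper-cased
  expect_equal(as.character(seqs[["s2"]]), "TTTTGGGG")  # whitespace joined
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  expect_equal(as.character(read_fasta(f2, "dna")), as.character(seqs))
})

test_that("FASTA reader rejects duplicates and empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), f)
  expect_error(read_fasta(f, "dna"), "dup")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f2)
  expect_error(read_fasta(f2, "dna"), "empty")
})

test_that("single-exon plus-strand gene model is the genomic slice", {
  chrom <- paste0(strrep("T", 100), "ATGGCTGCAGCTGCCGCAGCTGCGTAA",
                  strrep("G", 50))
  genome <- Biostrings::DNAStringSet(c(sc1 = chrom))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "sc1\ttest\tgene\t101\t127\t.\t+\t.\tID=g1",
               "sc1\ttest\tmRNA\t101\t127\t.\t+\t.\tID=g1.t1;Parent=g1",
               "sc1\ttest\texon\t101\t127\t.\t+\t.\tID=e1;Parent=g1.t1",
               "sc1\ttest\tCDS\t101\t127\t.\t+\t.\tID=c1;Parent=g1.t1"), f)
  mods <- read_gff3(f, genome)
  expect_length(mods, 1)
  m <- mods$g1
  expect_equal(m$cds, "ATGGCTGCAGCTGCCGCAGCTGCGTAA")
  expect_equal(m$protein, "MAAAAAAA")   # trailing stop in cds, not protein
  expect_true(m$complete)
  expect_equal(c(m$start, m$end), c(100, 127))  # 0-based half-open
})

test_that("two-exon minus-strand CDS is assembled in transcription order", {
  # hand-built: on the minus strand the rightmost exon is transcribed
  # first, so genomic [30,45) carries revcomp(cds[1..15]) and genomic
  # [10,22) carries revcomp(cds[16..27])
  cds <- "ATGGCTGCAGCTGCCGCAGCTGCGTAA"            # 27 bp
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  chrom <- paste0(strrep("A", 10), rc(substr(cds, 16, 27)), strrep("C", 8),
                  rc(substr(cds, 1, 15)), strrep("A", 15))
  genome <- Biostrings::DNAStringSet(c(sc1 = chrom))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "sc1\ttest\tgene\t11\t45\t.\t-\t.\tID=g1",
               "sc1\ttest\tmRNA\t11\t45\t.\t-\t.\tID=g1.t1;Parent=g1",
               "sc1\ttest\texon\t11\t22\t.\t-\t.\tID=e1;Parent=g1.t1",
               "sc1\ttest\texon\t31\t45\t.\t-\t.\tID=e2;Parent=g1.t1",
               "sc1\ttest\tCDS\t11\t22\t.\t-\t.\tID=c1;Parent=g1.t1",
               "sc1\ttest\tCDS\t31\t45\t.\t-\t.\tID=c2;Parent=g1.t1"), f)
  m <- read_gff3(f, genome)$g1
  expect_equal(m$cds, cds)
  expect_equal(m$protein, "MAAAAAAA")
  expect_true(m$complete)
})

test_that("CDS not divisible by 3 is flagged, absent scaffold errors", {
  genome <- Biostrings::DNAStringSet(c(sc1 = strrep("ACGT", 30)))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "sc1\ttest\tgene\t1\t10\t.\t+\t.\tID=g1",
               "sc1\ttest\tmRNA\t1\t10\t.\t+\t.\tID=g1.t1;Parent=g1",
               "sc1\ttest\tCDS\t1\t10\t.\t+\t.\tID=c1;Parent=g1.t1"), f)
  m <- read_gff3(f, genome)$g1
  expect_false(m$complete)
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "nope\ttest\tgene\t1\t9\t.\t+\t.\tID=g1",
               "nope\ttest\tmRNA\t1\t9\t.\t+\t.\tID=g1.t1;Parent=g1",
               "nope\ttest\tCDS\t1\t9\t.\t+\t.\tID=c1;Parent=g1.t1"), f2)
  expect_error(read_gff3(f2, genome), "absent scaffold")
})

test_that("promoter extraction is strand-aware, truncation-flagged", {
  # plus strand, gene at 2000 on a 10 kb scaffold -> bases [500, 2000)
  chrom <- random_cds(3400, seed = 5)   # 10200 bp of arbitrary sequence
  genome <- Biostrings::DNAStringSet(c(sc = chrom))
  model <- structure(list(gene_id = "g", seq_id = "sc", start = 2000,
                          end = 2300, strand = "+",
                          exons = cbind(2000, 2300),
                          cds_ranges = cbind(2000, 2300)),
                     class = "bbx_gene_model")
  pr <- extract_promoter(model, genome, length = 1500)
  expect_equal(as.character(pr), substr(chrom, 501, 2000))
  expect_false(attr(pr, "truncated"))

  # minus strand: revcomp of the 1500 bp 3' of the gene end
  model$strand <- "-"
  prm <- extract_promoter(model, genome, length = 1500)
  expect_equal(as.character(prm),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chrom, 2301, 3800)))))

  # gene 200 bp from the scaffold start: truncated 200 bp promoter
  model$strand <- "+"
  model$cds_ranges <- cbind(200, 500)
  prt <- extract_promoter(model, genome, length = 1500)
  expect_equal(length(prt), 200L)
  expect_true(attr(prt, "truncated"))

  # gene at position 0: zero-length promoter, flagged, not an error
  model$cds_ranges <- cbind(0, 300)
  pr0 <- extract_promoter(model, genome, length = 1500)
  expect_equal(length(pr0), 0L)
  expect_true(attr(pr0, "truncated"))
})

test_that("exon count histogram sums to the number of models", {
  fam <- default_family()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(fam$gff3[[1]], f)
  mods <- read_gff3(f, fam$genomes[[1]])
  ect <- exon_count_table(mods)
  expect_equal(sum(ect$histogram), length(mods))
  truth <- fam$truth$genes
  truth <- truth[truth$genome == names(fam$genomes)[1], ]
  expect_equal(unname(ect$counts[truth$gene_id]), truth$n_exons)
  expect_length(exon_count_table(list())$histogram, 0)
})

test_that("complete gene models satisfy the translation invariant", {
  fam <- default_family()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(fam$gff3[[2]], f)
  mods <- read_gff3(f, fam$genomes[[2]])
  for (m in mods) {
    expect_true(m$complete)
    expect_equal(nchar(m$cds), 3 * nchar(m$protein) + 3)
    expect_equal(m$protein, fam$proteins[[2]][[m$gene_id]])
  }
})
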