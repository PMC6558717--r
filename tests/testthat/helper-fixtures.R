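# shared fixtures and independent oracles, built in code at test time

.fixture_env <- new.env(parent = emptyenv())

# default synthetic family, generated once per test run
default_family <- function(seed = 11L) {
  key <- paste0("fam", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_family(sim_config(seed = seed))
  .fixture_env[[key]]
}

# random stop-free CDS of n codons
random_cds <- function(n, seed) {
  set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# wrap two equal-length gap-free CDS into a codon alignment
codon_aln_of <- function(ca, cb) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  structure(list(id_a = "a", id_b = "b",
                 codons_a = split3(ca), codons_b = split3(cb)),
            class = "bbx_codon_alignment")
}

# ---- independent NG86 oracle (enumeration written from scratch) -----------

oracle_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(nts, ch[pos]), function(b) {
      x <- ch; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    legal <- muts[code[muts] != "*"]
    if (length(legal))
      syn <- syn + mean(code[legal] == code[codon])
  }
  c(syn = syn, nonsyn = 3 - syn)
}

oracle_differences <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  if (!length(dpos)) return(c(Sd = 0, Nd = 0))
  perms <- if (length(dpos) == 1) list(dpos) else {
    pp <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { pp[[length(pp) + 1]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), dpos)
    pp
  }
  tot <- c(0, 0); n_legal <- 0
  for (pm in perms) {
    cur <- ca; sn <- c(0, 0); ok <- TRUE
    for (p in pm) {
      nxt <- cur; nxt[p] <- cb[p]
      if (code[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      same <- code[paste(nxt, collapse = "")] == code[paste(cur, collapse = "")]
      sn <- sn + if (same) c(1, 0) else c(0, 1)
      cur <- nxt
    }
    if (ok) { tot <- tot + sn; n_legal <- n_legal + 1 }
  }
  if (n_legal == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = tot[1] / n_legal, Nd = tot[2] / n_legal)
}

# ---- brute-force Fitch oracle (all internal assignments) ------------------

oracle_fitch_score <- function(tree, chars) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  chars <- chars[tree$tip.label, , drop = FALSE]
  total_min <- 0
  for (ch in seq_len(ncol(chars))) {
    best <- Inf
    for (mask in 0:(2^nnode - 1)) {
      internal <- as.integer(intToBits(mask))[seq_len(nnode)]
      states <- c(chars[, ch], internal)
      changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
      best <- min(best, changes)
    }
    total_min <- total_min + best
  }
  total_min
}

# ---- brute-force global alignment oracle (tiny sequences) -----------------

# enumerate all global alignments of a and b (as sequences of moves) and
# return the optimal affine-gap BLOSUM62 score
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  M <- BLOSUM62
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return()
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + M[ca[i], cb[j]], "d")
    if (i <= length(ca))
      rec(i + 1, j, score - (if (prev == "u") gap_extend else gap_open + gap_extend), "u")
    if (j <= length(cb))
      rec(i, j + 1, score - (if (prev == "l") gap_extend else gap_open + gap_extend), "l")
  }
  rec(1, 1, 0, "start")
  best
}
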