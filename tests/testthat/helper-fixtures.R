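## Shared fixtures and independent oracles, built in code at test time.

## A small width-6 TATA-like matrix (consensus TATAAA, 0.7/0.1).
toyMatrix <- function() {
  core <- function(b) {
    p <- rep(0.1, 4)
    p[match(b, c("A", "C", "G", "T"))] <- 0.7
    p
  }
  tataMatrix(sapply(c("T", "A", "T", "A", "A", "A"), core))
}

## Width-6 matrix with two informative columns (A at 0.5, C at 0.25,
## G/T at 0.125) and four uniform columns; its consensus score is 2*log(2),
## so a window matching one informative column at A and the other at C
## scores exactly half the maximum.
halfScoreMatrix <- function() {
  informative <- c(0.5, 0.25, 0.125, 0.125)
  uniform <- rep(0.25, 4)
  tataMatrix(cbind(informative, informative, uniform, uniform, uniform,
                   uniform))
}

## Independent brute-force best-window oracle: plain loops over substrings
## on both strands, scoring by sum(log(p/bg)), with the same tie rule the
## package documents (max score; forward first; smallest forward-strand
## start). Shares no code with the vectorized scanner.
bruteForceBest <- function(sequence, mat) {
  probs <- matrixProbs(mat)
  bg <- matrixBackground(mat)
  w <- matrixWidth(mat)
  bases <- c("A", "C", "G", "T")
  score1 <- function(win) {
    s <- 0
    for (j in seq_len(w)) {
      b <- match(substr(win, j, j), bases)
      s <- s + log(probs[b, j] / bg[b])
    }
    s
  }
  revcomp <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  L <- nchar(sequence)
  cands <- data.frame(score = numeric(0), strand = character(0),
                      fwd_start = integer(0))
  for (s in seq_len(L - w + 1)) {
    cands <- rbind(cands, data.frame(
      score = score1(substr(sequence, s, s + w - 1)),
      strand = "forward", fwd_start = s))
  }
  rc <- revcomp(sequence)
  for (s in seq_len(L - w + 1)) {
    cands <- rbind(cands, data.frame(
      score = score1(substr(rc, s, s + w - 1)),
      strand = "reverse", fwd_start = L - w - s + 2L))
  }
  best <- max(cands$score)
  hits <- cands[cands$score == best, , drop = FALSE]
  fwd <- hits[hits$strand == "forward", , drop = FALSE]
  pick <- if (nrow(fwd)) fwd[which.min(fwd$fwd_start), ] else
    hits[which.min(hits$fwd_start), ]
  list(score = best, strand = pick$strand, start = pick$fwd_start)
}

randomSeq <- function(n = 90, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

## A tiny labelled cohort built in memory.
makeCohort <- function(sequences, families = NULL, groups = NULL,
                       species = NULL, ids = NULL) {
  n <- length(sequences)
  PromoterCohort(
    sequences = sequences,
    info = data.frame(
      record_id = ids %||% sprintf("rec_%02d", seq_len(n)),
      species = species %||% rep("Zea mays", n),
      gene_family = families %||% rep("globulin", n),
      group = groups %||% rep("food", n)),
    provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Write a cohort-shaped FASTA + TSV pair from raw pieces (may be invalid,
## for error-path tests).
writeRawPair <- function(ids, seqs, meta, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("pair")
    dir.create(dir)
  }
  fa <- file.path(dir, "cohort.fa")
  tsv <- file.path(dir, "cohort.tsv")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fa)
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, metadata = tsv)
}
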