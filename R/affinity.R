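#' Calibration anchors for the three-step binding model
#'
#' The affinity scale is pinned by two equilibrium dissociation constants:
#' the nonspecific affinity of TBP sliding along the double helix (the
#' ceiling, default 1e-5 M) and the specific affinity of TBP for a perfect
#' recognition site (the floor, default 1e-9 M). A promoter's estimated KD
#' interpolates log-linearly between the two according to the normalized
#' recognition score of its best window.
#'
#' @param kd_nonspecific Nonspecific (sliding) KD in mol/L; default `1e-5`.
#' @param kd_specific Specific (site-bound) KD in mol/L; default `1e-9`.
#' @return A named list with components `kd_nonspecific` and `kd_specific`.
#' @export
affinityAnchors <- function(kd_nonspecific = 1e-5, kd_specific = 1e-9) {
  if (!(kd_specific > 0 && kd_specific < kd_nonspecific)) {
    stop("anchors must satisfy 0 < kd_specific < kd_nonspecific",
         call. = FALSE)
  }
  list(kd_nonspecific = kd_nonspecific, kd_specific = kd_specific)
}

#' Log-odds recognition score of one window
#'
#' Sum over positions of `log(p[base, pos] / background[base])`, the standard
#' position-weight-matrix score of a window against the matrix's background.
#' Maximal exactly when each position carries its consensus base.
#'
#' @param window A character string (or [Biostrings::DNAString]) over
#'   A/C/G/T whose length equals the matrix width.
#' @param matrix A [TataMatrix-class].
#' @return The log-odds score (natural log).
#' @seealso [normalizedSiteScore()], [estimateKd()]
#' @export
logOddsScore <- function(window, matrix) {
  codes <- .encodeWindow(window, matrix)
  lo <- .logOddsMatrix(matrix)
  .sumSeq(lo[cbind(codes, seq_along(codes))])
}

#' Normalized recognition score in [0, 1]
#'
#' The log-odds score divided by the consensus (maximal) score, clipped below
#' at zero: a perfect site scores 1, and windows at or below background
#' likelihood score 0. This is the quantity that interpolates between the
#' nonspecific and specific affinity anchors.
#'
#' @inheritParams logOddsScore
#' @return A value in `[0, 1]`.
#' @export
normalizedSiteScore <- function(window, matrix) {
  s_max <- .maxLogOdds(matrix)
  if (s_max <= 0) {
    stop("degenerate matrix: consensus log-odds score is not positive",
         call. = FALSE)
  }
  max(0, logOddsScore(window, matrix) / s_max)
}

.encodeWindow <- function(window, matrix) {
  window <- toupper(as.character(window))
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (length(chars) != matrixWidth(matrix)) {
    stop("window length must equal the matrix width (",
         matrixWidth(matrix), ")", call. = FALSE)
  }
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes)) {
    stop("window contains a base outside A/C/G/T: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "), call. = FALSE)
  }
  codes
}

## Integer-encode a DNAStringSet of equal widths as an n x L matrix
## (A=1, C=2, G=3, T=4). Errors on ambiguity codes, naming offenders.
.encodeSequences <- function(seqs) {
  m <- as.matrix(seqs)
  codes <- match(m, DNA_BASES)
  if (anyNA(codes)) {
    rows <- ((which(is.na(codes)) - 1L) %% nrow(m)) + 1L
    bad <- unique(rownames(m)[rows])
    offender <- if (length(bad)) paste(bad, collapse = ", ") else "unnamed"
    stop("sequence(s) contain ambiguous bases; run filterAmbiguous() first: ",
         offender, call. = FALSE)
  }
  dim(codes) <- dim(m)
  codes
}

## Scores of all windows of width w for each row of an integer code matrix:
## returns n x (L - w + 1). Column j of the motif contributes
## lo[code[, s + j - 1], j] to the window starting at s.
.windowScores <- function(codes, lo) {
  w <- ncol(lo)
  L <- ncol(codes)
  ns <- L - w + 1L
  n <- nrow(codes)
  S <- matrix(0, n, ns)
  for (j in seq_len(w)) {
    loj <- lo[, j]
    sub <- codes[, j:(j + ns - 1L), drop = FALSE]
    S <- S + matrix(loj[sub], n, ns)
  }
  S
}

## Best window over both strands for every row of `codes`.
## Tie rule: highest raw score; then forward strand; then smallest start in
## forward-strand coordinates. Reverse-strand windows are reported by the
## forward-strand coordinate of their leftmost base.
.bestWindows <- function(codes, matrix) {
  lo <- .logOddsMatrix(matrix)
  w <- ncol(lo)
  L <- ncol(codes)
  ns <- L - w + 1L
  n <- nrow(codes)
  Sf <- .windowScores(codes, lo)
  rc <- (5L - codes)[, L:1L, drop = FALSE]
  Sr <- .windowScores(rc, lo)
  best <- do.call(pmax, c(as.data.frame(Sf), as.data.frame(Sr)))
  start <- integer(n)
  strand <- character(n)
  for (i in seq_len(n)) {
    f <- which(Sf[i, ] == best[i])
    if (length(f)) {
      start[i] <- f[1L]
      strand[i] <- "forward"
    } else {
      r <- which(Sr[i, ] == best[i])
      ## reverse start s' maps to forward start L - w - s' + 2, which is
      ## decreasing in s': the last hit has the smallest forward start.
      start[i] <- L - w - r[length(r)] + 2L
      strand[i] <- "reverse"
    }
  }
  list(score = best, start = start, strand = strand, width = w)
}

## Map normalized scores to KD (mol/L). The anchors are pinned exactly so a
## consensus site returns kd_specific and a background-level sequence returns
## kd_nonspecific with no floating-point drift.
.kdFromScore <- function(s, anchors) {
  ln_ns <- log(anchors$kd_nonspecific)
  ln_sp <- log(anchors$kd_specific)
  kd <- exp(ln_ns + s * (ln_sp - ln_ns))
  kd[s >= 1] <- anchors$kd_specific
  kd[s <= 0] <- anchors$kd_nonspecific
  kd
}

#' Estimate TBP-promoter KD for every promoter in a cohort
#'
#' Implements the calibrated three-step binding model. For each 90 bp
#' promoter, all windows of the matrix width on the forward strand and on the
#' reverse complement are scored by position-weight-matrix log-odds; the best
#' window's normalized score `s* in [0, 1]` then sets the dissociation
#' constant by log-linear interpolation between the two anchors:
#'
#' `ln KD = ln KD_nonspecific + s* (ln KD_specific - ln KD_nonspecific)`
#'
#' so a promoter with a perfect recognition site is assigned the specific
#' affinity (1e-9 M by default), a promoter with no site above background the
#' nonspecific sliding affinity (1e-5 M), and intermediate sites fall between
#' the two. Ties between equally scoring windows are resolved toward the
#' forward strand, then the smaller start position; reverse-strand hits are
#' reported by the forward-strand coordinate of their leftmost base.
#'
#' @param cohort A [PromoterCohort-class] with a pure A/C/G/T alphabet
#'   (see [filterAmbiguous()]).
#' @param matrix A [TataMatrix-class]; default [defaultTataMatrix()].
#' @param anchors Output of [affinityAnchors()].
#' @return A [S4Vectors::DataFrame] with one row per record (in cohort
#'   order, row names = record ids) and columns `kd` (mol/L), `ln_kd`,
#'   `kd_nM` (nmol/L), `best_start` (1-based), `best_strand`
#'   (`forward`/`reverse`) and `best_score` (normalized, in `[0, 1]`).
#' @examples
#' mat <- defaultTataMatrix()
#' co <- PromoterCohort(
#'   sequences = paste0(strrep("G", 40), consensusWindow(mat), strrep("G", 35)),
#'   info = data.frame(record_id = "perfect", species = "Zea mays",
#'                     gene_family = "globulin", group = "food")
#' )
#' estimateAffinity(co, mat)  # kd = 1e-9 M
#' @export
estimateAffinity <- function(cohort, matrix = defaultTataMatrix(),
                             anchors = affinityAnchors()) {
  stopifnot(is(cohort, "PromoterCohort"), is(matrix, "TataMatrix"))
  s_max <- .maxLogOdds(matrix)
  if (s_max <= 0) {
    stop("degenerate matrix: consensus log-odds score is not positive",
         call. = FALSE)
  }
  if (!length(cohort)) {
    out <- S4Vectors::DataFrame(kd = numeric(0), ln_kd = numeric(0),
                                kd_nM = numeric(0), best_start = integer(0),
                                best_strand = character(0),
                                best_score = numeric(0))
    return(out)
  }
  codes <- .encodeSequences(promoterSequences(cohort))
  hit <- .bestWindows(codes, matrix)
  s_star <- pmax(0, hit$score / s_max)
  kd <- .kdFromScore(s_star, anchors)
  out <- S4Vectors::DataFrame(
    kd = kd,
    ln_kd = log(kd),
    kd_nM = kd * 1e9,
    best_start = hit$start,
    best_strand = hit$strand,
    best_score = s_star
  )
  rownames(out) <- recordIds(cohort)
  out
}

#' Estimate KD for a single 90 bp promoter sequence
#'
#' Convenience wrapper around [estimateAffinity()] for one sequence.
#'
#' @param sequence A 90 bp character string or [Biostrings::DNAString] over
#'   A/C/G/T.
#' @inheritParams estimateAffinity
#' @return A one-row [S4Vectors::DataFrame]; see [estimateAffinity()] for
#'   the columns.
#' @export
estimateKd <- function(sequence, matrix = defaultTataMatrix(),
                       anchors = affinityAnchors()) {
  sequence <- .asDNAStringSet(as.character(sequence))
  if (length(sequence) != 1L ||
      Biostrings::width(sequence) != PROMOTER_WIDTH) {
    stop("sequence must be a single ", PROMOTER_WIDTH, " bp promoter",
         call. = FALSE)
  }
  names(sequence) <- "query"
  co <- new("PromoterCohort", sequences = sequence,
            info = S4Vectors::DataFrame(record_id = "query",
                                        species = "unknown",
                                        gene_family = GENE_FAMILIES[1L],
                                        group = PLANT_GROUPS[1L]),
            provenance = "single-sequence query")
  estimateAffinity(co, matrix, anchors)
}
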