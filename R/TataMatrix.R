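#' Construct a TataMatrix from a probability or count matrix
#'
#' @param probs Numeric matrix with 4 rows (A, C, G, T order; row names are
#'   set if absent) and at least 6 columns. Columns that already sum to 1 and
#'   contain no zero are taken as probabilities; otherwise the column is
#'   treated as counts and normalized as `(x + pseudocount) / (sum(x) + 4 *
#'   pseudocount)`, which also resolves all-zero columns to uniform 0.25.
#' @param background Background nucleotide probabilities (A, C, G, T);
#'   uniform by default.
#' @param pseudocount Positive pseudocount for count input; default 0.25.
#' @return A [TataMatrix-class].
#' @export
tataMatrix <- function(probs, background = rep(0.25, 4), pseudocount = 0.25) {
  if (!is.matrix(probs) || !is.numeric(probs) || nrow(probs) != 4L) {
    stop("probs must be a numeric matrix with 4 rows (A, C, G, T)",
         call. = FALSE)
  }
  if (anyNA(probs)) stop("matrix contains non-numeric or missing cells",
                         call. = FALSE)
  if (any(probs < 0)) stop("matrix entries must be non-negative", call. = FALSE)
  if (ncol(probs) < 6L) stop("matrix width must be at least 6", call. = FALSE)
  rownames(probs) <- DNA_BASES
  norm <- apply(probs, 2L, function(col) {
    if (abs(sum(col) - 1) <= 1e-6 && all(col > 0)) {
      col / sum(col)  # already a positive probability column
    } else {
      (col + pseudocount) / (sum(col) + 4 * pseudocount)
    }
  })
  rownames(norm) <- DNA_BASES
  colnames(norm) <- NULL
  new("TataMatrix", probs = norm, background = background / sum(background),
      pseudocount = pseudocount)
}

#' Load a TataMatrix from a plain-text file
#'
#' The format is four labelled rows (`A`, `C`, `G`, `T`, any order) of
#' whitespace-separated numbers, one column per motif position; `#` starts a
#' comment. Both count and probability matrices are accepted; see
#' [tataMatrix()] for the normalization rule.
#'
#' @param path Path to the matrix file.
#' @inheritParams tataMatrix
#' @return A [TataMatrix-class].
#' @examples
#' m <- loadTataMatrix(system.file("extdata", "tata_pfm.txt",
#'                                 package = "tbpAffinity"))
#' m
#' @export
loadTataMatrix <- function(path, background = rep(0.25, 4),
                           pseudocount = 0.25) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 4L) {
    stop("matrix file must have exactly 4 data rows (A, C, G, T); found ",
         length(lines), call. = FALSE)
  }
  toks <- strsplit(lines, "[ \t]+")
  labels <- toupper(vapply(toks, `[`, character(1), 1L))
  if (!setequal(labels, DNA_BASES) || anyDuplicated(labels)) {
    stop("matrix rows must be labelled A, C, G, T", call. = FALSE)
  }
  vals <- lapply(toks, function(t) suppressWarnings(as.numeric(t[-1L])))
  widths <- lengths(vals)
  if (length(unique(widths)) != 1L) {
    stop("matrix rows have unequal numbers of columns", call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (anyNA(m)) stop("matrix file contains a non-numeric cell", call. = FALSE)
  rownames(m) <- labels
  tataMatrix(m[DNA_BASES, , drop = FALSE], background = background,
             pseudocount = pseudocount)
}

#' The package's default TATA-box matrix
#'
#' A 15-column position probability matrix built around the canonical
#' TATAWAWR core (consensus base 0.85, off-consensus 0.05; W positions split
#' A/T at 0.45; the R position splits A/G at 0.45), flanked by near-uniform
#' columns (A at 0.28, others 0.24) so that flanking context contributes only
#' weakly to the score. Shipped as `inst/extdata/tata_pfm.txt` and swappable
#' via [loadTataMatrix()].
#'
#' @inheritParams tataMatrix
#' @return A [TataMatrix-class].
#' @export
defaultTataMatrix <- function(background = rep(0.25, 4), pseudocount = 0.25) {
  loadTataMatrix(system.file("extdata", "tata_pfm.txt",
                             package = "tbpAffinity", mustWork = TRUE),
                 background = background, pseudocount = pseudocount)
}

#' @rdname TataMatrix-class
#' @export
setMethod("matrixWidth", "TataMatrix", function(x) ncol(x@probs))

#' @rdname TataMatrix-class
#' @export
setMethod("matrixProbs", "TataMatrix", function(x) x@probs)

#' @rdname TataMatrix-class
#' @export
setMethod("matrixBackground", "TataMatrix", function(x) x@background)

#' @describeIn TataMatrix-class The window maximizing the log-odds score:
#'   at each position, the base with the largest `log(p/background)` (ties
#'   broken toward the alphabetically first base).
#' @export
setMethod("consensusWindow", "TataMatrix", function(x) {
  lo <- log(x@probs / x@background)
  paste(DNA_BASES[apply(lo, 2L, which.max)], collapse = "")
})

setMethod("show", "TataMatrix", function(object) {
  cat(sprintf("TataMatrix of width %d (consensus %s)\n",
              matrixWidth(object), consensusWindow(object)))
  cat("  background:", paste(sprintf("%s=%.3g", DNA_BASES,
                                     object@background), collapse = " "), "\n")
  cat(sprintf("  max log-odds score: %.4f\n", .maxLogOdds(object)))
})

## Per-position log-odds matrix, 4 x width.
.logOddsMatrix <- function(matrix) {
  log(matrix@probs / matrix@background)
}

## Plain sequential double accumulation. base::sum() may accumulate in
## extended precision; window scores in the scanner are built by repeated
## double additions, and the consensus score must match them bit-for-bit so
## that a perfect site normalizes to exactly 1.
.sumSeq <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v
  acc
}

## Maximum attainable log-odds score (the consensus window's score).
.maxLogOdds <- function(matrix) {
  .sumSeq(apply(.logOddsMatrix(matrix), 2L, max))
}
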