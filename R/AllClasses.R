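#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

## Closed vocabularies used throughout the package.
GENE_FAMILIES <- c("albumin", "beta_amylase", "globulin")
PLANT_GROUPS <- c("food", "non_food")
DNA_BASES <- c("A", "C", "G", "T")

#' PromoterCohort: a set of labelled 90 bp proximal promoter sequences
#'
#' A `PromoterCohort` bundles a [Biostrings::DNAStringSet] of fixed-width
#' (90 bp) proximal promoter sequences with per-record metadata: the species
#' the promoter comes from, the gene family it drives (`albumin`,
#' `beta_amylase` or `globulin`) and the plant group (`food` or `non_food`).
#' Record order is preserved exactly as read or generated, and record
#' identifiers are unique within a cohort.
#'
#' Sequences are stored 5'->3' on the annotated strand with position 90
#' adjacent to the transcription start site; coordinates are 1-based and
#' inclusive. Sequences may contain IUPAC ambiguity codes until
#' [filterAmbiguous()] is applied; all affinity estimation requires a pure
#' A/C/G/T alphabet.
#'
#' @slot sequences A [Biostrings::DNAStringSet], all of width 90, named by
#'   record id.
#' @slot info A [S4Vectors::DataFrame] with columns `record_id`, `species`,
#'   `gene_family`, `group`, parallel to `sequences`.
#' @slot provenance Free-text label describing where the cohort came from.
#'
#' @seealso [readPromoterCohort()], [generateCohort()], [filterAmbiguous()],
#'   [partitionCohort()]
#' @exportClass PromoterCohort
setClass("PromoterCohort",
  representation(
    sequences = "DNAStringSet",
    info = "DataFrame",
    provenance = "character"
  )
)

setValidity("PromoterCohort", function(object) {
  msgs <- character(0)
  info <- object@info
  needed <- c("record_id", "species", "gene_family", "group")
  if (!all(needed %in% colnames(info))) {
    return(paste("info must have columns", paste(needed, collapse = ", ")))
  }
  n <- length(object@sequences)
  if (nrow(info) != n) {
    msgs <- c(msgs, "sequences and info must have the same length")
  } else {
    if (anyDuplicated(info$record_id)) {
      msgs <- c(msgs, sprintf(
        "duplicated record_id: %s",
        paste(unique(info$record_id[duplicated(info$record_id)]), collapse = ", ")
      ))
    }
    if (!identical(as.character(names(object@sequences)),
                   as.character(info$record_id))) {
      msgs <- c(msgs, "sequence names must equal info$record_id, in order")
    }
    bad_len <- which(Biostrings::width(object@sequences) != PROMOTER_WIDTH)
    if (length(bad_len)) {
      msgs <- c(msgs, sprintf(
        "sequence length must be %d bp; offending record(s): %s",
        PROMOTER_WIDTH, paste(info$record_id[bad_len], collapse = ", ")
      ))
    }
    bad_fam <- !(info$gene_family %in% GENE_FAMILIES)
    if (any(bad_fam)) {
      msgs <- c(msgs, sprintf(
        "unknown gene_family token(s): %s (allowed: %s)",
        paste(unique(info$gene_family[bad_fam]), collapse = ", "),
        paste(GENE_FAMILIES, collapse = ", ")
      ))
    }
    bad_grp <- !(info$group %in% PLANT_GROUPS)
    if (any(bad_grp)) {
      msgs <- c(msgs, sprintf(
        "unknown group token(s): %s (allowed: %s)",
        paste(unique(info$group[bad_grp]), collapse = ", "),
        paste(PLANT_GROUPS, collapse = ", ")
      ))
    }
  }
  if (length(object@provenance) != 1L) {
    msgs <- c(msgs, "provenance must be a single string")
  }
  if (length(msgs)) msgs else TRUE
})

## Fixed promoter width: the model operates on 90 bp proximal promoters.
PROMOTER_WIDTH <- 90L

#' TataMatrix: position probability matrix for the TBP recognition element
#'
#' Per-position nucleotide probabilities for the TATA-box recognition step of
#' the binding model, together with the background distribution against which
#' log-odds scores are computed. Probabilities are strictly positive at every
#' position (a pseudocount is applied on load where needed) and each column
#' sums to one.
#'
#' @slot probs Numeric matrix, 4 rows (A, C, G, T) by `width` columns;
#'   every column sums to 1 and all entries are strictly positive.
#' @slot background Numeric vector of 4 background probabilities (A, C, G, T),
#'   summing to 1; uniform 0.25 by default.
#' @slot pseudocount The pseudocount used when normalizing count input.
#'
#' @seealso [tataMatrix()], [loadTataMatrix()], [defaultTataMatrix()],
#'   [logOddsScore()]
#' @exportClass TataMatrix
setClass("TataMatrix",
  representation(
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("TataMatrix", function(object) {
  p <- object@probs
  msgs <- character(0)
  if (!is.numeric(p) || nrow(p) != 4L) {
    return("probs must be a numeric matrix with 4 rows (A, C, G, T)")
  }
  if (!identical(rownames(p), DNA_BASES)) {
    msgs <- c(msgs, "probs rows must be named A, C, G, T in that order")
  }
  if (ncol(p) < 6L) {
    msgs <- c(msgs, "matrix width must be at least 6")
  }
  if (any(p <= 0)) {
    msgs <- c(msgs, "all probabilities must be strictly positive")
  }
  if (any(abs(colSums(p) - 1) > 1e-9)) {
    msgs <- c(msgs, "each position's probabilities must sum to 1 (tol 1e-9)")
  }
  bg <- object@background
  if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-9) {
    msgs <- c(msgs, "background must be 4 positive probabilities summing to 1")
  }
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0) {
    msgs <- c(msgs, "pseudocount must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' GroupSummary: N, mean and SEM of KD for a promoter set
#'
#' Aggregates per-promoter dissociation-constant estimates for one labelled
#' set of promoters: `n` promoters, arithmetic mean `m0` and standard error
#' of the mean `sem`, both in nmol/L.
#'
#' @slot label Set label (e.g. a group or species name).
#' @slot n Number of promoters summarized.
#' @slot m0 Arithmetic mean KD, nmol/L.
#' @slot sem Standard error of the mean (sample SD / sqrt(n)), nmol/L.
#'
#' @seealso [summarizeKd()], [fisherZTest()]
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(
    label = "character",
    n = "integer",
    m0 = "numeric",
    sem = "numeric"
  )
)

setValidity("GroupSummary", function(object) {
  msgs <- character(0)
  if (length(object@n) != 1L || object@n < 1L) {
    msgs <- c(msgs, "n must be a single count >= 1")
  }
  if (length(object@sem) != 1L || object@sem < 0) {
    msgs <- c(msgs, "sem must be a single value >= 0")
  }
  if (length(object@m0) != 1L || !is.finite(object@m0)) {
    msgs <- c(msgs, "m0 must be a single finite number")
  }
  if (length(msgs)) msgs else TRUE
})

#' ZTestResult: difference-of-means Z-test between two group summaries
#'
#' The Z statistic `|m1 - m2| / sqrt(sem1^2 + sem2^2)` referred to the
#' standard normal distribution, its two-sided p-value, the highest
#' conventional significance level attained, and the sign of the first
#' group's mean minus the second's (the direction, carried separately from
#' the absolute Z).
#'
#' @slot z Absolute Z statistic (may be `Inf` when both SEMs are zero but the
#'   means differ).
#' @slot p_two_sided Two-sided p-value, `2 * (1 - pnorm(|z|))`.
#' @slot significant_at Highest level attained: one of `"none"`, `"0.05"`,
#'   `"0.01"`, `"0.001"`.
#' @slot direction Sign of `m0(a) - m0(b)`: -1, 0 or 1.
#'
#' @seealso [fisherZTest()]
#' @exportClass ZTestResult
setClass("ZTestResult",
  representation(
    z = "numeric",
    p_two_sided = "numeric",
    significant_at = "character",
    direction = "numeric"
  )
)

setValidity("ZTestResult", function(object) {
  msgs <- character(0)
  z <- object@z
  p <- object@p_two_sided
  if (length(z) != 1L || is.na(z) || z < 0) {
    msgs <- c(msgs, "z must be a single non-negative value")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    msgs <- c(msgs, "p_two_sided must be in [0, 1]")
  }
  expected <- if (is.finite(z)) 2 * stats::pnorm(abs(z), lower.tail = FALSE) else 0
  if (length(z) == 1L && length(p) == 1L && is.finite(p) &&
      abs(p - expected) > 1e-9) {
    msgs <- c(msgs, "p_two_sided must equal 2*(1 - pnorm(|z|)) within 1e-9")
  }
  if (!object@significant_at %in% c("none", "0.05", "0.01", "0.001")) {
    msgs <- c(msgs, "significant_at must be one of none, 0.05, 0.01, 0.001")
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: parameters of the synthetic promoter-cohort generator
#'
#' Describes a two-group synthetic cohort of 90 bp promoters: how many
#' promoters per group, how many species labels per group, which gene
#' families to cycle through, the background base composition, and the
#' distribution of planted TATA-site strengths (normalized recognition
#' scores in \[0, 1\]) in each group.
#'
#' Defaults encode the reference simulation conditions used throughout the
#' package's validation: 50 promoters per group, planted strength 0.8 (food)
#' versus 0.4 (non-food) with SD 0.1, 40% GC background.
#'
#' @slot n_food,n_nonfood Promoter counts per group.
#' @slot species_per_group Number of species labels per group; records are
#'   divided among species as evenly as possible (round-robin).
#' @slot families Character vector, subset of
#'   `c("albumin", "beta_amylase", "globulin")`, assigned round-robin.
#' @slot gc_background Fraction of G+C in the i.i.d. background, in (0, 1).
#' @slot strength_mean_food,strength_mean_nonfood Target mean normalized site
#'   score of the planted TATA element per group, in \[0, 1\].
#' @slot strength_sd SD of the (truncated-normal) strength distribution.
#' @slot seed Integer seed; identical spec + seed reproduce the cohort
#'   byte-identically.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    n_food = "integer",
    n_nonfood = "integer",
    species_per_group = "integer",
    families = "character",
    gc_background = "numeric",
    strength_mean_food = "numeric",
    strength_mean_nonfood = "numeric",
    strength_sd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  if (object@n_food < 1L || object@n_nonfood < 1L) {
    msgs <- c(msgs, "group sizes must be positive")
  }
  if (object@species_per_group < 1L) {
    msgs <- c(msgs, "species_per_group must be positive")
  }
  if (!length(object@families) || !all(object@families %in% GENE_FAMILIES)) {
    msgs <- c(msgs, sprintf(
      "families must be a nonempty subset of {%s}",
      paste(GENE_FAMILIES, collapse = ", ")
    ))
  }
  if (object@gc_background <= 0 || object@gc_background >= 1) {
    msgs <- c(msgs, "gc_background must lie in (0, 1)")
  }
  for (s in c(object@strength_mean_food, object@strength_mean_nonfood)) {
    if (s < 0 || s > 1) msgs <- c(msgs, "strength means must lie in [0, 1]")
  }
  if (object@strength_sd < 0) {
    msgs <- c(msgs, "strength_sd must be non-negative")
  }
  if (length(msgs)) unique(msgs) else TRUE
})
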