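#' Summarize KD values for one promoter set
#'
#' Arithmetic mean and standard error of the mean (sample standard deviation
#' with the n-1 denominator, divided by sqrt(n)) of per-promoter KD values,
#' conventionally in nmol/L. A single-value set is summarized with SEM 0 and
#' a warning, since no dispersion can be estimated.
#'
#' @param values Non-empty numeric vector of positive KD values (nmol/L).
#' @param label Label for the summarized set.
#' @return A [GroupSummary-class].
#' @examples
#' summarizeKd(c(1, 2, 3), "demo")  # m0 = 2, sem = 1/sqrt(3)
#' @export
summarizeKd <- function(values, label = "unlabelled") {
  if (!length(values)) stop("cannot summarize an empty set", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("KD values must be positive and finite", call. = FALSE)
  }
  n <- length(values)
  sem <- if (n == 1L) {
    warning("single-promoter set '", label, "': SEM set to 0", call. = FALSE)
    0
  } else {
    stats::sd(values) / sqrt(n)
  }
  new("GroupSummary", label = as.character(label), n = as.integer(n),
      m0 = mean(values), sem = sem)
}

#' @rdname GroupSummary-class
#' @param object A `GroupSummary`.
#' @export
setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary '%s': N = %d, M0 = %.4g, SEM = %.4g\n",
              object@label, object@n, object@m0, object@sem))
})

#' Difference-of-means Z-test between two group summaries
#'
#' Computes `Z = |M1 - M2| / sqrt(SEM1^2 + SEM2^2)` and refers it to the
#' standard normal distribution (two-sided). This is the large-sample
#' difference-of-means form of the Z-test used to compare mean TBP-promoter
#' affinities between promoter groups; the direction of the difference is
#' carried as a separate sign, so Z itself is always non-negative.
#'
#' When both SEMs are zero the statistic is undefined: equal means raise an
#' error, and different means return `z = Inf`, `p = 0` with a warning.
#'
#' @param a,b [GroupSummary-class] objects (order only affects `direction`).
#' @return A [ZTestResult-class].
#' @examples
#' food <- new("GroupSummary", label = "food", n = 74L, m0 = 2.97, sem = 0.21)
#' nonf <- new("GroupSummary", label = "non_food", n = 53L, m0 = 2.15,
#'             sem = 0.08)
#' fisherZTest(food, nonf)
#' @export
fisherZTest <- function(a, b) {
  stopifnot(is(a, "GroupSummary"), is(b, "GroupSummary"))
  diff <- a@m0 - b@m0
  denom <- sqrt(a@sem^2 + b@sem^2)
  if (denom == 0) {
    if (diff == 0) {
      stop("Z statistic undefined: both SEMs are zero and the means are equal",
           call. = FALSE)
    }
    warning("both SEMs are zero with unequal means: reporting z = Inf, p = 0",
            call. = FALSE)
    z <- Inf
    p <- 0
  } else {
    z <- abs(diff) / denom
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  }
  new("ZTestResult", z = z, p_two_sided = p,
      significant_at = .significanceLevel(p),
      direction = sign(diff))
}

.significanceLevel <- function(p) {
  if (p < 0.001) "0.001" else if (p < 0.01) "0.01" else if (p < 0.05) "0.05" else "none"
}

## Star codes mirroring the conventional ladder.
.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @rdname ZTestResult-class
#' @param object A `ZTestResult`.
#' @export
setMethod("show", "ZTestResult", function(object) {
  cat(sprintf("Z-test: Z = %.2f, p = %.3g %s (direction %+d)\n",
              object@z, object@p_two_sided, .stars(object@p_two_sided),
              object@direction))
})

#' Per-family report of group summaries and Z-tests
#'
#' For each gene family in the cohort, builds per-species summaries (within
#' group), overall food and non-food group summaries, and one Z-test
#' comparing the two groups. Group-level summaries pool over promoters by
#' default, so their N is the promoter count; set `species_weighted = TRUE`
#' to average species means instead. A family observed in only one group is
#' reported with its test marked not computable rather than raising an
#' error. With `bonferroni = TRUE`, p-values are multiplied by the number of
#' families tested (capped at 1) before star assignment.
#'
#' @param estimates The [S4Vectors::DataFrame] returned by
#'   [estimateAffinity()] for `cohort` (every record must have a row).
#' @param cohort The scored [PromoterCohort-class].
#' @param species_weighted Compute group means over species means instead of
#'   pooled promoters (default `FALSE`).
#' @param bonferroni Apply a Bonferroni correction across families
#'   (default `FALSE`).
#' @return A list with two data.frames: `summaries` (columns `family`,
#'   `group`, `species`, `n`, `m0_nM`, `sem_nM`; species rows carry the
#'   species name, group rows carry `species = "(all)"`) and `tests`
#'   (columns `family`, `z`, `p`, `stars`, `direction`, `computable`). Row
#'   order is deterministic: family, then group, then species
#'   alphabetically.
#' @export
buildFamilyReport <- function(estimates, cohort, species_weighted = FALSE,
                              bonferroni = FALSE) {
  stopifnot(is(cohort, "PromoterCohort"))
  ids <- recordIds(cohort)
  if (!all(ids %in% rownames(estimates))) {
    stop("every cohort record needs an affinity estimate", call. = FALSE)
  }
  kd_nM <- estimates[ids, "kd_nM"]
  info <- as.data.frame(cohortInfo(cohort))
  fams <- sort(unique(info$gene_family))
  sum_rows <- list()
  test_rows <- list()
  for (fam in fams) {
    fam_idx <- info$gene_family == fam
    group_sums <- list()
    for (grp in PLANT_GROUPS) {
      sel <- fam_idx & info$group == grp
      if (!any(sel)) next
      for (sp in sort(unique(info$species[sel]))) {
        sp_sel <- sel & info$species == sp
        gs <- suppressWarnings(summarizeKd(kd_nM[sp_sel], sp))
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          family = fam, group = grp, species = sp, n = gs@n,
          m0_nM = gs@m0, sem_nM = gs@sem)
      }
      gs <- if (species_weighted) {
        sp_means <- tapply(kd_nM[sel], info$species[sel], mean)
        suppressWarnings(summarizeKd(as.numeric(sp_means), grp))
      } else {
        suppressWarnings(summarizeKd(kd_nM[sel], grp))
      }
      group_sums[[grp]] <- gs
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        family = fam, group = grp, species = "(all)", n = gs@n,
        m0_nM = gs@m0, sem_nM = gs@sem)
    }
    if (length(group_sums) == 2L) {
      zt <- fisherZTest(group_sums$food, group_sums$non_food)
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        family = fam, z = zt@z, p = zt@p_two_sided,
        stars = .stars(zt@p_two_sided), direction = zt@direction,
        computable = TRUE)
    } else {
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        family = fam, z = NA_real_, p = NA_real_, stars = "",
        direction = NA_real_, computable = FALSE)
    }
  }
  summaries <- if (length(sum_rows)) do.call(rbind, sum_rows) else
    data.frame(family = character(0), group = character(0),
               species = character(0), n = integer(0), m0_nM = numeric(0),
               sem_nM = numeric(0))
  tests <- do.call(rbind, c(test_rows, list(
    data.frame(family = character(0), z = numeric(0), p = numeric(0),
               stars = character(0), direction = numeric(0),
               computable = logical(0)))))
  if (bonferroni && any(tests$computable)) {
    k <- sum(tests$computable)
    tests$p <- pmin(1, tests$p * k)
    tests$stars <- ifelse(tests$computable, .stars(tests$p), "")
  }
  rownames(summaries) <- NULL
  rownames(tests) <- NULL
  list(summaries = summaries, tests = tests)
}
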