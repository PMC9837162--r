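#' Specify a synthetic two-group promoter cohort
#'
#' Constructor for [CohortSpec-class]. The defaults are the package's
#' reference simulation conditions: 50 promoters per group divided among 5
#' species labels, all three gene families cycled round-robin, a 40% GC
#' i.i.d. background, and planted TATA-site strengths drawn from a truncated
#' normal with mean 0.8 (food) versus 0.4 (non-food) and SD 0.1.
#'
#' @param n_food,n_nonfood Promoters per group.
#' @param species_per_group Species labels per group (records assigned
#'   round-robin, hence as evenly as possible).
#' @param families Gene families to cycle through.
#' @param gc_background G+C fraction of the background, in (0, 1).
#' @param strength_mean_food,strength_mean_nonfood Target mean normalized
#'   site score per group, in \[0, 1\].
#' @param strength_sd SD of the strength distribution (0 = deterministic).
#' @param seed Integer seed for the generator.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(n_food = 50L, n_nonfood = 50L, species_per_group = 5L,
                       families = c("albumin", "beta_amylase", "globulin"),
                       gc_background = 0.40, strength_mean_food = 0.8,
                       strength_mean_nonfood = 0.4, strength_sd = 0.1,
                       seed = 1L) {
  new("CohortSpec",
      n_food = as.integer(n_food), n_nonfood = as.integer(n_nonfood),
      species_per_group = as.integer(species_per_group),
      families = as.character(families),
      gc_background = as.numeric(gc_background),
      strength_mean_food = as.numeric(strength_mean_food),
      strength_mean_nonfood = as.numeric(strength_mean_nonfood),
      strength_sd = as.numeric(strength_sd), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0(
    "CohortSpec: food n=%d @ strength %.2f, non-food n=%d @ %.2f (sd %.2f)\n",
    "  %d species/group, families {%s}, GC %.2f, seed %d\n"),
    object@n_food, object@strength_mean_food, object@n_nonfood,
    object@strength_mean_nonfood, object@strength_sd,
    object@species_per_group, paste(object@families, collapse = ", "),
    object@gc_background, object@seed))
})

## One draw from normal(mean, sd) truncated to [0, 1] (rejection sampling;
## sd = 0 collapses to the clamped mean).
.rStrength <- function(mean, sd) {
  if (sd == 0) return(min(1, max(0, mean)))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

#' Degrade a consensus window to a target normalized score
#'
#' Starting from the matrix's consensus window, repeatedly applies the
#' single base substitution whose resulting normalized score is closest to
#' `target`, stopping as soon as no substitution improves on the current
#' score's distance to the target. Because scores live on a discrete
#' lattice of substitution effects, the achieved score lands within one
#' substitution step of the target rather than exactly on it. Ties between
#' equally good substitutions are broken uniformly at random using R's
#' global random number generator.
#'
#' @param target Target normalized site score in \[0, 1\].
#' @param matrix A [TataMatrix-class].
#' @param window Starting window; defaults to [consensusWindow()].
#' @return A character window whose [normalizedSiteScore()] is as close to
#'   `target` as single substitutions allow.
#' @export
degradeToScore <- function(target, matrix, window = consensusWindow(matrix)) {
  if (!is.numeric(target) || target < 0 || target > 1) {
    stop("target must lie in [0, 1]", call. = FALSE)
  }
  lo <- .logOddsMatrix(matrix)
  s_max <- .maxLogOdds(matrix)
  if (s_max <= 0) {
    stop("degenerate matrix: consensus log-odds score is not positive",
         call. = FALSE)
  }
  codes <- .encodeWindow(window, matrix)
  w <- length(codes)
  s <- .sumSeq(lo[cbind(codes, seq_len(w))]) / s_max
  repeat {
    cur <- lo[cbind(codes, seq_len(w))]
    ## new normalized score after setting position j to base b
    news <- sweep(lo, 2L, cur, "-") / s_max + s
    news[cbind(codes, seq_len(w))] <- NA  # exclude no-op substitutions
    err <- abs(news - target)
    best <- min(err, na.rm = TRUE)
    if (best >= abs(s - target) - 1e-15) break
    cand <- which(!is.na(err) & err <= best + 1e-15)
    pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
    b <- ((pick - 1L) %% 4L) + 1L
    j <- ((pick - 1L) %/% 4L) + 1L
    codes[j] <- b
    s <- news[b, j]
  }
  paste(DNA_BASES[codes], collapse = "")
}

#' Generate a synthetic promoter cohort
#'
#' Emits a [PromoterCohort-class] with the statistical structure the
#' affinity analysis assumes: each 90 bp record is an i.i.d. background
#' sequence at the spec's GC fraction carrying exactly one planted TATA-like
#' site. The site is the consensus window degraded to a strength drawn from
#' the group's truncated-normal distribution, and is placed at a start drawn
#' uniformly so that the site lies within positions 21..70 of the 90-mer
#' (the region -70..-20 relative to the transcription start site at the
#' 3' end). Species and gene-family labels are assigned round-robin within
#' each group. Identical spec + seed reproduce the cohort byte-identically;
#' the generator uses the Mersenne-Twister RNG seeded from `spec@seed` and
#' restores the caller's RNG state on exit.
#'
#' @param spec A [CohortSpec-class].
#' @param matrix A [TataMatrix-class] defining the planted site.
#' @return A [PromoterCohort-class] with food records first.
#' @examples
#' co <- generateCohort(cohortSpec(n_food = 5, n_nonfood = 5, seed = 7))
#' co
#' @export
generateCohort <- function(spec, matrix = defaultTataMatrix()) {
  validObject(spec)
  stopifnot(is(matrix, "TataMatrix"))
  w <- matrixWidth(matrix)
  max_start <- 70L - w + 1L
  if (max_start < 21L) {
    stop("matrix width ", w, " exceeds the permitted site region ",
         "(site must fit within positions 21..70)", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec@seed, kind = "Mersenne-Twister")

  gc <- spec@gc_background
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  fams <- spec@families
  groups <- list(
    food = list(n = spec@n_food, mean = spec@strength_mean_food),
    non_food = list(n = spec@n_nonfood, mean = spec@strength_mean_nonfood)
  )
  seqs <- character(spec@n_food + spec@n_nonfood)
  info <- list()
  k <- 0L
  for (grp in names(groups)) {
    g <- groups[[grp]]
    rec_id <- sprintf("%s_%04d", grp, seq_len(g$n))
    species <- sprintf("%s_species_%02d",
                       grp, ((seq_len(g$n) - 1L) %% spec@species_per_group) + 1L)
    family <- fams[((seq_len(g$n) - 1L) %% length(fams)) + 1L]
    for (i in seq_len(g$n)) {
      target <- .rStrength(g$mean, spec@strength_sd)
      site <- strsplit(degradeToScore(target, matrix), "", fixed = TRUE)[[1L]]
      start <- if (max_start > 21L) sample(21:max_start, 1L) else 21L
      chars <- sample(DNA_BASES, PROMOTER_WIDTH, replace = TRUE,
                      prob = base_probs)
      chars[start:(start + w - 1L)] <- site
      seqs[k + i] <- paste(chars, collapse = "")
    }
    info[[grp]] <- data.frame(record_id = rec_id, species = species,
                              gene_family = family, group = grp,
                              stringsAsFactors = FALSE)
    k <- k + g$n
  }
  PromoterCohort(
    sequences = seqs,
    info = do.call(rbind, info),
    provenance = sprintf(
      paste0("synthetic cohort (Mersenne-Twister seed %d; ",
             "food n=%d @ %.3f, non_food n=%d @ %.3f, sd %.3f, GC %.2f)"),
      spec@seed, spec@n_food, spec@strength_mean_food, spec@n_nonfood,
      spec@strength_mean_nonfood, spec@strength_sd, gc)
  )
}
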