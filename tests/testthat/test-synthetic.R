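test_that("identical spec and seed reproduce the cohort byte-for-byte", {
  mat <- defaultTataMatrix()
  sp <- cohortSpec(n_food = 15, n_nonfood = 10, seed = 123)
  co1 <- generateCohort(sp, mat)
  co2 <- generateCohort(sp, mat)
  expect_identical(as.character(promoterSequences(co1)),
                   as.character(promoterSequences(co2)))
  expect_identical(as.data.frame(cohortInfo(co1)),
                   as.data.frame(cohortInfo(co2)))
  # written FASTA bytes identical too
  f1 <- tempfile(); f2 <- tempfile(); t1 <- tempfile(); t2 <- tempfile()
  writePromoterCohort(co1, f1, t1)
  writePromoterCohort(co2, f2, t2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed gives different sequences
  co3 <- generateCohort(cohortSpec(n_food = 15, n_nonfood = 10, seed = 124),
                        mat)
  expect_false(identical(as.character(promoterSequences(co1)),
                         as.character(promoterSequences(co3))))
  # the caller's RNG state is untouched
  set.seed(77); before <- .Random.seed
  generateCohort(sp, mat)
  expect_identical(.Random.seed, before)
})

test_that("cohort structure follows the spec: labels, counts, placement", {
  mat <- defaultTataMatrix()
  sp <- cohortSpec(n_food = 11, n_nonfood = 7, species_per_group = 3,
                   families = c("albumin", "globulin"), seed = 5)
  co <- generateCohort(sp, mat)
  info <- as.data.frame(cohortInfo(co))
  expect_identical(sum(info$group == "food"), 11L)
  expect_identical(sum(info$group == "non_food"), 7L)
  expect_identical(sort(unique(info$gene_family)), c("albumin", "globulin"))
  # round-robin species assignment is as even as possible
  tab <- table(info$species[info$group == "food"])
  expect_lte(max(tab) - min(tab), 1)
  # with consensus-strength planting the best window is the planted site,
  # and it always lies within positions 21..70 (starts 21..56 for width 15)
  sp_cons <- cohortSpec(n_food = 40, n_nonfood = 40, strength_mean_food = 1,
                        strength_mean_nonfood = 1, strength_sd = 0, seed = 6)
  est <- estimateAffinity(generateCohort(sp_cons, mat), mat)
  expect_true(all(est$best_score == 1))
  expect_true(all(est$best_start >= 21 & est$best_start <= 56))
  expect_gt(length(unique(est$best_start)), 5)  # placement actually varies

  # a matrix too wide for the 21..70 site region is a spec error
  wide <- tataMatrix(matrix(c(0.85, 0.05, 0.05, 0.05), 4, 51))
  expect_error(generateCohort(sp, wide), "21\\.\\.70")
})

test_that("degradeToScore lands within one substitution step of the target", {
  mat <- defaultTataMatrix()
  expect_identical(degradeToScore(1.0, mat), consensusWindow(mat))
  # the largest single-substitution effect bounds the achievable error
  lo <- log(matrixProbs(mat) / matrixBackground(mat))
  s_max <- sum(apply(lo, 2, max))
  step <- max(apply(lo, 2, function(col) max(col) - min(col))) / s_max
  set.seed(601)
  targets <- runif(60)
  for (tg in targets) {
    win <- degradeToScore(tg, mat)
    expect_lte(abs(normalizedSiteScore(win, mat) - tg), step)
  }
  expect_lte(normalizedSiteScore(degradeToScore(0, mat), mat), step)
})

test_that("planted strengths calibrate the KD distribution", {
  mat <- defaultTataMatrix()
  # zero-variance strength 1.0 plants consensus sites: KD pinned exactly
  sp1 <- cohortSpec(n_food = 6, n_nonfood = 6, strength_mean_food = 1,
                    strength_mean_nonfood = 1, strength_sd = 0, seed = 9)
  est1 <- estimateAffinity(generateCohort(sp1, mat), mat)
  expect_true(all(est1$kd == 1e-9))

  # empirical mean planted strength tracks the requested mean; measured at
  # strengths high enough that a chance background window essentially never
  # out-scores the planted site (the best window then IS the planted site)
  sp2 <- cohortSpec(n_food = 120, n_nonfood = 120, strength_mean_food = 0.9,
                    strength_mean_nonfood = 0.7, strength_sd = 0.05,
                    seed = 10)
  co2 <- generateCohort(sp2, mat)
  est2 <- estimateAffinity(co2, mat)
  grp <- as.data.frame(cohortInfo(co2))$group
  # tolerance: 2*sd/sqrt(n) plus the local substitution-lattice spacing
  expect_lt(abs(mean(est2$best_score[grp == "food"]) - 0.9), 0.05)
  expect_lt(abs(mean(est2$best_score[grp == "non_food"]) - 0.7), 0.05)

  # a stronger planted site means a smaller KD, group-wise
  expect_lt(mean(est2$ln_kd[grp == "food"]),
            mean(est2$ln_kd[grp == "non_food"]))
})
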