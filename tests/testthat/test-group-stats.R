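test_that("summarizeKd computes mean and SEM with the n-1 denominator", {
  gs <- summarizeKd(c(1, 2, 3), "demo")
  expect_identical(gs@n, 3L)
  expect_equal(gs@m0, 2)
  expect_equal(gs@sem, 1 / sqrt(3), tolerance = 1e-12)

  const <- summarizeKd(c(2, 2, 2), "const")
  expect_equal(const@sem, 0)

  expect_warning(single <- summarizeKd(5, "one"), "SEM set to 0")
  expect_equal(single@m0, 5)
  expect_equal(single@sem, 0)

  expect_error(summarizeKd(numeric(0)), "empty")
  expect_error(summarizeKd(c(1, -2)), "positive")

  # agrees with an independent two-pass computation on random input
  set.seed(501)
  for (i in 1:20) {
    x <- rexp(sample(2:40, 1)) + 0.1
    gs <- summarizeKd(x, "rand")
    m <- sum(x) / length(x)
    s2 <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(gs@m0, m, tolerance = 1e-12)
    expect_equal(gs@sem, sqrt(s2 / length(x)), tolerance = 1e-12)
  }
})

test_that("the Z-test is symmetric, scale-invariant and correctly referred", {
  a <- summarizeKd(c(2.1, 2.9, 3.4, 2.2), "a")
  b <- summarizeKd(c(1.1, 1.4, 1.9, 1.2), "b")
  zt <- fisherZTest(a, b)
  expect_equal(zt@z, abs(a@m0 - b@m0) / sqrt(a@sem^2 + b@sem^2),
               tolerance = 1e-12)
  expect_equal(zt@p_two_sided, 2 * pnorm(zt@z, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetry up to direction
  rev <- fisherZTest(b, a)
  expect_equal(rev@z, zt@z, tolerance = 1e-15)
  expect_identical(rev@direction, -zt@direction)

  # common positive rescaling of the KD values leaves Z unchanged
  k <- 37.5
  zt_scaled <- fisherZTest(summarizeKd(k * c(2.1, 2.9, 3.4, 2.2), "a"),
                           summarizeKd(k * c(1.1, 1.4, 1.9, 1.2), "b"))
  expect_equal(zt_scaled@z, zt@z, tolerance = 1e-12)

  # null case
  null <- fisherZTest(a, a)
  expect_equal(null@z, 0)
  expect_equal(null@p_two_sided, 1)
  expect_identical(null@significant_at, "none")

  # degenerate SEMs
  c1 <- new("GroupSummary", label = "c1", n = 2L, m0 = 1, sem = 0)
  c2 <- new("GroupSummary", label = "c2", n = 2L, m0 = 2, sem = 0)
  expect_error(fisherZTest(c1, c1), "undefined")
  expect_warning(inf <- fisherZTest(c1, c2), "Inf")
  expect_identical(inf@z, Inf)
  expect_identical(inf@p_two_sided, 0)
})

test_that("significance ladder assigns the highest attained level", {
  z_for <- function(p) qnorm(p / 2, lower.tail = FALSE)
  mk <- function(z) {
    a <- new("GroupSummary", label = "a", n = 10L, m0 = 1 + z, sem = 1)
    b <- new("GroupSummary", label = "b", n = 10L, m0 = 1, sem = 0)
    fisherZTest(a, b)
  }
  expect_identical(mk(z_for(0.0005))@significant_at, "0.001")
  expect_identical(mk(z_for(0.005))@significant_at, "0.01")
  expect_identical(mk(z_for(0.03))@significant_at, "0.05")
  expect_identical(mk(0.5)@significant_at, "none")
})

test_that("buildFamilyReport lays out species rows, group rows and tests", {
  set.seed(502)
  # one family, two species per group
  co <- makeCohort(
    replicate(8, randomSeq()),
    families = rep("albumin", 8),
    groups = rep(c("food", "non_food"), each = 4),
    species = c("sp_a", "sp_a", "sp_b", "sp_b", "sp_c", "sp_c", "sp_d",
                "sp_d"))
  est <- estimateAffinity(co, defaultTataMatrix())
  rep1 <- buildFamilyReport(est, co)
  expect_identical(nrow(rep1$summaries), 6L)  # 4 species + 2 group rows
  expect_identical(sum(rep1$summaries$species == "(all)"), 2L)
  expect_identical(nrow(rep1$tests), 1L)
  expect_true(rep1$tests$computable)
  # group-level N pools promoters, not species
  expect_identical(rep1$summaries$n[rep1$summaries$species == "(all)"],
                   c(4L, 4L))

  # species-weighted alternative averages species means
  repw <- buildFamilyReport(est, co, species_weighted = TRUE)
  grp_rows <- repw$summaries[repw$summaries$species == "(all)", ]
  sp_means <- tapply(est$kd_nM[1:4], c("sp_a", "sp_a", "sp_b", "sp_b"), mean)
  expect_equal(grp_rows$m0_nM[grp_rows$group == "food"],
               mean(sp_means), tolerance = 1e-12)
  expect_identical(grp_rows$n, c(2L, 2L))

  # a family observed in one group only is reported, not an error
  solo <- makeCohort(replicate(3, randomSeq()),
                     families = rep("globulin", 3),
                     groups = rep("food", 3))
  rep2 <- buildFamilyReport(estimateAffinity(solo, defaultTataMatrix()), solo)
  expect_false(rep2$tests$computable)
  expect_true(is.na(rep2$tests$z))

  # bonferroni multiplies p across families
  co2 <- makeCohort(
    replicate(12, randomSeq()),
    families = rep(c("albumin", "globulin"), each = 6),
    groups = rep(rep(c("food", "non_food"), each = 3), 2))
  est2 <- estimateAffinity(co2, defaultTataMatrix())
  plain <- buildFamilyReport(est2, co2)
  bonf <- buildFamilyReport(est2, co2, bonferroni = TRUE)
  expect_equal(bonf$tests$p, pmin(1, plain$tests$p * 2), tolerance = 1e-12)
})
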