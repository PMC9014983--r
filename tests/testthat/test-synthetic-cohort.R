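# Synthetic cohort generator: reproducibility, Hardy-Weinberg structure,
# planted effects, exclusions and the outlier rule.

test_that("generateCohort is reproducible and respects the score ceiling", {
  p <- cohortParams(nSubjects = 80, seed = 7)
  t1 <- generateCohort(p)
  t2 <- generateCohort(p)
  expect_identical(t1, t2)

  p0 <- cohortParams(
    nSubjects = 40,
    loadAgeSlopes = c(manipulation = 0, maintenance = 0, control = 0),
    noiseSD = 0, seed = 3)
  t0 <- generateCohort(p0)
  for (v in c("wm_manipulation", "wm_maintenance", "wm_control"))
    expect_equal(t0[[v]], rep(18, 40))
})

test_that("cohort draws ages from the declared cohorts and bounds scores", {
  p <- cohortParams(nSubjects = 500, seed = 21)
  tb <- generateCohort(p)
  expect_true(all(tb$age %in% p@ageCohorts[, 1]))
  expect_true(all(tb$sex %in% 0:1))
  for (v in c("wm_manipulation", "wm_maintenance", "wm_control")) {
    expect_true(all(tb[[v]] >= 0 & tb[[v]] <= 18))
  }
  # older subjects score lower under the default negative slopes
  expect_lt(cor(tb$age, tb$wm_manipulation), -0.3)
  expect_lt(cor(tb$age, tb$speed), -0.3)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohortParams(nSubjects = 1), "at least 2")
  expect_error(cohortParams(sexRatio = 1.4), "sexRatio")
  expect_error(cohortParams(alleleFreqs = c(a = 0.5, b = 1, c = 0.2)),
               "alleleFreqs")
})

test_that("genotype generation matches Hardy-Weinberg expectation", {
  expect_error(generateGenotypes(10, 1), "strictly in")
  expect_error(generateGenotypes(10, 0), "strictly in")

  # observed allele frequency concentrates around the target
  g <- generateGenotypes(10000, 0.47, seed = 11)
  counts <- as.integer(table(g))
  fhat <- (2 * counts[1] + counts[2]) / (2 * 10000)
  expect_lt(abs(fhat - 0.47), 0.02)

  # genotype proportions converge to (p^2, 2pq, q^2)
  g2 <- generateGenotypes(1e5, 297 / 630, seed = 12)
  props <- as.numeric(table(g2)) / 1e5
  pA <- 297 / 630
  expect_lt(max(abs(props - c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2))), 0.01)

  # HWE expected counts at n = 315 match the closed form
  h <- hweTest(as.integer(table(generateGenotypes(315, pA, seed = 13))))
  expect_equal(315 * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2),
               c(70.007, 156.986, 88.007), tolerance = 1e-4)
})

test_that("HWE chi-square of generated counts rejects at about alpha", {
  set.seed(31)
  rej <- vapply(seq_len(500), function(r) {
    g <- generateGenotypes(600, 0.35, seed = 31000 + r)
    hweTest(as.integer(table(g)))$chisq > qchisq(0.95, 1)
  }, logical(1))
  # expected 5%; binomial sd at 500 replicates is about 1%
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("metric stack plants the configured age slope", {
  sp <- syntheticSkeletonSpace(c(10, 10, 10))
  spec <- list(fracEffect = 0.1, fracMediating = 0, slopeAgeFA = -0.4,
               slopeFAWM = 0)
  p <- cohortParams(nSubjects = 200, mediationSpec = spec, seed = 5)
  tb <- generateCohort(p)
  st <- generateMetricStack(tb, sp, spec, seed = 6)
  pl <- plantedEffects(sp, spec)
  expect_length(pl$effect, 100)
  z <- scale(tb$age)[, 1]
  ahat <- apply(metricValues(st)[, pl$effect], 2, function(m)
    coef(lm(scale(m)[, 1] ~ z))[2])
  expect_lt(abs(mean(ahat) - (-0.4)), 0.05)
  expect_true(all(metricValues(st) >= 0 & metricValues(st) <= 1))
})

test_that("null voxels are calibrated when the planted slope is zero", {
  sp <- syntheticSkeletonSpace(c(20, 10, 10))
  spec <- list(fracEffect = 1, fracMediating = 0, slopeAgeFA = 0,
               slopeFAWM = 0)
  p <- cohortParams(nSubjects = 100, mediationSpec = spec, seed = 9)
  tb <- generateCohort(p)
  st <- generateMetricStack(tb, sp, spec, seed = 10)
  z <- scale(tb$age)[, 1]
  X <- cbind(1, z)
  tmap <- fitVoxelwiseGLM(st, X, c(0, 1))
  rate <- mean(statValues(tmap) > qt(0.975, 98))
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.05)
})

test_that("effect-voxel index sets are seed-independent by design", {
  sp <- syntheticSkeletonSpace(c(8, 5, 5))
  spec <- list(fracEffect = 0.3, fracMediating = 0.5, slopeAgeFA = -0.4,
               slopeFAWM = 0.3)
  p <- cohortParams(nSubjects = 50, mediationSpec = spec, seed = 2)
  tb <- generateCohort(p)
  s1 <- generateMetricStack(tb, sp, spec, seed = 100)
  s2 <- generateMetricStack(tb, sp, spec, seed = 200)
  expect_false(identical(metricValues(s1), metricValues(s2)))
  expect_identical(plantedEffects(sp, spec), plantedEffects(sp, spec))
  # mediating and age-only clusters sit at opposite ends of the skeleton
  pl <- plantedEffects(sp, spec)
  expect_equal(pl$mediating, 1:30)
  expect_equal(setdiff(pl$effect, pl$mediating), 171:200)
})

test_that("metric stack rejects invalid fractions", {
  sp <- tinySpace(c(3, 3, 3))
  p <- cohortParams(nSubjects = 20, seed = 2)
  tb <- generateCohort(p)
  expect_error(
    generateMetricStack(tb, sp, list(fracEffect = 1.2, fracMediating = 0,
                                     slopeAgeFA = 0, slopeFAWM = 0)),
    "invalid parameter")
})

test_that("exclusion ledger reproduces the staged participant counts", {
  # 372 initial; 20 medical, 9 morphology/surgery/lesion, 3 missing DTI,
  # 12 artifacts -> 328 remaining
  tb <- data.frame(subject_id = sprintf("s%03d", 1:372))
  stages <- c("medical", "morphology", "missing_dti", "artifacts")
  flags <- rep(NA_character_, 372)
  flags[1:20] <- "medical"
  flags[21:29] <- "morphology"
  flags[30:32] <- "missing_dti"
  flags[33:44] <- "artifacts"
  res <- applyExclusions(tb, flags, stages)
  expect_equal(initialCount(res$ledger), 372L)
  expect_equal(unname(stageCounts(res$ledger)), c(20L, 9L, 3L, 12L))
  expect_equal(finalCount(res$ledger), 328L)
  expect_equal(nrow(res$table), 328L)
})

test_that("exclusions handle edge cases and conserve counts", {
  tb <- data.frame(id = 1:10)
  none <- applyExclusions(tb, rep(NA_character_, 10), "any")
  expect_equal(nrow(none$table), 10)
  expect_equal(sum(stageCounts(none$ledger)), 0L)

  all <- applyExclusions(tb, rep("any", 10), "any")
  expect_equal(nrow(all$table), 0)
  expect_equal(sum(stageCounts(all$ledger)), 10L)

  expect_error(applyExclusions(tb, rep("mystery", 10), "any"), "unknown")

  # matrix flags: first-stage attribution, exact count conservation
  set.seed(14)
  fl <- matrix(runif(300) < 0.2, 100, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  res <- applyExclusions(data.frame(id = 1:100), fl)
  led <- res$ledger
  expect_equal(initialCount(led) - sum(stageCounts(led)), finalCount(led))
  expect_equal(finalCount(led), sum(rowSums(fl) == 0))
  # a subject flagged at b and c counts at b only
  fl2 <- matrix(FALSE, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  fl2[1, c(2, 3)] <- TRUE
  led2 <- applyExclusions(data.frame(id = 1:3), fl2)$ledger
  expect_equal(unname(stageCounts(led2)), c(0L, 1L, 0L))
})

test_that("outlier rule removes only points beyond k SDs", {
  set.seed(8)
  x <- rnorm(50)
  x <- (x - mean(x)) / sd(x) * 0.9          # everything within ~1 SD
  y <- rnorm(50)
  r <- removeOutliers(x, y, k = 3.5)
  expect_equal(r$removed, 0)

  x2 <- c(rnorm(49), 0)
  x2 <- x2 - mean(x2)
  x2[50] <- 5 * sd(x2[1:49])                 # planted extreme point
  y2 <- rnorm(50)
  r2 <- removeOutliers(x2, y2, k = 3.5)
  expect_equal(r2$removed, 1)
  expect_false(r2$keep[50])

  expect_warning(r3 <- removeOutliers(rep(1, 10), rnorm(10)), "constant")
  expect_equal(r3$removed, 0)
  expect_error(removeOutliers(1:2, 1:2), "at least 3")
  expect_error(removeOutliers(1:5, 1:4), "equal length")
})

test_that("subject table and ledger serialize to TSV / JSON", {
  p <- cohortParams(nSubjects = 20, seed = 4)
  tb <- generateCohort(p)
  d <- withr::local_tempdir()
  writeSubjectTable(tb, file.path(d, "subjects.tsv"))
  back <- read.delim(file.path(d, "subjects.tsv"))
  expect_equal(nrow(back), 20)
  expect_false(any(startsWith(names(back), ".")))

  led <- applyExclusions(tb, c(rep(NA, 18), "qc", "qc"), "qc")$ledger
  writeExclusionLedger(led, file.path(d, "ledger.json"))
  j <- jsonlite::read_json(file.path(d, "ledger.json"))
  expect_equal(j$final, 18)
  expect_equal(j$stages$qc, 2)
})
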