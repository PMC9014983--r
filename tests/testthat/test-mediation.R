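# Voxelwise Sobel mediation: unit values, invariances, calibration and
# planted-path recovery; change-in-effect summary.

test_that("Sobel z reproduces the closed form and its sign rule", {
  expect_equal(sobelZ(2, 3, 1, 1), 6 / sqrt(14), tolerance = 1e-9)
  expect_equal(sobelZ(0, 5, 1, 1), 0)
  expect_equal(sobelZ(5, 0, 1, 1), 0)
  expect_error(sobelZ(1, 1, 0, 0), "degenerate")
  expect_error(sobelZ(1, 1, -1, 1), "non-negative")

  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  sa <- runif(200, 0.1, 2); sb <- runif(200, 0.1, 2)
  z <- sobelZ(a, b, sa, sb)
  expect_equal(sign(z), sign(a * b))
})

test_that("age-effect mask recovers planted negative age effects", {
  sp <- syntheticSkeletonSpace(c(10, 10, 5))   # 500 voxels
  spec <- list(fracEffect = 0.2, fracMediating = 0.5, slopeAgeFA = -0.4,
               slopeFAWM = 0.3)
  p <- cohortParams(nSubjects = 200, mediationSpec = spec, seed = 31)
  tb <- generateCohort(p)
  st <- generateMetricStack(tb, sp, spec, seed = 32)
  pl <- plantedEffects(sp, spec)
  mask <- ageEffectMask(st, tb$age, cbind(sex = tb$sex), tfceParams(),
                        nPerm = 300, seed = 33)
  expect_gte(mean(pl$effect %in% which(mask)), 0.8)
  expect_lte(length(mask), nVoxels(sp))   # mask lives on the skeleton

  # a null stack rarely yields any masked voxel
  nullHits <- vapply(1:20, function(r) {
    stn <- randomStack(60, syntheticSkeletonSpace(c(8, 5, 4)),
                       seed = 400 + r)
    suppressWarnings(any(ageEffectMask(stn, rnorm(60), NULL, tfceParams(),
                                       nPerm = 200, seed = 500 + r)))
  }, logical(1))
  expect_lte(sum(nullHits), 3)
})

test_that("mediation z maps are internally consistent and shift-invariant", {
  sp <- syntheticSkeletonSpace(c(6, 5, 4))
  spec <- list(fracEffect = 0.4, fracMediating = 0.5, slopeAgeFA = -0.4,
               slopeFAWM = 0.3)
  p <- cohortParams(nSubjects = 80, mediationSpec = spec, seed = 41)
  tb <- generateCohort(p)
  st <- generateMetricStack(tb, sp, spec, seed = 42)
  mask <- seq_len(60)
  med <- voxelwiseMediation(st, tb$age, tb$wm_manipulation,
                            cbind(sex = tb$sex), mask, tfceParams(),
                            nPerm = 200, seed = 43)
  # per-voxel z equals sobelZ applied to that voxel's (a, b, sa, sb)
  expect_equal(med@z, sobelZ(med@a, med@b, med@sa, med@sb),
               tolerance = 1e-10)
  expect_true(peakVoxel(med) %in% analysisMask(med))

  # adding constants to age or outcome changes nothing
  med2 <- voxelwiseMediation(st, tb$age + 100,
                             tb$wm_manipulation + 7,
                             cbind(sex = tb$sex), mask, tfceParams(),
                             nPerm = 200, seed = 43)
  expect_equal(med2@z, med@z, tolerance = 1e-9)
  expect_equal(med2@p, med@p)

  expect_error(voxelwiseMediation(st, tb$age, tb$wm_manipulation,
                                  cbind(sex = tb$sex), integer(0),
                                  tfceParams(), 200, seed = 1), "empty")
})

test_that("constant-metric voxels are excluded with a count", {
  sp <- tinySpace(c(3, 3, 3))
  set.seed(44)
  Y <- matrix(runif(40 * 27, 0.3, 0.7), 40)
  Y[, 5] <- 0.5
  st <- metricStack("FA", Y, sp)
  med <- voxelwiseMediation(st, rnorm(40), rnorm(40), NULL, 1:27,
                            tfceParams(), nPerm = 150, seed = 45)
  expect_gte(med@nExcluded, 1)
  expect_true(is.na(med@z[5]))
})

test_that("planted mediation is detected with the constructed sign", {
  sp <- syntheticSkeletonSpace(c(10, 8, 5))   # 400 voxels
  spec <- list(fracEffect = 0.25, fracMediating = 0.8, slopeAgeFA = -0.4,
               slopeFAWM = 0.3)
  p <- cohortParams(nSubjects = 150, mediationSpec = spec, seed = 51)
  tb <- generateCohort(p)
  st <- generateMetricStack(tb, sp, spec, seed = 52)
  pl <- plantedEffects(sp, spec)
  med <- voxelwiseMediation(st, tb$age, tb$wm_manipulation,
                            cbind(sex = tb$sex), pl$effect, tfceParams(),
                            nPerm = 300, seed = 53)
  paths <- mediationPaths(med)
  planted <- paths$column %in% pl$mediating
  expect_gte(mean(paths$p[planted] < 0.05), 0.8)
  # a < 0 and b > 0 by construction, so the indirect effect is negative
  expect_true(all(paths$z[planted] < 0))
  expect_lt(mean(paths$a[planted]), -0.3)
  expect_gt(mean(paths$b[planted]), 0.2)
})

test_that("mediation is calibrated when the metric is pure noise", {
  hits <- vapply(1:30, function(r) {
    set.seed(600 + r)
    n <- 50
    sp <- syntheticSkeletonSpace(c(5, 5, 4))
    st <- randomStack(n, sp, seed = 700 + r)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    med <- voxelwiseMediation(st, x, y, NULL, 1:100, tfceParams(),
                              nPerm = 200, seed = 800 + r)
    any(med@p < 0.05)
  }, logical(1))
  # nominal 5%; binomial bound at 30 replicates
  expect_lte(mean(hits), 0.2)
})

test_that("outcome-scheme null is calibrated under a real age path", {
  sp <- syntheticSkeletonSpace(c(10, 6, 5))
  hits <- vapply(1:40, function(r) {
    set.seed(900 + r)
    n <- 60
    z <- scale(rnorm(n))[, 1]
    M <- matrix(rnorm(n * 300), n, 300)
    for (j in 1:150) M[, j] <- -0.4 * z + sqrt(0.84) * M[, j]
    st <- metricStack("MD", M, sp)
    y <- -0.36 * z + rnorm(n)          # direct age effect, no mediation
    med <- voxelwiseMediation(st, z, y, NULL, 1:150, tfceParams(),
                              nPerm = 200, seed = 1000 + r,
                              nullScheme = "outcome")
    any(med@p < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.175)   # nominal 5%, binomial bound at 40 reps
})

test_that("change-in-effect reports nesting and age attenuation", {
  set.seed(61)
  n <- 300
  age <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)

  # pure-noise mediator: nothing changes
  y <- -0.5 * age + rnorm(n)
  ec0 <- changeInEffect(y, age, sex, rnorm(n))
  expect_lt(abs(ec0$relativeChange), 0.05)
  expect_lt(abs(ec0$ageTAfter - ec0$ageTBefore) / abs(ec0$ageTBefore),
            0.1)

  # outcome equals the mediator, mediator tracks age: age t collapses
  m <- -0.7 * age + rnorm(n, sd = 0.4)
  ec1 <- suppressWarnings(changeInEffect(m, age, sex, m))
  expect_lt(abs(ec1$ageTAfter), abs(ec1$ageTBefore) / 5)
  expect_gte(ec1$r2After, ec1$r2Before)
  expect_lt(ec1$ageUniqueChange, -0.9)   # age's unique share vanishes

  # nesting property on arbitrary data
  for (r in 1:5) {
    set.seed(70 + r)
    ecr <- changeInEffect(rnorm(50), rnorm(50), rbinom(50, 1, 0.5),
                          rnorm(50))
    expect_gte(ecr$r2After, ecr$r2Before)
  }

  expect_error(suppressWarnings(
    changeInEffect(rep(1, 50), rnorm(50), rbinom(50, 1, 0.5), rnorm(50))),
    "undefined")
})
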