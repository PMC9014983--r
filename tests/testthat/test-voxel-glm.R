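# Voxelwise GLM: closed forms, oracles, calibration, contrasts.

test_that("single-voxel t equals the closed-form simple-regression t", {
  set.seed(1)
  n <- 20
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.3)
  sp <- makeSkeletonSpace(c(1, 1, 1), array(TRUE, c(1, 1, 1)))
  st <- metricStack("MD", matrix(y, n, 1), sp)
  tmap <- fitVoxelwiseGLM(st, cbind(intercept = 1, x = x), "x")
  r <- cor(x, y)
  expect_equal(statValues(tmap), r * sqrt(n - 2) / sqrt(1 - r^2),
               tolerance = 1e-10)
})

test_that("t-maps match a brute-force per-voxel lm oracle", {
  set.seed(2)
  n <- 20
  sp <- makeSkeletonSpace(c(5, 5, 2), array(TRUE, c(5, 5, 2)))
  Y <- matrix(rnorm(n * 50), n, 50)
  X <- cbind(intercept = 1, age = rnorm(n), sex = rbinom(n, 1, 0.5))
  st <- metricStack("MD", Y, sp)
  tmap <- fitVoxelwiseGLM(st, X, "age")
  oracle <- apply(Y, 2, function(y)
    summary(lm(y ~ X[, 2] + X[, 3]))$coefficients[2, "t value"])
  expect_equal(statValues(tmap), unname(oracle), tolerance = 1e-8)
  # "less" direction negates the map
  expect_equal(statValues(fitVoxelwiseGLM(st, X, "age", "less")),
               -statValues(tmap))
})

test_that("t is invariant to shifting another predictor", {
  set.seed(3)
  n <- 30
  sp <- tinySpace(c(2, 2, 2))
  st <- randomStack(n, sp, seed = 3)
  X1 <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  X2 <- X1
  X2[, "b"] <- X2[, "b"] + 100
  t1 <- fitVoxelwiseGLM(st, X1, "a")
  t2 <- fitVoxelwiseGLM(st, X2, "a")
  expect_equal(statValues(t1), statValues(t2), tolerance = 1e-9)
})

test_that("null t-maps are calibrated", {
  set.seed(4)
  n <- 40
  sp <- syntheticSkeletonSpace(c(20, 10, 10))
  st <- randomStack(n, sp, seed = 4)
  X <- cbind(intercept = 1, x = rnorm(n))
  tv <- statValues(fitVoxelwiseGLM(st, X, "x"))
  rate <- mean(abs(tv) > qt(0.975, n - 2))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.075)
})

test_that("a covariate orthogonal to predictor and outcome only costs df", {
  set.seed(5)
  n <- 25
  sp <- makeSkeletonSpace(c(1, 1, 1), array(TRUE, c(1, 1, 1)))
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  # orthogonalize a random column against intercept, x and y
  w <- residualize(rnorm(n), cbind(x, y))
  st <- metricStack("MD", matrix(y, n, 1), sp)
  t1 <- statValues(fitVoxelwiseGLM(st, cbind(1, x = x), c(0, 1)))
  t2 <- statValues(fitVoxelwiseGLM(st, cbind(1, x = x, w = w), c(0, 1, 0)))
  expect_equal(t2, t1 * sqrt((n - 3) / (n - 2)), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  sp <- tinySpace(c(2, 2, 1))
  st <- randomStack(10, sp, seed = 6)
  x <- rnorm(10)
  X <- cbind(intercept = 1, x = x, dup = 2 * x)
  expect_error(fitVoxelwiseGLM(st, X, "x"), "dup")
})

test_that("residualize centers and orthogonalizes", {
  set.seed(7)
  v <- rnorm(40, mean = 5)
  expect_equal(residualize(v), v - mean(v))
  Z <- cbind(rnorm(40), rnorm(40))
  r <- residualize(v, Z)
  expect_lt(max(abs(cor(r, Z))), 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  # values already orthogonal to the covariates are only centered
  vperp <- residualize(rnorm(40), Z)
  expect_equal(residualize(vperp, Z), vperp - mean(vperp),
               tolerance = 1e-10)
})

test_that("partial correlation matches double residualization", {
  set.seed(8)
  x <- rnorm(50)
  expect_equal(partialCorrelation(x, x), 1)
  Z <- cbind(rnorm(50), rbinom(50, 1, 0.5))
  y <- 0.5 * x + 0.3 * Z[, 1] + rnorm(50)
  expect_equal(partialCorrelation(x, y, Z),
               cor(residualize(x, Z), residualize(y, Z)))
  set.seed(9)
  big <- cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(big), 0.05)
  expect_error(partialCorrelation(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("condition-slope comparison behaves as constructed", {
  set.seed(10)
  n <- 60
  sp <- tinySpace(c(4, 3, 2))
  a <- rnorm(n)
  b <- rnorm(n)
  # metric driven by condition A only
  Y <- outer(a, rep(0.8, nVoxels(sp))) + matrix(rnorm(n * nVoxels(sp),
                                                      sd = 0.4), n)
  st <- metricStack("MD", Y, sp)
  tAB <- compareConditionSlopes(st, a, b)
  expect_true(all(statValues(tAB) > 2))
  tBA <- compareConditionSlopes(st, b, a)
  expect_equal(statValues(tBA), -statValues(tAB), tolerance = 1e-9)
  expect_error(compareConditionSlopes(st, a, a), "identical")
})

test_that("group contrasts detect planted offsets and are antisymmetric", {
  set.seed(11)
  n <- 80
  sp <- tinySpace(c(4, 3, 2))
  g <- factor(rep(c("ValVal", "ValMet"), each = n / 2))
  Y <- matrix(rnorm(n * nVoxels(sp), sd = 0.02), n) + 0.5
  Y[g == "ValMet", ] <- Y[g == "ValMet", ] + 0.05
  st <- metricStack("FA", Y, sp)
  cov <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  tm <- groupContrast(st, g, c("ValMet", "ValVal"), cov)
  expect_true(all(statValues(tm) > 0))
  tm2 <- groupContrast(st, g, c("ValVal", "ValMet"), cov)
  expect_equal(statValues(tm2), -statValues(tm), tolerance = 1e-9)
  expect_error(groupContrast(st, g, c("ValVal", "MetMet"), cov),
               "not found")

  # identical group distributions: calibrated small t values
  set.seed(12)
  g0 <- factor(rep(c("x", "y"), each = 500))
  sp1 <- makeSkeletonSpace(c(1, 1, 1), array(TRUE, c(1, 1, 1)))
  t0 <- replicate(200, {
    st0 <- metricStack("MD", matrix(rnorm(1000), 1000, 1), sp1)
    statValues(groupContrast(st0, g0, c("x", "y")))
  })
  expect_lt(mean(abs(t0) > qt(0.975, 998)), 0.1)
  expect_gt(mean(abs(t0) > qt(0.975, 998)), 0.005)
})

test_that("age-split interaction contrast isolates the product term", {
  set.seed(13)
  n <- 120
  sp <- tinySpace(c(2, 2, 2))
  g <- factor(sample(c("A", "B"), n, TRUE))
  ageGrp <- factor(sample(c("younger", "older"), n, TRUE),
                   levels = c("younger", "older"))
  # effect of group only within the older stratum
  eff <- 0.6 * (g == "A") * (ageGrp == "older")
  Y <- matrix(rnorm(n * 8, sd = 0.2), n) + eff
  st <- metricStack("MD", Y, sp)
  ti <- groupContrast(st, g, c("A", "B"), interactionWith = ageGrp)
  expect_true(all(statValues(ti) > 2))
})
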