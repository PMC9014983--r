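## Synthetic aging-cohort generator. The generator emulates the data
## structure the downstream statistics assume: a narrow-age-cohort (NAC)
## design where recruitment ages are fixed values, Hardy-Weinberg genotypes
## at stated allele frequencies, working-memory accuracies with load-graded
## age effects, and a partial-mediation path age -> white matter -> WM
## shared between the subject table and the metric stack.

.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

## sample-standardize; zero-variance vectors collapse to zeros
.std <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
  (v - mean(v)) / s
}

## residualize v on the columns of basis (with intercept), then standardize;
## used to plant standardized path coefficients exactly in-sample
.orthStd <- function(v, basis) {
  X <- cbind(1, basis)
  r <- v - X %*% qr.coef(qr(X), v)
  .std(as.numeric(r))
}

#' Cohort generator parameters
#'
#' Defaults emulate a population-based aging study with a narrow-age-cohort
#' design: 328 subjects recruited at fixed ages between 25 and 80 (weights
#' skewed toward older cohorts), 53% female, Hardy-Weinberg genotypes at
#' three dopamine-related loci (designated-allele frequencies 0.192, 0.562,
#' 0.471), three working-memory conditions scored out of 18 with load-graded
#' negative age effects, and a partial-mediation structure in which a
#' standardized age-to-white-matter path of -0.4 and a white-matter-to-WM
#' path of 0.3 run through a latent integrity factor.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param ageCohorts two-column matrix of (age, weight); weights sum to 1.
#' @param sexRatio proportion female (sex coded 0 = female, 1 = male).
#' @param alleleFreqs designated-allele frequency per locus, in (0, 1).
#' @param wmCeiling maximum accuracy per condition (18 items).
#' @param loadAgeSlopes total standardized age effect per condition
#'   (direct plus mediated), negative for age-related decline.
#' @param mediationSpec list with `fracEffect` (fraction of skeleton voxels
#'   with an age effect), `fracMediating` (fraction of those that also carry
#'   the mediated signal), `slopeAgeFA` (standardized age-to-metric path a)
#'   and `slopeFAWM` (standardized metric-to-WM path b).
#' @param noiseSD residual SDs: either a single number applied everywhere
#'   (0 switches all noise off) or a list with `wm` (score units, per
#'   condition), `faVoxel` (voxel-noise mixing weight in [0, 1)), `speed`
#'   (per subscore) and `latent` (SD of the latent factor draws).
#' @param seed master seed; all stage seeds derive from it.
#' @return A [CohortParams-class].
#' @export
cohortParams <- function(nSubjects = 328L,
                         ageCohorts = cbind(
                           age = c(25, 30, 35, 40, 45, 50,
                                   55, 60, 65, 70, 75, 80),
                           weight = c(9, 9, 9, 9, 9.5, 9.5,
                                      50, 50, 52, 52, 44.5, 44.5) / 348),
                         sexRatio = 173 / 328,
                         alleleFreqs = c(taq1a = 0.192, c957t = 0.562,
                                         comt = 0.471),
                         wmCeiling = 18,
                         loadAgeSlopes = c(manipulation = -0.36,
                                           maintenance = -0.23,
                                           control = -0.19),
                         mediationSpec = list(fracEffect = 0.3,
                                              fracMediating = 0.5,
                                              slopeAgeFA = -0.4,
                                              slopeFAWM = 0.3),
                         noiseSD = list(wm = c(1.90, 0.94, 0.96),
                                        faVoxel = 0.15,
                                        speed = 0.8, latent = 1),
                         seed = 1L) {
  if (is.numeric(noiseSD) && length(noiseSD) == 1L)
    noiseSD <- list(wm = rep(noiseSD, 3), faVoxel = min(noiseSD, 0.99),
                    speed = noiseSD, latent = noiseSD)
  defaults <- list(wm = c(1.90, 0.94, 0.96), faVoxel = 0.15,
                   speed = 0.8, latent = 1)
  noiseSD <- utils::modifyList(defaults, noiseSD)
  if (nSubjects < 2L)
    stop("invalid parameter: nSubjects must be at least 2")
  new("CohortParams", nSubjects = as.integer(nSubjects),
      ageCohorts = as.matrix(ageCohorts), sexRatio = sexRatio,
      alleleFreqs = alleleFreqs, wmCeiling = wmCeiling,
      loadAgeSlopes = loadAgeSlopes, mediationSpec = mediationSpec,
      noiseSD = noiseSD, seed = as.integer(seed))
}

setMethod("show", "CohortParams", function(object) {
  cat(sprintf(paste0("CohortParams: %d subjects, %d age cohorts ",
                     "(%g-%g y), seed %d\n"),
              object@nSubjects, nrow(object@ageCohorts),
              min(object@ageCohorts[, 1]), max(object@ageCohorts[, 1]),
              object@seed))
})

#' Hardy-Weinberg genotype column
#'
#' Draws genotypes with multinomial Hardy-Weinberg probabilities
#' (p^2, 2pq, q^2), where p is the frequency of the designated allele (the
#' allele of the first label).
#'
#' @param n number of subjects.
#' @param alleleFreq designated-allele frequency, strictly in (0, 1).
#' @param seed optional seed.
#' @param labels genotype labels: designated homozygote, heterozygote,
#'   other homozygote.
#' @return factor of length `n` with the given labels as levels.
#' @examples
#' table(generateGenotypes(315, 297 / 630, seed = 7,
#'                         labels = c("ValVal", "ValMet", "MetMet")))
#' @export
generateGenotypes <- function(n, alleleFreq, seed = NULL,
                              labels = c("AA", "Aa", "aa")) {
  if (!is.numeric(alleleFreq) || alleleFreq <= 0 || alleleFreq >= 1)
    stop("invalid parameter: alleleFreq must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- alleleFreq
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  factor(sample(labels, n, replace = TRUE, prob = probs), levels = labels)
}

#' Generate a synthetic subject table
#'
#' Draws ages from the configured narrow-age cohorts, sex as
#' Bernoulli(sexRatio) (0 = female), Hardy-Weinberg genotypes at the three
#' loci, working-memory accuracies per condition and a processing-speed
#' composite (sum of three standardized subscores).
#'
#' Accuracy model, per condition c (score units, clipped to
#' \[0, wmCeiling\]):
#' `ceiling - h_c + s_c * (L_c * (z - z_min) + b_c * (m - a*z) + f_c * g)
#'  + h_c * e`,
#' where z is standardized age, m the latent white-matter integrity factor
#' (`m = a*z + sqrt(1-a^2)*eps`), g a shared ability factor, L_c the total
#' standardized age slope, and h_c the residual SD (also the headroom of
#' the youngest cohort below the ceiling, so that zero slopes and zero
#' noise put every score exactly at the ceiling). Latent factors are
#' orthonormalized in-sample so the planted standardized paths hold exactly
#' for the drawn sample. The latent integrity factor is returned in the
#' hidden column `.integrity` and is shared with
#' [generateMetricStack()]'s mediating voxels; `.ability` holds g.
#'
#' @param params a [CohortParams-class].
#' @return data.frame with columns subject_id, age, sex, taq1a, c957t,
#'   comt, wm_manipulation, wm_maintenance, wm_control, speed, plus hidden
#'   columns .integrity and .ability.
#' @export
generateCohort <- function(params) {
  stopifnot(is(params, "CohortParams"))
  validObject(params)
  n <- params@nSubjects
  seed <- params@seed
  ns <- params@noiseSD

  set.seed(.subSeed(seed, 1))
  ages <- params@ageCohorts[, 1]
  w <- params@ageCohorts[, 2]
  age <- sample(ages, n, replace = TRUE, prob = w)
  set.seed(.subSeed(seed, 2))
  sex <- rbinom(n, 1, 1 - params@sexRatio)  # 0 = female

  geno <- list(
    taq1a = generateGenotypes(n, params@alleleFreqs[["taq1a"]],
                              .subSeed(seed, 3),
                              labels = c("AA", "GA", "GG")),
    c957t = generateGenotypes(n, params@alleleFreqs[["c957t"]],
                              .subSeed(seed, 4),
                              labels = c("TT", "CT", "CC")),
    comt = generateGenotypes(n, params@alleleFreqs[["comt"]],
                             .subSeed(seed, 5),
                             labels = c("ValVal", "ValMet", "MetMet")))

  # design (population) age scale: anchored at the youngest cohort
  mu <- sum(ages * w)
  sdw <- sqrt(sum(w * (ages - mu)^2))
  zs <- .std(age)
  if (all(zs == 0)) zs <- (age - mu) / sdw   # degenerate single-cohort draw
  zmin <- (min(ages) - mean(age)) / (if (sd(age) > 1e-12) sd(age) else sdw)

  a <- params@mediationSpec$slopeAgeFA
  bwm <- params@mediationSpec$slopeFAWM
  set.seed(.subSeed(seed, 6))
  epsm <- rnorm(n, sd = ns$latent)
  graw <- rnorm(n, sd = ns$latent)
  mperp <- .orthStd(epsm, zs)
  gperp <- .orthStd(graw, cbind(zs, mperp))
  integrity <- a * zs + sqrt(max(0, 1 - a^2)) * mperp

  sWM <- c(2.9, 1.9, 1.4)                 # score-unit scale per condition
  bShare <- bwm * c(1, 0.8, 0.5)          # load-graded mediated path
  fShare <- c(0.6, 0.8, 0.7)              # shared ability loadings
  L <- params@loadAgeSlopes
  conds <- c("manipulation", "maintenance", "control")
  set.seed(.subSeed(seed, 7))
  acc <- matrix(NA_real_, n, 3, dimnames = list(NULL, conds))
  for (ci in seq_along(conds)) {
    e <- .orthStd(rnorm(n), cbind(zs, mperp, gperp))
    y <- (L[[ci]] - bShare[ci] * a) * (zs - zmin) +
      bShare[ci] * (integrity - a * zmin) + fShare[ci] * gperp
    h <- ns$wm[ci]
    raw <- params@wmCeiling - h + sWM[ci] * y + h * e
    acc[, ci] <- pmin(pmax(raw, 0), params@wmCeiling)
  }

  set.seed(.subSeed(seed, 8))
  subs <- sapply(1:3, function(i) {
    -0.4 * zs + 0.3 * gperp + ns$speed * .orthStd(rnorm(n),
                                                  cbind(zs, gperp))
  })
  speed <- rowSums(apply(subs, 2, .std))

  out <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)),
    age = age, sex = sex,
    taq1a = geno$taq1a, c957t = geno$c957t, comt = geno$comt,
    wm_manipulation = acc[, 1], wm_maintenance = acc[, 2],
    wm_control = acc[, 3], speed = speed,
    .integrity = integrity, .ability = gperp,
    stringsAsFactors = FALSE)
  attr(out, "mediationSpec") <- params@mediationSpec
  out
}

#' Planted effect-voxel index sets
#'
#' The generator designates effect voxels deterministically (independent of
#' the seed): the mediating voxels are the first columns of the skeleton
#' and the age-only effect voxels are the last columns, so that each truth
#' class forms its own spatially contiguous cluster on the box-shaped
#' synthetic spaces while the two classes stay disconnected (cluster
#' enhancement cannot chain one class's signal into the other, which would
#' confound voxel-level truth labels).
#'
#' @param space a [SkeletonSpace-class].
#' @param spec mediation spec list (see [cohortParams()]).
#' @return list with integer column vectors `effect` (all voxels carrying
#'   an age effect) and `mediating` (the subset that also carries the
#'   mediated signal).
#' @export
plantedEffects <- function(space, spec) {
  v <- nVoxels(space)
  nEffect <- round(spec$fracEffect * v)
  nMed <- round(spec$fracMediating * nEffect)
  ageOnly <- if (nEffect > nMed) seq(v - (nEffect - nMed) + 1L, v)
             else integer(0)
  list(effect = c(seq_len(nMed), ageOnly), mediating = seq_len(nMed))
}

#' Generate a synthetic skeleton metric stack
#'
#' Builds a subjects-by-voxels FA stack with planted, tract-structured
#' negative age effects. Effect voxels carry the standardized age slope
#' `spec$slopeAgeFA`; the mediating subset is driven by the cohort's latent
#' integrity factor (column `.integrity` of the table) so that those voxels
#' also predict working memory; remaining voxels are pure noise.
#' Standardized voxel signals are mapped to FA scale as
#' `faMean + faSD * signal` and clipped to \[0, 1\].
#'
#' @param table subject table from [generateCohort()].
#' @param space a [SkeletonSpace-class].
#' @param spec mediation spec (defaults to the table's attribute).
#' @param seed seed for the voxel noise.
#' @param metric metric name (default "FA").
#' @param faMean,faSD FA-scale mapping parameters.
#' @param faVoxelNoise voxel-noise mixing weight in [0, 1) for effect
#'   voxels.
#' @return A [MetricStack-class].
#' @export
generateMetricStack <- function(table, space,
                                spec = attr(table, "mediationSpec"),
                                seed = 1L, metric = "FA",
                                faMean = 0.45, faSD = 0.08,
                                faVoxelNoise = 0.15) {
  if (is.null(spec)) stop("no mediation spec given or attached to table")
  if (nrow(table) < 2L || nVoxels(space) < 1L)
    stop("table and space must be nonempty")
  fr <- c(spec$fracEffect, spec$fracMediating)
  if (any(fr < 0 | fr > 1))
    stop("invalid parameter: fractions must lie in [0, 1]")
  n <- nrow(table)
  v <- nVoxels(space)
  a <- spec$slopeAgeFA
  tau <- faVoxelNoise
  planted <- plantedEffects(space, spec)
  medIdx <- planted$mediating
  ageIdx <- setdiff(planted$effect, medIdx)

  zs <- .std(table$age)
  integ <- table$.integrity
  if (is.null(integ) && length(medIdx))
    stop("table lacks the .integrity column needed for mediating voxels; ",
         "generate it with generateCohort()")

  set.seed(.subSeed(seed, 11))
  sig <- matrix(rnorm(n * v), n, v)    # voxel noise, N(0,1)
  ca <- sqrt(max(0, 1 - a^2))
  for (j in medIdx)
    sig[, j] <- sqrt(1 - tau^2) * integ + tau * sig[, j]
  for (j in ageIdx)
    sig[, j] <- a * zs + ca * sig[, j]

  vals <- pmin(pmax(faMean + faSD * sig, 0), 1)
  metricStack(metric, vals, space, table$subject_id)
}

#' Apply staged exclusions to a subject table
#'
#' Removes every flagged subject and reports per-stage counts in the
#' declared stage order; a subject flagged at several stages is counted
#' only at its first flagged stage.
#'
#' @param table subject table (data.frame).
#' @param flags either a logical matrix (subjects x stages, with stage
#'   names as column names, in declared order) or a character vector of
#'   stage labels (`NA` = keep).
#' @param stages declared stage labels in order; required for character
#'   flags, taken from column names for matrix flags.
#' @return list with the filtered `table` and an [ExclusionLedger-class]
#'   `ledger`.
#' @export
applyExclusions <- function(table, flags, stages = NULL) {
  n <- nrow(table)
  if (is.matrix(flags) || is.data.frame(flags)) {
    flags <- as.matrix(flags)
    if (is.null(stages)) stages <- colnames(flags)
    if (is.null(stages)) stop("stage labels missing")
    if (nrow(flags) != n) stop("flags must have one row per subject")
    firstStage <- apply(flags, 1, function(r) {
      w <- which(as.logical(r))
      if (length(w)) stages[w[1]] else NA_character_
    })
  } else {
    if (length(flags) != n) stop("flags must have one entry per subject")
    if (is.null(stages)) stop("stage labels missing")
    bad <- setdiff(unique(flags[!is.na(flags)]), stages)
    if (length(bad))
      stop("unknown stage label(s): ", paste(bad, collapse = ", "))
    firstStage <- as.character(flags)
  }
  counts <- setNames(integer(length(stages)), stages)
  tab <- table(factor(firstStage, levels = stages))
  counts[names(tab)] <- as.integer(tab)
  keep <- is.na(firstStage)
  ledger <- new("ExclusionLedger", initial = n, stages = counts,
                final = as.integer(sum(keep)))
  list(table = table[keep, , drop = FALSE], ledger = ledger)
}

#' @rdname wmskeleton-accessors
#' @export
setMethod("stageCounts", "ExclusionLedger", function(x) x@stages)

#' @rdname wmskeleton-accessors
#' @export
setMethod("initialCount", "ExclusionLedger", function(x) x@initial)

#' @rdname wmskeleton-accessors
#' @export
setMethod("finalCount", "ExclusionLedger", function(x) x@final)

setMethod("show", "ExclusionLedger", function(object) {
  cat(sprintf("ExclusionLedger: %d -> %d\n", object@initial, object@final))
  for (s in names(object@stages))
    cat(sprintf("  %-30s -%d\n", s, object@stages[[s]]))
})

#' Remove bivariate outliers by the k-SD rule
#'
#' Drops pairs where either value deviates from its variable's mean by more
#' than `k` standard deviations; mean and SD are computed once on the input
#' (not iteratively). A constant variable (SD = 0) removes nothing and
#' emits a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param k SD multiple (default 3.5).
#' @return list with filtered `x`, `y`, logical `keep`, and `removed`
#'   count.
#' @export
removeOutliers <- function(x, y, k = 3.5) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (k <= 0) stop("k must be positive")
  flag <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constant variable (SD = 0); no outliers removed on it")
      return(rep(FALSE, length(v)))
    }
    abs(v - mean(v)) > k * s
  }
  out <- flag(x) | flag(y)
  list(x = x[!out], y = y[!out], keep = !out, removed = sum(out))
}

#' Write a subject table as TSV / an exclusion ledger as JSON
#'
#' @param table subject table.
#' @param file output path.
#' @return the first argument, invisibly.
#' @export
writeSubjectTable <- function(table, file) {
  out <- table[, !startsWith(names(table), "."), drop = FALSE]
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' @rdname writeSubjectTable
#' @param ledger an [ExclusionLedger-class].
#' @export
writeExclusionLedger <- function(ledger, file) {
  jsonlite::write_json(
    list(initial = ledger@initial, stages = as.list(ledger@stages),
         final = ledger@final),
    file, auto_unbox = TRUE)
  invisible(ledger)
}
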