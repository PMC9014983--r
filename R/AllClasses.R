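#' @useDynLib wmskeleton, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aov chisq.test coef cor lm pchisq pf pt qt rbinom rnorm
#'   runif sd setNames var complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' SkeletonSpace: voxel grid and tract-skeleton mask
#'
#' Ties a 3D voxel grid (with a 4x4 voxel-to-world affine, mm) to the set of
#' skeleton voxels on which all statistics are computed. Skeleton voxels are
#' stored as sorted linear indices into the grid, which defines the
#' voxel-to-column bijection used by [MetricStack-class] and
#' [StatMap-class]. Optional integer tract labels (one per skeleton column,
#' 0 = unlabeled) support per-tract coverage summaries.
#'
#' @slot dim integer(3), grid shape.
#' @slot affine 4x4 voxel-to-world matrix (NIfTI convention, applied to
#'   0-based voxel indices).
#' @slot maskIdx sorted 1-based linear indices of the skeleton voxels.
#' @slot labels integer tract label per skeleton column (length 0 if
#'   unlabeled space).
#' @slot labelNames named character vector mapping label integers (names)
#'   to tract names.
#' @export
setClass("SkeletonSpace",
  slots = c(dim = "integer", affine = "matrix", maskIdx = "integer",
            labels = "integer", labelNames = "character"),
  prototype = prototype(labels = integer(0), labelNames = character(0)))

setValidity("SkeletonSpace", function(object) {
  msg <- character(0)
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  n <- prod(object@dim)
  if (length(object@maskIdx) < 1L)
    msg <- c(msg, "skeleton mask is empty")
  if (is.unsorted(object@maskIdx, strictly = TRUE))
    msg <- c(msg, "maskIdx must be strictly increasing")
  if (length(object@maskIdx) && (min(object@maskIdx) < 1L ||
      max(object@maskIdx) > n))
    msg <- c(msg, "maskIdx out of grid range")
  if (length(object@labels) &&
      length(object@labels) != length(object@maskIdx))
    msg <- c(msg, "labels must have one value per skeleton column")
  if (length(msg)) msg else TRUE
})

#' MetricStack: subjects-by-skeleton-voxels matrix of one DTI scalar
#'
#' Holds one scalar diffusion metric (FA, MD, RD or AD) sampled on the
#' skeleton for every subject; rows follow the subject table order.
#'
#' @slot metric one of "FA", "MD", "RD", "AD".
#' @slot values numeric matrix, subjects x skeleton columns.
#' @slot subjects character subject identifiers (row order).
#' @slot space the [SkeletonSpace-class] the columns refer to.
#' @export
setClass("MetricStack",
  slots = c(metric = "character", values = "matrix",
            subjects = "character", space = "SkeletonSpace"))

setValidity("MetricStack", function(object) {
  msg <- character(0)
  if (!object@metric %in% c("FA", "MD", "RD", "AD"))
    msg <- c(msg, "metric must be one of FA, MD, RD, AD")
  if (ncol(object@values) != length(object@space@maskIdx))
    msg <- c(msg, "value columns must match skeleton size")
  if (nrow(object@values) != length(object@subjects))
    msg <- c(msg, "rows must match subjects")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "undefined values inside the skeleton mask")
  if (object@metric == "FA" && length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 1))
    msg <- c(msg, "FA values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StatMap: one statistic value per skeleton voxel
#'
#' @slot values numeric, one per skeleton column.
#' @slot kind statistic kind: "t", "z", "tfce", "p" or "mean".
#' @slot direction contrast direction tag: "greater", "less" or "none".
#' @slot space the [SkeletonSpace-class].
#' @export
setClass("StatMap",
  slots = c(values = "numeric", kind = "character",
            direction = "character", space = "SkeletonSpace"),
  prototype = prototype(direction = "none"))

setValidity("StatMap", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@space@maskIdx))
    msg <- c(msg, "values must have one entry per skeleton column")
  if (!object@kind %in% c("t", "z", "tfce", "p", "mean"))
    msg <- c(msg, "kind must be t, z, tfce, p or mean")
  if (!object@direction %in% c("greater", "less", "none"))
    msg <- c(msg, "direction must be greater, less or none")
  if (object@kind == "p") {
    ok <- is.na(object@values) |
      (object@values > 0 & object@values <= 1)
    if (!all(ok)) msg <- c(msg, "p-kind values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' TFCEParams: threshold-free cluster enhancement settings
#'
#' @slot H height exponent (default 2, the TBSS convention).
#' @slot E extent exponent (default 1 for skeletonized data; 0.5 is the
#'   usual volumetric choice).
#' @slot steps number of integration steps (>= 10).
#' @slot connectivity voxel neighborhood: 6, 18 or 26.
#' @export
setClass("TFCEParams",
  slots = c(H = "numeric", E = "numeric", steps = "integer",
            connectivity = "integer"))

setValidity("TFCEParams", function(object) {
  msg <- character(0)
  if (object@H < 0 || object@E < 0)
    msg <- c(msg, "H and E must be non-negative")
  if (object@steps < 10L) msg <- c(msg, "steps must be at least 10")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: max-statistic permutation inference output
#'
#' @slot tMap observed t [StatMap-class].
#' @slot enhanced observed TFCE-enhanced [StatMap-class].
#' @slot pMap FWE-corrected p [StatMap-class].
#' @slot nullMax null sample of per-permutation maximum enhanced values
#'   (the identity permutation is entry 1).
#' @slot nPerm number of permutations (identity included).
#' @slot seed integer seed that generated the permutation order.
#' @slot scheme permutation scheme label.
#' @export
setClass("PermutationResult",
  slots = c(tMap = "StatMap", enhanced = "StatMap", pMap = "StatMap",
            nullMax = "numeric", nPerm = "integer", seed = "integer",
            scheme = "character"))

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (length(object@nullMax) != object@nPerm)
    msg <- c(msg, "null sample length must equal nPerm")
  p <- object@pMap@values
  if (any(p < 1 / object@nPerm - 1e-12 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p values must lie in [1/nPerm, 1]")
  if (length(msg)) msg else TRUE
})

#' MediationResult: voxelwise Sobel mediation output
#'
#' All per-voxel slots are indexed by the analysis mask columns.
#'
#' @slot space the [SkeletonSpace-class].
#' @slot mask integer skeleton column indices forming the analysis mask.
#' @slot a,sa standardized age-to-metric slope and its SE per mask voxel.
#' @slot b,sb standardized metric-to-outcome slope (controlling age) and SE.
#' @slot z Sobel z per mask voxel (NA where the voxel was degenerate).
#' @slot enhanced TFCE-enhanced z values on the mask.
#' @slot p FWE-corrected p per mask voxel.
#' @slot peak skeleton column index of the maximal enhanced mediation
#'   effect.
#' @slot nExcluded number of degenerate voxels excluded.
#' @slot direction which sign of the indirect effect was enhanced.
#' @slot scheme permutation null scheme ("mediator" or "outcome").
#' @slot nPerm,seed permutation count and seed.
#' @export
setClass("MediationResult",
  slots = c(space = "SkeletonSpace", mask = "integer", a = "numeric",
            sa = "numeric", b = "numeric", sb = "numeric", z = "numeric",
            enhanced = "numeric", p = "numeric", peak = "integer",
            nExcluded = "integer", direction = "character",
            scheme = "character", nPerm = "integer", seed = "integer"))

setValidity("MediationResult", function(object) {
  msg <- character(0)
  k <- length(object@mask)
  for (s in c("a", "sa", "b", "sb", "z", "enhanced", "p"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("slot %s must match the mask length", s))
  if (length(object@peak) == 1L && !object@peak %in% object@mask)
    msg <- c(msg, "peak voxel must belong to the analysis mask")
  if (length(msg)) msg else TRUE
})

#' ExclusionLedger: staged participant-exclusion bookkeeping
#'
#' @slot initial initial participant count.
#' @slot stages named integer vector of per-stage removal counts, in the
#'   declared stage order; a subject is counted at its first flagged stage.
#' @slot final remaining participant count.
#' @export
setClass("ExclusionLedger",
  slots = c(initial = "integer", stages = "integer", final = "integer"))

setValidity("ExclusionLedger", function(object) {
  msg <- character(0)
  if (any(object@stages < 0L) || object@initial < 0L || object@final < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (object@final != object@initial - sum(object@stages))
    msg <- c(msg, "final must equal initial minus the stage counts")
  if (length(msg)) msg else TRUE
})

#' CohortParams: synthetic aging-cohort generator settings
#'
#' See [cohortParams()] for field semantics and defaults.
#'
#' @slot nSubjects number of subjects.
#' @slot ageCohorts two-column matrix (age, weight); weights sum to 1.
#' @slot sexRatio proportion female in [0, 1].
#' @slot alleleFreqs named numeric(3): designated-allele frequency per locus.
#' @slot wmCeiling maximum working-memory accuracy.
#' @slot loadAgeSlopes named numeric(3): total standardized age effect on
#'   each working-memory condition.
#' @slot mediationSpec list(fracEffect, fracMediating, slopeAgeFA,
#'   slopeFAWM).
#' @slot noiseSD list of residual SDs: wm (score units, per condition),
#'   faVoxel (voxel-noise mixing weight), speed (per subscore), latent
#'   (latent factor SD).
#' @slot seed integer master seed.
#' @export
setClass("CohortParams",
  slots = c(nSubjects = "integer", ageCohorts = "matrix",
            sexRatio = "numeric", alleleFreqs = "numeric",
            wmCeiling = "numeric", loadAgeSlopes = "numeric",
            mediationSpec = "list", noiseSD = "list", seed = "integer"))

setValidity("CohortParams", function(object) {
  msg <- character(0)
  if (object@nSubjects < 2L)
    msg <- c(msg, "nSubjects must be at least 2")
  if (ncol(object@ageCohorts) != 2L || any(object@ageCohorts[, 2] < 0))
    msg <- c(msg, "ageCohorts must be an (age, weight >= 0) matrix")
  if (abs(sum(object@ageCohorts[, 2]) - 1) > 1e-8)
    msg <- c(msg, "cohort weights must sum to 1")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must lie in [0, 1]")
  if (length(object@alleleFreqs) != 3L ||
      any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
    msg <- c(msg, "alleleFreqs must be three values in (0, 1)")
  ms <- object@mediationSpec
  fr <- c(ms$fracEffect, ms$fracMediating)
  if (length(fr) != 2L || any(fr < 0 | fr > 1))
    msg <- c(msg, "mediation fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
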