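## Threshold-free cluster enhancement and max-statistic permutation
## inference with family-wise error corrected p-maps.

#' TFCE parameters
#'
#' Defaults follow the skeletonized-data convention: height exponent H = 2,
#' extent exponent E = 1, 100 integration steps, 26-neighborhood. For
#' volumetric (non-skeleton) maps E = 0.5 is the usual choice.
#'
#' @param H height exponent (>= 0).
#' @param E extent exponent (>= 0).
#' @param steps number of integration steps (>= 10).
#' @param connectivity 6, 18 or 26.
#' @return A [TFCEParams-class].
#' @export
tfceParams <- function(H = 2, E = 1, steps = 100L, connectivity = 26L) {
  new("TFCEParams", H = H, E = E, steps = as.integer(steps),
      connectivity = as.integer(connectivity))
}

setMethod("show", "TFCEParams", function(object) {
  cat(sprintf("TFCEParams: H = %g, E = %g, %d steps, %d-connectivity\n",
              object@H, object@E, object@steps, object@connectivity))
})

#' Threshold-free cluster enhancement
#'
#' Enhances a statistic map by integrating cluster extent and height over
#' all thresholds: for voxel v,
#' `sum over h of extent(h, v)^E * h^H * dh`, where extent(h, v) is the
#' size of the connected suprathreshold component containing v at height h
#' (connectivity restricted to the skeleton mask) and `dh = max(map)/steps`
#' unless a fixed `dh` is supplied. Negative input values are treated as
#' zero; direction is the caller's concern. An all-nonpositive map yields
#' an all-zero map.
#'
#' @param map a [StatMap-class] (or numeric vector of skeleton-column
#'   values).
#' @param space a [SkeletonSpace-class]; taken from `map` when it is a
#'   StatMap.
#' @param params a [TFCEParams-class].
#' @param dh optional fixed step height (overrides the map-maximum rule;
#'   used to compare maps on a shared threshold grid).
#' @return A [StatMap-class] of kind "tfce".
#' @export
tfceEnhance <- function(map, space = NULL, params = tfceParams(),
                        dh = NULL) {
  if (is(map, "StatMap")) {
    space <- map@space
    direction <- map@direction
    values <- map@values
  } else {
    direction <- "none"
    values <- as.numeric(map)
  }
  if (is.null(space)) stop("a SkeletonSpace is required")
  if (length(values) != nVoxels(space))
    stop("map length must match skeleton size")
  adj <- .skeletonAdjacency(space, params@connectivity)
  out <- cpp_tfce(values, adj$indptr, adj$indices, params@H, params@E,
                  params@steps, if (is.null(dh)) -1 else dh)
  statMap(out, "tfce", space, direction)
}

## internal: permutation index matrix, identity first, 0-based for C++
.permMatrix <- function(n, nPerm, seed, exact = FALSE) {
  if (exact && n <= 7L && factorial(n) <= nPerm) {
    allp <- .allPermutations(n)
    return(t(allp) - 1L)
  }
  set.seed(seed)
  P <- matrix(0L, n, nPerm)
  P[, 1] <- seq_len(n) - 1L
  for (j in 2:nPerm) P[, j] <- sample.int(n) - 1L
  P
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  # move identity to the front
  idx <- which(apply(out, 1, function(p) all(p == seq_len(n))))
  out[c(idx, setdiff(seq_len(nrow(out)), idx)), , drop = FALSE]
}

#' Max-statistic permutation FWE inference for a GLM contrast
#'
#' Fits the voxelwise GLM, enhances the directional t-map with TFCE, and
#' builds the null distribution of the maximum enhanced statistic by
#' Freedman-Lane permutation: residuals from the reduced (nuisance-only)
#' model are permuted, the full model is refitted, and the maximum
#' TFCE-enhanced value over the skeleton is recorded per permutation. The
#' identity permutation is always included as permutation 1, so the
#' FWE-corrected p-value `p(v) = #\{null max >= enhanced(v)\} / nPerm` has
#' floor 1/nPerm. Nuisance columns are those with zero contrast weight.
#' Each permuted map is enhanced with its own map-maximum step height,
#' matching standard practice.
#'
#' @param stack a [MetricStack-class].
#' @param design numeric design matrix (see [fitVoxelwiseGLM()]).
#' @param contrast contrast weights or a design column name.
#' @param params a [TFCEParams-class].
#' @param nPerm number of permutations (>= 100; fewer makes the null tail
#'   unstable).
#' @param seed integer seed (mandatory; permutation order is deterministic
#'   given the seed).
#' @param direction "greater" or "less".
#' @param exact use full enumeration when `factorial(n) <= nPerm`.
#' @return A [PermutationResult-class].
#' @export
permutationFWE <- function(stack, design, contrast, params = tfceParams(),
                           nPerm = 5000L, seed, direction = c("greater",
                                                              "less"),
                           exact = FALSE) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("a seed is required")
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be at least 100 (unstable tail)")
  X <- .checkDesign(design)
  if (is.character(contrast)) {
    cvec <- as.numeric(colnames(X) == contrast)
    if (!any(cvec != 0)) stop("unknown contrast column: ", contrast)
  } else cvec <- as.numeric(contrast)
  if (length(cvec) != ncol(X)) stop("contrast length must match design")
  if (direction == "less") cvec <- -cvec
  n <- nrow(stack@values)
  if (nrow(X) != n) stop("design rows must match stack subjects")

  nuisance <- which(cvec == 0) - 1L
  perms <- .permMatrix(n, nPerm, seed, exact)
  nPerm <- ncol(perms)
  adj <- .skeletonAdjacency(stack@space, params@connectivity)
  res <- cpp_perm_fwe(stack@values, X, cvec, nuisance, perms,
                      params@H, params@E, params@steps,
                      adj$indptr, adj$indices)
  p <- vapply(res$tfce, function(o) mean(res$nullmax >= o), numeric(1))
  new("PermutationResult",
      tMap = statMap(res$t, "t", stack@space, direction),
      enhanced = statMap(res$tfce, "tfce", stack@space, direction),
      pMap = statMap(p, "p", stack@space, direction),
      nullMax = as.numeric(res$nullmax), nPerm = nPerm,
      seed = as.integer(seed), scheme = "freedman-lane")
}

#' @rdname wmskeleton-accessors
#' @export
setMethod("nullMaxima", "PermutationResult", function(x) x@nullMax)

#' @rdname wmskeleton-accessors
#' @export
setMethod("fwePMap", "PermutationResult", function(x) x@pMap)

#' @rdname wmskeleton-accessors
#' @export
setMethod("tMap", "PermutationResult", function(x) x@tMap)

#' @rdname wmskeleton-accessors
#' @export
setMethod("enhancedMap", "PermutationResult", function(x) x@enhanced)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(paste0("PermutationResult (%s): %d voxels, %d permutations,",
                     " seed %d\n  min FWE p = %.4g, %d voxel(s) with",
                     " p < 0.05\n"),
              object@scheme, length(object@pMap@values), object@nPerm,
              object@seed, min(object@pMap@values),
              sum(object@pMap@values < 0.05)))
})

#' FWE-significant voxel set
#'
#' Voxels whose FWE-corrected p-value is strictly below `alpha`.
#'
#' @param result a [PermutationResult-class] (or a p-kind
#'   [StatMap-class]).
#' @param alpha significance level (default 0.05).
#' @return logical vector over skeleton columns.
#' @export
significantMask <- function(result, alpha = 0.05) {
  p <- if (is(result, "PermutationResult")) result@pMap@values
       else if (is(result, "StatMap") && result@kind == "p") result@values
       else stop("need a PermutationResult or a p-kind StatMap")
  p < alpha
}
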