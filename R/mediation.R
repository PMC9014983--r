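## Voxelwise Sobel mediation of the age -> white-matter -> working-memory
## path, with TFCE permutation inference and the change-in-effect summary.

#' Sobel z statistic for an indirect effect
#'
#' `z = (a * b) / sqrt(b^2 * s_a^2 + a^2 * s_b^2 + s_a^2 * s_b^2)`, where a
#' is the exposure-to-mediator slope, b the mediator-to-outcome slope, and
#' s_a, s_b their standard errors. The sign of z always equals the sign of
#' a * b. Vectorized over voxels.
#'
#' @param a,b path coefficients.
#' @param sa,sb their standard errors (non-negative).
#' @return Sobel z (numeric, same length as the inputs).
#' @examples
#' sobelZ(2, 3, 1, 1)   # 6 / sqrt(14)
#' @export
sobelZ <- function(a, b, sa, sb) {
  if (any(sa < 0 | sb < 0)) stop("standard errors must be non-negative")
  den2 <- b^2 * sa^2 + a^2 * sb^2 + sa^2 * sb^2
  bad <- den2 <= 0 & (a * b) != 0
  if (any(bad))
    stop("degenerate standard errors: zero denominator with nonzero a*b")
  ifelse(a * b == 0, 0, (a * b) / sqrt(den2))
}

#' Significant age-effect mask
#'
#' Runs the FWE permutation test for the (by default negative) age contrast
#' on the metric, controlling for the covariates, and returns the voxels
#' with FWE p < alpha. This mask restricts the mediation analysis to voxels
#' where age demonstrably affects the metric.
#'
#' @param stack a [MetricStack-class].
#' @param age numeric age per subject.
#' @param covariates numeric covariate matrix (e.g. sex) or NULL.
#' @param params a [TFCEParams-class].
#' @param nPerm,seed permutation settings.
#' @param direction age-contrast direction; "less" targets negative age
#'   effects.
#' @param alpha FWE level.
#' @return logical vector over skeleton columns (warns when empty).
#' @export
ageEffectMask <- function(stack, age, covariates = NULL,
                          params = tfceParams(), nPerm = 5000L, seed,
                          direction = "less", alpha = 0.05) {
  X <- cbind(intercept = 1, age = as.numeric(age), covariates)
  res <- permutationFWE(stack, X, "age", params, nPerm, seed, direction)
  mask <- significantMask(res, alpha)
  if (!any(mask))
    warning("empty age-effect mask; mediation analysis would be skipped")
  mask
}

#' Voxelwise Sobel mediation with TFCE permutation inference
#'
#' Tests, at every voxel of the analysis mask, whether the metric mediates
#' the association between an exposure (age) and an outcome (working
#' memory). The covariates are regressed out of the exposure, the outcome
#' and every voxel's metric; all three are then standardized so the path
#' coefficients are comparable across voxels. Per voxel, `a` (and S_a) come
#' from the OLS of the metric on the exposure, `b` (and S_b) from the OLS
#' of the outcome on the metric and exposure jointly, and the Sobel z
#' combines them. The z map (of the requested indirect-effect sign) is
#' TFCE-enhanced on the mask-restricted skeleton graph; FWE p-values follow
#' the max-statistic rule with the identity permutation included.
#'
#' Two permutation nulls are available. The default `"mediator"` scheme
#' permutes the subject rows of the residualized mediator stack against
#' exposure and outcome (implemented by jointly permuting exposure and
#' outcome), severing both mediated links while preserving the
#' exposure-outcome association: it tests the global null that the voxel
#' carries no signal, and is the scheme used by the standard voxelwise
#' mediation tooling. The `"outcome"` scheme instead permutes the
#' Freedman-Lane residuals of the outcome on the exposure, preserving both
#' the exposure-outcome association and the exposure-to-mediator path: it
#' is the calibrated test of the mediator-to-outcome (b) path at voxels
#' that already show a real exposure effect, i.e. exactly the voxels an
#' age-effect mask selects. Within an age-effect mask the mediator scheme
#' is anti-conservative for voxels with a real age path but no outcome
#' path; choose the scheme for the null you mean to reject.
#'
#' Voxels whose residualized metric is constant are excluded (z undefined)
#' and counted in `nExcluded`.
#'
#' @param stack a [MetricStack-class].
#' @param x exposure (age) per subject.
#' @param y outcome (working-memory score) per subject.
#' @param covariates numeric covariate matrix (e.g. sex) or NULL.
#' @param mask logical vector or integer skeleton column indices; from
#'   [ageEffectMask()].
#' @param params a [TFCEParams-class].
#' @param nPerm,seed permutation settings.
#' @param direction sign of the indirect effect to enhance: "negative"
#'   (age-related decline transmitted by the metric) or "positive".
#' @param nullScheme permutation null: "mediator" (default) or "outcome";
#'   see Details.
#' @return A [MediationResult-class].
#' @export
voxelwiseMediation <- function(stack, x, y, covariates = NULL, mask,
                               params = tfceParams(), nPerm = 5000L, seed,
                               direction = c("negative", "positive"),
                               nullScheme = c("mediator", "outcome")) {
  direction <- match.arg(direction)
  nullScheme <- match.arg(nullScheme)
  if (missing(seed)) stop("a seed is required")
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be at least 100 (unstable tail)")
  if (is.logical(mask)) mask <- which(mask)
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("analysis mask is empty")
  keep <- complete.cases(x, y,
                         if (is.null(covariates)) rep(TRUE, length(x))
                         else covariates)
  x <- as.numeric(x)[keep]
  y <- as.numeric(y)[keep]
  cov <- if (is.null(covariates)) NULL
         else as.matrix(covariates)[keep, , drop = FALSE]
  M <- stack@values[keep, mask, drop = FALSE]

  xr <- .std(residualize(x, cov))
  yr <- .std(residualize(y, cov))
  Mr <- residualize(M, cov)
  Mr <- apply(Mr, 2, .std)

  subSpace <- .maskedSpace(stack@space, mask)
  adj <- .skeletonAdjacency(subSpace, params@connectivity)
  perms <- .permMatrix(length(xr), nPerm, seed)
  dirSign <- if (direction == "negative") -1L else 1L
  res <- cpp_mediation_perm(Mr, xr, yr, perms, params@H, params@E,
                            params@steps, adj$indptr, adj$indices, dirSign,
                            if (nullScheme == "mediator") 0L else 1L)
  p <- vapply(res$tfce, function(o) mean(res$nullmax >= o), numeric(1))
  peak <- mask[which.max(res$tfce)]
  new("MediationResult", space = stack@space, mask = mask,
      a = res$a, sa = res$sa, b = res$b, sb = res$sb, z = res$z,
      enhanced = res$tfce, p = p, peak = as.integer(peak),
      nExcluded = sum(is.na(res$z)), direction = direction,
      scheme = nullScheme, nPerm = nPerm, seed = as.integer(seed))
}

## internal: skeleton space restricted to a column subset
.maskedSpace <- function(space, columns) {
  makeSkeletonSpace(space@dim, space@maskIdx[columns], space@affine)
}

#' @rdname wmskeleton-accessors
#' @export
setMethod("analysisMask", "MediationResult", function(x) x@mask)

#' @rdname wmskeleton-accessors
#' @export
setMethod("peakVoxel", "MediationResult", function(x) x@peak)

#' @rdname wmskeleton-accessors
#' @export
setMethod("fwePMap", "MediationResult", function(x) {
  v <- rep(NA_real_, nVoxels(x@space))
  v[x@mask] <- x@p
  statMap(v, "p", x@space)
})

#' @rdname wmskeleton-accessors
#' @export
setMethod("mediationPaths", "MediationResult", function(x) {
  data.frame(column = x@mask, a = x@a, sa = x@sa, b = x@b, sb = x@sb,
             z = x@z, enhanced = x@enhanced, p = x@p)
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf(paste0("MediationResult: %d mask voxels, %d permutations",
                     " (%s indirect effect, %s null)\n  peak column %d,",
                     " min FWE p = %.4g, %d voxel(s) with p < 0.05,",
                     " %d excluded\n"),
              length(object@mask), object@nPerm, object@direction,
              object@scheme, object@peak, min(object@p),
              sum(object@p < 0.05), object@nExcluded))
})

#' Change in explained outcome variance at the peak mediator
#'
#' Fits the outcome on age + sex (before) and on age + sex + metric
#' (after), and reports both r-squared values, the relative change
#' `(r2_after - r2_before) / r2_before`, and the age-coefficient t in both
#' models. Because the after-model nests the before-model, r2 can only
#' increase; what attenuates is the age coefficient and age's unique
#' (semipartial) contribution, which is reported alongside the literal
#' relative-change formula.
#'
#' @param y outcome (working-memory score).
#' @param age,sex subject covariates.
#' @param metricAtPeak per-subject metric at the peak mediation voxel.
#' @return list with `r2Before`, `r2After`, `relativeChange`, `ageTBefore`,
#'   `ageTAfter`, `ageUniqueBefore`, `ageUniqueAfter` (squared semipartial
#'   r2 of age) and `ageUniqueChange` (its relative drop).
#' @export
changeInEffect <- function(y, age, sex, metricAtPeak) {
  keep <- complete.cases(y, age, sex, metricAtPeak)
  d <- data.frame(y = y, age = age, sex = sex, m = metricAtPeak)[keep, ]
  if (sd(d$y) < 1e-12)
    stop("zero r-squared before mediation; relative change undefined")
  before <- lm(y ~ age + sex, data = d)
  after <- lm(y ~ age + sex + m, data = d)
  r2b <- summary(before)$r.squared
  r2a <- summary(after)$r.squared
  if (!is.finite(r2b) || r2b <= 1e-12)
    stop("zero r-squared before mediation; relative change undefined")
  tb <- summary(before)$coefficients["age", "t value"]
  ta <- summary(after)$coefficients["age", "t value"]
  # squared semipartial of age: r2 drop when age is removed from the model
  noAgeB <- lm(y ~ sex, data = d)
  noAgeA <- lm(y ~ sex + m, data = d)
  ub <- r2b - summary(noAgeB)$r.squared
  ua <- r2a - summary(noAgeA)$r.squared
  list(r2Before = r2b, r2After = r2a,
       relativeChange = (r2a - r2b) / r2b,
       ageTBefore = tb, ageTAfter = ta,
       ageUniqueBefore = ub, ageUniqueAfter = ua,
       ageUniqueChange = if (ub > 0) (ua - ub) / ub else NA_real_)
}
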