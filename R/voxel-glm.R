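## Voxelwise general linear models on skeleton metric stacks: directional
## t-maps, residualization, partial correlation, condition-pair slope
## contrasts and genotype / age-split group contrasts.

## internal: validate a design matrix, report collinear columns by name
.checkDesign <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Build a design matrix from a subject table
#'
#' Numeric columns enter as given; factors are expanded to treatment-coded
#' indicators. An intercept column is prepended unless disabled.
#'
#' @param table subject table (data.frame).
#' @param vars character column names to include.
#' @param intercept include an intercept column (default TRUE).
#' @return numeric design matrix with named columns.
#' @export
buildDesign <- function(table, vars, intercept = TRUE) {
  stopifnot(all(vars %in% names(table)))
  f <- stats::as.formula(paste("~", paste(c(
    if (!intercept) "0", vars), collapse = " + ")))
  X <- stats::model.matrix(f, data = table[, vars, drop = FALSE])
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  .checkDesign(X)
}

#' Voxelwise GLM t-map
#'
#' Fits an ordinary least-squares model at every skeleton voxel and returns
#' the t-statistic of the given contrast, with residual df = n - p. The
#' sign is oriented so that positive t favors the requested direction.
#'
#' @param stack a [MetricStack-class].
#' @param design numeric design matrix (subjects x predictors), intercept
#'   included as a column if wanted.
#' @param contrast numeric contrast weights, one per design column (or the
#'   name of a single design column).
#' @param direction "greater" (positive association favored) or "less".
#' @return A [StatMap-class] of kind "t".
#' @export
fitVoxelwiseGLM <- function(stack, design, contrast,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  X <- .checkDesign(design)
  Y <- stack@values
  n <- nrow(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match stack subjects")
  if (n <= p + 1L) stop("need more subjects than predictors")
  if (is.character(contrast)) {
    cvec <- as.numeric(colnames(X) == contrast)
    if (!any(cvec != 0)) stop("unknown contrast column: ", contrast)
  } else {
    cvec <- as.numeric(contrast)
  }
  if (length(cvec) != p) stop("contrast length must match design columns")
  if (all(cvec == 0)) stop("contrast must not be all zero")

  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  cb <- drop(crossprod(cvec, B))
  rss <- colSums(Y^2) - colSums(B * crossprod(X, Y))
  sigma2 <- pmax(rss, 0) / (n - p)
  cXc <- drop(crossprod(cvec, XtXinv %*% cvec))
  se <- sqrt(sigma2 * cXc)
  t <- ifelse(se > 0, cb / se, 0)
  if (direction == "less") t <- -t
  statMap(t, "t", stack@space, direction)
}

#' Residualize a vector on covariates
#'
#' Returns the values minus their OLS fit on the covariates (an intercept
#' is always included), so the residuals are orthogonal to every covariate
#' column and mean-centered.
#'
#' @param values numeric vector (or subjects x k matrix, residualized
#'   column-wise).
#' @param covariates numeric matrix of covariates (may be NULL for
#'   intercept-only centering).
#' @return residual vector (or matrix).
#' @export
residualize <- function(values, covariates = NULL) {
  X <- cbind(intercept = rep(1, NROW(values)), covariates)
  X <- .checkDesign(X)
  r <- as.matrix(values) - X %*% qr.coef(qr(X), as.matrix(values))
  if (is.null(dim(values))) drop(r) else r
}

#' Partial correlation given covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after both are
#' regressed on the covariates (with intercept).
#'
#' @param x,y numeric vectors.
#' @param covariates numeric covariate matrix or NULL.
#' @return correlation coefficient.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("zero-variance residual; partial correlation undefined")
  cor(rx, ry)
}

#' Condition-pair slope comparison map
#'
#' Regresses the metric on both (standardized) condition scores plus
#' covariates at every voxel and returns the t-map of the slope-difference
#' contrast (A minus B). Standardizing the scores makes the slopes
#' comparable across conditions.
#'
#' @param stack a [MetricStack-class].
#' @param scoresA,scoresB numeric condition scores (complete for all
#'   subjects).
#' @param covariates numeric covariate matrix or NULL.
#' @param direction "greater": positive t where A's slope exceeds B's.
#' @return A [StatMap-class] of kind "t".
#' @export
compareConditionSlopes <- function(stack, scoresA, scoresB,
                                   covariates = NULL,
                                   direction = c("greater", "less")) {
  direction <- match.arg(direction)
  dAB <- scoresA - scoresB
  if (sd(dAB) < 1e-12)
    stop("condition scores are identical; slope difference undefined")
  zA <- .std(scoresA)
  zB <- .std(scoresB)
  X <- cbind(intercept = 1, scoreA = zA, scoreB = zB, covariates)
  cvec <- c(0, 1, -1, rep(0, ncol(X) - 3L))
  fitVoxelwiseGLM(stack, X, cvec, direction)
}

#' Group contrast map (genotype or age-split groups)
#'
#' Indicator-coded GLM comparing two group levels, controlling for
#' covariates; optionally adds a group x stratum product term and tests the
#' interaction instead (the age-split-by-genotype analysis).
#'
#' @param stack a [MetricStack-class].
#' @param group factor of group labels per subject.
#' @param pair character(2): the two levels to compare (level1 minus
#'   level2).
#' @param covariates numeric covariate matrix or NULL.
#' @param interactionWith optional second binary factor (e.g. the age
#'   split); when given, the returned t-map tests the pair-difference x
#'   stratum product term.
#' @param direction "greater" or "less".
#' @return A [StatMap-class] of kind "t". Subjects outside the two levels
#'   are dropped (listwise per model).
#' @export
groupContrast <- function(stack, group, pair, covariates = NULL,
                          interactionWith = NULL,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  group <- as.factor(group)
  if (!all(pair %in% levels(group))) stop("pair levels not found in group")
  keep <- group %in% pair & !is.na(group)
  if (!is.null(interactionWith)) keep <- keep & !is.na(interactionWith)
  if (sum(group[keep] == pair[1]) < 3L || sum(group[keep] == pair[2]) < 3L)
    stop("both groups need at least 3 subjects")
  ind <- as.numeric(group[keep] == pair[1])
  Y <- stack@values[keep, , drop = FALSE]
  sub <- metricStack(stack@metric, Y, stack@space, stack@subjects[keep])
  cov <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE]
  if (is.null(interactionWith)) {
    X <- cbind(intercept = 1, group = ind, cov)
    cvec <- c(0, 1, rep(0, ncol(X) - 2L))
  } else {
    strat <- as.numeric(as.factor(interactionWith[keep])) - 1
    X <- cbind(intercept = 1, group = ind, stratum = strat,
               group_x_stratum = ind * strat, cov)
    cvec <- c(0, 0, 0, 1, rep(0, ncol(X) - 4L))
  }
  fitVoxelwiseGLM(sub, X, cvec, direction)
}
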