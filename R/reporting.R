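## Summary statistics: Hardy-Weinberg tests, slice profiles, tract
## coverage, cross-metric overlap, and demographic group tests.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' From genotype counts (designated homozygote, heterozygote, other
#' homozygote), estimates the designated-allele frequency
#' `p = (2 * hom1 + het) / (2n)`, computes the expected Hardy-Weinberg
#' counts (n p^2, 2 n p q, n q^2) and the 1-df chi-square
#' `sum((obs - exp)^2 / exp)` without continuity correction.
#'
#' @param counts integer(3): designated homozygote, heterozygote, other
#'   homozygote. A named vector keeps its names in the output.
#' @return list with `chisq`, `df`, `pValue`, `alleleFreq` (designated
#'   allele), `expected`.
#' @examples
#' hweTest(c(GG = 208, GA = 93, AA = 14))  # chisq 0.75, A freq 0.19
#' @export
hweTest <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be three non-negative genotype counts")
  n <- sum(counts)
  if (n < 2) stop("need at least 2 genotyped subjects")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) stop("zero expected count; test undefined")
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, df = 1L,
       pValue = pchisq(chisq, 1L, lower.tail = FALSE),
       alleleFreq = p, expected = expected)
}

#' Slice profile of a statistic map
#'
#' Averages the map over skeleton voxels within each slice along a grid
#' axis (e.g. the anterior-posterior or inferior-superior axis of the
#' stored orientation), the summary used to look for spatial gradients.
#' Slices without skeleton voxels are undefined (NA).
#'
#' @param map a [StatMap-class].
#' @param axis 1, 2 or 3 (or "x", "y", "z").
#' @return data.frame with `slice`, `mean` and skeleton voxel count `n`
#'   per slice; length equals the grid extent along the axis.
#' @export
sliceProfile <- function(map, axis) {
  if (is.character(axis))
    axis <- match(tolower(axis), c("x", "y", "z"))
  if (!axis %in% 1:3 || is.na(axis)) stop("axis must be 1, 2 or 3")
  space <- map@space
  co <- voxelCoords(space)[, axis]
  extent <- space@dim[axis]
  n <- tabulate(co, nbins = extent)
  s <- vapply(seq_len(extent), function(k) {
    v <- map@values[co == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(slice = seq_len(extent), mean = s, n = n)
}

#' Tract coverage of a significant voxel set
#'
#' For every tract label, the percentage of that tract's skeleton voxels
#' contained in the significant set, plus the whole-skeleton percentage.
#'
#' @param significant logical vector over skeleton columns (or integer
#'   column indices).
#' @param space a labeled [SkeletonSpace-class].
#' @return data.frame with `tract`, `label`, `nVoxels`, `nSignificant`,
#'   `percent`; the first row is the whole skeleton.
#' @export
tractCoverage <- function(significant, space) {
  if (!length(space@labels)) stop("space has no tract labels")
  v <- nVoxels(space)
  sig <- if (is.logical(significant)) significant
         else seq_len(v) %in% as.integer(significant)
  labs <- sort(unique(space@labels[space@labels > 0L]))
  nm <- space@labelNames
  rows <- lapply(labs, function(l) {
    inTract <- space@labels == l
    data.frame(
      tract = if (as.character(l) %in% names(nm)) nm[[as.character(l)]]
              else paste0("label_", l),
      label = l, nVoxels = sum(inTract),
      nSignificant = sum(sig & inTract),
      percent = 100 * sum(sig & inTract) / sum(inTract))
  })
  rbind(data.frame(tract = "whole_skeleton", label = 0L, nVoxels = v,
                   nSignificant = sum(sig), percent = 100 * sum(sig) / v),
        do.call(rbind, rows))
}

#' Cross-metric overlap of significant voxels
#'
#' Assigns every voxel significant in at least one metric to its exact
#' combination of metrics (the 2^k - 1 cells of the union) and returns the
#' proportion of the union in each nonempty cell; proportions sum to 1.
#'
#' @param pMaps named list of p-kind [StatMap-class] objects on one
#'   shared space (e.g. FA, MD, RD, AD).
#' @param alpha significance level (strict <).
#' @return data.frame with `combination`, `nVoxels`, `proportion`.
#' @export
metricOverlap <- function(pMaps, alpha = 0.05) {
  if (is.null(names(pMaps)) || any(names(pMaps) == ""))
    stop("pMaps must be a named list")
  spaces <- lapply(pMaps, function(m) list(m@space@dim, m@space@maskIdx))
  if (!all(vapply(spaces, identical, logical(1), spaces[[1]])))
    stop("all maps must share one skeleton space")
  sig <- vapply(pMaps, function(m) m@values < alpha,
                logical(length(pMaps[[1]]@values)))
  anySig <- rowSums(sig, na.rm = TRUE) > 0
  if (!any(anySig))
    return(data.frame(combination = character(0), nVoxels = integer(0),
                      proportion = numeric(0)))
  combo <- apply(sig[anySig, , drop = FALSE], 1, function(r)
    paste(names(pMaps)[which(r)], collapse = "+"))
  tab <- table(combo)
  data.frame(combination = names(tab), nVoxels = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             row.names = NULL)
}

#' Demographic group tests
#'
#' One-way ANOVA F for each numeric variable across the groups and a
#' contingency chi-square (no continuity correction) for sex-by-group,
#' the statistics reported in genotype demographic tables.
#'
#' @param table subject table.
#' @param grouping name of the grouping column (factor).
#' @param numericVars numeric column names to test (default: all numeric
#'   columns except the hidden ones and sex).
#' @param sexVar name of the sex column (NULL to skip).
#' @return data.frame with `variable`, `statistic` ("F" or "chisq"),
#'   `value`, `df1`, `df2`, `pValue`.
#' @export
demographicTests <- function(table, grouping, numericVars = NULL,
                             sexVar = "sex") {
  g <- droplevels(as.factor(table[[grouping]]))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 2L))
    stop("each group needs at least 2 subjects for the F test")
  if (is.null(numericVars)) {
    numericVars <- names(table)[vapply(table, is.numeric, logical(1))]
    numericVars <- setdiff(numericVars,
                           c(sexVar, grouping,
                             names(table)[startsWith(names(table), ".")]))
  }
  rows <- lapply(numericVars, function(v) {
    fit <- aov(table[[v]] ~ g)
    s <- summary(fit)[[1]]
    data.frame(variable = v, statistic = "F", value = s[["F value"]][1],
               df1 = s[["Df"]][1], df2 = s[["Df"]][2],
               pValue = s[["Pr(>F)"]][1])
  })
  out <- do.call(rbind, rows)
  if (!is.null(sexVar) && sexVar %in% names(table)) {
    ct <- chisq.test(base::table(table[[sexVar]], g), correct = FALSE)
    out <- rbind(out, data.frame(
      variable = sexVar, statistic = "chisq",
      value = unname(ct$statistic), df1 = unname(ct$parameter),
      df2 = NA_real_, pValue = ct$p.value))
  }
  out
}
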