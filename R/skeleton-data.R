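## Data model and I/O for skeletonized scalar maps.

#' Construct a SkeletonSpace
#'
#' @param dim integer(3) grid shape.
#' @param mask logical array of `dim` (or linear indices) marking skeleton
#'   voxels.
#' @param affine 4x4 voxel-to-world matrix; defaults to identity spacing.
#' @param labels optional integer tract label per skeleton column
#'   (0 = unlabeled), or a full-grid integer array sampled at mask voxels.
#' @param labelNames optional named character vector mapping label integers
#'   to tract names.
#' @return A [SkeletonSpace-class].
#' @examples
#' sp <- makeSkeletonSpace(c(4, 4, 3), array(TRUE, c(4, 4, 3)))
#' nVoxels(sp)
#' @export
makeSkeletonSpace <- function(dim, mask, affine = NULL, labels = NULL,
                              labelNames = character(0)) {
  dim <- as.integer(dim)
  if (is.null(affine)) affine <- diag(4)
  if (is.array(mask) || is.logical(mask)) {
    if (!is.logical(mask)) stop("mask array must be logical")
    idx <- which(as.vector(mask))
  } else {
    idx <- sort(unique(as.integer(mask)))
  }
  if (length(idx) == 0L) stop("skeleton mask is empty")
  if (!is.null(labels) && is.array(labels))
    labels <- as.integer(labels)[idx]
  new("SkeletonSpace", dim = dim, affine = affine,
      maskIdx = as.integer(idx),
      labels = if (is.null(labels)) integer(0) else as.integer(labels),
      labelNames = labelNames)
}

#' Synthetic box-shaped skeleton space
#'
#' A solid rectangular grid whose voxels are all skeleton voxels, with
#' columns contiguous in space. Used by the simulation modules, where
#' planted effect clusters must be spatially connected.
#'
#' @param dim integer(3) grid shape.
#' @param affine optional 4x4 affine (default 1 mm identity).
#' @param nLabels optional number of equal-sized synthetic "tract" labels
#'   to partition the skeleton into.
#' @return A [SkeletonSpace-class].
#' @export
syntheticSkeletonSpace <- function(dim, affine = NULL, nLabels = 0L) {
  dim <- as.integer(dim)
  mask <- array(TRUE, dim)
  labels <- NULL
  labelNames <- character(0)
  if (nLabels > 0L) {
    v <- prod(dim)
    labels <- as.integer(cut(seq_len(v), breaks = nLabels, labels = FALSE))
    labels <- array(labels, dim)
    labelNames <- setNames(paste0("tract_", seq_len(nLabels)),
                           seq_len(nLabels))
  }
  makeSkeletonSpace(dim, mask, affine, labels, labelNames)
}

## ---- accessors ----

#' @rdname wmskeleton-accessors
#' @export
setMethod("nVoxels", "SkeletonSpace", function(x) length(x@maskIdx))

#' @rdname wmskeleton-accessors
#' @export
setMethod("gridDim", "SkeletonSpace", function(x) x@dim)

#' @rdname wmskeleton-accessors
#' @export
setMethod("spaceAffine", "SkeletonSpace", function(x) x@affine)

#' @rdname wmskeleton-accessors
#' @export
setMethod("skeletonMask", "SkeletonSpace", function(x) {
  m <- array(FALSE, x@dim)
  m[x@maskIdx] <- TRUE
  m
})

#' @rdname wmskeleton-accessors
#' @param zeroBased return 0-based voxel indices (NIfTI convention).
#' @param ... passed between methods.
#' @export
setMethod("voxelCoords", "SkeletonSpace", function(x, zeroBased = FALSE,
                                                   ...) {
  co <- arrayInd(x@maskIdx, x@dim)
  colnames(co) <- c("i", "j", "k")
  if (zeroBased) co - 1L else co
})

#' @rdname wmskeleton-accessors
#' @export
setMethod("tractLabels", "SkeletonSpace", function(x) x@labels)

#' @rdname wmskeleton-accessors
#' @export
setMethod("labelNames", "SkeletonSpace", function(x) x@labelNames)

setMethod("show", "SkeletonSpace", function(object) {
  cat(sprintf("SkeletonSpace: %s grid, %d skeleton voxels%s\n",
              paste(object@dim, collapse = " x "),
              length(object@maskIdx),
              if (length(object@labels))
                sprintf(", %d tract labels",
                        length(unique(object@labels[object@labels > 0L])))
              else ""))
})

#' Voxel/column bijection
#'
#' `columnOf` maps voxel coordinates (rows of a matrix, 1-based) to skeleton
#' column indices; `coordsOf` is its inverse. Voxels outside the skeleton
#' map to `NA`.
#'
#' @param space a [SkeletonSpace-class].
#' @param coords integer matrix with 3 columns (1-based voxel indices).
#' @param columns integer skeleton column indices.
#' @return `columnOf`: integer column per row; `coordsOf`: coordinate matrix.
#' @export
columnOf <- function(space, coords) {
  coords <- matrix(as.integer(coords), ncol = 3)
  lin <- coords[, 1] + space@dim[1] * (coords[, 2] - 1L) +
    space@dim[1] * space@dim[2] * (coords[, 3] - 1L)
  match(lin, space@maskIdx)
}

#' @rdname columnOf
#' @export
coordsOf <- function(space, columns) {
  co <- arrayInd(space@maskIdx[columns], space@dim)
  colnames(co) <- c("i", "j", "k")
  co
}

## ---- MetricStack ----

#' Construct a MetricStack
#'
#' @param metric one of "FA", "MD", "RD", "AD".
#' @param values numeric matrix, subjects x skeleton columns.
#' @param space a [SkeletonSpace-class].
#' @param subjects character subject identifiers; defaults to rownames or
#'   "s1".."sn".
#' @return A [MetricStack-class].
#' @export
metricStack <- function(metric, values, space, subjects = NULL) {
  values <- as.matrix(values)
  if (is.null(subjects))
    subjects <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  new("MetricStack", metric = metric, values = values,
      subjects = as.character(subjects), space = space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname wmskeleton-accessors
#' @export
setMethod("nSubjects", "MetricStack", function(x) nrow(x@values))

#' @rdname wmskeleton-accessors
#' @export
setMethod("nVoxels", "MetricStack", function(x) ncol(x@values))

#' @rdname wmskeleton-accessors
#' @export
setMethod("metricName", "MetricStack", function(x) x@metric)

#' @rdname wmskeleton-accessors
#' @export
setMethod("metricValues", "MetricStack", function(x) x@values)

#' @rdname wmskeleton-accessors
#' @export
setMethod("subjectIds", "MetricStack", function(x) x@subjects)

#' @rdname wmskeleton-accessors
#' @export
setMethod("skeletonSpace", "MetricStack", function(x) x@space)

setMethod("show", "MetricStack", function(object) {
  cat(sprintf("MetricStack (%s): %d subjects x %d skeleton voxels\n",
              object@metric, nrow(object@values), ncol(object@values)))
})

## ---- StatMap ----

#' Construct a StatMap
#'
#' @param values numeric, one per skeleton column.
#' @param kind "t", "z", "tfce", "p" or "mean".
#' @param space a [SkeletonSpace-class].
#' @param direction "greater", "less" or "none".
#' @return A [StatMap-class].
#' @export
statMap <- function(values, kind, space, direction = "none") {
  new("StatMap", values = as.numeric(values), kind = kind,
      direction = direction, space = space)
}

#' @rdname wmskeleton-accessors
#' @export
setMethod("statValues", "StatMap", function(x) x@values)

#' @rdname wmskeleton-accessors
#' @export
setMethod("statKind", "StatMap", function(x) x@kind)

#' @rdname wmskeleton-accessors
#' @export
setMethod("statDirection", "StatMap", function(x) x@direction)

#' @rdname wmskeleton-accessors
#' @export
setMethod("skeletonSpace", "StatMap", function(x) x@space)

#' @rdname wmskeleton-accessors
#' @export
setMethod("nVoxels", "StatMap", function(x) length(x@values))

setMethod("show", "StatMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("StatMap (%s%s): %d voxels, range [%.4g, %.4g]\n",
              object@kind,
              if (object@direction != "none")
                paste0(", ", object@direction) else "",
              length(object@values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

## ---- DTI scalar computation ----

#' DTI scalar maps from tensor eigenvalues
#'
#' Computes the four standard diffusion-tensor scalars from the sorted
#' eigenvalues (lambda1 >= lambda2 >= lambda3) of each voxel:
#' MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2, and
#' FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2)).
#' An all-zero tensor has undefined anisotropy; its FA is set to 0 by
#' convention (matching common tooling) with a warning.
#'
#' @param eigenvalues numeric matrix with 3 columns (l1, l2, l3), one row
#'   per voxel, or a length-3 vector for a single voxel.
#' @return data.frame with columns FA, MD, RD, AD.
#' @examples
#' dtiScalars(c(1.7, 0.3, 0.3))
#' @export
dtiScalars <- function(eigenvalues) {
  ev <- matrix(as.numeric(eigenvalues), ncol = 3,
               byrow = is.null(dim(eigenvalues)) &&
                 length(eigenvalues) == 3)
  if (any(!is.finite(ev))) stop("eigenvalues must be finite")
  if (any(ev[, 1] < ev[, 2] - 1e-12 | ev[, 2] < ev[, 3] - 1e-12))
    stop("eigenvalues must be sorted: lambda1 >= lambda2 >= lambda3")
  md <- rowMeans(ev)
  ad <- ev[, 1]
  rd <- (ev[, 2] + ev[, 3]) / 2
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- numeric(nrow(ev))
  zero <- den <= 0
  if (any(zero))
    warning(sum(zero), " all-zero tensor(s); FA set to 0 by convention")
  fa[!zero] <- sqrt(1.5) * num[!zero] / den[!zero]
  fa <- pmin(pmax(fa, 0), 1)
  data.frame(FA = fa, MD = md, RD = rd, AD = ad)
}

#' Skeleton mask from a mean FA map
#'
#' Thresholds a mean FA skeleton image: a voxel enters the mask where the
#' mean FA is strictly greater than `threshold` (default 0.2, the TBSS
#' convention).
#'
#' @param meanFA numeric 3D array on the full grid.
#' @param threshold strict lower FA cutoff.
#' @param affine optional 4x4 affine for the resulting space.
#' @return A [SkeletonSpace-class].
#' @export
skeletonMaskFromMean <- function(meanFA, threshold = 0.2, affine = NULL) {
  if (length(dim(meanFA)) != 3L) stop("meanFA must be a 3D array")
  mask <- meanFA > threshold
  if (!any(mask)) stop("no voxels exceed the FA threshold (strict >)")
  makeSkeletonSpace(dim(meanFA), mask, affine)
}

#' Per-subject mean over the skeleton
#'
#' Arithmetic mean of a subject's metric over all skeleton columns, the
#' whole-skeleton summary used for scatter plots against behavior.
#'
#' @param stack a [MetricStack-class].
#' @return named numeric, one value per subject.
#' @export
meanSkeletonMetric <- function(stack) {
  stopifnot(is(stack, "MetricStack"))
  setNames(rowMeans(stack@values), stack@subjects)
}

## ---- volume mapping and NIfTI I/O ----

#' Expand skeleton-column values into a full 3D volume
#'
#' @param values numeric, one per skeleton column (or a [StatMap-class]).
#' @param space a [SkeletonSpace-class] (ignored when `values` is a StatMap).
#' @param fill value used outside the skeleton.
#' @return numeric 3D array.
#' @export
mapToVolume <- function(values, space = NULL, fill = 0) {
  if (is(values, "StatMap")) {
    space <- values@space
    values <- values@values
  }
  vol <- array(fill, space@dim)
  vol[space@maskIdx] <- values
  vol
}

#' Sample a full 3D volume at the skeleton columns
#'
#' @param volume numeric 3D (or 4D, subject last) array.
#' @param space a [SkeletonSpace-class].
#' @return numeric vector (3D input) or subjects x voxels matrix (4D).
#' @export
volumeToColumns <- function(volume, space) {
  d <- dim(volume)
  if (length(d) == 3L) {
    if (!all(d == space@dim)) stop("volume grid does not match space")
    return(as.vector(volume)[space@maskIdx])
  }
  if (length(d) != 4L || !all(d[1:3] == space@dim))
    stop("volume grid does not match space")
  nsub <- d[4]
  m <- matrix(as.vector(volume), nrow = prod(d[1:3]))[space@maskIdx, ,
                                                      drop = FALSE]
  t(m)
}

.asNiftiWithAffine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Read and write skeleton spaces, metric stacks, and stat maps as NIfTI
#'
#' Masks are written as 3D uint-like volumes (0/1), metric stacks as 4D
#' volumes with the subject as fourth axis, and stat maps as 3D volumes
#' that are zero outside the skeleton. Tract labels travel as an integer
#' 3D volume plus a JSON name table.
#'
#' @param space a [SkeletonSpace-class].
#' @param maskFile,labelFile,labelNamesFile NIfTI / JSON paths.
#' @return `readSkeletonSpace` returns a [SkeletonSpace-class]; writers
#'   return their first argument invisibly.
#' @export
writeSkeletonSpace <- function(space, maskFile, labelFile = NULL,
                               labelNamesFile = NULL) {
  m <- array(0, space@dim)
  m[space@maskIdx] <- 1
  RNifti::writeNifti(.asNiftiWithAffine(m, space@affine), maskFile)
  if (!is.null(labelFile) && length(space@labels)) {
    lv <- array(0L, space@dim)
    lv[space@maskIdx] <- space@labels
    RNifti::writeNifti(.asNiftiWithAffine(lv, space@affine), labelFile)
    if (!is.null(labelNamesFile))
      jsonlite::write_json(as.list(space@labelNames), labelNamesFile,
                           auto_unbox = TRUE)
  }
  invisible(space)
}

#' @rdname writeSkeletonSpace
#' @export
readSkeletonSpace <- function(maskFile, labelFile = NULL,
                              labelNamesFile = NULL) {
  img <- RNifti::readNifti(maskFile)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  mask <- array(as.vector(img) > 0.5, dim(img))
  labels <- NULL
  labelNames <- character(0)
  if (!is.null(labelFile)) {
    lv <- RNifti::readNifti(labelFile)
    labels <- array(as.integer(round(as.vector(lv))), dim(lv))
    if (!is.null(labelNamesFile)) {
      ln <- jsonlite::read_json(labelNamesFile)
      labelNames <- setNames(as.character(unlist(ln)), names(ln))
    }
  }
  makeSkeletonSpace(dim(img), mask, affine, labels, labelNames)
}

#' @rdname writeSkeletonSpace
#' @param stack a [MetricStack-class].
#' @param file NIfTI path.
#' @export
writeMetricStack <- function(stack, file) {
  space <- stack@space
  vol <- array(0, c(space@dim, nrow(stack@values)))
  npergrid <- prod(space@dim)
  for (s in seq_len(nrow(stack@values)))
    vol[(s - 1L) * npergrid + space@maskIdx] <- stack@values[s, ]
  RNifti::writeNifti(.asNiftiWithAffine(vol, space@affine), file)
  invisible(stack)
}

#' @rdname writeSkeletonSpace
#' @param metric metric name for the stack being read.
#' @param subjects optional subject ids for the stack being read.
#' @export
readMetricStack <- function(file, space, metric, subjects = NULL) {
  img <- RNifti::readNifti(file)
  vals <- volumeToColumns(array(as.vector(img), dim(img)), space)
  metricStack(metric, vals, space, subjects)
}

#' @rdname writeSkeletonSpace
#' @param map a [StatMap-class].
#' @export
writeStatMap <- function(map, file) {
  RNifti::writeNifti(
    .asNiftiWithAffine(mapToVolume(map), map@space@affine), file)
  invisible(map)
}

#' @rdname writeSkeletonSpace
#' @param kind statistic kind for the map being read.
#' @param direction direction tag for the map being read.
#' @export
readStatMap <- function(file, space, kind, direction = "none") {
  img <- RNifti::readNifti(file)
  statMap(volumeToColumns(array(as.vector(img), dim(img)), space),
          kind, space, direction)
}

## internal: CSR adjacency of the skeleton graph
.skeletonAdjacency <- function(space, connectivity) {
  cpp_adjacency(voxelCoords(space), space@dim, as.integer(connectivity))
}
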