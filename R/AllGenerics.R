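#' @name wmskeleton-accessors
#' @title Accessors for wmskeleton S4 containers
#' @description Slot accessors for the package's data classes. Accessors are
#'   the supported interface; slot access is internal.
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @return The slot value described by each accessor.
NULL

#' @rdname wmskeleton-accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("spaceAffine", function(x) standardGeneric("spaceAffine"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("voxelCoords", function(x, ...) standardGeneric("voxelCoords"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("tractLabels", function(x) standardGeneric("tractLabels"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("statKind", function(x) standardGeneric("statKind"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("statDirection", function(x) standardGeneric("statDirection"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("skeletonSpace", function(x) standardGeneric("skeletonSpace"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("nullMaxima", function(x) standardGeneric("nullMaxima"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("fwePMap", function(x) standardGeneric("fwePMap"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("enhancedMap", function(x) standardGeneric("enhancedMap"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("peakVoxel", function(x) standardGeneric("peakVoxel"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("mediationPaths", function(x) standardGeneric("mediationPaths"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("initialCount", function(x) standardGeneric("initialCount"))

#' @rdname wmskeleton-accessors
#' @export
setGeneric("finalCount", function(x) standardGeneric("finalCount"))
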