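#' Extract the voxel array of an image-like object
#'
#' @param x A \linkS4class{VolumeImage}, \linkS4class{LabelAtlas} or
#'   \linkS4class{StatMap}.
#' @return For `voxels()`, the underlying 3-D array; for `voxelSize()`, the
#'   voxel edge lengths in millimetres.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Region metadata accessors for a label atlas
#'
#' @param x A \linkS4class{LabelAtlas}.
#' @return `regionNames()` returns the label-to-name map (character vector
#'   named by integer label); `referenceRegion()` the name of the reference
#'   region; `regionSizes()` the voxel count of each region.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname regionNames
#' @export
setGeneric("referenceRegion", function(x) standardGeneric("referenceRegion"))

#' @rdname regionNames
#' @export
setGeneric("regionSizes", function(x) standardGeneric("regionSizes"))

#' Accessors for phantom ground truth
#'
#' @param x A \linkS4class{PhantomTruth}.
#' @return `truthTable()` returns the long data frame of true regional uptake;
#'   `subjectTable()` the per-subject covariate/outcome table.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' Accessors for voxelwise statistic maps
#'
#' @param x A \linkS4class{StatMap}.
#' @return The requested 3-D statistic array (`tValues`, `zValues`,
#'   `dValues`), the analysis mask (`maskArray`), or the paired-t degrees of
#'   freedom (`statDf`).
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname tValues
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname tValues
#' @export
setGeneric("dValues", function(x) standardGeneric("dValues"))

#' @rdname tValues
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname tValues
#' @export
setGeneric("statDf", function(x) standardGeneric("statDf"))
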