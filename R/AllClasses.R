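#' @include AllGenerics.R
#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib longpet, .registration = TRUE
NULL

#' VolumeImage: a 3-D scalar brain image
#'
#' The elementary container all PET arithmetic operates on: a 3-D numeric
#' array of tracer uptake (or SUVR) values together with the physical voxel
#' size in millimetres.
#'
#' @slot voxels 3-D numeric array of voxel values; all values must be finite.
#' @slot voxelSize Numeric length-3 vector of positive voxel edge lengths (mm).
#'
#' @seealso [volumeImage()] for construction, [gaussianBlur()],
#'   [vanCittertPVC()], [computeSuvr()].
#' @export
setClass("VolumeImage",
  representation(voxels = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3-D array")
    if (!all(is.finite(object@voxels)))
      return("voxels must be finite")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive finite values (mm)")
    TRUE
  }
)

#' Construct a VolumeImage
#'
#' @param voxels 3-D numeric array.
#' @param voxelSize Voxel edge lengths in mm; a scalar is recycled to 3.
#' @return A \linkS4class{VolumeImage}.
#' @examples
#' img <- volumeImage(array(1, c(4, 4, 4)), 1.5)
#' dim(img)
#' @export
volumeImage <- function(voxels, voxelSize = c(1.5, 1.5, 1.5)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("VolumeImage", voxels = voxels, voxelSize = as.numeric(voxelSize))
}

#' LabelAtlas: integer region labels on an image grid
#'
#' An integer parcellation aligned with companion \linkS4class{VolumeImage}
#' grids. Label 0 is background; every non-zero label carries a region name,
#' and one named region (by default the cerebellum) is designated as the
#' reference tissue for SUVR normalisation.
#'
#' @slot labels 3-D integer array (0 = background).
#' @slot regionNames Character vector of region names, named by their integer
#'   label (as character).
#' @slot voxelSize Numeric length-3 voxel edge lengths (mm).
#' @slot referenceRegion Name of the reference region; must exist and be
#'   non-empty in `labels`.
#'
#' @seealso [makeAtlas()], [roiMeans()], [computeSuvr()].
#' @export
setClass("LabelAtlas",
  representation(labels = "array", regionNames = "character",
                 voxelSize = "numeric", referenceRegion = "character"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3-D array")
    labs <- sort(unique(as.integer(object@labels)))
    labs <- labs[labs != 0L]
    if (any(labs < 0L)) return("labels must be non-negative integers")
    named <- suppressWarnings(as.integer(names(object@regionNames)))
    if (anyNA(named)) return("regionNames must be named by integer labels")
    if (!all(labs %in% named))
      return("every non-zero label must have a region name")
    if (anyDuplicated(object@regionNames))
      return("region names must be unique")
    if (length(object@referenceRegion) != 1L ||
        !(object@referenceRegion %in% object@regionNames))
      return("referenceRegion must name one of the regions")
    ref <- named[match(object@referenceRegion, object@regionNames)]
    if (!any(object@labels == ref))
      return("reference region has no voxels")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive values (mm)")
    TRUE
  }
)

#' PhantomTruth: ground truth for a synthetic cohort
#'
#' The noiseless per-visit regional uptake of every simulated subject, the
#' subject covariate table, and the generating parameters. The reference
#' region's truth is held at exactly 1.0 at every visit, so true uptake and
#' true SUVR coincide by construction.
#'
#' @slot truth Long data frame with columns `subject_id`, `month`, `region`,
#'   `uptake` (all uptake values strictly positive).
#' @slot subjects Data frame with one row per subject: `subject_id`,
#'   `carrier`, `sex`, `education_years`, `baseline_age`, `converted`,
#'   `event_or_censor_month`.
#' @slot scanMonths Sorted numeric vector of scan months, starting at 0.
#' @slot effectParams Per-region generating parameters (intercepts and slopes
#'   per group).
#' @slot noiseSd Additive image-noise standard deviation (uptake units).
#' @slot atrophyRate Fractional region volume loss per month (0 = off).
#'
#' @seealso [simulateCohort()], [renderVisitImage()], [simulateSuvrTable()].
#' @export
setClass("PhantomTruth",
  representation(truth = "data.frame", subjects = "data.frame",
                 scanMonths = "numeric", effectParams = "data.frame",
                 noiseSd = "numeric", atrophyRate = "numeric"),
  validity = function(object) {
    need <- c("subject_id", "month", "region", "uptake")
    if (!all(need %in% names(object@truth)))
      return("truth must have columns subject_id, month, region, uptake")
    if (any(object@truth$uptake <= 0)) return("true uptake must be > 0")
    sm <- object@scanMonths
    if (length(sm) < 1L || sm[1] != 0 || is.unsorted(sm, strictly = TRUE))
      return("scanMonths must start at 0 and be strictly increasing")
    sn <- c("subject_id", "carrier", "sex", "education_years",
            "baseline_age", "converted", "event_or_censor_month")
    if (!all(sn %in% names(object@subjects)))
      return("subjects table is missing required columns")
    if (any(object@subjects$education_years < 0))
      return("education_years must be >= 0")
    if (any(object@subjects$event_or_censor_month > max(sm)))
      return("event_or_censor_month must not exceed the last scan month")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@atrophyRate < 0) return("atrophyRate must be >= 0")
    TRUE
  }
)

#' StatMap: voxelwise paired-t statistics
#'
#' Holds the t, probability-matched z, and Cohen's d maps of a voxelwise
#' paired-t analysis, together with the analysis mask and degrees of freedom.
#' Statistics are defined (finite) only inside the mask; voxels whose paired
#' differences had zero variance are removed from the mask.
#'
#' @slot tValues 3-D array of paired-t values (NA outside mask).
#' @slot zValues 3-D array of probability-matched z values.
#' @slot dValues 3-D array of Cohen's d (z / sqrt(n) convention).
#' @slot mask 3-D logical array of analysed voxels.
#' @slot df Degrees of freedom (number of pairs minus 1).
#' @slot nPairs Number of matched pairs.
#' @slot nZeroVariance Count of voxels dropped for zero difference variance.
#' @slot voxelSize Voxel edge lengths (mm).
#'
#' @seealso [pairedTMap()], [formClusters()], [permutationClusterFwer()].
#' @export
setClass("StatMap",
  representation(tValues = "array", zValues = "array", dValues = "array",
                 mask = "array", df = "numeric", nPairs = "numeric",
                 nZeroVariance = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@tValues)
    if (length(d) != 3L) return("tValues must be a 3-D array")
    if (!identical(d, dim(object@mask))) return("mask shape mismatch")
    if (object@df != object@nPairs - 1) return("df must equal nPairs - 1")
    if (any(!is.finite(object@tValues[object@mask])))
      return("statistics must be finite inside the mask")
    TRUE
  }
)

setMethod("voxels", "VolumeImage", function(x) x@voxels)
setMethod("voxelSize", "VolumeImage", function(x) x@voxelSize)
setMethod("dim", "VolumeImage", function(x) dim(x@voxels))

setMethod("voxels", "LabelAtlas", function(x) x@labels)
setMethod("voxelSize", "LabelAtlas", function(x) x@voxelSize)
setMethod("dim", "LabelAtlas", function(x) dim(x@labels))
setMethod("regionNames", "LabelAtlas", function(x) x@regionNames)
setMethod("referenceRegion", "LabelAtlas", function(x) x@referenceRegion)
setMethod("regionSizes", "LabelAtlas", function(x) {
  tab <- tabulate(as.integer(x@labels),
                  nbins = max(as.integer(names(x@regionNames))))
  sizes <- tab[as.integer(names(x@regionNames))]
  names(sizes) <- x@regionNames
  sizes
})

setMethod("truthTable", "PhantomTruth", function(x) x@truth)
setMethod("subjectTable", "PhantomTruth", function(x) x@subjects)

setMethod("tValues", "StatMap", function(x) x@tValues)
setMethod("zValues", "StatMap", function(x) x@zValues)
setMethod("dValues", "StatMap", function(x) x@dValues)
setMethod("maskArray", "StatMap", function(x) x@mask)
setMethod("statDf", "StatMap", function(x) x@df)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeImage %dx%dx%d, voxel %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize, trim = TRUE), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelAtlas", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelAtlas %dx%dx%d, %d regions, reference '%s'\n",
              d[1], d[2], d[3], length(object@regionNames),
              object@referenceRegion))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d subjects (%d carriers), %d scan months, %d regions\n",
    nrow(object@subjects), sum(object@subjects$carrier),
    length(object@scanMonths), length(unique(object@truth$region))))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf(
    "StatMap: %d pairs (df %d), %d voxels in mask, %d zero-variance dropped\n",
    object@nPairs, object@df, sum(object@mask), object@nZeroVariance))
})
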