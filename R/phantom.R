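#' Default 25-region parcellation names
#'
#' Region names used by the synthetic atlas: the cerebellum reference, the
#' nine cortical members of the global-cortex composite, and further cortical
#' and subcortical regions typical of an FDG-PET ROI study (including small
#' structures such as the amygdala and caudate that are most affected by
#' partial volume effects).
#'
#' @param n Number of names to return (2..25); `"cerebellum"` is always first.
#' @return Character vector of `n` region names.
#' @export
defaultRegionNames <- function(n = 25L) {
  all <- c("cerebellum",
           # regions with a carrier/non-carrier slope contrast built in
           "superior_frontal", "lateral_temporal", "medial_temporal",
           "parietal", "posterior_cingulate", "amygdala", "caudate",
           "thalamus",
           # remaining global-cortex members
           "orbital_frontal", "prefrontal", "posterior_precuneus",
           "occipital", "anterior_cingulate",
           # additional cortical / subcortical regions
           "putamen", "insula", "hippocampus", "parahippocampal",
           "fusiform", "precentral", "postcentral", "superior_parietal",
           "inferior_frontal", "middle_frontal", "cuneus")
  if (n < 2L || n > length(all))
    stop("n must be between 2 and ", length(all))
  all[seq_len(n)]
}

#' Members of the global-cortex composite
#'
#' @return Character vector of the nine cortical regions whose union defines
#'   the global cortex.
#' @export
globalCortexMembers <- function() {
  c("orbital_frontal", "prefrontal", "superior_frontal", "lateral_temporal",
    "parietal", "posterior_precuneus", "occipital", "anterior_cingulate",
    "posterior_cingulate")
}

# Mean percent change per follow-up interval implied by a linear trajectory
# intercept + slope * month evaluated on a scan schedule.
meanPctForSlope <- function(slope, intercept, scanMonths) {
  m <- scanMonths
  prev <- intercept + slope * m[-length(m)]
  mean(100 * slope * diff(m) / prev)
}

#' Solve for the monthly slope giving a target mean percent change
#'
#' Inverts the consecutive-interval mean-percent-change summary: finds the
#' linear slope (SUVR per month) such that a trajectory
#' `intercept + slope * month`, sampled at `scanMonths`, has the requested
#' mean percent change per follow-up interval.
#'
#' @param pctPerInterval Target mean percent change per interval (negative =
#'   decline).
#' @param intercept Baseline SUVR.
#' @param scanMonths Scan schedule (months, starting at 0, >= 2 visits).
#' @return Slope in SUVR units per month.
#' @examples
#' s <- slopeForPercentChange(-1.5, 1.034, c(0, 6, 12, 18, 24, 36, 48, 60, 72, 84))
#' @export
slopeForPercentChange <- function(pctPerInterval, intercept, scanMonths) {
  stopifnot(length(scanMonths) >= 2)
  if (pctPerInterval == 0) return(0)
  f <- function(s) meanPctForSlope(s, intercept, scanMonths) - pctPerInterval
  lim <- 0.9 * intercept / max(scanMonths)  # keep trajectory positive
  stats::uniroot(f, lower = -lim, upper = lim, tol = 1e-12)$root
}

#' Default per-region generating parameters for the phantom cohort
#'
#' Per-region baseline SUVR intercepts and monthly slopes for carriers and
#' non-carriers. Eight regions (superior frontal, lateral/medial temporal,
#' parietal, posterior cingulate, amygdala, caudate, thalamus) carry a
#' carrier-vs-non-carrier decline contrast on the scale reported for
#' longitudinal FDG studies of ApoE e4 MCI cohorts (e.g. parietal carriers
#' declining about 1.5% per follow-up interval against about 0.3% in
#' non-carriers); all other regions share a mild common decline of 0.2% per
#' interval, and the cerebellum reference is constant at 1.
#'
#' @param scanMonths Scan schedule used to convert percent-per-interval
#'   targets into monthly slopes.
#' @param regions Regions to include (default the full 25-name set).
#' @return Data frame with columns `region`, `interceptCarrier`,
#'   `interceptNoncarrier`, `pctCarrier`, `pctNoncarrier`, `slopeCarrier`,
#'   `slopeNoncarrier`.
#' @export
defaultEffectParams <- function(scanMonths = defaultScanMonths(),
                                regions = defaultRegionNames(25L)) {
  contrast <- data.frame(
    region = c("superior_frontal", "lateral_temporal", "medial_temporal",
               "parietal", "posterior_cingulate", "amygdala", "caudate",
               "thalamus"),
    interceptCarrier    = c(1.139, 0.971, 0.755, 1.034, 1.231, 0.726, 1.104,
                            1.363),
    interceptNoncarrier = c(1.184, 1.009, 0.780, 1.054, 1.287, 0.751, 1.072,
                            1.344),
    pctCarrier    = c(-0.58, -1.044, -0.824, -1.5, -1.266, -0.428, -1.686,
                      -0.803),
    pctNoncarrier = c(-0.132, -0.363, -0.22, -0.31, -0.632, 0.291, -0.055,
                      1.152),
    stringsAsFactors = FALSE)
  otherIntercepts <- c(
    cerebellum = 1.0, orbital_frontal = 1.15, prefrontal = 1.20,
    posterior_precuneus = 1.22, occipital = 1.25, anterior_cingulate = 1.18,
    putamen = 1.25, insula = 1.10, hippocampus = 0.80, parahippocampal = 0.85,
    fusiform = 1.05, precentral = 1.15, postcentral = 1.10,
    superior_parietal = 1.12, inferior_frontal = 1.15, middle_frontal = 1.18,
    cuneus = 1.20)
  rows <- lapply(regions, function(rg) {
    if (rg %in% contrast$region) {
      contrast[contrast$region == rg, , drop = FALSE]
    } else {
      i <- otherIntercepts[[rg]]
      if (is.null(i)) stop("no default parameters for region '", rg, "'")
      pct <- if (rg == "cerebellum") 0 else -0.2
      data.frame(region = rg, interceptCarrier = i, interceptNoncarrier = i,
                 pctCarrier = pct, pctNoncarrier = pct,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$slopeCarrier <- vapply(seq_len(nrow(out)), function(i)
    slopeForPercentChange(out$pctCarrier[i], out$interceptCarrier[i],
                          scanMonths), numeric(1))
  out$slopeNoncarrier <- vapply(seq_len(nrow(out)), function(i)
    slopeForPercentChange(out$pctNoncarrier[i], out$interceptNoncarrier[i],
                          scanMonths), numeric(1))
  rownames(out) <- NULL
  out
}

#' Default longitudinal scan schedule
#'
#' @return Scan months 0, 6, 12, 18, 24, 36, 48, 60, 72, 84.
#' @export
defaultScanMonths <- function() c(0, 6, 12, 18, 24, 36, 48, 60, 72, 84)

#' Build a seeded synthetic label atlas
#'
#' Partitions an ellipsoidal brain-like mask into `nRegions` contiguous
#' regions by a Voronoi tessellation over randomly placed seed points, then
#' trims designated small regions (amygdala, caudate, hippocampus,
#' parahippocampal by default) to at most `smallSize` voxels so the atlas
#' exposes partial volume effects; trimmed voxels are reassigned to the
#' nearest large region. The mask is inset from the grid edge so an 8 mm PSF
#' has room to spill into background.
#'
#' @param gridShape Integer grid dimensions (default 40 x 48 x 40).
#' @param nRegions Number of regions, >= 2 (default 25).
#' @param voxelSizeMm Voxel size in mm (scalar or length 3; default 1.5).
#' @param seed Integer seed; the atlas is deterministic given it.
#' @param regionNames Names for the regions; must contain `"cerebellum"`.
#' @param smallRegions Regions to cap at `smallSize` voxels.
#' @param smallSize Voxel cap for small regions (default 150).
#' @param maskPad Voxels of background margin around the ellipsoid mask
#'   (capped at a quarter of the smallest grid dimension).
#' @return A \linkS4class{LabelAtlas} with reference region `"cerebellum"`.
#' @examples
#' atl <- makeAtlas(c(24, 28, 24), nRegions = 10, seed = 1)
#' regionSizes(atl)
#' @export
makeAtlas <- function(gridShape = c(40L, 48L, 40L), nRegions = 25L,
                      voxelSizeMm = 1.5, seed = 1L,
                      regionNames = defaultRegionNames(nRegions),
                      smallRegions = c("amygdala", "caudate", "hippocampus",
                                       "parahippocampal"),
                      smallSize = 150L, maskPad = NULL) {
  gridShape <- as.integer(gridShape)
  if (is.null(maskPad))
    maskPad <- min(6L, max(1L, min(gridShape) %/% 4L))
  if (nRegions < 2L) stop("nRegions must be >= 2")
  if (length(regionNames) != nRegions)
    stop("regionNames must have length nRegions")
  if (!"cerebellum" %in% regionNames)
    stop("regionNames must include 'cerebellum'")
  if (length(voxelSizeMm) == 1L) voxelSizeMm <- rep(voxelSizeMm, 3L)
  semi <- gridShape / 2 - maskPad
  if (any(semi < 2)) stop("grid too small for the requested mask margin")
  ctr <- (gridShape + 1) / 2
  ijk <- as.matrix(expand.grid(i = seq_len(gridShape[1]),
                               j = seq_len(gridShape[2]),
                               k = seq_len(gridShape[3])))
  inside <- ((ijk[, 1] - ctr[1]) / semi[1])^2 +
            ((ijk[, 2] - ctr[2]) / semi[2])^2 +
            ((ijk[, 3] - ctr[3]) / semi[3])^2 <= 1
  maskIdx <- which(inside)
  if (length(maskIdx) < nRegions)
    stop("grid too small to host ", nRegions, " non-empty regions")
  set.seed(seed)
  seedIdx <- sample(maskIdx, nRegions)
  coords <- sweep(ijk[maskIdx, , drop = FALSE], 2, voxelSizeMm, `*`)
  seedCoords <- sweep(ijk[seedIdx, , drop = FALSE], 2, voxelSizeMm, `*`)
  d2 <- matrix(0, length(maskIdx), nRegions)
  for (r in seq_len(nRegions))
    d2[, r] <- (coords[, 1] - seedCoords[r, 1])^2 +
               (coords[, 2] - seedCoords[r, 2])^2 +
               (coords[, 3] - seedCoords[r, 3])^2
  assign <- max.col(-d2, ties.method = "first")
  smallLabs <- which(regionNames %in% smallRegions)
  bigLabs <- setdiff(seq_len(nRegions), smallLabs)
  for (s in smallLabs) {
    vox <- which(assign == s)
    if (length(vox) > smallSize) {
      keep <- vox[order(d2[vox, s])][seq_len(smallSize)]
      drop <- setdiff(vox, keep)
      # reassign excess voxels to the nearest large region
      assign[drop] <- bigLabs[max.col(-d2[drop, bigLabs, drop = FALSE],
                                      ties.method = "first")]
    }
  }
  labels <- array(0L, gridShape)
  labels[maskIdx] <- assign
  names(regionNames) <- as.character(seq_len(nRegions))
  new("LabelAtlas", labels = labels, regionNames = regionNames,
      voxelSize = as.numeric(voxelSizeMm), referenceRegion = "cerebellum")
}

#' Simulate a two-group longitudinal phantom cohort
#'
#' Draws a cohort of ApoE e4 carriers and non-carriers with a common scan
#' schedule and builds the noiseless ground-truth regional uptake of every
#' visit: per region, `truth = intercept(group) + subjectDev + slope(group) *
#' month + visitDev`, where `subjectDev` is a per-subject-per-region random
#' intercept (SD `subjectSd`) and `visitDev` a per-visit biological
#' fluctuation (SD `visitSd`). The cerebellum reference is held at exactly
#' 1.0 at every visit so true uptake and true SUVR coincide. Conversion to
#' dementia is drawn from exponential hazards (carrier hazard >= non-carrier)
#' with administrative censoring at the last scan month.
#'
#' @param nPerGroup Subjects per group, >= 2 (default 24).
#' @param scanMonths Common scan schedule, starting at 0.
#' @param effectParams Per-region generating parameters; defaults to
#'   [defaultEffectParams()] on `scanMonths`.
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param subjectSd SD of per-subject regional intercept deviations (SUVR).
#' @param visitSd SD of per-visit regional fluctuations (SUVR).
#' @param noiseSd Additive voxel noise SD recorded for image rendering.
#' @param atrophyRate Fractional region volume loss per month (0 = off).
#' @param hazards Named vector `c(carrier=, noncarrier=)` of monthly
#'   conversion hazards; carrier must be >= non-carrier.
#' @return A \linkS4class{PhantomTruth}.
#' @export
simulateCohort <- function(nPerGroup = 24L,
                           scanMonths = defaultScanMonths(),
                           effectParams = NULL,
                           seed = 1L,
                           subjectSd = 0.05, visitSd = 0.015,
                           noiseSd = 0.02, atrophyRate = 0,
                           hazards = c(carrier = 0.00929,
                                       noncarrier = 0.00560)) {
  if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
  if (!0 %in% scanMonths) stop("scanMonths must include 0")
  scanMonths <- sort(unique(as.numeric(scanMonths)))
  if (is.null(effectParams)) effectParams <- defaultEffectParams(scanMonths)
  if (hazards[["carrier"]] < hazards[["noncarrier"]])
    stop("carrier hazard must be >= non-carrier hazard")
  set.seed(seed)
  nTot <- 2L * nPerGroup
  carrier <- rep(c(TRUE, FALSE), each = nPerGroup)
  ids <- sprintf("%s%02d", ifelse(carrier, "C", "N"),
                 c(seq_len(nPerGroup), seq_len(nPerGroup)))
  sex <- ifelse(stats::runif(nTot) < 0.708, "M", "F")
  edu <- pmin(20, pmax(8, round(stats::rnorm(nTot, 15.4, 2.9))))
  age <- pmin(85, pmax(55, stats::rnorm(nTot,
                                        ifelse(carrier, 71.9, 75.6), 7)))
  maxM <- max(scanMonths)
  evt <- stats::rexp(nTot, rate = ifelse(carrier, hazards[["carrier"]],
                                         hazards[["noncarrier"]]))
  converted <- evt <= maxM
  eventMonth <- pmin(evt, maxM)
  subjects <- data.frame(
    subject_id = ids, carrier = carrier, sex = sex,
    education_years = edu, baseline_age = age,
    converted = converted, event_or_censor_month = eventMonth,
    stringsAsFactors = FALSE)

  regions <- effectParams$region
  nR <- length(regions)
  nM <- length(scanMonths)
  refRegion <- "cerebellum"
  # per subject x region intercept deviations (zero for the reference)
  subjDev <- matrix(stats::rnorm(nTot * nR, 0, subjectSd), nTot, nR)
  grid <- expand.grid(monthIdx = seq_len(nM), regionIdx = seq_len(nR),
                      subjIdx = seq_len(nTot))
  isCar <- carrier[grid$subjIdx]
  intc <- ifelse(isCar, effectParams$interceptCarrier[grid$regionIdx],
                 effectParams$interceptNoncarrier[grid$regionIdx])
  slp <- ifelse(isCar, effectParams$slopeCarrier[grid$regionIdx],
                effectParams$slopeNoncarrier[grid$regionIdx])
  mo <- scanMonths[grid$monthIdx]
  up <- intc + subjDev[cbind(grid$subjIdx, grid$regionIdx)] + slp * mo +
    stats::rnorm(nrow(grid), 0, visitSd)
  isRef <- regions[grid$regionIdx] == refRegion
  up[isRef] <- 1.0
  if (any(up <= 0))
    stop("generating parameters produced non-positive true uptake; ",
         "reduce slopes or deviations")
  truth <- data.frame(subject_id = ids[grid$subjIdx], month = mo,
                      region = regions[grid$regionIdx], uptake = up,
                      stringsAsFactors = FALSE)
  attr(effectParams, "subjectSd") <- subjectSd
  attr(effectParams, "visitSd") <- visitSd
  new("PhantomTruth", truth = truth, subjects = subjects,
      scanMonths = scanMonths, effectParams = effectParams,
      noiseSd = noiseSd, atrophyRate = atrophyRate)
}

#' SUVR table directly from phantom ground truth
#'
#' The fast path for model calibration studies: because the reference-region
#' truth is 1 by construction, the true regional uptake is already the true
#' SUVR, so a long SUVR table can be taken from a \linkS4class{PhantomTruth}
#' without rendering, blurring, and re-measuring images.
#'
#' @param truth A \linkS4class{PhantomTruth}.
#' @param pvc Logical flag recorded in the `pvc` column.
#' @return Data frame with columns `subject_id`, `month`, `region`, `suvr`,
#'   `pvc` (one row per subject, visit and region).
#' @export
simulateSuvrTable <- function(truth, pvc = FALSE) {
  stopifnot(is(truth, "PhantomTruth"))
  tt <- truthTable(truth)
  data.frame(subject_id = tt$subject_id, month = tt$month, region = tt$region,
             suvr = tt$uptake, pvc = pvc, stringsAsFactors = FALSE)
}

# Deterministic erosion order: voxels of each region sorted by decreasing
# distance from the region centroid (boundary first).
erosionOrder <- function(atlas) {
  labs <- as.integer(names(regionNames(atlas)))
  arr <- voxels(atlas)
  ijk <- which(arr > 0L, arr.ind = TRUE)
  lab <- arr[arr > 0L]
  lin <- which(arr > 0L)
  out <- vector("list", length(labs))
  names(out) <- regionNames(atlas)
  for (i in seq_along(labs)) {
    sel <- lab == labs[i]
    pts <- ijk[sel, , drop = FALSE]
    ctr <- colMeans(pts)
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2
    out[[i]] <- lin[sel][order(-d2, lin[sel])]
  }
  out
}

#' Render one phantom visit as an image
#'
#' Paints the subject's true regional uptake for the requested month onto the
#' atlas grid as a piecewise-constant image (optionally eroding each region
#' by the accumulated fractional atrophy, boundary voxels first), convolves
#' it with the Gaussian point spread function, and adds i.i.d. Gaussian
#' noise. With `psfFwhmMm = 0` and `noiseSd = 0` the rendered image equals
#' the piecewise-constant truth exactly.
#'
#' @param truth A \linkS4class{PhantomTruth}.
#' @param subjectId,month Visit to render; must exist in the truth table.
#' @param atlas A \linkS4class{LabelAtlas} on the target grid.
#' @param psfFwhmMm PSF full width at half maximum in mm (default 8).
#' @param noiseSd Additive noise SD; defaults to the cohort's `noiseSd`.
#' @param seed Integer seed for the noise draw.
#' @return A \linkS4class{VolumeImage}.
#' @export
renderVisitImage <- function(truth, subjectId, month, atlas, psfFwhmMm = 8,
                             noiseSd = NULL, seed = 1L) {
  stopifnot(is(truth, "PhantomTruth"), is(atlas, "LabelAtlas"))
  if (psfFwhmMm < 0) stop("psfFwhmMm must be >= 0")
  if (is.null(noiseSd)) noiseSd <- truth@noiseSd
  tt <- truthTable(truth)
  rows <- tt[tt$subject_id == subjectId & tt$month == month, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no truth for subject '", subjectId, "' at month ", month)
  rn <- regionNames(atlas)
  up <- rows$uptake[match(rn, rows$region)]
  if (anyNA(up))
    stop("truth table lacks regions: ",
         paste(rn[is.na(up)], collapse = ", "))
  labArr <- voxels(atlas)
  img <- array(0, dim(labArr))
  pos <- labArr > 0L
  img[pos] <- up[labArr[pos]]
  rate <- truth@atrophyRate
  if (rate > 0 && month > 0) {
    frac <- min(0.5, rate * month)
    ord <- erosionOrder(atlas)
    for (rg in rn) {
      nDrop <- floor(length(ord[[rg]]) * frac)
      if (nDrop > 0) img[ord[[rg]][seq_len(nDrop)]] <- 0
    }
  }
  out <- volumeImage(img, voxelSize(atlas))
  if (psfFwhmMm > 0) out <- gaussianBlur(out, psfFwhmMm)
  if (noiseSd > 0) {
    set.seed(seed)
    out <- volumeImage(voxels(out) +
                         stats::rnorm(length(voxels(out)), 0, noiseSd),
                       voxelSize(atlas))
  }
  out
}

#' Sphere-style contrast phantom for PVC validation
#'
#' The standard resolution-recovery phantom: spherical regions of graded size
#' and contrast embedded in a uniform warm background, used to quantify how
#' much of each region's true contrast survives blurring and how much
#' partial volume correction recovers. Spheres are placed on a fixed
#' deterministic lattice well inside the grid so an 8 mm PSF never reaches
#' the volume edge.
#'
#' @param gridShape Grid dimensions (default 40 x 48 x 40).
#' @param voxelSizeMm Voxel size in mm (default 1.5).
#' @param radiiVox Sphere radii in voxels (default 3.2 to 4.8, giving sizes
#'   of roughly 130 to 460 voxels).
#' @param contrasts True sphere values against a background of 1 (default a
#'   mix of hot and cold contrasts from 5% to 30%).
#' @param background Background uptake (default 1).
#' @return List with `atlas` (a \linkS4class{LabelAtlas} whose regions are
#'   `sphere_1 ... sphere_k` plus `background`, the reference), `image` (the
#'   noiseless piecewise-constant \linkS4class{VolumeImage}), and `truth`
#'   (named vector of true region values).
#' @export
makeContrastPhantom <- function(gridShape = c(40L, 48L, 40L),
                                voxelSizeMm = 1.5,
                                radiiVox = c(3.2, 3.6, 3.8, 4.2, 4.5, 4.8),
                                contrasts = c(1.05, 0.90, 1.20, 0.80,
                                              1.10, 1.30),
                                background = 1) {
  k <- length(radiiVox)
  if (k > 6L) stop("at most 6 spheres fit the placement lattice")
  if (length(contrasts) != k)
    stop("radiiVox and contrasts must have equal length")
  if (any(abs(contrasts - background) < 1e-12))
    stop("every sphere needs non-zero contrast against the background")
  gridShape <- as.integer(gridShape)
  if (any(gridShape < c(40L, 48L, 40L)))
    stop("grid too small for the sphere lattice")
  # fixed staggered lattice well inside the volume: pairwise centre
  # distances exceed the summed radii by several PSF sigmas
  frac <- cbind(x = c(0.33, 0.67, 0.33, 0.67, 0.33, 0.67),
                y = c(0.30, 0.30, 0.50, 0.50, 0.72, 0.72),
                z = c(0.40, 0.60, 0.60, 0.40, 0.40, 0.60))
  centres <- round(sweep(frac[seq_len(k), , drop = FALSE], 2, gridShape, `*`))
  labels <- array(0L, gridShape)
  ijk <- as.matrix(expand.grid(i = seq_len(gridShape[1]),
                               j = seq_len(gridShape[2]),
                               k = seq_len(gridShape[3])))
  for (s in seq_len(k)) {
    d2 <- (ijk[, 1] - centres[s, 1])^2 + (ijk[, 2] - centres[s, 2])^2 +
      (ijk[, 3] - centres[s, 3])^2
    labels[d2 <= radiiVox[s]^2] <- s
  }
  bgLab <- k + 1L
  labels[labels == 0L] <- bgLab
  nm <- c(sprintf("sphere_%d", seq_len(k)), "background")
  names(nm) <- as.character(seq_len(bgLab))
  atlas <- new("LabelAtlas", labels = labels, regionNames = nm,
               voxelSize = rep(voxelSizeMm, 3), referenceRegion = "background")
  truth <- c(contrasts, background)
  names(truth) <- nm
  img <- array(background, gridShape)
  for (s in seq_len(k)) img[labels == s] <- contrasts[s]
  list(atlas = atlas, image = volumeImage(img, voxelSizeMm), truth = truth)
}
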