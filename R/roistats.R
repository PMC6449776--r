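#' Region-of-interest mean uptake
#'
#' Arithmetic mean of voxel values within each labelled atlas region;
#' background (label 0) is excluded. Empty regions are dropped with a
#' warning.
#'
#' @param image A \linkS4class{VolumeImage} on the atlas grid.
#' @param atlas A \linkS4class{LabelAtlas}.
#' @return Named numeric vector of region means.
#' @export
roiMeans <- function(image, atlas) {
  stopifnot(is(image, "VolumeImage"), is(atlas, "LabelAtlas"))
  if (!identical(dim(image), dim(atlas)))
    stop("image and atlas grids differ")
  lab <- as.integer(voxels(atlas))
  v <- as.numeric(voxels(image))
  keep <- lab > 0L
  sums <- rowsum(v[keep], lab[keep])
  counts <- tabulate(lab[keep], nbins = max(lab))
  labsPresent <- as.integer(rownames(sums))
  means <- as.numeric(sums) / counts[labsPresent]
  rn <- regionNames(atlas)
  out <- means[match(as.integer(names(rn)), labsPresent)]
  names(out) <- rn
  if (anyNA(out)) {
    warning("empty regions excluded: ",
            paste(rn[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Reference-normalised SUVR image and ROI SUVRs
#'
#' Divides every voxel by the mean uptake of the reference region (cerebellum
#' by default), yielding a standardised uptake value ratio image, and reports
#' the ROI means of the scaled image. The reference region's SUVR is 1 by
#' construction, and the result is invariant to global rescaling of the
#' input.
#'
#' @param image A \linkS4class{VolumeImage} of tracer uptake.
#' @param atlas A \linkS4class{LabelAtlas}.
#' @param reference Reference region name; defaults to the atlas reference.
#' @return List with `image` (the SUVR \linkS4class{VolumeImage}),
#'   `regionSuvrs` (named vector), and `referenceMean` (the divisor).
#' @export
computeSuvr <- function(image, atlas, reference = referenceRegion(atlas)) {
  means <- roiMeans(image, atlas)
  if (!reference %in% names(means))
    stop("reference region '", reference, "' not present")
  refMean <- means[[reference]]
  if (!is.finite(refMean) || refMean <= 0)
    stop("reference region mean must be > 0 (got ", refMean, ")")
  list(image = volumeImage(voxels(image) / refMean, voxelSize(image)),
       regionSuvrs = means / refMean,
       referenceMean = refMean)
}

#' Global-cortex composite SUVR
#'
#' The SUVR of the union of the member cortical regions: a voxel-count
#' weighted mean of the member ROI SUVRs, which equals the ROI mean of the
#' merged mask.
#'
#' @param regionSuvrs Named vector of ROI SUVRs.
#' @param regionVoxelCounts Named vector of region voxel counts (e.g.
#'   [regionSizes()]).
#' @param members Member region names (default [globalCortexMembers()]).
#' @return The composite SUVR (scalar).
#' @export
globalCortex <- function(regionSuvrs, regionVoxelCounts,
                         members = globalCortexMembers()) {
  miss <- setdiff(members, intersect(names(regionSuvrs),
                                     names(regionVoxelCounts)))
  if (length(miss))
    stop("missing global-cortex members: ", paste(miss, collapse = ", "))
  w <- regionVoxelCounts[members]
  sum(regionSuvrs[members] * w) / sum(w)
}

#' Long SUVR table for a rendered phantom cohort
#'
#' Runs the image pipeline for every visit of a phantom cohort: render the
#' visit image (PSF blur + noise), optionally apply Van Cittert partial
#' volume correction, normalise to the reference region, and collect ROI
#' SUVRs into a long table. Per-visit noise seeds are derived
#' deterministically from `seed`.
#'
#' @param truth A \linkS4class{PhantomTruth}.
#' @param atlas A \linkS4class{LabelAtlas}.
#' @param psfFwhmMm PSF full width at half maximum in mm (default 8).
#' @param pvc Apply partial volume correction before SUVR scaling?
#' @param alpha,tolPercent,maxIter Van Cittert settings (see
#'   [vanCittertPVC()]).
#' @param seed Base seed for the per-visit noise draws.
#' @return Data frame with columns `subject_id`, `month`, `region`, `suvr`,
#'   `pvc`.
#' @export
cohortSuvrTable <- function(truth, atlas, psfFwhmMm = 8, pvc = TRUE,
                            alpha = 1.5, tolPercent = 1, maxIter = 30L,
                            seed = 1L) {
  stopifnot(is(truth, "PhantomTruth"), is(atlas, "LabelAtlas"))
  subs <- subjectTable(truth)$subject_id
  months <- truth@scanMonths
  rows <- vector("list", length(subs) * length(months))
  i <- 0L
  for (s in seq_along(subs)) {
    for (m in seq_along(months)) {
      i <- i + 1L
      visitSeed <- (seed + 7919L * i) %% .Machine$integer.max
      img <- renderVisitImage(truth, subs[s], months[m], atlas,
                              psfFwhmMm = psfFwhmMm, seed = visitSeed)
      if (pvc && psfFwhmMm > 0)
        img <- vanCittertPVC(img, fwhmMm = psfFwhmMm, alpha = alpha,
                             tolPercent = tolPercent,
                             maxIter = maxIter)$corrected
      sv <- computeSuvr(img, atlas)$regionSuvrs
      rows[[i]] <- data.frame(subject_id = subs[s], month = months[m],
                              region = names(sv), suvr = as.numeric(sv),
                              pvc = pvc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean percent change of SUVR over follow-up intervals
#'
#' For every subject in the chosen group and every pair of consecutive scans,
#' computes the relative change `100 * (SUVR_next - SUVR_prev) / SUVR_prev`
#' and averages over all intervals of all subjects (negative = decline).
#' Subjects with fewer than two visits contribute nothing; intervals with a
#' zero denominator are excluded with a warning.
#'
#' @param table Long SUVR table (`subject_id`, `month`, `region`, `suvr`).
#' @param region Region name.
#' @param subjects Subject table with `subject_id` and `carrier` columns.
#' @param carrier Logical: summarise carriers (TRUE) or non-carriers (FALSE).
#' @return Mean percent change per follow-up interval (scalar).
#' @export
meanPercentChange <- function(table, region, subjects, carrier = TRUE) {
  ids <- subjects$subject_id[subjects$carrier == carrier]
  sub <- table[table$region == region & table$subject_id %in% ids, ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for region '", region, "'")
  pcts <- unlist(lapply(split(sub, sub$subject_id), function(d) {
    d <- d[order(d$month), , drop = FALSE]
    if (nrow(d) < 2L) return(numeric(0))
    prev <- d$suvr[-nrow(d)]
    ok <- prev != 0
    if (!all(ok)) warning("zero-SUVR denominator intervals excluded")
    100 * diff(d$suvr)[ok] / prev[ok]
  }), use.names = FALSE)
  mean(pcts)
}
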