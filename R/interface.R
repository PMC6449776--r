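#' Read a 3-D NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @return A \linkS4class{VolumeImage} carrying the header voxel size.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("only 3-D volumes are supported (got ", length(d), "-D)")
  volumeImage(array(as.numeric(img), d), RNifti::pixdim(img)[1:3])
}

#' Write a VolumeImage as NIfTI-1 (float32)
#'
#' @param image A \linkS4class{VolumeImage}.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(image, path) {
  stopifnot(is(image, "VolumeImage"))
  n <- RNifti::asNifti(voxels(image))
  RNifti::pixdim(n) <- voxelSize(image)
  RNifti::writeNifti(n, path, datatype = "float")
  invisible(path)
}

#' Default pipeline configuration
#'
#' The settings of the reference analysis: 8 mm PSF, Van Cittert step length
#' 1.5 stopped at 1% relative change, one-tailed voxel cluster-forming
#' p < 0.001 with cluster-level FWER 0.05, cerebellum reference, 24 subjects
#' per group scanned at months 0-84.
#'
#' @return Named list of configuration fields.
#' @export
defaultConfig <- function() {
  list(
    psf_fwhm_mm = 8, alpha = 1.5, tol_percent = 1, max_iter = 30,
    cft_p = 0.001, cluster_alpha = 0.05, n_permutations = 1000,
    seed = 1, reference_region = "cerebellum",
    scan_months = defaultScanMonths(),
    n_per_group = 24, n_regions = 25,
    grid_shape = c(40, 48, 40), voxel_size_mm = 1.5,
    noise_sd = 0.02, visit_sd = 0.015, subject_sd = 0.05,
    atrophy_rate = 0,
    pvc = "both",           # "pvc", "nopvc" or "both"
    followup_month = 72,    # voxelwise contrast: this month vs baseline
    output_dir = "longpet-run"
  )
}

#' Read and validate a pipeline configuration file
#'
#' Loads a YAML or JSON configuration, fills unspecified fields from
#' [defaultConfig()], and validates numeric ranges.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file (NULL = defaults).
#' @return Validated configuration list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config fields: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  validateConfig(cfg)
}

#' @rdname readConfig
#' @param cfg Configuration list to validate.
#' @export
validateConfig <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config: ", msg)
  chk(cfg$psf_fwhm_mm >= 0, "psf_fwhm_mm must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 2, "alpha must be in (0, 2)")
  chk(cfg$tol_percent > 0, "tol_percent must be > 0")
  chk(cfg$max_iter >= 1, "max_iter must be >= 1")
  chk(cfg$cft_p > 0 && cfg$cft_p <= 0.5, "cft_p must be in (0, 0.5]")
  chk(cfg$cluster_alpha > 0 && cfg$cluster_alpha < 1,
      "cluster_alpha must be in (0, 1)")
  chk(cfg$n_permutations >= 1, "n_permutations must be >= 1")
  chk(length(cfg$scan_months) >= 2 && 0 %in% cfg$scan_months,
      "scan_months must include 0 and at least one follow-up")
  chk(cfg$n_per_group >= 2, "n_per_group must be >= 2")
  chk(cfg$noise_sd >= 0 && cfg$visit_sd >= 0 && cfg$subject_sd >= 0,
      "noise/visit/subject SDs must be >= 0")
  chk(cfg$atrophy_rate >= 0, "atrophy_rate must be >= 0")
  chk(cfg$pvc %in% c("pvc", "nopvc", "both"),
      "pvc must be 'pvc', 'nopvc' or 'both'")
  chk(cfg$followup_month %in% cfg$scan_months,
      "followup_month must be one of scan_months")
  cfg
}

.logLine <- function(logPath, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = logPath, append = TRUE, sep = "")
  invisible(line)
}

.writeCsv <- function(x, path) {
  utils::write.csv(format(x, trim = TRUE, digits = 12), path,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Run the full phantom analysis pipeline
#'
#' Executes simulate -> render -> (optional) PVC -> SUVR -> per-region mixed
#' model -> voxelwise paired-t with permutation cluster FWER -> cohort
#' conversion statistics, and writes all result tables, a structured log and
#' a machine-readable run manifest into `config$output_dir`. All randomness
#' derives from `config$seed`, so identical configurations give
#' byte-identical outputs.
#'
#' Outputs: `suvr_table.csv` (long SUVR table with a `pvc` column),
#' `lmm_report.csv`, `clusters_<group>[ _nopvc].csv`,
#' `survival_summary.csv`, `subjects.csv`, `manifest.json`, `pipeline.log`.
#'
#' @param config Configuration list (see [defaultConfig()] / [readConfig()]).
#' @return The output directory path, invisibly.
#' @export
runPipeline <- function(config = defaultConfig()) {
  cfg <- validateConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$output_dir, "pipeline.log")
  cat("", file = logPath)
  stage <- "simulate"
  result <- tryCatch({
    .logLine(logPath, stage, sprintf("n_per_group=%d seed=%d",
                                     cfg$n_per_group, as.integer(cfg$seed)))
    atlas <- makeAtlas(cfg$grid_shape, nRegions = cfg$n_regions,
                       voxelSizeMm = cfg$voxel_size_mm, seed = cfg$seed)
    truth <- simulateCohort(cfg$n_per_group, cfg$scan_months,
                            seed = cfg$seed, subjectSd = cfg$subject_sd,
                            visitSd = cfg$visit_sd, noiseSd = cfg$noise_sd,
                            atrophyRate = cfg$atrophy_rate)
    subjects <- subjectTable(truth)
    .writeCsv(subjects, file.path(cfg$output_dir, "subjects.csv"))

    variants <- switch(cfg$pvc, pvc = TRUE, nopvc = FALSE, both = c(TRUE, FALSE))
    tables <- list()
    imagesByVariant <- list()
    for (usePvc in variants) {
      stage <- if (usePvc) "pvc+suvr" else "suvr"
      .logLine(logPath, stage, sprintf(
        "rendering %d visits, fwhm=%g mm, alpha=%g, tol=%g%%",
        nrow(subjects) * length(cfg$scan_months), cfg$psf_fwhm_mm,
        cfg$alpha, cfg$tol_percent))
      key <- if (usePvc) "pvc" else "nopvc"
      imgs <- list()
      rows <- list()
      i <- 0L
      negTotal <- 0L
      for (sid in subjects$subject_id) {
        for (m in cfg$scan_months) {
          i <- i + 1L
          visitSeed <- (as.integer(cfg$seed) + 7919L * i) %%
            .Machine$integer.max
          img <- renderVisitImage(truth, sid, m, atlas,
                                  psfFwhmMm = cfg$psf_fwhm_mm,
                                  seed = visitSeed)
          if (usePvc && cfg$psf_fwhm_mm > 0) {
            res <- vanCittertPVC(img, cfg$psf_fwhm_mm, cfg$alpha,
                                 cfg$tol_percent, cfg$max_iter)
            img <- res$corrected
            negTotal <- negTotal + res$negativeVoxels
            if (i == 1L)
              .logLine(logPath, stage, sprintf(
                "first visit PVC: %d iterations, change history %s",
                res$nIterations,
                paste(sprintf("%.3f", res$changeHistory), collapse = " ")))
          }
          sv <- computeSuvr(img, atlas, cfg$reference_region)
          suvrImg <- sv$image
          if (m %in% c(0, cfg$followup_month))
            imgs[[sprintf("%s_%g", sid, m)]] <- suvrImg
          rows[[i]] <- data.frame(subject_id = sid, month = m,
                                  region = names(sv$regionSuvrs),
                                  suvr = as.numeric(sv$regionSuvrs),
                                  pvc = usePvc, stringsAsFactors = FALSE)
        }
      }
      if (usePvc)
        .logLine(logPath, stage,
                 sprintf("negative voxels across PVC images: %d", negTotal))
      tables[[key]] <- do.call(rbind, rows)
      imagesByVariant[[key]] <- imgs
    }
    suvrTable <- do.call(rbind, tables)
    rownames(suvrTable) <- NULL
    .writeCsv(suvrTable, file.path(cfg$output_dir, "suvr_table.csv"))

    stage <- "lmm"
    regions <- setdiff(regionNames(atlas), cfg$reference_region)
    reports <- lapply(names(tables), function(key) {
      fits <- lapply(regions, function(rg)
        fitRoiLmm(tables[[key]], rg, subjects))
      rep <- summarizeRegions(fits, alpha = 0.05)
      rep$pvc <- key == "pvc"
      rep
    })
    lmmReport <- do.call(rbind, reports)
    .logLine(logPath, stage, sprintf("%d region fits (%d flagged)",
                                     nrow(lmmReport), sum(lmmReport$flagged)))
    .writeCsv(lmmReport, file.path(cfg$output_dir, "lmm_report.csv"))

    stage <- "voxelwise"
    brainMask <- voxels(atlas) > 0L
    for (key in names(imagesByVariant)) {
      imgs <- imagesByVariant[[key]]
      for (grp in c("carrier", "noncarrier")) {
        ids <- subjects$subject_id[subjects$carrier == (grp == "carrier")]
        base <- imgs[sprintf("%s_0", ids)]
        fup <- imgs[sprintf("%s_%g", ids, cfg$followup_month)]
        tab <- permutationClusterFwer(base, fup, mask = brainMask,
                                      cftP = cfg$cft_p,
                                      nPermutations = cfg$n_permutations,
                                      seed = as.integer(cfg$seed) + 101L)
        .logLine(logPath, stage, sprintf(
          "%s %s: %d clusters, %d significant at alpha=%g (%d permutations)",
          key, grp, nrow(tab), sum(tab$corrected_p < cfg$cluster_alpha),
          cfg$cluster_alpha, attr(tab, "nPermUsed")))
        fname <- sprintf("clusters_%s%s.csv", grp,
                         if (key == "nopvc") "_nopvc" else "")
        .writeCsv(tab, file.path(cfg$output_dir, fname))
      }
    }

    stage <- "survival"
    rec <- survivalRecords(subjects)
    conv <- table(factor(rec$group, c("carrier", "non-carrier")), rec$event)
    chi <- chisq2x2(conv["carrier", "TRUE"], conv["carrier", "FALSE"],
                    conv["non-carrier", "TRUE"], conv["non-carrier", "FALSE"],
                    tail = "one")
    fh <- flemingHarringtonTest(rec, p = 1, q = 0)
    km <- kmCurves(rec)
    kmSummary <- summary(km)
    survTab <- data.frame(
      group = sub("group=", "", as.character(kmSummary$strata)),
      time_months = kmSummary$time, n_risk = kmSummary$n.risk,
      n_event = kmSummary$n.event, survival = kmSummary$surv,
      lower95 = kmSummary$lower, upper95 = kmSummary$upper)
    survTab$conversion_chi2_one_tailed_p <- chi$p
    survTab$fleming_harrington_p <- fh$p.value
    .writeCsv(survTab, file.path(cfg$output_dir, "survival_summary.csv"))
    .logLine(logPath, stage, sprintf(
      "conversion chi2 one-tailed p=%.4f, Fleming-Harrington p=%.4f",
      chi$p, fh$p.value))

    manifest <- list(package = "longpet",
                     version = as.character(utils::packageVersion("longpet")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     config = cfg)
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cfg$output_dir
  }, error = function(e) {
    .logLine(logPath, stage, paste("FAILED:", conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
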