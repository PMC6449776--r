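#' Per-region longitudinal mixed-effects model
#'
#' Fits, for one region, the linear mixed-effects model
#' `suvr ~ sex + education_years + baseline_age + month * carrier +
#' (1 | subject_id)` by REML, and tests the carrier-by-time interaction (the
#' coefficient of `month:carrier`, in SUVR per month) by a Wald z test on
#' estimate / SE. Time is the scan month from baseline, continuous; the
#' carrier main effect is retained alongside the interaction for model
#' hierarchy. Optionally a per-subject random slope in month is added.
#'
#' @param table Long SUVR table (`subject_id`, `month`, `region`, `suvr`).
#' @param region Region to fit.
#' @param subjects Subject table with `subject_id`, `carrier`, `sex`,
#'   `education_years`, `baseline_age`.
#' @param randomSlope Add a random month slope per subject? (default FALSE).
#' @return A one-row data frame: `region`, `estimate` (interaction, SUVR per
#'   month), `se`, `z`, `p` (two-sided; NA when the fit did not converge),
#'   `nObs`, `converged`, plus the full fixed-effect vector as an attribute
#'   `"coefficients"`.
#' @export
fitRoiLmm <- function(table, region, subjects, randomSlope = FALSE) {
  sub <- table[table$region == region, , drop = FALSE]
  if (nrow(sub) == 0L) stop("region '", region, "' not present in table")
  dat <- merge(sub, subjects[, c("subject_id", "carrier", "sex",
                                 "education_years", "baseline_age")],
               by = "subject_id")
  if (length(unique(dat$subject_id[dat$carrier])) < 2L ||
      length(unique(dat$subject_id[!dat$carrier])) < 2L)
    stop("need at least 2 subjects per group")
  if (min(table(dat$subject_id)) < 2L)
    stop("every subject needs at least 2 visits")
  dat$carrier <- as.logical(dat$carrier)
  form <- if (randomSlope)
    suvr ~ sex + education_years + baseline_age + month * carrier +
      (1 + month | subject_id)
  else
    suvr ~ sex + education_years + baseline_age + month * carrier +
      (1 | subject_id)
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular =
                                               lme4::.makeCC("ignore",
                                                             tol = 1e-4))),
      error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    out <- data.frame(region = region, estimate = NA_real_, se = NA_real_,
                      z = NA_real_, p = NA_real_, nObs = nrow(dat),
                      converged = FALSE, stringsAsFactors = FALSE)
    attr(out, "diagnostics") <- conditionMessage(fit)
    return(out)
  }
  coefs <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  term <- grep("month:carrier", names(coefs), value = TRUE)
  if (length(term) != 1L) stop("interaction term not found in fit")
  est <- unname(coefs[term])
  se <- sqrt(vc[term, term])
  z <- est / se
  out <- data.frame(region = region, estimate = est, se = se, z = z,
                    p = if (converged) 2 * stats::pnorm(-abs(z)) else NA_real_,
                    nObs = nrow(dat), converged = converged,
                    stringsAsFactors = FALSE)
  attr(out, "coefficients") <- coefs
  out
}

#' Region-level interaction report
#'
#' Stacks per-region mixed-model results, sorts by interaction p-value, and
#' flags regions showing a significantly greater decline in carriers
#' (negative interaction estimate with p below `alpha`). When a matching set
#' of results from a non-PVC run is supplied, its estimate/p/flag columns are
#' reported side by side. No multiplicity correction is applied across
#' regions; flags are per-region tests at `alpha`.
#'
#' @param results List of one-row data frames from [fitRoiLmm()] (or a
#'   pre-bound data frame).
#' @param alpha Significance level (default 0.05).
#' @param nonPvcResults Optional companion results from images without
#'   partial volume correction.
#' @return Data frame sorted by `p` with a logical `flagged` column (and
#'   `estimateNoPvc`, `pNoPvc`, `flaggedNoPvc` when supplied).
#' @export
summarizeRegions <- function(results, alpha = 0.05, nonPvcResults = NULL) {
  bind <- function(x) {
    if (is.data.frame(x)) x else do.call(rbind, x)
  }
  res <- bind(results)
  if (nrow(res) == 0L) stop("results must be non-empty")
  res$flagged <- !is.na(res$p) & res$estimate < 0 & res$p < alpha
  if (!is.null(nonPvcResults)) {
    np <- bind(nonPvcResults)
    np$flaggedNoPvc <- !is.na(np$p) & np$estimate < 0 & np$p < alpha
    np <- np[, c("region", "estimate", "p", "flaggedNoPvc")]
    names(np)[2:3] <- c("estimateNoPvc", "pNoPvc")
    res <- merge(res, np, by = "region", all.x = TRUE, sort = FALSE)
  }
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
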