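#' Probability-matched z statistic from a t statistic
#'
#' Maps a t value to the standard normal quantile of equal cumulative
#' probability, `z = qnorm(pt(t, df))`, the convention used when reporting
#' voxel peak statistics as Z. Monotone in t, and equal to t in the df ->
#' infinity limit; computed on the log-probability scale for tail accuracy.
#'
#' @param t Numeric vector of t values.
#' @param df Degrees of freedom (>= 1).
#' @return z values (non-finite t propagates).
#' @export
tToZ <- function(t, df) {
  if (df < 1) stop("df must be >= 1")
  z <- rep(NA_real_, length(t))
  ok <- is.finite(t)
  neg <- ok & t <= 0
  posv <- ok & t > 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[posv] <- -stats::qnorm(stats::pt(-t[posv], df, log.p = TRUE),
                           log.p = TRUE)
  z[!ok] <- t[!ok]
  z
}

#' Cohen's d for a paired peak statistic
#'
#' The paired-design effect size convention `d = z / sqrt(n)`, where z is the
#' probability-matched peak statistic and n the number of pairs.
#'
#' @param z Peak z value(s).
#' @param n Number of matched pairs (>= 2).
#' @return Cohen's d.
#' @examples
#' cohensDFromZ(5.33, 24) # about 1.09
#' @export
cohensDFromZ <- function(z, n) {
  if (n < 2) stop("n must be >= 2")
  z / sqrt(n)
}

# difference matrix (pairs x voxels) from matched image lists
.pairedDiffs <- function(baselineImages, followupImages) {
  n <- length(baselineImages)
  if (n != length(followupImages)) stop("image lists must be matched")
  d0 <- dim(baselineImages[[1]])
  for (img in c(baselineImages, followupImages))
    if (!identical(dim(img), d0)) stop("all images must share one grid")
  D <- matrix(0, n, prod(d0))
  for (i in seq_len(n))
    D[i, ] <- as.numeric(voxels(followupImages[[i]])) -
      as.numeric(voxels(baselineImages[[i]]))
  D
}

#' Voxelwise paired t map
#'
#' Computes, at every in-mask voxel, the paired t statistic of follow-up
#' minus baseline differences (`t = mean(d) / (sd(d) / sqrt(n))`, df = n -
#' 1), with decline appearing as negative t. Voxels whose differences have
#' zero variance are undefined and removed from the mask (their count is kept
#' in the result). z and Cohen's d maps use [tToZ()] and the `z / sqrt(n)`
#' convention with the sign of t.
#'
#' @param baselineImages,followupImages Matched lists of
#'   \linkS4class{VolumeImage}s (>= 3 pairs).
#' @param mask Optional logical array restricting the analysis (default: all
#'   voxels).
#' @return A \linkS4class{StatMap}.
#' @export
pairedTMap <- function(baselineImages, followupImages, mask = NULL) {
  n <- length(baselineImages)
  if (n < 3) stop("need at least 3 matched pairs")
  d0 <- dim(baselineImages[[1]])
  if (is.null(mask)) mask <- array(TRUE, d0)
  if (!identical(dim(mask), d0)) stop("mask shape mismatch")
  D <- .pairedDiffs(baselineImages, followupImages)
  idx <- which(mask)
  Dm <- D[, idx, drop = FALSE]
  m <- colMeans(Dm)
  v <- (colSums(Dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0 # guard rounding
  zeroVar <- v <= 0
  t <- rep(NA_real_, length(idx))
  t[!zeroVar] <- m[!zeroVar] / sqrt(v[!zeroVar] / n)
  df <- n - 1
  tArr <- array(NA_real_, d0)
  tArr[idx] <- t
  zArr <- array(NA_real_, d0)
  zArr[idx] <- tToZ(t, df)
  dArr <- zArr / sqrt(n)
  maskOut <- array(FALSE, d0)
  maskOut[idx[!zeroVar]] <- TRUE
  new("StatMap", tValues = tArr, zValues = zArr, dValues = dArr,
      mask = maskOut, df = df, nPairs = n, nZeroVariance = sum(zeroVar),
      voxelSize = voxelSize(baselineImages[[1]]))
}

#' Suprathreshold cluster formation
#'
#' Applies the one-tailed cluster-forming threshold for decline: voxels with
#' `-t >= qt(1 - cftP, df)` inside the mask are grouped into connected
#' components (18-neighbour connectivity by default, the SPM convention).
#'
#' @param statmap A \linkS4class{StatMap}.
#' @param cftP One-tailed cluster-forming p (in (0, 0.5], default 0.001).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return List with `labels` (integer array, 0 = background), `extents`
#'   (voxel counts per cluster, decreasing cluster id order not guaranteed),
#'   and `threshold` (the t cutoff applied to -t).
#' @export
formClusters <- function(statmap, cftP = 0.001, connectivity = 18L) {
  stopifnot(is(statmap, "StatMap"))
  if (cftP <= 0 || cftP > 0.5) stop("cftP must be in (0, 0.5]")
  tStar <- stats::qt(1 - cftP, statDf(statmap))
  supra <- maskArray(statmap) & !is.na(tValues(statmap)) &
    (-tValues(statmap) >= tStar)
  labels <- .label3d(as.logical(supra), dim(supra), as.integer(connectivity))
  nl <- max(labels)
  list(labels = labels,
       extents = if (nl > 0) tabulate(labels[labels > 0], nbins = nl)
                 else integer(0),
       threshold = tStar)
}

# max cluster extent for one suprathreshold logical vector over mask indices
.maxExtent <- function(supraVec, idx, dims, connectivity) {
  if (!any(supraVec)) return(0L)
  arr <- logical(prod(dims))
  arr[idx[supraVec]] <- TRUE
  labels <- .label3d(arr, dims, connectivity)
  if (max(labels) == 0L) 0L else max(tabulate(labels[labels > 0L]))
}

#' Cluster-level FWER by sign-flip permutation
#'
#' Family-wise error corrected cluster p-values for the paired decline
#' analysis. Under the null of symmetrically distributed paired differences,
#' each pair's difference image can have its sign flipped; the null
#' distribution of the maximum suprathreshold cluster extent is built over
#' random sign flips, and each observed cluster receives
#' `corrected_p = (1 + #(permutation max extent >= observed extent)) /
#' (1 + nPermutations)`. When `nPermutations >= 2^n` the 2^n flip patterns
#' are enumerated exhaustively and p-values are exact
#' (`#(max extent >= observed) / 2^n`). Deterministic for a fixed seed.
#'
#' @param baselineImages,followupImages Matched lists of
#'   \linkS4class{VolumeImage}s.
#' @param mask Optional logical analysis mask.
#' @param cftP One-tailed cluster-forming p (default 0.001).
#' @param nPermutations Requested number of sign-flip permutations (>= 100
#'   recommended; capped at exhaustive enumeration).
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity (default 18).
#' @return A data frame (cluster table) with columns `cluster_id`,
#'   `extent_voxels`, `corrected_p`, `peak_z`, `peak_d` (decline-positive
#'   convention), `x_mm`, `y_mm`, `z_mm` (grid-centre origin), sorted by
#'   extent; attributes `nullMaxExtent` (the permutation null), `nPermUsed`,
#'   `exhaustive`, and `statmap`.
#' @export
permutationClusterFwer <- function(baselineImages, followupImages,
                                   mask = NULL, cftP = 0.001,
                                   nPermutations = 1000L, seed = 1L,
                                   connectivity = 18L) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  sm <- pairedTMap(baselineImages, followupImages, mask)
  n <- sm@nPairs
  dims <- dim(tValues(sm))
  clus <- formClusters(sm, cftP, connectivity)
  labArr <- clus$labels
  extents <- clus$extents
  tStar <- clus$threshold
  # differences restricted to the analysis mask
  idx <- which(maskArray(sm))
  D <- .pairedDiffs(baselineImages, followupImages)[, idx, drop = FALSE]
  S2 <- colSums(D^2)
  exhaustive <- log2(nPermutations) >= n || nPermutations >= 2^n
  if (exhaustive) {
    B <- as.integer(2^n)
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
  } else {
    B <- as.integer(nPermutations)
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
    allPlus <- rowSums(flips == 1) == n
    while (any(allPlus)) { # identity is never a sampled permutation
      flips[allPlus, ] <- sample(c(-1, 1), sum(allPlus) * n, replace = TRUE)
      allPlus <- rowSums(flips == 1) == n
    }
  }
  nullMax <- integer(B)
  chunk <- max(1L, min(B, as.integer(2^22 / max(1, length(idx)))))
  start <- 1L
  while (start <= B) {
    rows <- start:min(B, start + chunk - 1L)
    M <- flips[rows, , drop = FALSE] %*% D / n
    V <- sweep(-n * M^2, 2, S2, `+`) / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    supra <- is.finite(Tm) & (-Tm >= tStar)
    for (r in seq_along(rows))
      nullMax[rows[r]] <- .maxExtent(supra[r, ], idx, dims, connectivity)
    start <- start + chunk
  }
  K <- length(extents)
  if (K == 0L) {
    tab <- data.frame(cluster_id = integer(0), extent_voxels = integer(0),
                      corrected_p = numeric(0), peak_z = numeric(0),
                      peak_d = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0))
  } else {
    ord <- order(-extents)
    ctr <- (dims + 1) / 2
    vs <- sm@voxelSize
    rows <- lapply(seq_along(ord), function(i) {
      lab <- ord[i]
      vox <- which(labArr == lab)
      declineZ <- -zValues(sm)[vox]
      peak <- vox[which.max(declineZ)]
      pk <- arrayInd(peak, dims)
      if (exhaustive)
        p <- sum(nullMax >= extents[lab]) / B
      else
        p <- (1 + sum(nullMax >= extents[lab])) / (1 + B)
      data.frame(cluster_id = i, extent_voxels = extents[lab],
                 corrected_p = p, peak_z = max(declineZ),
                 peak_d = cohensDFromZ(max(declineZ), n),
                 x_mm = (pk[1] - ctr[1]) * vs[1],
                 y_mm = (pk[2] - ctr[2]) * vs[2],
                 z_mm = (pk[3] - ctr[3]) * vs[3])
    })
    tab <- do.call(rbind, rows)
  }
  attr(tab, "nullMaxExtent") <- nullMax
  attr(tab, "nPermUsed") <- B
  attr(tab, "exhaustive") <- exhaustive
  attr(tab, "statmap") <- sm
  tab
}
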