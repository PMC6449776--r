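# Shared fixtures and independent oracles, all built in code.

# A tiny hand-built two-region atlas on an nxnxn grid: a cubic "hot" region
# and a cerebellum slab, the rest background.
tinyAtlas <- function(n = 16L, voxel = 1.5) {
  labs <- array(0L, c(n, n, n))
  labs[3:6, 3:6, 3:6] <- 1L                 # small target region
  labs[(n - 4):(n - 2), 2:(n - 1), 2:(n - 1)] <- 2L  # cerebellum slab
  nm <- c("1" = "target", "2" = "cerebellum")
  new("LabelAtlas", labels = labs, regionNames = nm,
      voxelSize = rep(voxel, 3), referenceRegion = "cerebellum")
}

# piecewise-constant image over a tiny atlas
paintAtlas <- function(atlas, values, background = 0) {
  labs <- voxels(atlas)
  img <- array(background, dim(labs))
  for (l in seq_along(values)) img[labs == l] <- values[l]
  volumeImage(img, voxelSize(atlas)[1])
}

# Direct loop-based 1-D reblurred Van Cittert oracle with the same
# half-sample-symmetric boundary handling as the package convolution.
conv1dReflect <- function(x, kern) {
  n <- length(x)
  r <- (length(kern) - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (t in -r:r) {
      j <- i + t
      if (j < 1L) j <- 1L - j
      if (j > n) j <- 2L * n + 1L - j
      s <- s + kern[t + r + 1L] * x[j]
    }
    out[i] <- s
  }
  out
}

vanCittert1dOracle <- function(g, kern, alpha, tolPercent, maxIter) {
  f <- g
  for (k in seq_len(maxIter)) {
    resid <- g - conv1dReflect(f, kern)
    fNew <- f + alpha * conv1dReflect(resid, kern)
    ch <- 100 * sum(abs(fNew - f)) / sum(abs(f))
    f <- fNew
    if (ch < tolPercent) break
  }
  f
}

# Minimal null-effect parameter set: one test region plus the reference,
# identical slopes in both groups.
nullEffectParams <- function(scanMonths, pct = -0.3) {
  ep <- defaultEffectParams(scanMonths, regions = c("cerebellum", "parietal"))
  ep$pctNoncarrier <- ep$pctCarrier
  ep$slopeNoncarrier <- ep$slopeCarrier
  ep
}

# random VolumeImage helper
randomImage <- function(dims, sd = 1, voxel = 1.5) {
  volumeImage(array(stats::rnorm(prod(dims), sd = sd), dims), voxel)
}
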