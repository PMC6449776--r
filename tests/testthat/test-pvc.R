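test_that("FWHM-to-sigma conversion matches its closed form and inverts", {
  expect_identical(fwhmToSigma(0), 0)
  expect_equal(fwhmToSigma(8), 8 / (2 * sqrt(2 * log(2))))
  expect_equal(fwhmToSigma(8), 3.39728, tolerance = 1e-5)
  expect_equal(fwhmToSigma(2.35482), 1, tolerance = 1e-4)
  expect_error(fwhmToSigma(-1), "non-negative")
})

test_that("Gaussian blur is an identity at zero FWHM and on constant fields", {
  set.seed(3)
  img <- randomImage(c(10, 12, 10))
  expect_identical(voxels(gaussianBlur(img, 0)), voxels(img))
  const <- volumeImage(array(2.7, c(12, 12, 12)), 1.5)
  expect_equal(voxels(gaussianBlur(const, 8)), voxels(const),
               tolerance = 1e-12)
})

test_that("blurred delta reproduces the discretised separable kernel", {
  d <- array(0, c(41, 41, 41))
  d[21, 21, 21] <- 1
  b <- gaussianBlur(volumeImage(d, 1.5), 8)
  k <- longpet:::gaussianKernel1D(fwhmToSigma(8) / 1.5)
  r <- (length(k) - 1) / 2
  # center value is the product of the three axis kernel peaks
  expect_equal(voxels(b)[21, 21, 21], max(k)^3, tolerance = 1e-12)
  # full neighbourhood equals the outer product of the 1-D kernels
  sub <- voxels(b)[21 + (-r:r), 21 + (-r:r), 21 + (-r:r)]
  expect_equal(sub, outer(outer(k, k), k), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(voxels(b)), 1, tolerance = 1e-6)
})

test_that("anisotropic voxel sizes get per-axis kernel widths", {
  d <- array(0, c(31, 31, 31))
  d[16, 16, 16] <- 1
  b <- gaussianBlur(volumeImage(d, c(1, 2, 4)), 8)
  # wider voxels mean fewer voxels per sigma: profile along z decays fastest
  v <- voxels(b)
  expect_gt(v[18, 16, 16], v[16, 18, 16])
  expect_gt(v[16, 18, 16], v[16, 16, 18])
  expect_equal(sum(v), 1, tolerance = 1e-6)
})

test_that("relative percent change matches hand arithmetic", {
  a <- volumeImage(array(c(1, 2, 3, 4), c(2, 2, 1)), 1.5)
  expect_equal(relativePercentChange(a, a), 0)
  b <- volumeImage(1.01 * voxels(a), 1.5)
  expect_equal(relativePercentChange(b, a), 1, tolerance = 1e-12)
  c2 <- volumeImage(array(c(1.1, 2, 2.8, 4.4), c(2, 2, 1)), 1.5)
  # sum|diff| = .1+0+.2+.4 = .7 over sum|old| = 10
  expect_equal(relativePercentChange(c2, a), 7)
  expect_error(relativePercentChange(a, volumeImage(array(1, c(3, 3, 1)), 1.5)),
               "shapes differ")
  expect_error(relativePercentChange(a, volumeImage(array(0, c(2, 2, 1)), 1.5)),
               "identically zero")
})

test_that("a constant image is a Van Cittert fixed point", {
  const <- volumeImage(array(1.3, c(14, 14, 14)), 1.5)
  res <- vanCittertPVC(const, 8)
  expect_equal(res$nIterations, 1L)
  expect_equal(res$changeHistory, 0)
  expect_equal(voxels(res$corrected), voxels(const), tolerance = 1e-12)
})

test_that("stopping rule: last change below tolerance, history finite", {
  set.seed(11)
  atl <- tinyAtlas()
  img <- gaussianBlur(paintAtlas(atl, c(1.4, 1.0), background = 0.5), 8)
  res <- vanCittertPVC(img, 8, tolPercent = 1, maxIter = 30)
  expect_true(all(is.finite(res$changeHistory)))
  expect_lt(res$nIterations, 30)
  expect_lt(res$changeHistory[res$nIterations], 1)
  expect_true(all(res$changeHistory[-res$nIterations] >= 1))
})

test_that("flux-error recursion has ratio -(1 - alpha) and PVC conserves flux", {
  set.seed(4)
  atl <- tinyAtlas()
  g <- gaussianBlur(paintAtlas(atl, c(1.2, 1.0), background = 0.8), 8)
  alpha <- 1.5
  sG <- sum(voxels(g))
  # start the recursion from an iterate whose sum deliberately differs
  f <- volumeImage(voxels(g) + 0.01, voxelSize(g))
  errs <- numeric(5)
  for (k in 1:5) {
    resid <- volumeImage(voxels(g) - voxels(gaussianBlur(f, 8)), voxelSize(g))
    f <- volumeImage(voxels(f) + alpha * voxels(gaussianBlur(resid, 8)),
                     voxelSize(g))
    errs[k] <- sum(voxels(f)) - sG
  }
  ratios <- errs[-1] / errs[-5]
  expect_equal(ratios, rep(1 - alpha, 4), tolerance = 1e-8)
  # the standard iteration starts at g, so its flux never deviates
  res <- vanCittertPVC(g, 8, alpha = alpha)
  expect_equal(sum(voxels(res$corrected)) / sG, 1, tolerance = 1e-8)
})

test_that("3-D iteration restricted to one axis matches the 1-D loop oracle", {
  set.seed(21)
  n <- 64
  fTrue <- rep(1, n)
  fTrue[25:40] <- 1.5 # boxcar
  sigmaVox <- fwhmToSigma(8) / 1.5
  kern <- longpet:::gaussianKernel1D(sigmaVox)
  g1 <- conv1dReflect(fTrue, kern)
  # replicate the profile along y and z: constant in those axes, so the 3-D
  # separable blur reduces to the 1-D convolution along x
  arr <- array(rep(g1, times = 144), c(n, 12, 12))
  res3d <- vanCittertPVC(volumeImage(arr, 1.5), 8, alpha = 1.5,
                         tolPercent = 1, maxIter = 30)
  oracle <- vanCittert1dOracle(g1, kern, alpha = 1.5, tolPercent = 1,
                               maxIter = 30)
  expect_equal(voxels(res3d$corrected)[, 6, 6], oracle, tolerance = 1e-10)
  # deconvolution recovers the boxcar better than the blurred input
  rmse <- function(x) sqrt(mean((x - fTrue)^2))
  expect_lt(rmse(oracle), rmse(g1))
})

test_that("PVC pulls small-region means back toward truth under 8 mm blur", {
  atl <- tinyAtlas()
  truthVals <- c(1.2, 1.0)
  truthImg <- paintAtlas(atl, truthVals, background = 1.0)
  blurred <- gaussianBlur(truthImg, 8)
  pvc <- vanCittertPVC(blurred, 8)$corrected
  mBlur <- roiMeans(blurred, atl)
  mPvc <- roiMeans(pvc, atl)
  # hot region 20% above surround: blurred mean lies between truth and
  # background, PVC strictly closer to truth
  expect_gt(mBlur[["target"]], 1.0)
  expect_lt(mBlur[["target"]], 1.2)
  expect_lt(abs(mPvc[["target"]] - 1.2), abs(mBlur[["target"]] - 1.2))
})

test_that("invalid PVC settings are rejected", {
  img <- volumeImage(array(1, c(8, 8, 8)), 1.5)
  expect_error(vanCittertPVC(img, 0), "fwhmMm")
  expect_error(vanCittertPVC(img, 8, alpha = 2), "alpha")
  expect_error(vanCittertPVC(img, 8, tolPercent = 0), "tolPercent")
  expect_error(vanCittertPVC(img, 8, maxIter = 0), "maxIter")
})
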