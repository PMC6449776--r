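test_that("paired t map matches hand arithmetic and the loop oracle", {
  # single-voxel hand case: diffs -0.1, -0.2, -0.3
  base <- lapply(c(1, 1, 1), function(v) volumeImage(array(v, c(1, 1, 1)), 1.5))
  fup <- lapply(c(0.9, 0.8, 0.7),
                function(v) volumeImage(array(v, c(1, 1, 1)), 1.5))
  sm <- pairedTMap(base, fup)
  expect_equal(statDf(sm), 2)
  expect_equal(tValues(sm)[1, 1, 1], -0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tValues(sm)[1, 1, 1], -3.4641, tolerance = 1e-4)

  # identical pairs: every voxel has zero variance and is masked out
  same <- replicate(4, randomImage(c(4, 4, 4)), simplify = FALSE)
  smNull <- pairedTMap(same, same)
  expect_equal(sum(maskArray(smNull)), 0)
  expect_equal(smNull@nZeroVariance, 64)
  expect_true(all(is.na(tValues(smNull))))

  # full-map brute-force oracle on an 8x8x8 grid
  set.seed(5)
  n <- 6
  b <- replicate(n, randomImage(c(8, 8, 8)), simplify = FALSE)
  f <- replicate(n, randomImage(c(8, 8, 8)), simplify = FALSE)
  sm2 <- pairedTMap(b, f)
  for (vox in list(c(1, 1, 1), c(3, 5, 2), c(8, 8, 8))) {
    d <- vapply(seq_len(n), function(i)
      voxels(f[[i]])[vox[1], vox[2], vox[3]] -
        voxels(b[[i]])[vox[1], vox[2], vox[3]], numeric(1))
    expect_equal(tValues(sm2)[vox[1], vox[2], vox[3]],
                 mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-10)
  }
})

test_that("t-to-z mapping is probability-matched and asymptotically identity", {
  expect_equal(tToZ(0, 5), 0)
  expect_equal(tToZ(2.5, 1e6), 2.5, tolerance = 1e-3)
  expect_equal(tToZ(-1.7, 23), -tToZ(1.7, 23), tolerance = 1e-12)
  # quadrature oracle: integrate the t density at df = 23
  for (t in c(-3.2, -1.1, 0.7, 2.4, 4.8)) {
    dens <- function(x) dt(x, 23)
    p <- integrate(dens, -Inf, t, rel.tol = 1e-12)$value
    expect_equal(tToZ(t, 23), qnorm(p), tolerance = 1e-8)
  }
  expect_true(is.na(tToZ(NA_real_, 23)))
})

test_that("paired effect-size convention is z over root n", {
  expect_equal(cohensDFromZ(0, 24), 0)
  expect_equal(cohensDFromZ(5.33, 24), 1.09, tolerance = 0.005)
  expect_equal(cohensDFromZ(3.59, 24), 0.73, tolerance = 0.005)
  expect_error(cohensDFromZ(1, 1), "n must be")
})

test_that("cluster formation thresholds -t and respects connectivity", {
  mkStat <- function(tArr, n = 10) {
    dims <- dim(tArr)
    new("StatMap", tValues = tArr, zValues = tArr, dValues = tArr / sqrt(n),
        mask = array(TRUE, dims), df = n - 1, nPairs = n,
        nZeroVariance = 0, voxelSize = rep(1.5, 3))
  }
  zero <- mkStat(array(0, c(6, 6, 6)))
  expect_length(formClusters(zero)$extents, 0)

  # two disjoint 5-voxel blobs of strong decline
  tArr <- array(0, c(10, 10, 10))
  tArr[1:5, 1, 1] <- -10
  tArr[1:5, 8, 8] <- -10
  cl <- formClusters(mkStat(tArr), cftP = 0.001)
  expect_equal(sort(cl$extents), c(5, 5))

  # an edge-diagonal pair merges under 18- but not 6-connectivity
  tArr2 <- array(0, c(5, 5, 5))
  tArr2[2, 2, 2] <- -10
  tArr2[2, 3, 3] <- -10 # shares an edge: distance (0,1,1)
  expect_length(formClusters(mkStat(tArr2), connectivity = 18)$extents, 1)
  expect_length(formClusters(mkStat(tArr2), connectivity = 6)$extents, 2)
})

test_that("permutation cluster p-values behave as exact sign-flip inference", {
  set.seed(71)
  n <- 5
  dims <- c(8, 8, 8)
  b <- replicate(n, randomImage(dims, sd = 0.05), simplify = FALSE)
  f <- lapply(b, function(img) {
    v <- voxels(img) + array(rnorm(prod(dims), 0, 0.05), dims)
    v[3:5, 3:5, 3:5] <- v[3:5, 3:5, 3:5] - 1.5 # strong focal decline
    volumeImage(v, 1.5)
  })
  tab <- permutationClusterFwer(b, f, nPermutations = 1e6, seed = 1)
  # exhaustive cap: 2^5 = 32 patterns used despite the huge request
  expect_equal(attr(tab, "nPermUsed"), 32L)
  expect_true(attr(tab, "exhaustive"))
  expect_gte(nrow(tab), 1)
  expect_equal(tab$extent_voxels[1], 27)
  # p monotone non-increasing in extent
  expect_true(all(diff(tab$corrected_p[order(-tab$extent_voxels)]) >= 0))
  # invariant to relabeling pair order (exhaustive enumeration)
  ord <- c(3, 1, 5, 2, 4)
  tab2 <- permutationClusterFwer(b[ord], f[ord], nPermutations = 1e6, seed = 9)
  expect_equal(tab$corrected_p, tab2$corrected_p)
  expect_equal(tab$extent_voxels, tab2$extent_voxels)
})

test_that("negating every pair maps decline analysis onto increase analysis", {
  set.seed(14)
  n <- 6
  dims <- c(7, 7, 7)
  b <- replicate(n, randomImage(dims), simplify = FALSE)
  f <- lapply(b, function(img)
    volumeImage(voxels(img) + array(rnorm(prod(dims), 0.4, 1), dims), 1.5))
  smFwd <- pairedTMap(b, f)   # increases dominate: few decline clusters
  smRev <- pairedTMap(f, b)   # swapped: the increases become declines
  expect_equal(tValues(smRev), -tValues(smFwd), tolerance = 1e-10)
  clFwdUp <- which(-tValues(smFwd) <= -qt(0.999, statDf(smFwd)))
  clRev <- formClusters(smRev, cftP = 0.001)
  expect_identical(sort(which(clRev$labels > 0)), sort(clFwdUp))
})

test_that("d equals z over root n across a cluster table", {
  set.seed(33)
  n <- 8
  b <- replicate(n, randomImage(c(8, 8, 8), sd = 0.2), simplify = FALSE)
  f <- lapply(b, function(img) {
    v <- voxels(img) - 0.05
    v[2:4, 2:4, 2:4] <- v[2:4, 2:4, 2:4] - 1
    volumeImage(v + array(rnorm(512, 0, 0.2), c(8, 8, 8)), 1.5)
  })
  tab <- permutationClusterFwer(b, f, nPermutations = 200, seed = 5)
  expect_gte(nrow(tab), 1)
  expect_equal(tab$peak_d, tab$peak_z / sqrt(n), tolerance = 0.005)
})
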