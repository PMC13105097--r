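test_that("the dyadic tensor is traceless, sign-invariant and of fixed norm", {
  d <- c(4L, 4L, 4L)
  fz <- dyadicField(constantField(d, c(0, 0, 1)))
  expect_equal(fz@comps[1, 1, 1, ], c(-1/3, -1/3, 2/3, 0, 0, 0))
  vminus <- dyadicField(constantField(d, c(0, 0, -1)))
  expect_equal(fz@comps, vminus@comps)
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    comp <- dyadicField(constantField(d, v))@comps[1, 1, 1, ]
    expect_equal(sum(comp[1:3]), 0, tolerance = 1e-12)          # trace
    expect_equal(sum(comp[1:3]^2) + 2 * sum(comp[4:6]^2), 2 / 3,
                 tolerance = 1e-12)                             # |T|_F^2
  }
  # invalid voxels carry the zero tensor
  fld <- constantField(d, c(0, 0, 1))
  fld@valid[1, 1, 1] <- FALSE
  expect_equal(dyadicField(fld)@comps[1, 1, 1, ], rep(0, 6))
})

test_that("the spectral ACF matches direct summation and is symmetric with unit zero lag", {
  set.seed(5)
  d <- c(10L, 10L, 10L)
  ax <- fiberarch:::canonicalizeAxes(
    fiberarch:::unitRows(matrix(rnorm(prod(d) * 3), ncol = 3)))
  fld <- new("OrientationField", axis = array(ax, c(d, 3L)),
             coherence = array(1, d), energy = array(1, d),
             valid = array(runif(prod(d)) > 0.3, d), voxelSize = rep(1, 3))
  dy <- dyadicField(fld)
  av <- acf3d(dy, maxLagVox = 5, minSide = 8L)
  expect_lt(max(abs(av@acf - bruteForceACF(dy, 5L)), na.rm = TRUE), 1e-10)
  expect_equal(av@acf[6, 6, 6], 1)
  flip <- av@acf[11:1, 11:1, 11:1]
  expect_lt(max(abs(av@acf - flip), na.rm = TRUE), 1e-10)
})

test_that("constant orientation fields are flagged homogeneous and refuse profiling", {
  av <- acf3d(dyadicField(constantField(c(32L, 32L, 32L), c(0, 0, 1))))
  expect_true(av@homogeneous)
  expect_error(radialProfiles(av, diag(3)), "homogeneous")
})

test_that("regions below the valid-fraction floor are reported insufficient", {
  d <- c(32L, 32L, 32L)
  valid <- array(FALSE, d)
  valid[1:4, 1:4, 1:4] <- TRUE # 0.2% valid
  fld <- constantField(d, c(0, 0, 1), valid = valid)
  expect_error(acf3d(dyadicField(fld)), "insufficient")
})

test_that("block frames are orthonormal with peaks mapped to the leading axes", {
  fr <- blockFrame(rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(abs(fr[1, ]), c(0, 0, 1))
  expect_equal(abs(fr[2, ]), c(1, 0, 0))
  expect_equal(abs(fr[3, ]), c(0, 1, 0)) # e3 = e1 x e2 up to sign
  frZ <- blockFrame(matrix(c(0, 0, 1), 1))
  expect_equal(frZ %*% t(frZ), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:20) {
    pk <- fiberarch:::unitRows(matrix(rnorm(6), ncol = 3))
    fr <- blockFrame(pk)
    expect_equal(abs(det(fr)), 1, tolerance = 1e-9)
    expect_equal(fr %*% t(fr), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(blockFrame(matrix(numeric(), 0, 3)), "no peaks")
})

test_that("profiles of an isotropic exponential ACF reproduce the decay on every axis and plane", {
  L <- 10L
  g <- -L:L
  xi0 <- 6
  C <- exp(-sqrt(outer(outer(g^2, g^2, `+`), g^2, `+`)) / xi0)
  av <- new("ACFVolume", acf = C, lagSpacing = rep(1, 3),
            nPairs = array(1, dim(C)), variance0 = 1, homogeneous = FALSE)
  fr <- blockFrame(rbind(c(0, 0, 1), c(1, 0, 0)))
  pr <- radialProfiles(av, fr)
  expect_equal(pr@r[1], 0)
  target <- exp(-pr@r / xi0)
  for (a in 1:3) expect_equal(pr@axial[a, ], target, tolerance = 0.02,
                              ignore_attr = TRUE)
  expect_equal(pr@fiberPlaneRadial, target, tolerance = 0.02)
  expect_equal(pr@transverseRadial, target, tolerance = 0.02)
  expect_equal(pr@transverseRadial[1], 1)
})

test_that("exponential correlation lengths are recovered exactly and degenerate profiles are capped or rejected", {
  r <- 0:50
  f <- fitCorrelationLength(r, exp(-r / 20))
  expect_true(f$ok)
  expect_false(f$capped)
  expect_equal(f$xi, 20, tolerance = 1e-6)
  expect_gt(f$r2, 0.999)

  flat <- fitCorrelationLength(r, rep(1, 51))
  expect_true(flat$capped)
  expect_equal(flat$xi, 50)

  osc <- fitCorrelationLength(r, cos(2 * pi * r / 40) * exp(-r / 30))
  expect_true(osc$ok)
  expect_lt(osc$r2, 0.9) # exponential model misfit is detectable

  few <- fitCorrelationLength(0:3, exp(-(0:3) / 2))
  expect_false(few$ok)
})

test_that("the maximum autocorrelation length is the max over frame axes with failure propagation", {
  expect_identical(maxAutocorrelationLength(c(20, 8, 8)), 20)
  expect_identical(maxAutocorrelationLength(c(NA, 12, NA)), 12)
  expect_error(maxAutocorrelationLength(c(NA_real_, NA, NA)), "undefined")
})

test_that("mean-subtracted ACFs decay to zero beyond the correlation support on meshwork fields", {
  an <- fxAnalysis("meshwork", seed = 1L)
  f <- fxMeshworkField()
  av <- acf3d(dyadicField(f$field),
              region = list(origin = c(0L, 0L, 0L), size = rep(100L, 3)))
  lag <- (dim(av@acf) - 1) / 2
  idx <- which(!is.na(av@acf), arr.ind = TRUE)
  rr <- sqrt((idx[, 1] - lag[1] - 1)^2 + (idx[, 2] - lag[2] - 1)^2 +
               (idx[, 3] - lag[3] - 1)^2)
  far <- av@acf[idx][rr > 20] # well beyond the few-um meshwork support
  expect_lt(abs(mean(far)), 0.05)
})

test_that("correlation lengths are stable under default imaging noise on bundles", {
  xiNoisy <- fxAnalysis("bundled", seed = 1L)$table$xi_max
  an0 <- fxAnalysis("bundled", seed = 1L, noiseSd = 0)
  xi0 <- an0$table$xi_max
  expect_lt(abs(xiNoisy - xi0) / xi0, 0.25)
})

test_that("bundles organize over longer scales than meshwork at matched settings", {
  xiB <- fxAnalysis("bundled", seed = 1L)$table$xi_max
  xiM <- fxAnalysis("meshwork", seed = 1L)$table$xi_max
  expect_gt(xiB, xiM)
})
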