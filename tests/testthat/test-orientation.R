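test_that("structure tensor of a constant volume vanishes and a pure ramp gives a rank-one x tensor", {
  const <- array(5, c(16, 16, 16))
  tf <- computeStructureTensor(const, 1)
  expect_lt(max(abs(tf@tensors)), 1e-12)

  # 21^3 so the tensor window at the center sees no mirror-boundary voxels
  ramp <- array(0, c(21, 21, 21))
  for (x in 1:21) ramp[, , x] <- x
  tr <- computeStructureTensor(ramp, 1, structureTensorParams(0.8, 1.2))
  ctr <- tr@tensors[11, 11, 11, ]
  expect_equal(ctr[1], 1, tolerance = 1e-9)       # xx = |dI/dx|^2 = 1
  expect_lt(max(abs(ctr[2:6])), 1e-9)             # all other components 0
})

test_that("tensor at the center of a tiny volume equals the direct windowed sum of gradient outer products", {
  set.seed(11)
  d <- c(9, 9, 9)
  vol <- array(rnorm(prod(d)), d)
  p <- structureTensorParams(0.8, 1.0)
  tf <- computeStructureTensor(vol, 1, p)

  # independent oracle: explicit correlation sums with mirror boundary
  refl <- function(i, n) {
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  corr1 <- function(a, k, axis) {
    out <- array(0, dim(a))
    cK <- (length(k) + 1) / 2
    for (t in seq_along(k)) {
      sh <- t - cK
      idx <- lapply(dim(a), seq_len)
      idx[[axis]] <- refl(idx[[axis]] + sh, dim(a)[axis])
      out <- out + k[t] * do.call(`[`, c(list(a), idx))
    }
    out
  }
  sep <- function(a, ks) corr1(corr1(corr1(a, ks[[1]], 1), ks[[2]], 2), ks[[3]], 3)
  g <- fiberarch:::gaussKernel1d(0.8)
  dg <- fiberarch:::dogKernel1d(0.8)
  gx <- sep(vol, list(g, g, dg))
  gy <- sep(vol, list(g, dg, g))
  gz <- sep(vol, list(dg, g, g))
  w <- fiberarch:::gaussKernel1d(1.0)
  smooth <- function(a) sep(a, list(w, w, w))
  expect_equal(tf@tensors[5, 5, 5, 1], smooth(gx * gx)[5, 5, 5], tolerance = 1e-10)
  expect_equal(tf@tensors[5, 5, 5, 4], smooth(gx * gy)[5, 5, 5], tolerance = 1e-10)
  expect_equal(tf@tensors[5, 5, 5, 6], smooth(gy * gz)[5, 5, 5], tolerance = 1e-10)
})

test_that("an extruded 2D texture yields the extrusion axis everywhere valid", {
  set.seed(4)
  tex <- matrix(runif(32 * 32), 32, 32)
  vol <- array(0, c(32, 32, 32))
  for (z in 1:32) vol[z, , ] <- tex
  fld <- principalOrientation(computeStructureTensor(vol, 1))
  n <- 32^3
  vi <- which(validMask(fld))
  expect_gt(length(vi), 1000)
  vz <- abs(fld@axis[vi + 2 * n])
  expect_true(all(vz > 0.99))
})

test_that("bundled phantom orientations are recovered with sub-degree median error without noise", {
  f <- fxCleanBundle48()
  err <- medianAxisError(f$field, f$phantom@truthMask, c(1, 2, 2) / 3)
  expect_lt(err, 5)
})

test_that("orientation estimation is equivariant under a 90-degree rotation about z", {
  f <- fxCleanBundle48()
  ph <- f$phantom
  f1 <- f$field
  nn <- 48L
  vol2 <- array(0, c(nn, nn, nn))
  for (x2 in 1:nn) vol2[, , x2] <- ph@volume[, nn + 1 - x2, ]
  f2 <- principalOrientation(computeStructureTensor(vol2, 1))
  n3 <- nn^3
  idx2 <- which(validMask(f2))
  co <- arrayInd(idx2, c(nn, nn, nn))
  co1 <- cbind(co[, 1], nn + 1 - co[, 3], co[, 2])
  keep <- validMask(f1)[co1]
  idx2 <- idx2[keep]; co1 <- co1[keep, , drop = FALSE]
  V2 <- cbind(f2@axis[idx2], f2@axis[idx2 + n3], f2@axis[idx2 + 2 * n3])
  i1 <- co1[, 1] + (co1[, 2] - 1) * nn + (co1[, 3] - 1) * nn^2
  V1 <- cbind(f1@axis[i1], f1@axis[i1 + n3], f1@axis[i1 + 2 * n3])
  rot <- cbind(-V1[, 2], V1[, 1], V1[, 3]) # +90 deg about z
  err <- fiberarch:::axialAngleDeg(V2, rot)
  expect_lt(median(err), 0.5)
})

test_that("structure tensors are symmetric positive semidefinite on noise volumes", {
  set.seed(13)
  vol <- array(rnorm(32^3)^2, c(32, 32, 32))
  tf <- computeStructureTensor(vol, 1)
  ev <- fiberarch:::.eigSymField(matrix(tf@tensors, ncol = 6))$eigenvalues
  tr <- rowSums(ev)
  expect_true(all(ev[, 1] >= -1e-8 * pmax(tr, 1e-300)))
})

test_that("sign canonicalization is idempotent and leaves the largest component positive", {
  set.seed(7)
  V <- fiberarch:::unitRows(matrix(rnorm(3000), ncol = 3))
  C1 <- fiberarch:::canonicalizeAxes(V)
  expect_identical(fiberarch:::canonicalizeAxes(C1), C1)
  a <- abs(C1)
  m <- pmax(a[, 1], a[, 2], a[, 3])
  picked <- C1[cbind(seq_len(nrow(C1)),
                     ifelse(a[, 3] == m, 3L, ifelse(a[, 2] == m, 2L, 1L)))]
  expect_true(all(picked > 0))
})

test_that("pure noise volumes are less coherent than structured phantoms", {
  set.seed(19)
  noiseVol <- array(abs(rnorm(48^3, 0.5, 0.2)), c(48, 48, 48))
  fn <- principalOrientation(computeStructureTensor(noiseVol, 1))
  cohNoise <- mean(fn@coherence[validMask(fn)])
  f <- fxCleanBundle48()
  cohPhantom <- mean(f$field@coherence[validMask(f$field)])
  expect_lt(cohNoise, cohPhantom)
})

test_that("orientation error grows monotonically with imaging noise", {
  u <- c(1, 2, 2) / 3
  errs <- vapply(c(0, 0.3, 1.0), function(ns) {
    ph <- generatePhantom(phantomSpec("bundled", shape = c(64, 64, 64),
                                      bundleAxis = u, angularJitterDeg = 0,
                                      noiseSd = ns, seed = 8))
    fld <- principalOrientation(computeStructureTensor(ph@volume, 1))
    medianAxisError(fld, ph@truthMask, u)
  }, 0)
  expect_true(all(diff(errs) >= 0))
})

test_that("orientation-coded RGB maps anatomical axes to pure channels and blacks out invalid voxels", {
  d <- c(4L, 4L, 4L)
  fld <- constantField(d, c(1, 0, 0))
  fld@valid[1, 1, 1] <- FALSE
  rgb <- orientationToRGB(fld)
  expect_equal(rgb[2, 2, 2, ], c(1, 0, 0))        # medio-lateral: red
  expect_equal(rgb[1, 1, 1, ], c(0, 0, 0))        # invalid: black
  fldZ <- constantField(d, c(0, 0, 1))
  expect_equal(orientationToRGB(fldZ)[2, 2, 2, ], c(0, 0, 1)) # AP: blue
})

test_that("degenerate and invalid inputs are handled as specified", {
  expect_error(structureTensorParams(3, 1), "sigmaGradient")
  expect_error(computeStructureTensor(array(0, c(4, 4, 4)), 1),
               "too small")
  expect_error(computeStructureTensor(array(0, c(32, 32, 32)),
                                      c(1, -1, 1)), "voxelSize")
  # isotropic tensors: coherence 0, conventional axis e_z
  const <- array(1, c(16, 16, 16))
  fld <- principalOrientation(computeStructureTensor(const, 1))
  expect_true(all(fld@coherence == 0))
  expect_false(any(validMask(fld)))
  expect_true(all(fld@axis[, , , 3] == 1))
})
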