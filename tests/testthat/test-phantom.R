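test_that("identical specs give bit-identical phantoms", {
  spec <- phantomSpec("bundled", shape = c(48, 48, 48), seed = 21)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a@volume, b@volume)
  expect_identical(a@truthAxis, b@truthAxis)
  expect_identical(a@truthMask, b@truthMask)
})

test_that("bundled phantom without jitter carries the bundle axis as exact ground truth", {
  u <- c(1, 2, 2) / 3
  ph <- generatePhantom(phantomSpec("bundled", shape = c(48, 48, 48),
                                    bundleAxis = u, angularJitterDeg = 0,
                                    seed = 5))
  n <- prod(dim(ph@volume))
  idx <- which(ph@truthMask)
  ta <- cbind(ph@truthAxis[idx], ph@truthAxis[idx + n],
              ph@truthAxis[idx + 2 * n])
  uc <- as.numeric(fiberarch:::canonicalizeAxes(u))
  expect_true(all(abs(sweep(ta, 2, uc)) == 0))
  # orientation is NA exactly off the tube interiors
  expect_true(all(is.na(ph@truthAxis[, , , 1][!ph@truthMask])))
})

test_that("laminar ground truth alternates between layer axes with the set period", {
  ph <- generatePhantom(phantomSpec("laminar", shape = c(120, 48, 48),
                                    laminarPeriod = 40, angularJitterDeg = 0,
                                    noiseSd = 0, seed = 3))
  idx <- which(ph@truthMask)
  isX <- abs(ph@truthAxis[, , , 1][idx]) > 0.9
  zc <- arrayInd(idx, dim(ph@volume))[, 1]
  byPlane <- tapply(isX, zc, mean) # fraction x-oriented per z plane
  frac <- rep(0, 120)              # fiber-free border planes count as 0
  frac[as.integer(names(byPlane))] <- byPlane
  # dominant nonzero spatial frequency of the alternation = 1/40 um^-1:
  # 3 full cycles in the 120-voxel window, so bin k = 3 exactly
  pw <- Mod(fft(frac - mean(frac)))^2
  expect_identical(unname(which.max(pw[2:60])), 3L)
})

test_that("meshwork foreground fraction matches the analytic tube volume within 20%", {
  K <- 40L; rad <- 1; L <- 30
  ph <- generatePhantom(phantomSpec("meshwork", shape = c(64, 64, 64),
                                    fiberCount = K, fiberLength = L,
                                    fiberRadius = rad, seed = 6))
  expected <- K * pi * rad^2 * L / 64^3
  expect_lt(abs(mean(ph@truthMask) - expected) / expected, 0.2)
})

test_that("tube rendering is radially symmetric, identity on empty input and idempotent under coincident fibers", {
  d <- c(33, 33, 33)
  path <- list(cbind(16, 16, c(0, 32))) # along z through the xy center
  canvas <- array(0, d)
  one <- renderFibers(path, radius = 2, canvas, voxelSize = 1)
  sl <- one[17, , ]
  # radial symmetry of any xy slice about the axis
  expect_equal(sl[17 + 5, 17], sl[17 - 5, 17], tolerance = 1e-12)
  expect_equal(sl[17, 17 + 5], sl[17 - 5, 17], tolerance = 1e-12)
  expect_equal(sl[17 + 3, 17 + 4], sl[17 - 5, 17], tolerance = 1e-12)
  expect_equal(max(one), 1, tolerance = 1e-9) # peak amplitude 1 on the axis

  expect_identical(renderFibers(list(), 2, canvas), canvas)
  two <- renderFibers(c(path, path), radius = 2, canvas, voxelSize = 1)
  expect_identical(two, one)
  expect_error(renderFibers(path, radius = 0.2, canvas, voxelSize = 1),
               "unresolvable")
})

test_that("imaging noise model: identity without degradation, constant background, mean preserved", {
  vol <- array(runif(32^3), c(32, 32, 32))
  expect_equal(addImagingNoise(vol, 0, 0, 0), vol)
  zero <- array(0, c(16, 16, 16))
  expect_true(all(addImagingNoise(zero, 0, 0, backgroundLevel = 0.7) == 0.7))
  vol2 <- array(runif(64^3), c(64, 64, 64))
  out <- addImagingNoise(vol2, psfSigma = 1, noiseSd = 0.1,
                         backgroundLevel = 0.5, seed = 7)
  expect_lt(abs(mean(out) - mean(vol2) - 0.5), 3 * 0.1 / sqrt(64^3))
})

test_that("foreground density orders bundled > laminar > meshwork at default specs", {
  dens <- vapply(c("meshwork", "laminar", "bundled"), function(m)
    mean(generatePhantom(phantomSpec(m, shape = c(96, 96, 96),
                                     seed = 2))@truthMask), 0)
  expect_true(dens[["bundled"]] > dens[["laminar"]])
  expect_true(dens[["laminar"]] > dens[["meshwork"]])
})

test_that("an unreachable fill target fails naming the achieved density", {
  spec <- phantomSpec("bundled", shape = c(32, 32, 32), fillTarget = 0.9,
                      seed = 1)
  expect_error(generatePhantom(spec, maxBatches = 1L), "achieved density")
})

test_that("phantom specifications enforce their invariants", {
  expect_error(phantomSpec("laminar", laminarPeriod = -1), "laminarPeriod")
  expect_error(phantomSpec("laminar",
                           layerAxes = rbind(c(1, 0, 0),
                                             c(cos(pi / 6), sin(pi / 6), 0))),
               "60 degrees")
  expect_error(phantomSpec("bundled", fiberRadius = 0.2), "unresolvable")
  expect_error(phantomSpec("bundled", bundleAxis = c(1, 1, 0)), "unit norm")
})

test_that("patchwork orientation fields are valid unit axial fields", {
  fld <- patchworkOrientationField(c(24, 24, 24), 8, seed = 4)
  n <- 24^3
  V <- cbind(fld@axis[1:n], fld@axis[n + 1:n], fld@axis[2 * n + 1:n])
  expect_equal(max(abs(sqrt(rowSums(V^2)) - 1)), 0, tolerance = 1e-12)
  expect_true(all(validMask(fld)))
})

test_that("curved fibers carry varying local tangents as ground truth and stay deterministic", {
  spec <- phantomSpec("bundled", shape = c(48, 48, 48), curvatureAmp = 6,
                      angularJitterDeg = 0, fillTarget = 0.05, seed = 14)
  a <- generatePhantom(spec)
  expect_identical(a@volume, generatePhantom(spec)@volume)
  idx <- which(a@truthMask)
  n3 <- prod(dim(a@volume))
  tang <- paste(round(a@truthAxis[idx], 5), round(a@truthAxis[idx + n3], 5),
                round(a@truthAxis[idx + 2 * n3], 5))
  # a bowed bundle has a spread of local tangents, not a single axis
  expect_gt(length(unique(tang)), 5)
  # straight default remains a single axis
  b <- generatePhantom(phantomSpec("bundled", shape = c(48, 48, 48),
                                   angularJitterDeg = 0, fillTarget = 0.05,
                                   seed = 14))
  vb <- b@truthAxis[, , , 1][which(b@truthMask)]
  expect_identical(length(unique(vb)), 1L)
})
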