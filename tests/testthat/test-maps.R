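test_that("pyramid voxel arithmetic matches the expansion-factor convention", {
  meta <- pyramidMeta(physicalVoxelUm = 0.75, expansionFactor = 3)
  expect_equal(meta@baseVoxelUm, 0.25)
  expect_equal(mipVoxelSize(meta, 0), 0.25)
  expect_equal(mipVoxelSize(meta, 1), 0.50)
  expect_equal(100 * mipVoxelSize(meta, 4), 400) # 0.4 mm analysis regions
  expect_error(mipVoxelSize(meta, -1), "level")
  expect_error(new("PyramidMeta", baseVoxelUm = 1, level = 0L,
                   expansionFactor = 3, physicalVoxelUm = 0.75),
               "expansionFactor")
})

.mkTable <- function() {
  tab <- expand.grid(i = 0:1, j = 0:1, k = 0:2)
  tab$cz <- (tab$i + 0.5) * 100
  tab$cy <- (tab$j + 0.5) * 100
  tab$cx <- (tab$k + 0.5) * 100
  tab$n_valid <- 8e5
  tab$gfa <- 0.8
  tab$xi_max <- 20
  tab$is_laminar <- FALSE
  tab$motif <- "bundled"
  tab$masked <- FALSE
  tab$mask_reason <- ""
  attr(tab, "blockSize") <- 100L
  attr(tab, "voxelUm") <- rep(1, 3)
  tab
}

test_that("block masking applies the GFA floor, border margin and valid-fraction rules with reasons", {
  tab <- .mkTable()
  tab$gfa[1] <- 0.2
  tab$n_valid[2] <- 100
  m <- maskBlocks(tab, gfaFloor = 0.4, borderMarginBlocks = 1L,
                  minValidFraction = 0.05)
  expect_true(m$masked[1])
  expect_match(m$mask_reason[1], "low_fa")
  expect_true(m$masked[2])
  expect_match(m$mask_reason[2], "low_valid")
  corner <- which(tab$i == 0 & tab$j == 0 & tab$k == 0)
  expect_match(m$mask_reason[corner], "border")
  expect_true(all(is.na(m$motif[m$masked])))
  # an interior high-GFA block stays unmasked when no border margin applies
  m0 <- maskBlocks(.mkTable(), gfaFloor = 0.4)
  expect_false(any(m0$masked))
})

test_that("masking is monotone in the GFA floor", {
  tab <- .mkTable()
  tab$gfa <- seq(0.1, 0.95, length.out = nrow(tab))
  lo <- maskBlocks(tab, gfaFloor = 0.3)
  hi <- maskBlocks(tab, gfaFloor = 0.6)
  expect_true(all(hi$masked[lo$masked])) # raising the floor never unmasks
})

test_that("maps assemble per-block values with NA at masked cells and round-trip bit-exactly", {
  tab <- .mkTable()
  tab$gfa <- runif(nrow(tab))
  tab$masked[3] <- TRUE
  maps <- assembleMaps(tab)
  expect_identical(dim(maps$gfa_map), c(2L, 2L, 3L))
  expect_true(is.na(maps$gfa_map[tab$i[3] + 1, tab$j[3] + 1, tab$k[3] + 1]))
  expect_identical(sum(is.na(maps$gfa_map)), 1L)
  ord <- order(tab$k, tab$j, tab$i)
  expect_identical(as.vector(maps$xi_map)[2], tab$xi_max[ord][2])

  # one-unmasked-block table gives a single finite cell
  tab1 <- .mkTable()
  tab1$masked <- rep(TRUE, nrow(tab1))
  tab1$masked[5] <- FALSE
  expect_identical(sum(is.finite(assembleMaps(tab1)$gfa_map)), 1L)

  path <- tempfile(fileext = ".csv")
  writeArchitectureTable(tab, path)
  back <- readArchitectureTable(path)
  expect_identical(back$gfa, tab$gfa)        # full-precision round trip
  expect_identical(back$masked, tab$masked)
  expect_identical(attr(back, "blockSize"), 100L)
})

test_that("volumes round-trip through TIFF with voxel metadata and synthesized pyramid levels", {
  set.seed(2)
  vol <- array(runif(8 * 10 * 12), c(8, 10, 12))
  path <- tempfile(fileext = ".tif")
  meta <- pyramidMeta(physicalVoxelUm = 0.75, expansionFactor = 3)
  writeVolume(vol, path, meta = meta)
  rd <- readVolume(path)
  expect_equal(rd$volume, vol, tolerance = 1e-6) # 32-bit float storage
  expect_equal(rd$meta@expansionFactor, 3)
  expect_equal(rd$voxelUm, rep(0.25, 3))

  expect_warning(lv1 <- readVolume(path, level = 1), "downsampling")
  expect_equal(lv1$volume, downsampleVolume(rd$volume), tolerance = 1e-6)
  expect_equal(lv1$voxelUm, rep(0.5, 3))

  # no sidecar: explicit voxel size required
  path2 <- tempfile(fileext = ".tif")
  file.copy(path, path2)
  rd2 <- readVolume(path2, voxelUm = 2)
  expect_equal(rd2$voxelUm, rep(2, 3))
  expect_error(readVolume(path2), "voxel-size metadata")
})

test_that("anisotropic voxel metadata survives the round trip and feeds per-axis sigmas", {
  vol <- array(runif(24 * 24 * 24), c(24, 24, 24))
  path <- tempfile(fileext = ".tif")
  writeVolume(vol, path, voxelUm = c(2, 1, 1))
  rd <- readVolume(path)
  expect_equal(rd$voxelUm, c(2, 1, 1))
  tf <- computeStructureTensor(rd$volume, rd$voxelUm,
                               structureTensorParams(1.5, 3))
  expect_identical(tf@voxelSize, c(2, 1, 1)) # sigma conversion is per-axis
})

test_that("downsampling halves each axis by 2x averaging", {
  vol <- array(1:64, c(4, 4, 4))
  dn <- downsampleVolume(vol)
  expect_identical(dim(dn), c(2L, 2L, 2L))
  expect_equal(dn[1, 1, 1], mean(vol[1:2, 1:2, 1:2]))
})

test_that("block centers from analysis tables land inside the volume bounds", {
  tab <- fxAnalysis("laminar", seed = 1L, lam = 30)$table
  ext <- 120 * attr(tab, "voxelUm")
  expect_true(all(tab$cz > 0 & tab$cz < ext[1]))
  expect_true(all(tab$cy > 0 & tab$cy < ext[2]))
  expect_true(all(tab$cx > 0 & tab$cx < ext[3]))
})

test_that("map renders are written as PNG files", {
  maps <- assembleMaps(.mkTable())
  path <- tempfile(fileext = ".png")
  renderMapPNG(maps$gfa_map, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
})
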