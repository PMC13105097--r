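#' @include AllClasses.R utils.R
NULL

#' Multiresolution pyramid metadata
#'
#' Voxel sizes are expressed at tissue scale: a physical voxel of the
#' expanded gel divided by the expansion factor. Level-`L` voxels of the
#' factor-2 pyramid measure `baseVoxelUm * 2^L`.
#'
#' @param physicalVoxelUm voxel size in the expanded gel, um.
#' @param expansionFactor gel expansion factor (dimensionless).
#' @param level pyramid level of the stored data (default 0).
#' @return A [PyramidMeta-class].
#' @examples
#' meta <- pyramidMeta(physicalVoxelUm = 0.75, expansionFactor = 3)
#' mipVoxelSize(meta, 0) # 0.25 um at tissue scale
#' mipVoxelSize(meta, 1) # 0.50 um
#' @export
pyramidMeta <- function(physicalVoxelUm, expansionFactor = 1, level = 0L) {
  new("PyramidMeta", baseVoxelUm = physicalVoxelUm / expansionFactor,
      level = as.integer(level), expansionFactor = as.numeric(expansionFactor),
      physicalVoxelUm = as.numeric(physicalVoxelUm))
}

#' Tissue-scale voxel size at a pyramid level
#'
#' @param meta a [PyramidMeta-class].
#' @param level pyramid level (integer >= 0).
#' @return Voxel size in um at tissue scale: `baseVoxelUm * 2^level`.
#' @export
mipVoxelSize <- function(meta, level = meta@level) {
  stopifnot(is(meta, "PyramidMeta"))
  if (level < 0) stop("pyramid level must be >= 0")
  meta@baseVoxelUm * 2^level
}

#' Mask analysis cubes ineligible for spatial maps
#'
#' Cubes are masked when their GFA falls below `gfaFloor`, when they touch
#' the volume border within `borderMarginBlocks` blocks, or when their
#' valid-voxel fraction falls below `minValidFraction` (tissue border /
#' background cubes). Reasons are recorded; masking is monotone in
#' `gfaFloor`.
#'
#' @param table an architecture table from [analyzeArchitecture()] (one
#'   row per cube, columns including `gfa`, `n_valid`, `i`, `j`, `k`).
#' @param gfaFloor GFA floor (default 0.4, the lower end of the displayed
#'   GFA range).
#' @param borderMarginBlocks blocks from the volume border to mask
#'   (default 0: voxel-level border handling already removed the filter
#'   support).
#' @param minValidFraction minimum `n_valid / blockSize^3` (default 0.05).
#' @return The table with updated `masked` / `mask_reason` columns.
#' @export
maskBlocks <- function(table, gfaFloor = 0.4, borderMarginBlocks = 0L,
                       minValidFraction = 0.05) {
  nb <- c(max(table$i), max(table$j), max(table$k)) + 1L
  B3 <- attr(table, "blockSize")^3
  reasons <- character(nrow(table))
  masked <- logical(nrow(table))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], why, sep = ";"), why)
    masked <<- masked | cond
  }
  flag(is.na(table$gfa) | table$n_valid == 0, "empty")
  flag(!is.na(table$gfa) & table$gfa < gfaFloor, "low_fa")
  if (borderMarginBlocks > 0) {
    m <- borderMarginBlocks
    border <- table$i < m | table$i >= nb[1] - m |
      table$j < m | table$j >= nb[2] - m |
      table$k < m | table$k >= nb[3] - m
    flag(border, "border")
  }
  flag(table$n_valid / B3 < minValidFraction, "low_valid")
  table$masked <- masked
  table$mask_reason <- reasons
  table$motif[masked] <- NA_character_
  table
}

#' Assemble per-block maps from an architecture table
#'
#' Builds one grid per metric over the block lattice (deterministic
#' z-major cell order, 0-based block indices): the GFA heatmap, the
#' maximum-correlation-length heatmap, the binary laminar map and the
#' motif map. Masked cells are `NA`.
#'
#' @param table a (masked) architecture table.
#' @return List of 3D arrays `gfa_map`, `xi_map`, `laminar_map`,
#'   `motif_map` with dimension = blocks per `(z,y,x)` axis.
#' @export
assembleMaps <- function(table) {
  nb <- c(max(table$i), max(table$j), max(table$k)) + 1L
  ord <- order(table$k, table$j, table$i) # z-major linear order
  masked <- if ("masked" %in% names(table)) table$masked else
    rep(FALSE, nrow(table))
  put <- function(v) {
    v[masked[ord]] <- NA
    array(v, nb)
  }
  list(gfa_map = put(table$gfa[ord]),
       xi_map = put(table$xi_max[ord]),
       laminar_map = put(as.integer(table$is_laminar[ord])),
       motif_map = put(table$motif[ord]))
}

#' Read / write volumes with voxel-size metadata
#'
#' Volumes are stored as multi-page 32-bit float TIFF stacks (one page per
#' z slice) with a YAML sidecar (`<path>.meta.yaml`) holding the pyramid
#' metadata: axis order `(z, y, x)`, tissue-scale voxel size in um per
#' axis, pyramid level and expansion factor. `readVolume()` refuses files
#' without voxel metadata unless `voxelUm` is given explicitly. Requesting
#' a pyramid level above the stored one synthesizes it by repeated 2x mean
#' downsampling, with a warning.
#'
#' @param path TIFF file path.
#' @param volume 3D `(z,y,x)` array; values are stored as 32-bit floats.
#' @param meta a [PyramidMeta-class] (or `NULL` with `voxelUm`).
#' @param voxelUm explicit voxel size in um when no metadata exists.
#' @param level requested pyramid level (defaults to the stored level).
#' @return `readVolume()`: list with `volume`, `meta`
#'   ([PyramidMeta-class]) and `voxelUm` (per-axis `(z,y,x)` voxel size at
#'   the delivered level); `writeVolume()`: the path, invisibly.
#' @export
writeVolume <- function(volume, path, meta = NULL, voxelUm = NULL) {
  if (is.null(meta)) {
    if (is.null(voxelUm)) stop("provide meta or voxelUm")
    meta <- pyramidMeta(physicalVoxelUm = mean(voxelSize3(voxelUm)),
                        expansionFactor = 1)
  }
  vox3 <- if (is.null(voxelUm)) rep(mipVoxelSize(meta), 3) else
    voxelSize3(voxelUm)
  slices <- lapply(seq_len(dim(volume)[1]), function(z) {
    m <- volume[z, , ]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(
    axis_order = "zyx", voxel_um = vox3,
    base_voxel_um = meta@baseVoxelUm, level = meta@level,
    expansion_factor = meta@expansionFactor,
    physical_voxel_um = meta@physicalVoxelUm,
    indexing = "0-based, half-open blocks"),
    paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, level = NULL, voxelUm = NULL) {
  metaPath <- paste0(path, ".meta.yaml")
  if (file.exists(metaPath)) {
    y <- yaml::read_yaml(metaPath)
    meta <- new("PyramidMeta", baseVoxelUm = y$base_voxel_um,
                level = as.integer(y$level),
                expansionFactor = y$expansion_factor,
                physicalVoxelUm = y$physical_voxel_um)
  } else if (!is.null(voxelUm)) {
    meta <- pyramidMeta(physicalVoxelUm = voxelUm, expansionFactor = 1)
  } else {
    stop("missing voxel-size metadata for ", path,
         ": pass voxelUm explicitly")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  vol <- array(0, d)
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  vox3 <- if (file.exists(metaPath) && !is.null(y$voxel_um))
    as.numeric(y$voxel_um) else rep(mipVoxelSize(meta), 3)
  if (is.null(level)) level <- meta@level
  if (level < meta@level) stop("level ", level, " finer than stored level ",
                               meta@level)
  while (level > meta@level) {
    warning("synthesizing pyramid level ", meta@level + 1L,
            " by 2x mean-downsampling")
    vol <- downsampleVolume(vol)
    vox3 <- vox3 * 2
    meta <- new("PyramidMeta", baseVoxelUm = meta@baseVoxelUm,
                level = meta@level + 1L,
                expansionFactor = meta@expansionFactor,
                physicalVoxelUm = meta@physicalVoxelUm)
  }
  list(volume = vol, meta = meta, voxelUm = vox3)
}

#' 2x mean downsampling of a volume
#'
#' Averages non-overlapping 2x2x2 voxel neighborhoods (trailing odd voxels
#' are dropped), the operation generating successive pyramid levels.
#'
#' @param volume 3D `(z,y,x)` array.
#' @return Array of halved dimensions.
#' @export
downsampleVolume <- function(volume) {
  d <- dim(volume) %/% 2L * 2L
  v <- volume[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  out <- (v[seq(1, d[1], 2), , ] + v[seq(2, d[1], 2), , ]) / 2
  out <- (out[, seq(1, d[2], 2), ] + out[, seq(2, d[2], 2), ]) / 2
  (out[, , seq(1, d[3], 2)] + out[, , seq(2, d[3], 2)]) / 2
}

#' Write / read an architecture table as CSV
#'
#' The header comment documents the geometry conventions (axis order
#' `(z,y,x)`, 0-based block indices, half-open blocks, centers in um).
#' Values round-trip bit-exactly (17 significant digits).
#'
#' @param table architecture table.
#' @param path CSV path.
#' @return `readArchitectureTable()`: the table; `writeArchitectureTable()`:
#'   the path, invisibly.
#' @export
writeArchitectureTable <- function(table, path) {
  con <- file(path, "w")
  writeLines(c(
    "# fiberarch architecture table",
    "# axis order (z,y,x); block indices (i,j,k) 0-based along (z,y,x);",
    sprintf("# half-open blocks of %d voxels; centers in um",
            attr(table, "blockSize")),
    sprintf("# blockSize=%d voxel_um=%s", attr(table, "blockSize"),
            paste(format(attr(table, "voxelUm"), digits = 17),
                  collapse = ","))), con)
  df <- as.data.frame(lapply(table, function(col)
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col),
    stringsAsFactors = FALSE)
  write.csv(df, con, row.names = FALSE, quote = TRUE)
  close(con)
  invisible(path)
}

#' @rdname writeArchitectureTable
#' @export
readArchitectureTable <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- grep("^# blockSize=", hdr, value = TRUE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in names(tab))
    if (col %in% c("is_laminar", "masked", "capped_e1", "capped_e2", "capped_e3"))
      tab[[col]] <- as.logical(tab[[col]])
  if (length(meta) == 1) {
    kv <- strsplit(sub("^# ", "", meta), " ")[[1]]
    attr(tab, "blockSize") <- as.integer(sub("blockSize=", "", kv[1]))
    attr(tab, "voxelUm") <- as.numeric(strsplit(sub("voxel_um=", "", kv[2]),
                                                ",")[[1]])
  }
  tab
}

#' Render a block map to a grayscale PNG
#'
#' Writes the central z slab of a block map with a fixed value range
#' (defaults to the displayed GFA range 0.4-1.0); masked cells are black.
#'
#' @param map 3D block map array.
#' @param path PNG path.
#' @param valueRange fixed color scale range.
#' @param zIndex block-slab index (default middle).
#' @return The path, invisibly.
#' @export
renderMapPNG <- function(map, path, valueRange = c(0.4, 1.0), zIndex = NULL) {
  if (is.null(zIndex)) zIndex <- ceiling(dim(map)[1] / 2)
  sl <- map[zIndex, , , drop = TRUE]
  if (is.null(dim(sl))) sl <- matrix(sl, dim(map)[2], dim(map)[3])
  v <- (as.numeric(sl) - valueRange[1]) / diff(valueRange)
  v[is.na(v)] <- 0
  v <- pmin(1, pmax(0, v))
  png::writePNG(matrix(v, nrow(sl), ncol(sl)), path)
  invisible(path)
}
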