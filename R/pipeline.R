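#' @include orientation.R odf.R acf.R laminar.R maps_io.R phantom.R
NULL

.defaultParams <- function() list(
  sigma_gradient_um = 1, sigma_window_um = 3, energy_floor = 0.1,
  block_size = 100L, n_sphere = 6500L, weighting = "count",
  min_separation_deg = 45, rel_amplitude = 0.3,
  fit_floor = 0.05, min_cycles = 1.5, snr_1d = 3, snr_2d = 3,
  period_band_um = c(10, NA), gfa_bundled_floor = 0.4,
  gfa_floor = 0.4, border_margin_blocks = 0L, min_valid_fraction = 0.05,
  acf_min_valid_fraction = 0.1)

#' Quantify fiber architecture over analysis cubes
#'
#' Runs the per-cube analysis chain on an orientation field: discrete ODF
#' accumulation with GFA and separation-constrained peaks, dyadic-tensor
#' autocorrelation with fiber-frame profiles and exponential correlation
#' lengths, the spectral laminar-periodicity screen, and motif
#' classification. This is the computational core behind [runPipeline()].
#'
#' @param field an [OrientationField-class].
#' @param params named list overriding entries of the default parameter
#'   set (see the vignette); unknown names fail.
#' @param sphere optional [SphereSampling-class] (default: cached sampling
#'   with `params$n_sphere` directions).
#' @return List with `table` (one row per analysis cube: block index,
#'   center, `n_valid`, `gfa`, peak axes, `xi` per frame axis and
#'   `xi_max`, periodicity call and motif), `odfs`, `calls`, `fits`,
#'   `nBlocks`, and the effective `params`.
#' @export
analyzeArchitecture <- function(field, params = list(), sphere = NULL) {
  stopifnot(is(field, "OrientationField"))
  p <- .defaultParams()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(params)] <- params
  if (is.null(sphere)) sphere <- defaultSphere(p$n_sphere)
  grid <- blockGrid(p$block_size)
  odfs <- accumulateODF(field, grid, sphere, weighting = p$weighting,
                        minSeparationDeg = p$min_separation_deg,
                        relAmplitude = p$rel_amplitude)
  dy <- dyadicField(field)
  crit <- periodicityCriteria(minCycles = p$min_cycles, snr1d = p$snr_1d,
                              snr2d = p$snr_2d, periodBand = p$period_band_um)
  d <- dim(field@coherence)
  org <- blockOrigins(d, grid)
  B <- grid@blockSize
  capUm <- (B %/% 2L) * mean(field@voxelSize)

  rows <- vector("list", length(odfs))
  calls <- vector("list", length(odfs))
  fits <- vector("list", length(odfs))
  for (bi in seq_along(odfs)) {
    odf <- odfs[[bi]]
    idx <- odf@blockIndex
    row <- list(i = idx[1], j = idx[2], k = idx[3],
                cz = odf@centerUm[1], cy = odf@centerUm[2],
                cx = odf@centerUm[3],
                n_valid = odf@nValid, gfa = odf@gfa,
                n_peaks = if (odf@empty) 0L else nrow(odf@peaks))
    pk <- matrix(NA_real_, 2, 3)
    if (!odf@empty) {
      np <- min(2, nrow(odf@peaks))
      pk[seq_len(np), ] <- odf@peaks[seq_len(np), , drop = FALSE]
    }
    row <- c(row, list(peak1_x = pk[1, 1], peak1_y = pk[1, 2],
                       peak1_z = pk[1, 3], peak2_x = pk[2, 1],
                       peak2_y = pk[2, 2], peak2_z = pk[2, 3]))

    xi <- rep(NA_real_, 3); r2 <- rep(NA_real_, 3)
    capped <- rep(NA, 3); xiMax <- NA_real_
    call <- NULL
    if (!odf@empty) {
      origin <- c(org[[1]][idx[1] + 1], org[[2]][idx[2] + 1],
                  org[[3]][idx[3] + 1])
      av <- tryCatch(
        acf3d(dy, region = list(origin = origin, size = rep(B, 3)),
              minValidFraction = p$acf_min_valid_fraction),
        error = function(e) NULL)
      if (is.null(av)) {
        call <- NULL # insufficient region: no periodicity evidence
      } else if (av@homogeneous) {
        xi <- rep(capUm, 3); capped <- rep(TRUE, 3); xiMax <- capUm
        r2 <- rep(NA_real_, 3)
        call <- NULL
      } else {
        frame <- blockFrame(odf)
        prof <- radialProfiles(av, frame)
        fit <- fitBlockCorrelation(prof, fitFloor = p$fit_floor)
        fits[[bi]] <- fit
        xi <- fit@xi; r2 <- fit@r2; capped <- fit@capped
        xiMax <- if (all(is.na(xi))) NA_real_ else max(xi, na.rm = TRUE)
        call <- detectPeriodicity(prof, crit)
      }
    }
    cls <- classifyBlock(odf, call, gfaBundledFloor = p$gfa_bundled_floor)
    calls[[bi]] <- cls$call
    rows[[bi]] <- c(row, list(
      xi_e1 = xi[1], xi_e2 = xi[2], xi_e3 = xi[3],
      r2_e1 = r2[1], r2_e2 = r2[2], r2_e3 = r2[3],
      capped_e1 = capped[1], capped_e2 = capped[2], capped_e3 = capped[3],
      xi_max = xiMax,
      is_laminar = isTRUE(cls$call@isLaminar),
      period_um = cls$call@periodUm, snr1 = cls$call@snr1,
      snr2 = cls$call@snr2,
      reasons = paste(cls$call@reasons, collapse = ";"),
      motif = cls$motif, masked = FALSE, mask_reason = ""))
  }
  table <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  attr(table, "blockSize") <- B
  attr(table, "voxelUm") <- field@voxelSize
  list(table = table, odfs = odfs, calls = calls, fits = fits,
       nBlocks = lengths(org), params = p)
}

#' Run the full fiber-architecture pipeline
#'
#' Executes phantom generation (or volume reading), structure tensor
#' orientation estimation, per-cube ODF / GFA / peak analysis, tensor-field
#' autocorrelation with correlation lengths, the laminar periodicity
#' screen, block masking and map assembly, and writes the architecture
#' table (CSV), the block maps (long-format CSV plus a GFA PNG render) and
#' a provenance record (YAML: every parameter, the seed and the package
#' version). Reruns with the same configuration produce identical output.
#'
#' @param config configuration list or path to a YAML file with entries:
#'   `input` (either `phantom:` with [phantomSpec()] arguments or `path:`
#'   plus optional `voxel_um` / `level` for a TIFF volume), optional
#'   `params` (see [analyzeArchitecture()]), optional
#'   `sigma` overrides and `seed`.
#' @param outDir output directory, created if missing; `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `table` (masked architecture table),
#'   `maps`, `field`, `analysis` and `provenance`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$seed)) config$input$phantom$seed <- config$seed

  # --- input stage ---
  if (!is.null(config$input$phantom)) {
    args <- config$input$phantom
    if (!is.null(args$shape)) args$shape <- as.integer(unlist(args$shape))
    spec <- do.call(phantomSpec, args)
    ph <- generatePhantom(spec)
    volume <- ph@volume
    voxelUm <- rep(spec@voxelSize, 3)
  } else if (!is.null(config$input$path)) {
    rd <- readVolume(config$input$path, level = config$input$level,
                     voxelUm = config$input$voxel_um)
    volume <- rd$volume
    voxelUm <- rd$voxelUm
  } else stop("input stage: config$input needs a phantom spec or a path")

  p <- .defaultParams()
  p[names(config$params)] <- config$params

  # --- orientation stage ---
  field <- tryCatch({
    tens <- computeStructureTensor(volume, voxelUm,
                                   structureTensorParams(p$sigma_gradient_um,
                                                         p$sigma_window_um))
    principalOrientation(tens, energyFloor = p$energy_floor)
  }, error = function(e) stop("orientation stage: ", conditionMessage(e)))

  # --- odf / acf / laminar stages ---
  analysis <- analyzeArchitecture(field, params = p[names(.defaultParams())])

  # --- maps stage ---
  table <- maskBlocks(analysis$table, gfaFloor = p$gfa_floor,
                      borderMarginBlocks = p$border_margin_blocks,
                      minValidFraction = p$min_valid_fraction)
  maps <- assembleMaps(table)

  provenance <- list(
    package = "fiberarch",
    version = as.character(utils::packageVersion("fiberarch")),
    date = format(Sys.time(), "%Y-%m-%d"),
    seed = config$seed,
    input = config$input,
    parameters = p,
    geometry = list(axis_order = "zyx", indexing = "0-based",
                    blocks = "half-open", voxel_um = voxelUm))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeArchitectureTable(table, file.path(outDir, "architecture_table.csv"))
    for (nm in names(maps)) {
      m <- maps[[nm]]
      idx <- which(!is.na(m) | TRUE, arr.ind = TRUE)
      df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                       k = idx[, 3] - 1L, value = as.vector(m))
      write.csv(df, file.path(outDir, paste0(nm, ".csv")), row.names = FALSE)
    }
    renderMapPNG(maps$gfa_map, file.path(outDir, "gfa_map.png"))
    yaml::write_yaml(provenance, file.path(outDir, "provenance.yaml"))
  }
  invisible(list(table = table, maps = maps, field = field,
                 analysis = analysis, provenance = provenance))
}
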