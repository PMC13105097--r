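#' @include AllClasses.R utils.R
NULL

#' Build a dense spherical sampling for discrete ODFs
#'
#' Constructs an antipodally symmetric, approximately equal-area layout of
#' `nPoints` unit directions: `nPoints / 2` points are placed on the upper
#' hemisphere by a golden-angle (Fibonacci) spiral and mirrored through the
#' origin, so every direction has an exact antipode and the antipode map is
#' an involution. The nearest-neighbor angular spacing is close to the
#' equal-area value `sqrt(4 * pi / nPoints)` radians (about 2.5 degrees at
#' the default 6500 points). A symmetric k-nearest-neighbor graph over the
#' directions supports ODF smoothing and local-maximum peak detection.
#'
#' @param nPoints even number of directions (>= 12); default 6500.
#' @param k neighbors per direction in the adjacency graph.
#' @param layout `"spiral"` (default) or `"octahedral"`, the 6-point
#'   fixture `(+-x, +-y, +-z)` used in unit tests.
#' @return A [SphereSampling-class].
#' @examples
#' sph <- buildSphere(500)
#' sph
#' @export
buildSphere <- function(nPoints = 6500L, k = 6L, layout = c("spiral", "octahedral")) {
  layout <- match.arg(layout)
  if (layout == "octahedral") {
    dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
    anti <- c(4L, 5L, 6L, 1L, 2L, 3L)
    nb <- lapply(1:6, function(i) setdiff(1:6, c(i, anti[i])))
    return(new("SphereSampling", directions = dirs, neighbors = nb,
               antipodeIndex = anti))
  }
  nPoints <- as.integer(nPoints)
  if (nPoints < 12 || nPoints %% 2 != 0)
    stop("nPoints must be an even integer >= 12")
  m <- nPoints %/% 2L
  i <- seq_len(m)
  z <- (i - 0.5) / m
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  H <- cbind(rho * cos(phi), rho * sin(phi), z)
  dirs <- rbind(H, -H)
  anti <- c(m + i, i)
  nb <- .knnGraph(dirs, k)
  new("SphereSampling", directions = dirs, neighbors = nb,
      antipodeIndex = as.integer(anti))
}

# Symmetric k-NN adjacency over unit directions (true angular distance,
# not axial). Chunked to bound memory at large n.
.knnGraph <- function(dirs, k) {
  n <- nrow(dirs)
  k <- min(k, n - 1L)
  nbr <- vector("list", n)
  chunk <- max(1L, as.integer(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    G <- dirs[s:e, , drop = FALSE] %*% t(dirs)
    for (r in seq_len(e - s + 1L)) {
      g <- G[r, ]
      g[s + r - 1L] <- -Inf
      nbr[[s + r - 1L]] <- order(g, decreasing = TRUE)[seq_len(k)]
    }
  }
  # symmetrize
  for (i in seq_len(n)) for (j in nbr[[i]])
    if (!(i %in% nbr[[j]])) nbr[[j]] <- c(nbr[[j]], i)
  lapply(nbr, as.integer)
}

# Cached default sampling (building the 6500-point graph costs seconds).
defaultSphere <- function(nPoints = 6500L) {
  key <- paste0("sphere", nPoints)
  if (is.null(.fiberarchCache[[key]]))
    .fiberarchCache[[key]] <- buildSphere(nPoints)
  .fiberarchCache[[key]]
}
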