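# fiberarch

Quantification of white-matter fiber architecture in 3D light-microscopy
volumes of labeled axons.

High-resolution volumes of immunolabeled axons (for example neurofilament
heavy chain in human white matter) reveal distinct local organizational
motifs: a low-density **multi-orientation meshwork**, **laminar/orthogonal**
stacks of alternating near-orthogonal fiber layers, and dense, coherent
**bundles**. `fiberarch` measures this organization per analysis cube and is
aimed at microscopists and neuroanatomists who have such volumes (TIFF
stacks with voxel size in micrometers) and want quantitative, mappable
summaries rather than visual impressions.

## What it computes

Per-voxel fiber orientations come from 3D structure tensor analysis,
`T = G_sigma_w * (grad I grad I')`, with the fiber axis taken as the
eigenvector of the smallest eigenvalue (intensity varies least along a
bright tube). Within each analysis cube (default 100^3 voxels) the axial
orientations are binned on a 6,500-direction antipodally symmetric sphere
sampling into a discrete orientation distribution function (ODF) `psi`,
summarized by generalized fractional anisotropy

    GFA = sqrt( n * sum((psi - mean(psi))^2) / ((n-1) * sum(psi^2)) )

(0 = all orientations equally represented, 1 = a single dominant
direction), and by ODF peaks separated by at least 45 degrees. The spatial
scale of organization comes from the 3D autocorrelation of the orientation
dyadic tensor field `v v' - I/3`: exponential fits `C(r) = exp(-r/xi)`
along fiber-frame axes give per-cube correlation lengths, and a spectral
screen of transverse autocorrelation profiles (>= 1.5 full cycles in the
window, signal-to-noise and modulation-depth thresholds in both the 1D and
2D Fourier domains, plus at least two ODF peaks) yields a binary laminar
map with the estimated laminar period. A bundled synthetic phantom
generator (tube renderings of all three motifs with voxel-level
ground-truth orientations, optical blur and noise) supports end-to-end
validation; everything is deterministic given a seed.

See the vignette (`vignettes/fiber-architecture.Rmd`) for the model
details, parameter defaults and limitations.

## Worked example

Generate a laminar phantom with a 40 um period, estimate orientations and
run the per-cube analysis:

```r
library(fiberarch)

spec  <- phantomSpec("laminar", shape = c(120, 120, 120),
                     laminarPeriod = 40, seed = 1)
ph    <- generatePhantom(spec)
tens  <- computeStructureTensor(ph@volume, voxelSize = 1)
field <- principalOrientation(tens)
an    <- analyzeArchitecture(field)
an$table[, c("gfa", "n_peaks", "xi_max", "is_laminar", "period_um", "motif")]
```

```
       gfa n_peaks xi_max is_laminar period_um   motif
1 0.997762       2     50       TRUE  40.19774 laminar
```

Reading the row: the cube's ODF is extremely anisotropic (GFA 0.998 — the
fibers lie along just two axes) with exactly 2 orientation peaks (the two
alternating layer directions); the maximum autocorrelation length is capped
at the 50 um window half-length (fibers are coherent along their axis
through the whole cube); the periodicity screen fires and recovers the
laminar period as 40.2 um against the 40 um ground truth, so the cube is
classified laminar. A bundled phantom instead gives a single peak, high
GFA and no periodicity; a meshwork phantom gives many broad peaks and low
GFA (about 0.27 at default density, below the 0.4 map display floor).

`runPipeline()` wraps the same chain behind a YAML/list configuration and
writes the architecture table (CSV), block maps (CSV + PNG) and a
provenance record; `inst/scripts/fiberarch_run.R` is a command-line front
end over it.

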