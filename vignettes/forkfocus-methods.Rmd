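---
title: "Models and methods behind forkfocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forkfocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forkfocus)
```

# What the package computes

`forkfocus` quantifies replication-fork activity from two complementary
assays:

1. **Single-molecule localization microscopy (SMLM)** of fluorophore-tagged
   nascent DNA (EdU, click-labeled at roughly 1:1 stoichiometry). Blinking
   fluorophores imaged over thousands of frames are localized one at a
   time; pair-correlation analysis of the resulting coordinate list yields
   the average number of labeled molecules per replication focus and,
   dividing the (relative) total molecule count per nucleus by that
   per-focus average, the number of EdU foci per nucleus.
2. **DNA fiber spreading**, where sequential IdU/CldU pulses mark
   replication periods along single DNA fibers. Scoring first-label-only
   tracks against first-then-second-label tracks gives the percentage of
   stalled forks; tract lengths, converted at 2.59 kb per micrometre,
   measure restart efficiency, nascent-strand degradation, or synthesis
   under stress depending on the labeling scheme.

Because raw microscope data for such experiments are rarely shareable, the
package includes a first-class synthetic-data generator that emulates every
input: ground-truth emitter fields, two-state blinking, an sCMOS camera
model, two-channel bead fields under a polynomial warp, and fiber datasets
with configurable stall fractions. Each analysis stage is therefore
testable by parameter recovery against known truth.

# The simulation model

## Emitter fields

A nucleus is an elliptical mask (semi-axes 0.4 and 0.3 of the field extent
by default; arbitrary raster masks are accepted, since real masks are
derived from images). `nClusters` focus centres are placed uniformly in the
mask; each receives `moleculesPerCluster` fluorophores scattered as an
isotropic Gaussian of s.d. `clusterSigma`, truncated at 4 radii and
rejection-sampled into the mask. A uniform monomer background
(`backgroundDensity` per µm²) completes the field, so the emitter count is
exactly `nClusters * moleculesPerCluster + nBackground`.

Defaults encode the emulated acquisition: 96 px field at 110 nm pixels,
40 clusters × 30 molecules, 33 Hz for 2000 frames, ~2000 photons per
on-frame, 100 nm PSF sigma. Two acquisition lengths appear in the source
protocol (2000 and 200 frames); 2000 is the default and the other is a
configuration away. The cluster width default is 25 nm (≈70 nm FWHM foci),
chosen inside the pair-correlation estimator's operating range (see
*Operating range* below) and consistent with reported sizes of replication
foci in SMLM. `minClusterSep` optionally enforces a hard-core
("well-separated") focus layout; the default 0 keeps placement uniform.

## Blinking and the camera

Photophysics is a deliberately minimal memoryless two-state process: an
off emitter activates per frame with probability `pOn`, stays on for a
geometric number of frames (mean `meanOnFrames`), and emits
Poisson(`photonsMean`) photons per on-frame. There is no bleaching, no
dark-state hierarchy, and no partial-frame emission; the model is
sufficient to test localization and counting, not to study photochemistry.

Pixel values follow the sCMOS model

$$\mathrm{ADU}_k = g_k\,\mathrm{Pois}(\mu_k) + g_k\,\mathcal N(0, \sqrt{v_k}) + o_k,$$

with per-pixel gain $g_k$, offset $o_k$, and read-noise variance $v_k$
(photon-equivalent units) drawn uniformly from a configurable range to
mimic patterned sCMOS readout. PSFs are integrated symmetric 2-D Gaussians
(error-function differences over pixel areas), rendered over a ±6σ
support so that photon flux is conserved to better than 1e-6 for interior
emitters.

A single master seed expands deterministically into per-stage substreams
(`substreamSeed`), so identical configuration + seed reproduces every
output bit for bit while stages stay independently re-runnable.

# Localization

Each frame is converted to photons, `(ADU - offset)/gain`, box-filtered
(uniform mean, mirror-reflected edges, width 3 by default), and searched
for strict 8-neighbour local maxima above a robust threshold
(median + 5 MAD of the filtered frame; the source protocol names no
threshold, so it is expressed in robust units and configurable).
Candidates closer than `minSeparation` keep only the strongest, ties
resolved towards the lowest (row, col). Square ROIs (11 px default) are
cut with their read-noise variance patches; candidates nearer the border
than half an ROI are dropped and counted.

## The sCMOS likelihood

Fitting maximizes the standard Poisson-plus-variance approximation: pixel
$k$ with expectation $\mu_k = N\,\mathrm{PSF}_k(x, y, \sigma) + b$ is
treated as Poisson with effective rate $\mu_k + v_k$ observed as
$d_k + v_k$. This folds the Gaussian readout noise into the Poisson
likelihood exactly in the regime where the approximation is standard, and
keeps the estimator and its Cramér–Rao bound in one framework. The fit is
a damped per-parameter Newton ascent from a centroid/border-median
initialization, vectorized across all ROIs simultaneously; position steps
are clamped to 1 px, photons floored at 0.01, background at 0.
Convergence is a relative parameter step below 1e-6 or 50 iterations.
Fixed-σ fitting is the default (σ from configuration); free-σ is
available. The per-ROI independence contract means results are identical
whatever order frames are processed in.

The CRLB is the square root of the diagonal of the inverse Fisher
information of the same likelihood,
$I_{ij} = \sum_k \partial_i\mu_k\,\partial_j\mu_k/(\mu_k + v_k)$. The
matrix is Jacobi-preconditioned before inversion because the background
information diverges as $b, v \to 0$; a genuinely singular matrix flags
the record rather than returning a number. In the shot-noise limit
($b = v = 0$) the lateral bound reduces to $\approx\sigma/\sqrt N$ and
halves exactly when $N$ quadruples, which the test suite asserts; on noisy
repeats the fitter's RMSE sits within a few percent of the mean CRLB.

Quality filters (minimum photons 100, maximum lateral CRLB 50 nm,
convergence required) are explicit, logged per rejection reason, and
idempotent. No blinking re-linking is performed by default: repeated
activations of one fluorophore remain separate records, matching the
"relative total" counting convention downstream.

# Channel registration

Bead fiducials imaged in both channels are related by a per-axis
polynomial over the monomial basis $\{1, x, y, x^2, xy, y^2\}$ (degree 2
default), fitted by least squares from the moving onto the reference
channel. Coordinates are centred and scaled to the bead bounding box
purely for conditioning; coefficients are re-expanded into nm units, so
the fitted mapping is identical either way. Rank-deficient bead layouts
(collinear beads) raise an error naming the deficiency rather than
returning a junk fit. A known degree-2 warp is recovered from 20
noise-free beads to ~1e-12 relative; with 5 nm localization noise per
channel the holdout RMS 2-D residual is √2 × 5 nm, the propagation law
the tests assert.

# Pair-correlation cluster metrics

For localizations inside a nucleus mask, the auto-pair-correlation
estimate in the annulus around radius $r$ is observed pair count divided
by the count expected under complete spatial randomness (CSR) at the
observed density $\rho$, with edge correction. The package derives the
per-focus molecule count with the standard cluster integral

$$N_c = 1 + \rho \int_0^{R} (g(r) - 1)\, 2\pi r \, dr,$$

whose "+1" makes the monomer limit exact ($g \equiv 1 \Rightarrow
N_c = 1$), and reports foci per nucleus as
$\mathrm{total\ localizations} / N_c$. The upper limit $R$ defaults to
the first radial bin where $g \le 1$ (capped at `rMax`), since the source
recipe names no limit; a fixed override is available. Counts are
*relative*: no blinking correction is applied, so absolute recovery is
validated on ground-truth (blinking-free) coordinates and biological
contrasts rely on ratios between conditions.

## Edge correction

Expected annulus counts are weighted by the average fraction of each
annulus circle lying inside the mask. The weight is computed from the mask
geometry alone — a deterministic grid of ~2048 reference points inside the
mask, each probing 180 equally spaced points on the circle of the bin
radius — so it is reusable across nuclei sharing a geometry and adds
negligible noise (standard error per bin ≈ 0.001). Binned pair counts
themselves are exact and are tested against an all-pairs brute-force
histogram.

## Operating range of the estimator

The cluster integral assumes cluster positions are Poisson. Two
departures matter at realistic densities, and both are quantifiable:

* **Baseline deficit.** The CSR baseline subtracted inside the
  integration radius is offset by cross-cluster pairs only if cluster
  centres are Poisson. Any regularity (including a hard-core layout)
  leaves a negative bias of roughly $\rho_{\mathrm{tot}}\,\pi R^2$
  excess-neighbour units against $M - 1$; with $R \approx 4\sigma_c$ this
  dictates how tight foci must be for accurate recovery. At the default
  geometry (σ_c = 25 nm, ~32 localizations/µm²) the deficit is ~3–4% of
  a 30-molecule focus, and stays under ~10% across cluster counts 10–100
  and sizes 10–100 — the grid the tests sweep. At σ_c = 50 nm it would
  already be ~14%, which is why the default is 25 nm.
* **Chance cluster proximity.** Under uniform placement, a few of 40
  foci typically land within ~2 integration radii of each other; that is
  genuine mid-range clustering which the first-crossing rule integrates,
  inflating $N_c$ on affected nuclei by up to ~25% while leaving the mean
  across nuclei unbiased. Recovery tests therefore use the well-separated
  layout (`minClusterSep` = 8 σ_c), which matches the premise they are
  stated under; per-nucleus spread then drops below 1%. Condition
  contrasts, which rely on ratios, use plain uniform placement.

The residual ~5% underestimate of $N_c$ (and matching ~7% overestimate of
foci) at the default geometry comes from the Rayleigh tail beyond the
crossing radius and the small baseline deficit; both are documented
behaviour, well inside the 15% recovery tolerance the suite enforces.

Cross-channel colocalization uses the same machinery between two
registered channels; the estimate is symmetric in the two sets, requires
a common coordinate frame (the `space` label set by `applyMapping`), and
calibrates to 1 for independent uniform patterns.

# Fiber statistics

A fork event requires a first-label tract; "stalled" means the
second-label tract is absent (exactly 0 µm by default; a tolerance
`minSecondLabel` accommodates digitization noise). Rows with second label
but no first label (new origins) are excluded from the restart denominator
and counted separately. Percent stalled is 100 × stalled / events per
replicate; replicates with fewer than 150 events warn (the scoring
convention's minimum), as does pooled length analysis below 60 tracts per
replicate. Tract lengths convert at 1 µm = 2.59 kb. For restart-scheme
second-label analysis only restarted forks are measured (the tracts must
exist to be measured); protection and under-stress schemes use all tracts.

Condition summaries mirror the field's reporting conventions exactly:
percent stalled as mean ± s.d. of replicate-level percentages with
two-sided Welch t-tests against the control; tract lengths pooled across
replicates as mean ± s.e.m. with two-sided Mann–Whitney tests. On null
simulations (both conditions identical) the Welch comparison's observed
type-I error at α = 0.05 sits near nominal (asserted within [0.02, 0.08]
over 500 datasets); a 30% injected CldU shortening at 200 tracts per group
is detected at p < 0.01.

# Numerical choices

* MLE: relative-step tolerance 1e-6, 50 iterations maximum, step clamps
  as above; non-converged or negative-photon fits are flagged and
  filtered, never silently kept.
* Effective-rate floors (1e-9 in fitting, 1e-12 in the Fisher matrix)
  guard logs and divisions in empty-corner pixels.
* Detection ties between equal maxima break towards the lowest
  (row, col); candidate order is canonical (frame, row, col) and output
  order (frame, y, x), so concurrency or chunking cannot reorder results.
* Pair histogram bins are left-open intervals with zero distances
  assigned to the first bin; the brute-force oracle in the tests encodes
  the identical rule, so equality is exact, not approximate.
* Coordinates are written to CSV rounded to 1e-3 nm so manifest checksums
  are stable across platforms.
* Hard-core centre placement uses sequential rejection with an attempt
  cap, erroring on infeasible packings rather than looping forever.

# What the tests do and do not show

The suite runs entirely on synthetic data at desk scale: 1000-ROI
localization batches at 200–5000 photons, 10⁴-point CSR calibrations,
ten Fig-5-scale nuclei for recovery, 40 nuclei per condition for
contrasts, 500 null fiber datasets, and a tiny (64 px, 200-frame)
end-to-end pipeline run — sizes chosen so the whole suite completes in a
few minutes on one CPU. Passing them shows the estimators are correct,
calibrated and deterministic *under the generative model*: Gaussian PSFs,
memoryless blinking, Gaussian read noise, log-normal tract lengths.
Real data add drift, PSF aberrations, structured photophysics,
labeling inefficiency, antibody background and fiber-tracing ambiguity,
none of which the generator emulates; absolute molecule counts in
particular remain *relative* in the presence of blinking. Biological
numbers from the original experiments (stall percentages per condition,
foci per nucleus) derive from unreleased raw images and are not
reproduction targets; the package reproduces the *methods*, with
direction-and-significance contrasts validated on simulated effects.

# Known limitations

Single-emitter fitting only (overlapping emitters are detected as one
candidate or rejected by quality filters); no drift correction, 3-D PSFs
or Fourier-ring-correlation resolution estimates; no DBSCAN-style
alternative clustering; fiber image tracing is upstream and out of scope.
The CSR baseline of the cluster estimator assumes Poisson cluster
positions, with the quantified consequences above.
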