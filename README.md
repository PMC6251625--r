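# forkfocus

Quantify replication-fork activity from single-molecule localization
microscopy (SMLM) of nascent-DNA labeling and from DNA fiber spreading
assays — with a synthetic-data generator that stands in for the raw
microscopy so every stage is testable by parameter recovery.

## Who this is for

Labs measuring replication stress responses typically combine two assays:

* **SMLM of EdU-labeled nascent DNA.** Blinking fluorophores are imaged
  over thousands of frames, localized one molecule at a time, and the
  coordinate list is summarized into *EdU molecules per focus* and
  *EdU foci per nucleus*.
* **DNA fiber assays.** Sequential IdU/CldU pulses mark replication
  periods; scoring first-label-only tracks ("stalled forks") against
  first-then-second-label tracks ("restarted forks") and measuring tract
  lengths quantifies fork restart, protection, and synthesis under stress.

`forkfocus` implements the complete computational chain for both, in
Bioconductor-style S4, with deterministic seeding end to end.

## The methods at the core

* **sCMOS-aware MLE localization.** Frames are box-filtered, local maxima
  segmented into ROIs, and each PSF fitted by maximum likelihood under the
  Poisson-plus-variance model: pixel *k* with expectation
  `mu_k = N PSF_k(x, y, sigma) + b` and per-pixel read-noise variance
  `v_k` is treated as Poisson with rate `mu_k + v_k`. Precision is
  reported as the Cramér–Rao lower bound (CRLB) of the same likelihood —
  in the shot-noise limit `crlb_x ≈ sigma/sqrt(N)`.
* **Polynomial channel registration.** A degree-2 polynomial per axis,
  least-squares fitted on bead fiducial pairs, maps the moving color
  channel onto the reference channel (coefficients in nm over the basis
  `{1, x, y, x², xy, y²}`).
* **Pair-correlation cluster metrics.** With g(r) estimated inside the
  nucleus mask (edge-corrected, CSR-normalized), the average molecules per
  focus is `N_c = 1 + rho * integral (g(r) - 1) 2 pi r dr`, and foci per
  nucleus is total localizations divided by `N_c`.
* **Fiber statistics.** Percent stalled = 100 × stalled / fork events per
  replicate, compared across conditions with Welch t-tests on replicate
  means; tract lengths (1 µm = 2.59 kb) pooled across replicates and
  compared with Mann–Whitney tests — the field's standard reporting.

The methods vignette (`vignettes/forkfocus-methods.Rmd`) derives the
models, defaults, and the estimator's operating range.

## Worked example

Simulate a study-scale nucleus (40 foci of 30 tagged molecules each),
recover the cluster metrics from the ground-truth coordinates, then score
a two-condition fiber experiment:

```r
library(forkfocus)

cfg <- simulationConfig(seed = 11L, minClusterSep = 200)  # well-separated foci
gt  <- simulateGroundTruth(cfg)
gt
#> GroundTruthField: 1221 emitters (1200 clustered, 21 background), 40 cluster centers

pr  <- autoPairCorrelation(emitters(gt), nucleusMask(gt), binWidth = 10, rMax = 500)
fociPerNucleus(pr)
#> ClusterMetrics: N_c 28.48 molecules/cluster, 1221 localizations -> 42.87 foci (integrated to 110 nm)

fibers <- combineFiberDatasets(
  simulateFiberDataset(300L, 0.2, condition = "control", seed = 1L),
  simulateFiberDataset(300L, 0.5, condition = "treated", seed = 2L))
summarizeFibers(fibers, "control")
#> FiberSummary (control: control )
#> % stalled (mean +/- sd across replicates, Welch p vs control):
#>  condition n_replicates mean_percent_stalled sd_percent_stalled welch_p_vs_control
#>    control            3                   21          0.3333333                 NA
#>    treated            3                   51          3.5118846        0.004253302
#> tract lengths kb (pooled, mean +/- sem, Mann-Whitney p vs control):
#>  condition   n  mean_kb    sem_kb mannwhitney_p_vs_control
#>    control 711 16.41271 0.2236693                       NA
#>    treated 441 16.37246 0.2891066                0.7587136
```

Reading the output: the cluster estimator recovers ~28.5 of the simulated
30 molecules per focus (the small shortfall is the documented truncation
of the Gaussian tail at the g(r) = 1 crossing) and ~43 of 40 foci; the
fiber summary recovers the injected 20% vs 50% stall fractions with the
Welch comparison flagging the difference, while tract lengths — simulated
identically in both conditions among restarted forks — correctly show no
effect.

The full imaging chain (blinking → camera frames → localization →
metrics) runs the same way from `renderStack()` + `localizeStack()`, or
end to end from a YAML config:

```r
fx <- makeDemoFixture(tempdir(), "tiny", seed = 7L)
manifest <- runPipeline(fx$config)   # simulate, localize, register, cluster, fiber
```

A thin CLI over the same functions lives at `inst/cli/forkfocus.R`
(`run`, `simulate`, `localize`, `register`, `cluster`, `fiber`,
`fixture` subcommands).

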