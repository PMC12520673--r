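# ktrpipe

Single-cell imaging analysis for kinase translocation reporter (KTR)
experiments in R.

## The problem

In live cells carrying KTR sensors, kinase activity is read out as
geometry: phosphorylated reporter leaves the nucleus, so the
cytoplasm-to-nucleus (C/N) fluorescence ratio tracks CDK4/6 or CDK2
activity in every individual cell over time. This is the workhorse assay
for studying *drug persisters* — cancer cells that arrest under CDK4/6
inhibitor treatment but later re-activate CDK2 and resume cycling while
the drug is still present. Quantifying that phenotype requires a chain of
image analysis: illumination correction, nuclear segmentation, cell
tracking with mitosis detection, ring-based C/N quantification, trace
assembly, and a windowed classification rule, plus companion analytics
(IC50 fitting, Bliss synergy of drug combinations, tumor-section
immune-infiltration morphometry).

`ktrpipe` implements that chain end to end for R users, together with a
seeded synthetic-data generator that produces movies, trace populations,
dose matrices and tumor sections with complete ground truth, so every
stage can be validated quantitatively.

## The core definitions

* **C/N ratio**: median intensity of an annular cytoplasm ring 2–10 µm
  from the nuclear mask (contested ring pixels excluded per pixel),
  divided by the median nuclear intensity.
* **Persister**: CDK2 C/N activity > 1.0 for one contiguous run of
  strictly more than 4 h within 30–48 h after treatment.
* **Bliss excess**: observed inhibition minus `ya + yb − ya·yb` from the
  single-agent margins; the summary score is the mean excess over
  combination wells × 100.
* **Periphery / core**: tumor-section regions within (≤ 500 µm) or
  beyond (> 500 µm) the margin-distance field; densities are cells/mm².
* **Tumor volume**: caliper formula `width² × length / 2` (shorter
  dimension as width).

## Worked example

Simulate a 48-h movie of 12 cells under CDK4/6 inhibition (half of them
fated to become persisters), run the full pipeline, and classify:

```r
library(ktrpipe)

cfg <- sim_config(rng_seed = 8, n_cells = 12, n_frames = 240, snr = 20)
sim <- simulate_timelapse(cfg, "cdk46i")
sim$stack
#> frame_stack: 320 x 320 px, 240 frame(s), 4 channel(s)
#>   channels: h2b, cdk46, cdk2, degron
#>   pixel size 1.3 um, frame interval 0.2 h

res <- analyze_timelapse(sim$stack)   # segment -> track -> quantify -> traces
res$tracks
#> cell_tracks: 2880 record(s), 12 track(s), frames 1-240
#>   0 division(s)

pf <- persister_fraction(classify_persisters(res$traces))
pf$fraction          # 0.5  (6 of 12 cells; matches the constructed truth)
```

Every one of the 12 cells is tracked across all 240 frames; the
classifier recovers exactly the 6 cells whose true CDK2 trajectory
crosses 1.0 and stays up — the recovered persister fraction (0.50) equals
the generator's ground truth.

Dose–response and synergy:

```r
d <- c(0, 10^seq(-1, 3, length.out = 7))
fit_ic50(d, 1 / (1 + d / 10))
#> ic50_fit: IC50 = 10, hill = 1, top = 1, bottom = 1.28e-10 (RSS 2.43e-20)

dm <- simulate_dose_matrix(10, 1, 100, 1.5, interaction = 0.1,
                           doses_a = c(0, 1, 10, 100),
                           doses_b = c(0, 10, 100, 1000),
                           noise_sd = 0.02, n_replicates = 3, rng_seed = 2)
bliss_synergy(dm)
#> bliss_synergy: 4 x 4 grid, score = 0.894 (95% CI -0.162 to 1.965, 1000 resamples)
```

The noiseless 4PL fit returns the generating IC50 to machine precision;
the synergy score is positive because the matrix was built with a
synergistic interaction term on top of Bliss independence.

Tumor-section morphometry:

```r
sec <- simulate_section(n_cd8 = 500, periphery_enrichment = 4,
                        rng_seed = 3, snr = 30)
analyze_section(sec$image)
#> section_morphometry: periphery 435 cells / 2.4 mm^2 = 181 per mm^2
#>   core 33 cells / 0.744 mm^2 = 44.4 per mm^2
```

The recovered periphery:core density ratio (~4) matches the enrichment
the section was generated with — a T-cell-exclusion-like pattern.

See `vignettes/ktrpipe-methods.Rmd` for the model assumptions, parameter
rationale and known limitations.

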