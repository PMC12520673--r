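---
title: "Methods: single-cell KTR imaging analysis with ktrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell KTR imaging analysis with ktrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktrpipe)
```

## The measurement problem

Kinase translocation reporters (KTRs) turn kinase activity into geometry: a
fluorescent substrate fragment is exported from the nucleus when
phosphorylated, so the ratio of cytoplasmic to nuclear fluorescence (the
C/N ratio) tracks the activity of the kinase — here CDK4/6 and CDK2 — in
each individual live cell. Combined with an H2B nuclear marker for
segmentation/tracking and a degron reporter (geminin accumulates in S/G2;
the Cdt1 fragment is degraded in S) for cell-cycle phase, a time-lapse
movie yields per-cell activity trajectories over days of drug treatment.

The biological readout this package targets is the **drug persister**: a
cell that, under CDK4/6 inhibition, first arrests but later re-activates
CDK2 and re-enters the cycle while the drug is still present.
Operationally a cell is called a persister when its CDK2 C/N activity
exceeds 1.0 for more than 4 h (one contiguous run) within the 30–48 h
window after treatment. Around this core sit standard companion analyses:
EdU/EU incorporation readouts (S-phase and transcription), four-parameter
logistic dose–response (IC50) fits, Bliss-independence synergy scoring of
dose checkerboards, caliper tumor volumes, and tumor-section morphometry
(CD8⁺ T-cell densities in the tumor periphery vs. core).

Because the underlying microscopy data are not publicly available, the
package ships a seeded synthetic-data generator that emulates the
statistical structure the analysis assumes, with full ground truth. All
validation is against that ground truth or against independent brute-force
oracles.

## Pipeline

1. **Flat-field correction** (`flatfield_correct`). Illumination bias is
   modelled as a smooth multiplicative field. It is either supplied or
   estimated by fitting a low-order (default quadratic) 2-D polynomial to
   background pixels — pixels below an Otsu threshold on log intensity,
   with one robust refit pass that discards pixels far above the fitted
   surface (blurred object halos).
2. **Nuclear segmentation.** Fixed cells (`segment_fixed`): global Otsu
   threshold on log intensity (bimodal DNA-stain histograms are much
   closer to bimodal on the log scale), 4-connected labelling, area
   filtering (default 30–800 µm², mammalian nucleus scale) and watershed
   splitting on the Euclidean distance transform for components above the
   area cap. Live cells (`segment_live`): multi-scale
   Laplacian-of-Gaussian detection with 8 log-spaced sigmas spanning
   `radius_range/√2` (the standard blob-scale relation). The
   scale-normalized response is thresholded in robust-SNR units (multiples
   of the image MAD), which makes detection invariant to rescaling the
   image by a positive constant. Seeds closer than the minimum radius are
   merged into the brighter one; masks grow from seeds by per-seed local
   Otsu in a `(4·rmax)²` window, keeping the connected component that
   contains the seed, with contested pixels resolved to the nearer seed
   and ties to the lower label id (deterministic).
3. **Tracking** (`link_frames`, `detect_mitosis`). Frame-to-frame linking
   is a globally optimal one-to-one assignment (Hungarian algorithm)
   minimizing summed centroid displacement among pairs within
   `max_step_um` (default 40 µm per 12-min frame); birth/death "slots"
   cost one `max_step_um` each, so the global optimum automatically
   repairs the *deflection* failure of greedy linkers, where a newborn
   detection steals a continuing track's match. Track ends may bridge
   over up to `max_gap_frames` (default 2) missed frames to later track
   starts within `max_step_um · (gap+1)`, again by global assignment.
   Mitoses are called from the appearance of two adjacent daughter nuclei
   whose combined integrated H2B intensity matches the parent's within a
   relative tolerance (default 0.3, pair distance ≤ 25 µm). Under
   globally optimal linking the parent almost never "ends" — it deflects
   onto the nearer daughter — so a continuing track with one adjacent
   newborn is tested with the same combined-intensity rule and, if it
   passes, split at the division frame; the literal two-newborn case is
   also handled and takes precedence. The paper-style thresholds
   ("closely adjacent", "comparable intensity") have no published numeric
   values; the defaults here are package decisions and are configurable.
4. **KTR quantification** (`cn_ratio`). The cytoplasm is approximated as
   an annular ring 2–10 µm from the nuclear mask (Euclidean distance from
   the mask boundary — the standard reading of "from the nuclear mask").
   Ring pixels inside or within 2 µm of *any* other nucleus are excluded,
   and pixels claimed by two rings are excluded from both (per-pixel
   exclusion retains more data than dropping whole cells while honouring
   the overlap rule). The readout is median(ring)/median(nucleus); medians
   on both sides for symmetry and outlier robustness. The nuclear median
   is computed on the mask eroded by 2 px (falling back to the full mask
   for tiny nuclei): boundary pixels are partial-volume mixtures of
   nucleus and cytoplasm after PSF blur, and when activity is high
   (cytoplasm brighter than nucleus) they bias the full-mask median
   upward by several percent. Cells with fewer than 30 valid ring pixels
   are flagged invalid rather than guessed.
5. **Traces and phase calls** (`build_traces`,
   `call_phase_transitions`). Readouts are joined to tracks on the frame
   grid, re-indexed relative to treatment time; only bridged gaps (≤ 2
   frames) are linearly interpolated, and interpolated points stay
   flagged — longer gaps are never filled, to avoid fabricating dynamics.
   Traces shorter than 18 h are excluded from persister analysis (they
   cannot cover the 30–48 h window meaningfully). Cdt1 phase calling:
   G1/S is the first sustained (3-frame) drop below 0.5× the running
   maximum; S/G2 the subsequent sustained recovery above 0.7× the
   pre-drop level. Geminin: S entry is the first sustained rise above the
   baseline + 3 MAD. All fractions are configuration, not published
   values.
6. **Persister classification** (`classify_persister`). Longest
   contiguous run of frames with CDK2 activity strictly above 1.0,
   clipped to the closed window [30 h, 48 h]; a run of k frames lasts
   (k−1)·Δt; a cell is a persister when that run is strictly longer than
   4 h. "Over 4 h" is read as a single contiguous run with strict
   inequality (the plain reading); a cumulative variant is available via
   a flag. Frames exactly at the window edges count; invalid frames break
   runs. Cells with less than 80% valid coverage of the window are
   excluded from both numerator and denominator, with a reason code.
7. **Dose–response and synergy** (`fit_ic50`, `bliss_synergy`). The 4PL
   model `y = bottom + (top−bottom)/(1+(d/IC50)^hill)` is fitted by
   Levenberg–Marquardt least squares with the IC50 parameterized on the
   log scale (positivity) and multi-start initialization (5 log-spaced
   IC50 starts × 3 Hill slopes); flat responses are flagged
   non-converged with `NA` IC50 rather than returning an arbitrary
   number. Bliss scoring implements the plain independence model:
   single-agent effects come from the dose-0 margins, the expectation is
   `ya + yb − ya·yb`, the excess is observed minus expected, and the
   summary score is the mean excess over combination wells × 100, with a
   seeded cell-wise nonparametric bootstrap (default 1000 resamples) for
   the 95% CI. The smoothing and outlier-correction layers of web synergy
   tools are deliberately not replicated — the formula is the defined
   computation. Responses are converted to inhibition fractions before
   scoring because Bliss operates on effect probabilities.
8. **Morphometry** (`segment_tumor`, `margin_distance`, `detect_cd8`,
   `region_densities`). Tumor masks come from Otsu thresholding,
   morphological closing, largest-component selection and hole filling.
   The margin-distance field is the exact Euclidean distance transform
   (physical-distance convention, not chessboard), in µm. CD8⁺ cells are
   detected with the same LoG machinery at lymphocyte scale (3–6 µm
   radius) — the original counting method is not specified, and spot
   detection is the decision here. The periphery is the in-mask band with
   margin distance ≤ 500 µm and the core everything deeper; the
   measure-zero boundary tie at exactly 500 µm goes to the periphery,
   mirroring the "<500 µm" / ">500 µm" wording. Counts are conserved by
   construction (periphery + core = in-mask total), and a tumor too thin
   to have a core reports `NaN` core density with a flag.

## The synthetic generator

`simulate_timelapse` renders 4-channel movies (H2B, CDK4/6 sensor, CDK2
sensor, degron) at the study cadence of one frame per 12 min (0.2 h).
What it emulates, and why:

* **Nuclei** are Gaussian-blurred disks (default radius 8 µm, PSF sigma
  1 px) doing a reflected Gaussian random walk (default 0.8 µm/frame)
  with hard-core exclusion: a step may not bring two nuclei closer than
  contact distance, unless they are already closer (so freshly placed
  daughters can separate). Real nuclei exclude each other the same way;
  without this the random walk produces physically impossible overlaps.
* **Cytoplasm** is an annulus of uniform mean intensity around each
  nucleus. Its width (12 µm) covers the downstream 2–10 µm
  quantification ring with a 2 µm guard band; a narrower annulus would
  put the outer ring on background and make the rendered C/N ratio
  systematically wrong. Where annuli overlap, a pixel takes the value of
  the *nearest* cell, and cytoplasm is never painted over a nucleus —
  cytoplasm is occlusive, not additive, exactly as in a monolayer.
* **Sensor levels** are chosen so that the pixelwise C/N ratio *including
  the flat background* equals the cell's true activity; extracting ratios
  from noiseless frames with true masks recovers the truth to well under
  1%.
* **Activity trajectories** are piecewise smooth. Untreated cells cycle
  (both activities ramp through the cycle and reset at mitosis); under
  CDK4/6 inhibition all cells relax to an arrest plateau (CDK4/6 ≈ 0.35,
  CDK2 ≈ 0.5, tau 6 h), and a configurable fraction re-activates CDK2
  along a sigmoid (tau 1.5 h) crossing the 1.0 line at a time drawn
  uniformly from 24–36 h. The distribution of rise times is not published
  anywhere; it is therefore an explicit parameter, not an assertion. The
  combination scenario multiplies the persister fraction by
  `combo_factor` (default 0.25). Ground-truth persister labels are always
  *recomputed* from the true CDK2 trace with the sliding-window rule, so
  label and trajectory cannot disagree.
* **Divisions** (untreated) occur on cycle completion (mean cycle length
  `1/division_rate_per_h`, jittered ±20%); daughters appear one nuclear
  radius to either side along a random axis and split the parent's
  integrated H2B intensity ~45/55 — satisfying the mitosis-detection
  definition by construction.
* **Noise** is Poisson shot noise calibrated so the SNR at the nuclear
  signal level equals `snr`, plus Gaussian read noise; the illumination
  bias is a smooth quadratic multiplicative field whose corner-to-center
  ratio is `1 − amplitude`.

What it does **not** emulate: nuclear texture, photobleaching, focus
drift, apoptosis, cell shape irregularity, 3-D effects, or
pharmacokinetics. Passing tests therefore demonstrate correctness of the
*computational pipeline* under the stated geometric and noise model, not
performance on real microscopy.

`simulate_traces` generates the same trajectories without rendering
(plus i.i.d. Gaussian measurement noise on the activities) for
population-scale classifier studies; `simulate_dose_matrix` produces
checkerboards that satisfy Bliss independence exactly at zero interaction
(the interaction term is a Gaussian bump in log-dose centered at the two
IC50s, zero on the margins); `simulate_section` builds a star-convex
tumor mask and places CD8 points with a configurable periphery:core
density ratio, labelling each point with the 500 µm rule applied to the
exact distance field of the true mask.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_interval_h` | 0.2 | h | the imaging cadence (12 min) |
| `nucleus_radius_um` | 8 | µm | mammalian nucleus scale |
| ring inner/outer | 2 / 10 | µm | the cytoplasm-proxy annulus |
| `nucleus_erode_px` | 2 | px | excludes partial-volume boundary pixels |
| `min_ring_px` | 30 | px | below this the ratio is flagged invalid |
| persister threshold | 1.0 | C/N | activity line for "CDK2 on" |
| persister window | 30–48 | h | analysis window after treatment |
| persister duration | > 4 | h | strict, single contiguous run |
| coverage minimum | 0.8 | — | window QC before classification |
| `max_step_um` | 40 | µm/frame | motility bound per 12-min frame |
| `max_gap_frames` | 2 | frames | detection dropouts bridged |
| mitosis pair distance | 25 | µm | "closely adjacent" daughters |
| intensity tolerance | 0.3 | — | "comparable" combined H2B |
| periphery depth | 500 | µm | tumor periphery vs. core |

## Numerical choices and degenerate inputs

* Histogram thresholding is Otsu on 256 bins; on log intensity for
  DNA-stain and EdU data. Blank images yield empty masks, not errors.
* All tie-breaks are deterministic: contested growth pixels go to the
  nearer seed then the lower label id; equal-mismatch division candidates
  are resolved by distance; plateau maxima keep one pixel.
* The LoG detector also requires a seed to reach 2% of the strongest
  response, which suppresses blur ripples in noiseless images without
  breaking scale invariance (both sides scale with the image).
* `fit_ic50` refuses to report an IC50 when the response span is below
  0.05 (unidentifiable) and bounds the Hill slope to [0.05, 10].
* The IC50 noise study uses triplicate wells over 8 doses spanning four
  decades, matching the replication level of a typical dose–response
  assay (and this study's n = 3); with single wells a free 4-parameter
  fit at 5% response noise is information-limited — even a fit started
  at the true parameters shows ~19% median IC50 error, so replication,
  not optimization, is what buys precision.
* Distance fields use the exact Euclidean transform; equality with a
  brute-force all-pairs minimum is asserted in the tests.
* `eu_summarize` subsamples without replacement with a fixed seed
  (default 1000 cells per condition per replicate, the usual reporting
  convention) and degrades gracefully when fewer cells exist.

## Validation problem sizes

The test suite validates: the persister classifier against a brute-force
window-enumeration oracle on 10,000 random traces (exact agreement); the
full movie pipeline on a noiseless 20-cell, 240-frame (48 h) arrest
movie (max CDK2 trace error < 0.05, persister fraction recovered
exactly); 20 seeded 200-cell noisy trace populations (fraction within
binomial bounds); a 30-cell, 60-frame dividing movie for
segmentation/tracking QC (recall/precision ≥ 0.98, purity ≥ 0.95,
division recall ≥ 0.9); the C/N extractor against a per-pixel oracle on
50 random ≤ 64² fixtures (exact); IC50 recovery (0.1% noiseless, < 10%
median at 5% noise over 100 simulations); Bliss independence and
transpose symmetry (exact); and the distance transform on 20 random
masks (exact). These sizes were chosen to exercise every code path at
full fidelity while keeping the whole suite comfortably runnable on a
laptop.

## Known limitations

* The ring cytoplasm proxy fails for very crowded fields where most ring
  pixels are contested; such cells are flagged invalid rather than
  rescued.
* The tracker is purely positional (intensity is used only in the
  mitosis test, matching the simplest contract consistent with the
  method description); extremely fast or densely packed cells can swap.
* Phase calling assumes reasonably clean degron traces; it returns no
  transitions rather than guessing on noise-only input.
* The generator's persister dynamics are a parametric idealization;
  recovered persister fractions on real data depend on segmentation and
  sensor calibration quality in ways synthetic tests cannot capture.
* Tumor-section analysis is 2-D, single-marker, and assumes one dominant
  tumor region per section.
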