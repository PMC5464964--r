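---
title: "Cell-cycle analysis from a single endogenous PCNA reporter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle analysis from a single endogenous PCNA reporter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

`pcnatrack` treats a 2-D fluorescence time-lapse movie as a set of nuclei
whose per-frame summary statistics carry all cell-cycle information. For a
nucleus mask $M_t$ on the PCNA channel $I_t$ with per-frame background
$b_t$, two features are computed:

- the nuclear mean $\mu_t = \mathrm{mean}\{I_t(p) - b_t : p \in M_t\}$, and
- the distribution width $\sigma_t = \mathrm{sd}\{I_t(p) - b_t : p \in M_t\}$,
  the within-nucleus pixel standard deviation used as a proxy for
  replication-foci granularity (an IQR variant is available via
  `width_stat = "iqr"`).

The cell-cycle phase structure is then read off the trajectories
$(\mu_t, \sigma_t)$:

- **G1/S**: $\mu_t$ leaves its post-mitotic baseline. The baseline is the
  median of the smoothed $\mu_t$ over the first 4 h after birth; a candidate
  onset must exceed baseline $\times (1 + 0.10)$ for 3 consecutive frames;
  the reported onset is a two-segment flat-then-ramp least-squares
  changepoint $y = a + s\,(t-\tau)_+$ fitted over [birth, candidate + 3].
- **S/G2**: $\sigma_t$ peaks at the end of S phase; the S/G2 frame is the
  argmax of the smoothed width over the open interval (G1/S, NEBD), with
  ties broken toward the latest frame because the width maximum sits at the
  end of S.
- **NEBD/M**: an abrupt drop of the smoothed nuclear mean,
  $\mu_{t+1} \le (1 - 0.3)\,\mu_t$, caused by reporter redistribution into
  the cytoplasm at nuclear envelope breakdown. When a chromatin channel is
  present, a local maximum of its within-nucleus width within $\pm 2$ frames
  (chromosome condensation) is additionally required.
- **G0**: with no G1/S onset detected, a track is quiescent when the
  smoothed mean falls below $(1 - 0.4)$ of its birth-window level along a
  non-increasing run (5% per-step tolerance on the running minimum) lasting
  at least 24 h; the decline onset is the first frame of that run.

All detectors act on ratios or ranks of the series, so every event estimate
is invariant under a global positive rescaling of the intensities — a
property the test suite asserts directly.

Assumptions: 2-D imaging with nuclei resolvable as connected regions; the
PCNA-like reporter is predominantly nuclear in interphase; frame intervals
are short relative to phase lengths (minutes, not hours); cells do not leave
the field during the window of interest.

# Segmentation and tracking

Segmentation is a conventional chain: Gaussian smoothing (default
$\sigma = 1.5$ px), subtraction of a per-frame background percentile
(default the median — most pixels are background), a global Otsu threshold
on the result (normalized by the frame maximum, so label maps are invariant
under rescaling) plus an additive offset, hole filling, watershed splitting
on the distance transform seeded at local maxima at least 8 px apart (ties
toward the lowest (row, col)), and an area filter (20–4000 px). A
scale-invariant noise floor — six times the MAD of the smoothed frame —
guards against spurious labels on frames with no real foreground, where
Otsu would otherwise split smoothed noise.

Two refinements matter in practice:

- **Local re-segmentation after tracking.** Dim G1 nuclei can fall under a
  global threshold dominated by brighter S/G2 cells. For frames where a
  track's area drops more than 30% below its rolling median, the nucleus is
  re-thresholded locally (Otsu within the dilated bounding box of the
  previous frame's mask, background at the 10th local percentile since the
  crop is foreground-dominated) and the component maximally overlapping the
  prior mask replaces the detection when larger.
- **Eroded-core intensity statistics.** Mask boundaries carry partial-volume
  pixels whose inclusion couples $\mu_t$ and $\sigma_t$ to the exact
  threshold; a frame-to-frame threshold shift would otherwise masquerade as
  an expression change. Feature statistics are therefore taken over the
  mask eroded by 2 px (falling back to the full mask for very small nuclei);
  reported areas remain those of the full mask.

Tracking links consecutive label maps greedily by maximal Jaccard overlap
(minimum 0.2; ties by larger overlap area, then smaller centroid distance,
then lower label), with a nearest-centroid fallback within 6 px for labels
without a qualifying overlap. Gap closing merges a terminated and a
later-born track when the gap is at most 2 frames, displacement at most
6 px per gap frame, and the area ratio within [0.5, 2]. A division links a
mother ending at frame $f$ to exactly two tracks born within 3 frames of
$f$, centroids within 24 px, preferring the pair whose summed area best
matches the mother's, and requiring the NEBD drop signature in the mother's
last 5 frames; a single plausible daughter is never linked. The minimum
Jaccard of 0.2 is chosen so that a mother's M-phase mask does not capture a
daughter (that overlap is ~0.15 at the simulated division geometry) while
true frame-to-frame continuations (overlap > 0.6 at sub-pixel motion)
always link.

# Quantification and calibration

Co-reporter levels are extracted per cell and compartment: the nuclear mean
over the nucleus mask, and the cytoplasmic mean over the annulus between
2-px and 6-px dilations of the nucleus, excluding all nuclei and dropping
pixels contested by another cell's annulus (conservative and
deterministic). Background is the 5th percentile of pixels outside all
masks and rings. Note the 5th-percentile convention sits ~1.6 noise SD
below the mean background, so background-only channels read a small
positive offset; the tests bound recovery accordingly.

Fluorescence from one tagged allele is converted to a total-protein
estimate by dividing by the tagged-allele fraction (defaults: 0.5 for a
cyclin-A2-like reporter expressed at similar levels to the untagged allele,
0.30 for cyclin B1, 0.73 for cyclin D1), and standardized across exposure
times and fluorophores as
intensity $\times$ (reference exposure / exposure) / fluorophore factor —
the minimal linear reading of a purified-fluorophore calibration.

Population curves report, per aligned time point, the mean and the
2.5th/97.5th percentiles of contributing tracks (a band holding 95% of the
values, read literally as percentiles rather than a parametric interval).
Sister-cell analyses use in-package Spearman correlation (average-rank
ties) and a two-sided Mann-Whitney U test (exact enumeration when both
groups have at most 8 observations, otherwise the normal approximation with
tie correction and no continuity correction); both are pinned against
brute-force oracles and base R in the tests. Cyclin-D1-like G1 kinetics are
classed I (non-increasing within a 2%-of-birth-level tolerance *and* a net
decrease from birth to G1/S) versus II (everything else — including an
exactly constant series, which shows no decrease).

# The synthetic movie generator

The generator is first-class, tested code that encodes the study
conditions the pipeline is validated under: G1 duration truncated-normal
7.7 ± 3.0 h (floor 1 h), S phase 10 h spanned by a linear PCNA ramp from
baseline to a 2-fold plateau, G2 4 h, mitosis 0.5 h, co-reporter onsets
45 min (cyclin-A2-like) and 16 min (hGem-like) after the PCNA ramp onset,
and a serum-starvation mode with an exponential PCNA decline (half-time
16 h, so a ~8-fold loss over 48 h) and no S entry. Nuclei are ellipses
(axis ratio 1.0–1.3, semi-axis 8 ± 0.8 px) on a random walk (0.3 px/frame),
imaged at background 10 AFU with Poisson shot noise and 2 AFU Gaussian read
noise.

Rendering choices that required a decision:

- **Foci redistribute rather than add.** Replication foci are Gaussian
  spots (count 4→10, width 1→1.3 px across S) carrying a fraction 0→0.5 of
  the nuclear signal, with positions drawn once per cell (foci persist
  across frames) uniformly over the nucleus. Concentrating a growing
  fraction of a *fixed* total keeps the nuclear mean exactly on the
  programmed ramp while the pixel SD rises through S — matching the
  biological picture in which the abundance ramp and the granularity rise
  are one phenomenon viewed through two statistics. Spot-count and
  fraction schedules are per-cell fields, so tests can vary them directly.
- **NEBD rendering.** At NEBD the nuclear-region PCNA mean drops to 45% of
  the plateau in one frame and the cytoplasm of the rounded cell carries
  20% of the plateau; chromatin condenses to half area at twice intensity.
  These magnitudes keep the M-phase cell segmentable (the nuclear region
  stays above realistic global thresholds) while the drop (>50%)
  comfortably exceeds the 30% detector threshold.
- **Division geometry.** Daughters appear at the mother's position at
  division (not her starting position) offset ±1.35 mean radii along an
  axis chosen to keep both in the field, with radii reduced by $\sqrt 2$.
  This geometry makes mother-to-daughter masks overlap below the linker's
  Jaccard threshold, so mother tracks terminate at division and divisions
  are detected rather than silently continued.
- **Interphase cytoplasmic PCNA** is rendered at 3% of the nuclear
  baseline — predominantly nuclear, as for the endogenous reporter — so
  nuclear segmentation is not confounded by a bright cytoplasm.

What the generator does **not** emulate: photobleaching, illumination
gradients, drift, 3-D effects, apoptosis, cell crowding/contact, irregular
nuclear shapes, and segmentation-relevant texture beyond foci. Passing
tests therefore demonstrate correctness of the algorithms under the stated
reporter model and imaging noise, not performance on arbitrary real
microscopy; on real data the configurable segmentation block and the
re-segmentation refinement are the intended adaptation points.

# Numerical choices

- Smoothing is a running median of window 3 frames — the smallest window
  suppressing single-frame detector noise without shifting onsets;
  configurable via `class_params(w = ...)`.
- The G1/S changepoint is fitted on an integer grid and then refined to a
  continuous onset time within the best grid cell (1-D minimization of the
  two-segment RSS). The integer event frame is the first frame past the
  fitted onset; the continuous estimate is kept as an attribute and used
  where onset *lags* between two reporters are compared, because integer
  knots carry opposite half-frame biases for ramps of different steepness.
- Degenerate inputs are contracts, not crashes: constant or saturated
  frames give empty label maps with a warning; an empty prior mask gives an
  empty re-segmentation; a flat width interval flags S/G2 undefined; tracks
  shorter than the baseline or quiescence windows are flagged, not guessed.
- Time is hours internally; frame intervals are minutes; file outputs use
  0-based frame indices. Frame 1 is acquired at t = 0.
- Label maps are 16-bit TIFF; intensity stacks are stored on a 16-bit grid
  under a power-of-two scale (quantization step scale/65535 AFU), making a
  write/read cycle exactly idempotent.

# Validation scale

The packaged validation (`scripts/acceptance.R`, mirrored in the test
suite) simulates 54 founder cells over 181 frames at 10-min intervals on a
416 × 416 px field and analyses the movie twice — segmenting once on PCNA
and once on chromatin, with PCNA features both times. It reports the
maximum per-cell difference between the two G1/S estimates, the 90th
percentile of the per-time-point relative deviation of co-reporter nuclear
intensity between the mask sets, the mean extracted plateau/initial PCNA
fold, and the median PCNA-to-cyclin-A2 onset lag. Unit and property tests
run on smaller movies (typically 6 cells, 100 frames at 15 min, and a
91-frame starvation movie at 20 min) chosen to exercise every code path,
including divisions, in seconds.

# Known limitations

- Greedy overlap linking is adequate at the simulated densities; heavily
  crowded or fast-moving fields would need global assignment, which is out
  of scope.
- Division detection requires both daughters to be segmented within 3
  frames; a daughter lost at birth (e.g. out of field) terminates the
  mother track without a lineage link, by design.
- Quiescence classification needs tracks spanning 24 h; shorter tracks are
  flagged unknown rather than classified.
- The S/G2 width maximum assumes foci dominate the width signal near the
  end of S; reporters with strong non-foci texture would need the IQR
  variant or a recalibrated granularity proxy.
- M-phase masks on the PCNA channel deliberately differ from chromatin
  masks (the reporter is cell-wide after NEBD); per-frame area agreement
  between the two segmentations is asserted outside M only.
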