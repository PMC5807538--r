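---
title: "How cometscore measures DNA damage: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How cometscore measures DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometscore)
```

## The measurement model

A comet image is a non-negative intensity raster with a physical scale
(default 1 µm/px, the resolution of plate-scanning cytometers used with
single-focal-plane comet arrays) and a declared electrophoresis direction.
All analysis happens in a canonical frame in which DNA migrates toward
increasing column index; `normalize_migration()` re-orients any input.

The damage metric chain rests on one modelling assumption: *a comet is
separable along the migration axis into a head and a tail by a single
dividing line*. Everything else follows from intensity bookkeeping:

1. **Detection.** A pixel is foreground iff its intensity strictly exceeds
   `mean + k·sd` of the scanning box centred on it (box clipped at image
   edges, sample standard deviation). Local statistics make the rule
   insensitive to smooth illumination gradients and to adding a constant
   to the whole image. Foreground is split into 8-connected components —
   comet tails are thin, diagonal-prone structures, so 4-connectivity
   would shear them apart.

2. **Classification.** Five rules, all evaluated (no short-circuit) so the
   reason set is a complete QC diagnostic, and all geometric or
   correlation-based so classification is invariant to intensity
   rescaling: area bounds; orientation of the major axis relative to the
   migration direction (waived for near-circular objects — an undamaged
   comet is a disc whose orientation is meaningless); a shape composite
   (roundness of the leading third of the mask × monotone decay of the
   axial profile after its peak); and mirror symmetry about the axis
   through the intensity centroid parallel to migration, scored as a
   Pearson correlation mapped to [0, 1].

3. **Background correction.** Non-specific background fluorescence is
   modelled as a bilinear surface `a + b·row + c·col + d·row·col`
   least-squares fitted to pixels *surrounding* the comet, then
   subtracted, with negatives clamped to zero so intensity sums stay
   non-negative. The fit's residual standard deviation is the local noise
   floor. Two exclusions define "surrounding": the detection mask dilated
   by `bg_guard` (default 10 px) — the blurred fringe of an object is not
   background — and every candidate's *migration corridor* (its row band,
   from just ahead of the head to one scanning-box width downstream).
   The corridor matters because faint tails routinely fall below the
   detection threshold, and on a regular microwell grid the neighbours'
   tails are column-aligned with the measured comet's tail: fitting them
   as background would selectively erase exactly the dim-tail signal the
   assay needs at low damage.

4. **Markers and metrics.** The corrected intensities in the candidate's
   row band are summed perpendicular to migration into an axial profile
   (the projection conserves total intensity exactly). Head start and
   tail end are the first and last profile positions above a signal
   threshold; the head/tail dividing line mirrors the leading rise about
   the profile peak — the head is modelled as symmetric about its peak,
   so its trailing edge sits as far beyond the peak as its leading edge
   sits before it, clipped to the tail end. A symmetric unimodal profile
   (undamaged comet) therefore yields an empty tail and 0% tail DNA by
   construction. % tail DNA is the tail interval's share of the comet's
   corrected intensity; tail length is head edge to tail tip in µm; tail
   moment is the exact identity `tail length × tail fraction`. The Olive
   moment (centroid-separation form) is available behind
   `olive_moment = TRUE` but off by default; the extent form is the
   primary statistic.

## Numerical choices that matter

- **Signal threshold.** The threshold is
  `max(noise term, peak_frac · profile peak)` with `peak_frac = 0.01`.
  Because negatives are clamped before profiling, a pure-noise line of
  `w` pixels with residual sd σ sums to `w·σ/√(2π)` on average, not zero;
  the noise term is that baseline plus `noise_k` (default 3) standard
  deviations of the clamped sum, `σ·√(w·(1/2 − 1/(2π)))`, with the
  per-position quantile sharpened for multiplicity over the profile
  length. Without the baseline, the tail-end marker drifts into noise for
  any profile band wider than ~56 rows; without the multiplicity
  correction, a single stray noise column (expected a few times per
  hundred columns at 3σ) drags a marker far from the comet.
- **Tied peaks.** Discretized round heads produce exactly tied profile
  plateaus (a disc with a half-integer centre has a flat top). The peak
  used by the mirror rule is the midpoint of the earliest maximal run, so
  a rectangular head of width `w` yields `head_end = head_start + w − 1`
  — the whole head — rather than mirroring about the plateau's first
  sample and cutting the head in half.
- **Degenerate inputs.** Constant images threshold to empty foreground
  (strict inequality); zero-variance symmetry patches score 1 (uniform
  discs must not be rejected as asymmetric); single-row objects score 1;
  background fits refuse boxes with fewer than 10 background pixels;
  profiles with nothing above threshold reject the object with a
  "no signal" reason instead of aborting the image.
- **Exact windowed sums.** The scanning-box statistics and the box
  smoothing are computed with integral images (summed-area tables), which
  are exact up to floating point and match a per-pixel loop oracle — an
  FFT convolution would not.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `box_rows × box_cols` | 180 × 220 | px | analysis/scanning box sized to hold a heavily damaged comet without overlapping neighbours at 1 µm/px |
| `threshold_k` | 2 | – | standard adaptive-threshold multiplier; higher = stricter foreground |
| `min_seed_area` | 40 | px² | drops specks; biological size limits belong to the classifier |
| `min_area / max_area` | 200 / 39600 | px² | nucleus cross-sections of 10–25 µm bound head areas from below; the analysis box bounds comets from above |
| `max_orientation_dev` | 30 | degrees | tails must follow the field direction |
| `max_aspect` | 1.2 | – | at or below this the object is effectively round and orientation is waived |
| `min_symmetry` | 0.6 | – | mirror-correlation floor |
| `min_shape_score` | 0.5 | – | roundness × profile-decay floor |
| `box_pad`, `profile_pad`, `bg_guard` | 24, 10, 10 | px | analysis-box margin, profile row-band padding, background guard dilation |
| `noise_k`, `peak_frac` | 3, 0.01 | – | marker threshold constants (see above) |

All are settable programmatically and through the YAML config's
`detection:`, `classifier:` and `quantification:` blocks.

## What the synthetic generator emulates — and what it does not

`spec_for_target()` / `render_comet()` / `render_well()` implement the
classical validation substrate for automated comet scoring: a circular
head and a half-elliptical tail of chosen grey values, blurred with a
normalized 15×15 box filter for a realistic soft appearance, placed on a
regular grid with a planar background and additive Gaussian noise
(clamped at zero), all under a fixed seed (bit-identical reruns). Ground
truth is defined on the *pre-blur* region masks — head pixels win where
regions overlap, and the tail occupies columns strictly beyond the head
edge, so the region sums are exact and consistent with the profile
partition. True tail length is the tail extent itself; the tail-moment
identity holds exactly by construction.

Given a target % tail DNA, the solver picks the tail envelope the way
real comets behave: damage fills and then lengthens the tail while the
head/tail boundary stays resolvable. Tail grey is kept between 2% and
75% of head grey — below the floor a faint tail sinks under the profile
signal threshold; above the ceiling the tail's profile rivals the head
peak and no scoring method can place the dividing line (that is the
physics behind the assay's well-known ~70–80% quantitative ceiling, which
the `saturated` flag mirrors) — and the tail area tracks the target
within that band, capped at a 1700 px² reference envelope (≈ 90 px tails
for a 12 px head at 1 µm/px). Explicitly supplied `tail_extent` is
honoured, with only the grey value solved.

The generator deliberately does **not** model: optical point-spread
functions, microwell walls, multi-channel fluorescence, non-planar
background, intensity-dependent (shot) noise, cell-to-cell biological
variability, or electrophoresis physics. Passing the validation suite
therefore demonstrates that the measurement chain is *internally
accurate* — it recovers known intensity partitions through detection,
background fitting and marker placement — not that any particular
biological dose–response will be recovered; assay-level figures
(inter-assay CVs, dose curves) require real images.

Default study conditions for the validation runs: 20–25 comets spanning
0–80% target tail DNA on one well (an image of roughly 300 × 1700 px),
background plane at 10 levels with a 0.002 levels/px gradient, Gaussian
noise sd 2 levels on a 0–255 scale. These sizes keep a full validation
run in seconds while every stage (thresholding over ~0.5 Mpx, per-comet
background fits, marker placement) is exercised end to end.

## Design choices where the design was open

- **Adaptive rule.** "Local mean + k·sd over a dense scanning box" is the
  standard adaptive-threshold family; a coarse box stride would introduce
  blocking artifacts, so windowed statistics are computed per pixel.
- **Head/tail dividing line.** Mirroring the leading rise about the peak
  is the classical comet-scoring construction for "the most likely
  dividing line": it needs no model of tail shape and reduces to the
  correct answers for the two extremes (symmetric undamaged comet → no
  tail; rectangular head + shelf → head ends where the plateau ends).
- **Pooled-variance t.** "Student's t-test" is implemented as the classic
  pooled-variance test; Welch's correction is available behind a flag but
  is not the default, matching the naming convention of the statistics
  the pipeline reports. One-sided tests take the alternative that treated
  damage exceeds control — the direction a genotoxin screen asks about.
- **Raw p-values by default.** Per-compound t-tests are reported raw; a
  Benjamini–Hochberg column can be added by downstream code from the
  per-comparison output, but the plate report mirrors the conventional
  per-compound presentation.
- **Tile order.** `stitch_tiles()` assumes row-major, top-left origin,
  abutting tiles (no registration or blending). Comets straddling tile
  seams are a documented caveat of seam-blind stitching.
- **Peripheral wells.** Rows A/H plus columns 1/12 — the outermost ring
  of a 96-well plate — for the edge-effect report.
- **Profile-based % tail DNA.** The tail share is computed from the 1-D
  axial profile (what the projection machinery naturally supports); a
  full 2-D region partition is a possible alternative that would differ
  only in how off-axis pixels at the boundary column are attributed.
- **No watershed splitting.** Merged objects are meant to be *rejected*
  (double cell loading), not split: adjacent cells perpendicular or
  diagonal to the migration axis fail orientation and/or symmetry. A pair
  merged exactly in-line with migration genuinely mimics a comet and is
  the known blind spot of any rule-based screen.

## Known limitations

- The 15-px blur mixes intensity across the head/tail boundary; the
  mirror rule assigns the mixed columns to the head, so measured % tail
  DNA carries a mild multiplicative deficit against pre-blur truth
  (the regression slope the validation suite computes sits a few percent
  below 1). The effect is a stable scale factor, not curvature, which is
  why linearity (r²) is the meaningful validation statistic.
- In noisy images the tail-end marker is occasionally placed beyond the
  true tail tip (tail *length* is noise-sensitive); % tail DNA is robust
  because the extra columns carry negligible intensity.
- Very long, faint tails can be split by the threshold into fragments;
  fragments are measured as part of their comet's profile, but a bright
  fragment can additionally be reported as its own accepted object in
  noisy wells.
- Above ~80% tail DNA the head/tail boundary is not resolvable and
  measurements are flagged `saturated` and under-report — a property of
  the assay, not of any particular scorer.
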