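---
title: "Methods: quantifying cytokinesis and abscission dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cytokinesis and abscission dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocutr)
```

This vignette explains the measurements nocutr implements, the assumptions
behind them, the parameters that matter, and the design decisions taken
where the underlying procedures are usually done by eye.

## Conventions

All images are numeric matrices `[row = y, col = x]`, 1-based, with pixel
centers at integer coordinates; physical units come from `pixel_size_um`
and `frame_interval_min`, and frame `f` is acquired at
`(f − 1) · frame_interval_min` minutes. Connectivity is 8-connected
everywhere, so a one-pixel-wide diagonal chromatin bridge stays a single
object. An event that is not observed before the end of a recording is
*censored*: it is reported as `NA` and kept in denominators where the
readout is a fraction of all cells — completion-fraction plots here are raw
fractions, not Kaplan–Meier estimates, because censored cells genuinely
count as "not yet completed" in that readout.

## Nucleus segmentation and bridge scoring

Nuclei come from a thresholded histone channel (Otsu by default; a fixed
threshold is available and is what synthetic closed-loop tests use, since
exact pixel sets matter there). Components smaller than `min_area_px`
(default 20 px — a nucleus of diameter 5 px at 0.2 µm/px is already
implausibly small) are discarded, border-touching components are flagged
and excluded from geometry, and each region is measured by its unweighted
mask centroid and a major axis of `4·sqrt(λ₁)` from the second-order pixel
moments, which recovers the diameter of a disk exactly. Centroids are
deliberately *unweighted*: intensity weighting would couple the ROI
geometry to bleaching and expression level.

A chromatin bridge is scored inside the midzone corridor (the ROI below).
A frame is `CONNECTED` if one positive component touches both nucleus
masks, `FRAGMENTED` if objects of at least `min_object_px` (default 4 px)
sit in the corridor without connecting the nuclei, and `RESOLVED`
otherwise. Fragmented bridges count as **unresolved** when timing
resolution: stretched bridge DNA can locally drop below the detection
limit while the bridge persists, so only a corridor that stays clean —
never followed by a reappearance — marks resolution. In practice the
bridge is dimmer than the nuclei, so the bridge mask uses a lower
threshold than the nucleus mask; the pipeline exposes both.

Anaphase onset is "rapid nuclear elongation": the first frame whose
chromatin-mass major axis reaches `elongation_factor` (default 1.5) times
the median of the first `baseline_frames` (default 5) frames, sustained
for 2 frames. The factor crossing makes onset detection exact only when
elongation is fast relative to the frame interval — which is what anaphase
looks like; for slow synthetic separations the detected onset lags the
true one by up to a frame, and tests assert recovery within one frame.

RPA-like foci are local maxima inside nucleus masks brighter than the
nucleoplasmic background, operationalised as median + k·MAD (k default 3)
over the nuclear pixels, merged within `min_separation_px`. The median/MAD
pair makes the background estimate insensitive to the foci themselves;
focus counts are non-increasing in k by construction.

## The actin-cluster index

The midzone ROI is the rectangle centred on the midpoint of the two
nucleus centroids, with height = half the internuclear distance along the
internuclear axis and width = twice the mean nuclear major axis across it
— the region where the cleavage furrow and post-anaphase actin patches
sit. A pixel belongs to the ROI when its center lies inside the oriented
rectangle (inclusive); rasterisation is therefore deterministic and
rotation-equivariant up to pixelisation.

Within the ROI, the actin-positive set *P* excludes sub-threshold pixels
entirely (they are set to zero, not averaged in). The top set is the
`ceiling(0.05·|P|)` brightest pixels, never empty when *P* is nonempty,
with ties broken by intensity then row-major scan order so that reruns are
bit-identical. Then

- enrichment `E = (Int_top − Int_all)/Int_all`,
- `COM` = intensity-weighted centroid of the top set,
- clustering `C = d_all/d_top` (unweighted mean distances to the COM),
- index `= E · C`.

Weighting the COM by intensity and leaving the distances unweighted is a
deliberate split: the COM should sit on the brightest material, while the
distance ratio is a purely geometric dispersion contrast. An unweighted
COM variant is available by flag. Two guards avoid infinities: frames with
`|P| < min_positive_px` (default 20) are invalid with reason
`"too_few_positive"`, and frames whose top set is degenerate
(`d_top ≤ 1e−6` px, e.g. a single-pixel top set) are invalid with reason
`"degenerate_top"`. The index is dimensionless, zero for any uniform
field, and invariant under multiplicative intensity scaling once the
positive set is fixed.

**Clearance scoring.** Visual scoring of "actin cleared from the division
plane" is replaced by a threshold rule: clearance is the first frame at or
after anaphase onset whose effective index stays below threshold for
`k_frames` (default 2) consecutive scored frames. The threshold is
`tau_rel` (default 0.5) times the median pre-anaphase index when such a
baseline exists; otherwise an absolute `tau_abs` is used with a notice —
the usual case, because frames before nuclear separation contain one
nucleus and are dropped by the two-nuclei rule. `tau_abs = 0.3` is the
default exposed by the pipeline: well below the index of any furrow or
cluster signal (≳ 0.8 in rendered scenes) and above the zero of empty
frames. Frames invalid for lack of positive pixels are scored as index 0
rather than skipped: no detectable actin *is* clearance, and a rule that
only looked at valid frames could never see actin vanish completely.
Frames invalid for a degenerate top set are skipped, since their index is
genuinely undefined.

## Membrane profiles and abscission

Profiles are sampled along the annotated mother–daughter axis at ~1 px
spacing, bilinearly interpolated, and averaged over a perpendicular band
of ±`half_width_px` (default 2 px). Z-stacks are reduced by maximum
projection before profiling (mean projection by flag): the neck ridge is
the brightest structure along Z, so the maximum keeps it while averaging
would dilute it with out-of-focus planes.

Peaks are local maxima with topographic prominence at least
`prominence_rel` (default 0.25) of the profile maximum — a relative
cutoff, so classification is invariant under intensity scaling. One
accepted peak is `SINGLE`; two or more separated by at least
`min_separation_um` (default 0.4 µm, about two membrane thicknesses plus
the optical resolution limit) is `DOUBLE`; everything else, including flat
or all-zero profiles, is `AMBIGUOUS`. Abscission is the first frame at or
after ingression with `DOUBLE` sustained for `persistence_frames`
(default 2) — a single-frame double peak is treated as a fluctuation.
Ingression itself is a sustained drop of the profile FWHM below
`ingression_fraction` (default 0.6) of its early-movie baseline.

## Midbody quantification

The best-focused slice maximises tubulin intensity variance in the seed
ROI (sharp structure = high local contrast; an integrated-intensity
variant is available), ties resolving to the lowest slice. All channels
are then maximum-projected over the five slices centred there, clipped at
stack edges. The "tight ellipse" is the moments-matched ellipse of the
largest 8-connected component of the Otsu-thresholded tubulin projection:
centroid from first moments, semi-axes `2·sqrt(eigenvalues)` of the pixel
covariance (exact for a filled ellipse), orientation from the principal
eigenvector. By default the moments are weighted by background-subtracted
tubulin intensity: a maximum projection drags a dim defocus halo into the
segmented component, and intensity weighting keeps the fit on the
structure rather than the halo (binary-moment variant by flag). Total
intensity is the exact product of the pixel-count area and the mean
intensity of the channel of interest inside the fitted ellipse; the only
background correction in scope is a constant offset subtracted from the
mean, typically estimated as the projection median.

## Statistics and qPCR

Group comparisons use the Mann–Whitney rank-sum test (exact enumeration
for small tie-free samples, normal approximation with tie and continuity
corrections otherwise) and Fisher's exact test for pooled fractions; both
are delegated to R's reference implementations and are cross-checked in
the test suite against independent full-enumeration oracles. Box
summaries use linearly interpolated quartiles and Tukey whiskers (most
extreme points within 1.5 IQR of the quartiles). Relative expression is
`2^−ΔCt` with ΔCt from replicate-mean Cts (per-replicate variant by
flag), normalised to the control sample; the result is invariant under a
constant Ct shift of a run. Primer efficiency is `10^(−1/slope) − 1` from
the Ct-vs-log10(dilution) regression, with the conventional >90% pass
rule.

## The synthetic-data generator

`generate_division_movie()` renders an analytic scene — two Gaussian
nuclei separating from anaphase onset, a chromatin bridge (contiguous or
two disjoint fragments) until resolution, a furrow band then Gaussian
actin clusters in the midzone, a membrane neck ridge that narrows at
ingression and splits into two ridges at abscission, a midbody tubulin
ellipse — and applies the camera model last: Poisson on the clean signal,
additive Gaussian read noise, constant offset, clipped at zero. All
randomness flows from one seed through fixed per-purpose sub-streams, so
identical parameters give bit-identical movies. Channel SNR is defined as
peak signal over read-noise SD. Default conditions are a HeLa-style
recording (0.2 µm/px, 5 min/frame, 60 frames, anaphase at 20 min, actin
clearance 60 min after onset, midbody lifetime 130 min); yeast-style
membrane recordings use 2-min frames and 0.1 µm/px. `generate_midbody_stack()`
renders the midbody with physical thickness — in focus across the five
central slices with mild extra blur per slice, defocusing steeply beyond —
because a micrometre-scale structure genuinely spans five 0.3-µm slices;
that is the geometry a five-slice projection is designed for, and it is
what makes background subtraction on the projection unbiased.

The generator emulates geometry, event timing and camera noise. It does
not emulate photobleaching, cell crowding, drift, autofluorescence,
3-D point-spread functions, or the biology of checkpoint signalling
itself. Passing closed-loop tests therefore shows that the measurements
recover what they are defined to measure under realistic noise — not that
they are robust to every artefact of real microscopy; on real data the
thresholds and annotation inputs (neck axes, seed ROIs) remain the
analyst's responsibility.

## Problem sizes and tolerance-driven choices in the test suite

The oracle-equivalence checks run 100 random ROIs at |Δ| < 1e−9; the
closed-loop recovery checks use 50 seeded movies per assay at channel SNR
5 (and a handful of zero-noise movies where recovery must be exact);
midbody recovery uses 100 renders at SNR 10 on both channels. Synthetic
cohort comparisons use n = 100 cells per arm. Where a check asserts
median recovery within 2 minutes, the arm distributions are chosen so
that four standard errors of the sample median fit inside that window
(e.g. SD 4 min for midbody-lifetime arms at n = 100); this is a property
of the estimator, fixed a priori, not a quantity fitted to outcomes.
Cluster-clearance ordering arms use a control clearance median of 45 min
after anaphase (83% cleared by 60 min) against a bridge arm whose
clusters never clear within the 800-min horizon.

## Known limitations

- Nucleus tracking is per-frame; identities are not linked across frames,
  so the two-nuclei rule, not tracking, gates the trace.
- Automatic bud-neck detection is out of scope: axes come from annotation
  or ground truth.
- The clearance rule is an automated surrogate for visual scoring; its
  parameters (`tau_rel`, `tau_abs`, `k_frames`) are exposed and should be
  fixed per study before scoring.
- TIFF output stores 32-bit floats scaled to [0, 1] with a JSON sidecar
  for calibration and channel roles; round trips are exact only to
  float32 precision.
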