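# nocutr

Quantification toolkit for fluorescence time-lapse studies of cytokinesis and
the NoCut/abscission checkpoint — the surveillance pathway that delays the
final membrane cut (abscission) while chromatin persists in the division
plane. It is written for cell biologists who score division events from
multi-channel movies (histone/chromatin, actin, membrane, tubulin, focus
markers) and need those scores to be reproducible, parameterised and
testable rather than visual.

## What it computes

**Actin-cluster index.** Within a midzone region of interest — the rectangle
between the two nucleus centroids with height half the internuclear distance
and width twice the mean nuclear major axis — let *P* be the actin-positive
pixels and *T* the top 5% brightest of them. The index is the product of

- *brightness enrichment* E = (Int_top5% − Int_all) / Int_all, and
- *clustering* C = d̄(P → COM) / d̄(T → COM),

where COM is the intensity-weighted center of mass of *T* and d̄ denotes the
mean Euclidean pixel distance. Bright, compact actin accumulations give a
high E·C; diffuse or dim signal gives ~0. A per-frame trace of the index,
with an automated threshold rule, yields the actin clearance time from
anaphase onset.

**Membrane abscission classifier.** Intensity profiles of the membrane
channel along the mother–daughter axis through the bud neck are classified
per frame as SINGLE (one prominent peak: membranes unresolved), DOUBLE (two
peaks separated by ≥ 0.4 µm: membranes separated) or AMBIGUOUS; the
abscission time is the first sustained DOUBLE after membrane ingression
(itself detected as a sustained halving of the profile's FWHM).

**Segmentation and event rules.** Otsu or fixed thresholding, 8-connected
labelling with border exclusion, chromatin-bridge status (CONNECTED /
FRAGMENTED / RESOLVED — fragmented bridges count as *unresolved*, since
stretched DNA can fall below the detection limit), bridge resolution timing,
anaphase onset from rapid nuclear elongation, and RPA-like focus calls
against the nucleoplasmic background (median + k·MAD).

**Midbody quantification.** Best-focused slice by tubulin variance, maximum
projection of the five surrounding Z-slices, a moments-matched "tight"
ellipse on the segmented tubulin signal, and total intensity = ellipse area
× mean intensity of the channel of interest.

**Timing statistics and qPCR.** Midbody lifetimes with censoring, cumulative
completion fractions whose denominators keep censored cells, Mann–Whitney
and Fisher exact tests, Tukey box summaries, binucleation frequency tables,
relative expression RE = 2^−ΔCt normalised to a control, and primer
efficiency 10^(−1/slope) − 1 from dilution standard curves.

**Synthetic movies with ground truth.** A seeded generator renders dividing
cells (separating nuclei, chromatin bridges with tunable persistence and
fragmentation, furrow-then-cluster actin, a neck ridge that splits in two at
abscission, a midbody ellipse) under a Poisson + Gaussian camera model, with
every event time known — so every measurement above can be verified in a
closed loop.

## Worked example

```r
library(nocutr)

sp  <- scene_params(read_noise_sd = 0, poisson_noise = FALSE, background_offset = 0)
sim <- generate_division_movie(sp)
sim$movie
#> <division_movie> 96 x 128 px, 4 channel(s) [histone, actin, membrane, tubulin], 60 frame(s)
#>   calibration: 0.2 um/px, 5 min/frame

sets <- lapply(seq_len(n_frames(sim$movie)), function(f) {
  mask <- threshold_positive(movie_channel(sim$movie, "histone", f), "fixed", value = 100)
  label_nuclei(mask, frame = f)
})
kept <- select_two_nuclei_frames(sets)
tr   <- actin_trace(sim$movie, kept, t_anaphase_min = 20,
                    threshold_method = "fixed", threshold_value = 30)
head(dplyr::select(tibble::as_tibble(tr), frame, n_positive, enrichment, clustering, index), 4)
#> # A tibble: 4 x 5
#>   frame n_positive enrichment clustering index
#> 1     7        224      0.617       7.29  4.50
#> 2     8         91      0.895       3.82  3.42
#> 3     9         91      0.895       3.82  3.42
#> 4    10         91      0.895       3.82  3.42

score_clearance(tr, tau_abs = 0.3)
#> 60
```

The trace is elevated while the furrow (frame 7) and the actin clusters
(frames 8–16) occupy the midzone, and the clearance time, 60 min after
anaphase onset, matches the generator's ground truth (`t_clear_min = 80`
minus `t_anaphase_min = 20`) exactly at zero noise. `autoplot(tr)` draws the
trace; `glance(tr)` summarises it (54 scored frames, peak index 4.50).

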