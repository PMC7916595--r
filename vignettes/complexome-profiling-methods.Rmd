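---
title: "Methods: SILAC complexome profiling with comprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SILAC complexome profiling with comprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comprof)
```

## The measurement and its model

Complexome profiling reads the assembly state of membrane protein
complexes from a single native gel lane: intact complexes are separated
by blue-native PAGE, the lane is cut into slices (64 here), each slice is
digested and measured by mass spectrometry, and a protein's per-slice
intensity vector — its *migration profile* — reveals which complexes and
subcomplexes it resides in.  With SILAC labelling, two conditions are
mixed 1:1 before electrophoresis; every peptide appears as a light and a
heavy variant measured in the same run, so the heavy/light intensity
ratio compares the two conditions slice by slice with high precision,
and a label swap between the duplicate experiments cancels any
label-specific bias.

`comprof` implements this analysis in five stages — channel separation,
representative-peptide quantification, profile normalisation,
calibration, and comparative analysis — plus a generative model of the
experiment used throughout the tests.

## Quantification choices

**Representative peptide.**  Each protein is quantified by a single
peptide, required to have been observed in both SILAC channels so that
the same molecular species underlies both conditions' profiles.
"Most frequent" is counted in distinct (experiment, replicate, slice,
channel) cells rather than spectrum counts: cells are what the profile
is built from, and the count is invariant to repeated measurements of
one slice.  Ties break deterministically (summed intensity, then
sequence order).  When no peptide is seen in both channels the most
frequent single-channel peptide is used and flagged — the profile is
still informative, the ratio is not silently trusted.

**Normalisation.**  Replicate profiles are averaged *raw* and the mean
profile is max-normalised once.  The alternative — normalising each
replicate first — would up-weight the noisier, lower-intensity replicate;
averaging first keeps the weighting proportional to measured signal and
matches the convention that heatmap value 1 marks the slice with the
highest averaged intensity.  No between-replicate loading normalisation
is applied by default: within a lane, the 1:1 SILAC mix already controls
composition.

**Ratios.**  Condition ratios use the representative peptide's summed
intensities per replicate and combine replicates by geometric mean:
ratios are scale quantities, and the geometric mean of a label-swapped
pair cancels multiplicative label bias exactly.  A protein with signal
in only one condition is reported as `absent-in-perturbed` (or
`-reference`) instead of an infinite ratio, and complex-level summaries
use the *median* over subunit ratios with absent subunits counted
separately — a single infinity or an atypical module (see the N-module
below) would dominate a mean.

## The synthetic experiment

The generator represents the sample as a list of *assembly forms*:
native species with an apparent mass, a member set with stoichiometry,
and an abundance per condition.  The default scenario encodes a HEK293
COX4 knock-out phenotype against wild type:

* assembled complex IV (monomer 215 kDa, dimer 430 kDa, III₂IV 730 kDa,
  respirasome 1700 kDa) present only in wild type; the knock-out retains
  a 130 kDa MT-CO1/COA3/HIGD2A intermediate and a free low-mass
  COX5B/NDUFA4/HIGD1A/HIGD2A pool;
* complex I fivefold depleted overall (wild type 60+25+15 across
  respirasome, I III₂ and monomer vs knock-out 12+8 across I III₂ and a
  750 kDa precomplex), with the four N-module subunits excluded from the
  precomplex member set, so they deplete more than fivefold;
* complex III shifted from supercomplexes to its free 500 kDa dimer,
  total content only mildly reduced; complex II (125 kDa) identical in
  both conditions; complex V mildly reduced with F₁-subassembly
  accumulation;
* mitoribosomal large (1650 kDa) and small (850 kDa) subunits at
  knock-out = wild-type/1.75, and DDX28/ERAL1 halved.

Masses of the diagnostic species (130 and 750 kDa) and the holoenzyme
masses follow standard native-gel assignments; abundances are generator
defaults chosen to give realistic relative band intensities.  Values the
phenotype does not pin down — mitoribosome wild-type abundance 35,
DDX28/ERAL1 at 10 with masses 55/48 kDa, 3–8 peptides per protein — were
fixed once at field-plausible levels.

**Migration model.**  log10(mass) maps linearly onto slice index
(slice 1 = gel top = 3162 kDa, slice 64 = 31.6 kDa), and each form
deposits a Gaussian band in *slice* coordinates (σ = 1 slice, truncated
at ±4σ, renormalised to sum to one so total signal is conserved
exactly).  Gaussian-in-slice rather than Gaussian-in-mass is a
deliberate simplification that matches the smeared appearance of native
bands and keeps the closed-form oracle trivial.

**Noise.**  Three multiplicative lognormal components: a per-peptide
response factor (σ = 0.3) fixed across replicates and channels, so it
cancels from every ratio; per-observation measurement noise (σ = 0.2);
and censoring — observations below the detection floor (0.01, set so
roughly 10% of nonzero signals drop) are *absent rows*, not zeros.
Measurement noise is split into a component common to the co-measured
heavy/light pair of a peptide in a slice and a channel-specific residual
(`channel_cor = 0.9`, i.e. 90% of the variance is shared).  This mirrors
the physics of SILAC: both isotopologues are quantified from the same
spectra, so per-slice handling and ionisation fluctuations hit both
channels together and within-run ratios are far more precise than the
raw intensities.  With fully independent noise the ratio CV would be
~10% and "unchanged" proteins would routinely leave a ±10% band — a
behaviour SILAC experiments do not show.

**What the generator does not emulate:** spectrum-level identification,
charge states and isotope envelopes, retention time, ratio compression,
shared peptides between paralogues, and slice-to-slice carry-over.
Passing the recovery tests therefore demonstrates that the analysis
logic is correct under the stated statistical model, not that every
real-data pathology is handled.

## Calibration and peak calling

Calibration fits log10(mass) on slice by least squares; with two markers
it interpolates exactly, and the RMS residual (in log10 units) is
reported so an inadequate log-linear model is visible rather than
silently absorbed.  The default, self-contained marker set is the two
gel endpoints implied by the gel's stated mass range plus the detected
wild-type peaks of the complex III dimer (500 kDa, via UQCRC2) and the
complex V monomer (700 kDa, via ATP5MC1); marker peaks are located as
the detected peak nearest the endpoint-implied position (within 3
slices), which avoids the circularity of needing a calibration to find
the calibrants.

Peaks are called on the normalised profile after 3-point moving-average
smoothing: strict local maxima at or above `min_rel_height = 0.2`, with
boundary maxima allowed and sub-slice positions refined by parabolic
interpolation.  The threshold and the peak-matching tolerance
(`match_tol = 1.5` slices) are set so that, at the default noise level,
band ripples are not called as species and genuinely distinct forms
(e.g. 730 vs 500 kDa, 5 slices apart) never merge; both are exposed in
the configuration.  Matching between conditions is greedy
nearest-slice: with at most a handful of peaks per protein, greedy and
optimal matching coincide except in pathological ties, and greedy is
order-stable.

Degenerate inputs are handled explicitly: all-zero profiles yield an
`undetected` flag and no peaks; constant profiles have no defined
co-migration correlation and are flagged `not-a-score`; co-migration
requires at least 5 informative slices (`insufficient-support`
otherwise); slices outside the calibrated range extrapolate with a
warning.

## Problem sizes and determinism

The default scenario has 144 proteins, 18 forms, two label-swapped
replicates and ~34,000 evidence rows; one simulate-and-quantify cycle
takes about a second.  Stochastic recovery checks use 20 seeds for
ratio-level claims and 5 fully analysed runs for peak-mass claims —
enough to see the seed-to-seed spread (a few percent) without inflating
runtimes.  All randomness flows through a single integer seed; the
generator draws noise indexed by condition rather than channel, which is
why swapping the heavy label provably relabels channels without changing
condition-level data, and why identical configuration and seed give
byte-identical output files.

## Known limitations

* One profile per (protein, condition): the two channels of the same
  condition in different replicates are averaged, not reported
  separately.
* Shared peptides are assigned to every mapped protein and flagged, not
  apportioned.
* The log-linear calibration ignores gel-edge compression; the residual
  diagnostic will flag this on real gradient gels, but no spline
  alternative is provided.
* Complex-level fold changes assume subunit ratios are exchangeable
  within a complex; genuinely module-resolved changes (as for the
  N-module) appear only through the per-protein table and peak calls.
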