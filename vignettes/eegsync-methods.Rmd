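---
title: "Methods: band power, ciPLV connectivity, and group inference in eegsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, ciPLV connectivity, and group inference in eegsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsync)
```

## The analysis problem

Resting-state EEG group studies ask two questions of a pair of cohorts:
does oscillatory *power* differ between the groups, electrode by electrode
and band by band; and does *phase synchrony* between electrode pairs differ,
after discounting the synchrony that volume conduction creates for free.
eegsync implements that sensor-space chain: common-average re-referencing,
zero-phase 2--46 Hz band-pass filtering, 1-s epoching with z-score artifact
rejection, Welch relative band power, per-band connectivity via the
corrected imaginary phase-locking value (ciPLV), and nonparametric group
statistics (cluster-based permutation correction for electrode maps,
edge-wise permutation tests with Benjamini--Hochberg FDR for connectivity).

## Phase-locking metrics and volume conduction

For two channels with instantaneous phases $\phi_a(t)$, $\phi_b(t)$, let

$$C = \frac{1}{N}\sum_{n=1}^{N} e^{\,i(\phi_a(t_n)-\phi_b(t_n))}.$$

The classical phase-locking value is $\mathrm{PLV} = |C|$, the imaginary
PLV is $\mathrm{iPLV} = |\mathrm{Im}\,C|$, and the corrected imaginary PLV
is

$$\mathrm{ciPLV} = \frac{|\mathrm{Im}\,C|}{\sqrt{1-(\mathrm{Re}\,C)^2}}.$$

Volume conduction -- the instantaneous spread of one cortical source's
field to many electrodes -- produces phase differences locked at exactly
zero (or $\pi$ for opposite-sign mixing weights), inflating
$\mathrm{Re}\,C$ but contributing nothing to $\mathrm{Im}\,C$.  iPLV
discards that zero-lag component but is *biased downward* when a genuine
lagged interaction coexists with a strong zero-lag one; the ciPLV
denominator removes that bias.  When $1-(\mathrm{Re}\,C)^2 < \varepsilon$
(default $\varepsilon = 10^{-12}$) the pair is perfectly zero-lag locked
and ciPLV is defined as 0: perfect zero-lag locking carries no lagged
synchrony.  All three metrics depend on phases only, so rescaling any
channel's amplitude changes nothing (verified to $10^{-9}$ in the tests).

Phases come from the analytic signal of the band-filtered trace.  Filtering
and the Hilbert transform are applied to the *continuous* record before
epoching: 1-s epochs are far too short to band-filter cleanly at theta.
Epoch boundaries and the artifact-rejection mask are then inherited from
the broadband preprocessing, the per-epoch metric is computed, and epochs
are averaged.  Epoch-wise averaging of $|\cdot|$-statistics has a positive
chance floor (for narrowband theta in 1-s epochs, roughly 0.2--0.3) that
decreases with epoch length but not with epoch count; group *contrasts*
are unaffected because both groups share the floor.  The whole-record
estimate is available by skipping segmentation.

## Filtering

All filters are linear-phase Hamming-window FIR designs applied by FFT
convolution with exact group-delay compensation, giving zero phase in the
passband (phase metrics must not inherit filter phase), passband ripple
below 1%, and stopband attenuation beyond 50 dB one transition width
(default 1 Hz) outside the band.  Every band filter shares one tap count
($\lceil 3.3 f_s \rceil$ at a 1-Hz transition), so the pipeline computes
one padded forward FFT per subject and derives the broadband filter and
every band's analytic signal from it; this fast path is asserted equal to
the step-by-step public-API chain in the test suite.  Filter edges (half a
filter length at each end) are computed against zero padding; analyses in
the tests exclude them where they matter.

## Spectral analysis

Welch's method averages modified periodograms of 2-s, 50%-overlap,
Hamming-tapered segments cut from the concatenated retained epochs (the
concatenation discontinuities are mild after artifact rejection and bias
all bands alike).  The normalization satisfies Parseval's theorem: the PSD
integrates to the signal variance within windowing bias (checked to 5% on
white noise).  Relative band power divides each band's summed PSD by the
total over the analysis range, with *no* removal of the aperiodic (1/f)
component -- the 1/f background is part of the quantity by definition here.

The five canonical bands are usually printed with integer limits (delta
2--3, theta 4--8, alpha 9--13, beta 14--30, gamma 31--45 Hz), which leaves
1-Hz gaps.  The default scheme is the contiguous half-open partition
$[2,4), [4,9), [9,14), [14,31), [31,46)$, so relative powers sum to one;
`band_scheme("printed")` keeps the integer limits for strict replication
of tabulated conventions.

## Group statistics

*Electrode maps* (relative power per electrode) are compared with a
cluster-based permutation test: pooled two-sample t per electrode,
two-sided thresholding at $\alpha = 0.05$, clusters formed from
same-signed supra-threshold electrodes that are neighbours in the montage
adjacency graph, cluster mass $\sum |t|$, and a max-statistic permutation
null, $p = (1 + \#\{\max\text{-mass}_{perm} \ge \text{mass}\})/(1 + B)$.
The cluster-forming threshold and the mass statistic are conventional
choices and configurable.  The adjacency graph connects electrodes closer
than a chord distance of 0.5 on the unit sphere, which gives a median
degree of 8 on the packaged 64-channel montage (a typical EEG
neighbourhood count) and a connected graph.

*Connectivity edges* are compared edge-by-edge with the same permutation t
machinery under one *shared* relabeling schedule (identical permutations
across edges, as simultaneous inference requires), followed by
Benjamini--Hochberg FDR across the 2016 edges within each band.  When the
number of distinct relabelings is no larger than the requested permutation
count the tests enumerate exhaustively and the p-value is exact; otherwise
Monte-Carlo relabelings with the $+1$ numerator/denominator convention
keep p strictly positive.  The default permutation count is 50,000; the
validation suites use 999, which changes only the resolution of the
p-values, not their calibration (the null rejection rate and familywise
error checks below use 999).

One resolution subtlety matters for the edge-wise test: with $B$
permutations the smallest attainable p-value is $1/(B+1)$, and BH across
$m = 2016$ edges can reject at $q = 0.05$ only if at least
$m/(q\,(B+1)) \approx 41$ edges (at $B = 999$) reach that floor.  The
max-statistic cluster test has no such constraint.  The pipeline therefore
accepts a separate `n_perm_edges` (the validation experiments use 4,999,
bringing the requirement down to about 8 floor edges); at the 50,000
default the issue vanishes.

Supporting statistics follow the field's standard definitions: pooled-SD
Cohen's d, Spearman rank correlation, Kendall's tau-b with tie correction,
and 1.5-IQR outlier fences with interpolated quartiles.

## The synthetic study generator

The study's recordings are not public, so the generator manufactures a
two-group study in which every downstream stage has a known target:

* **Conditions.** Two groups of 28 and 27 subjects, 64 channels on an
  idealized 10-10 unit-sphere montage, 256 Hz, 300 s per subject (the
  validation experiments use 60 s to keep a full Monte-Carlo affordable on
  one CPU; effect calibration was done at the same scale).
* **Sources.** Narrowband oscillators (Gaussian noise band-filtered to
  centre frequency $\pm 1$ Hz): bilateral occipital alpha (10 Hz) common
  to both groups, centroparietal theta (6 Hz) anchored at CPz/Pz,
  frontotemporal theta at FT7/FT8, right frontoparietal beta (20 Hz) at
  F4/P4.
* **Planted effects.** The first group gets (i) a theta power multiplier
  (default 2.2) on the centroparietal sources, (ii) an FT7--FT8 theta
  coupling at lag $\pi/2$, strength 0.7, (iii) an F4--P4 beta coupling at
  the same lag and strength.  Couplings replace the target's phase with
  $\phi_i(t) + \text{lag} + (1-\text{strength})\,W(t)$, where $W$ is a
  random walk (0.2 rad per sample), so synchrony rises monotonically from
  chance at strength 0 to a hard lock at strength 1.
* **Mixing.** Sensor signals are $M S + \text{noise}$ with Gaussian
  leakage weights $M_{ek} = \exp(-d_{ek}^2 / 2\sigma^2)$ (chord distance,
  $\sigma = 0.35$).  Mixing is strictly same-sample: it can create
  zero-lag correlations of any strength but never lagged ones, which is
  exactly the confound ciPLV must reject and PLV must fall for.
* **Noise and variability.** Independent per-channel $1/f$ noise; the
  noise amplitude is a deterministic function of the configuration
  (matched to the *baseline* expected source variance at SNR 1 in the
  2--46 Hz band).  Matching it to each subject's realized signals instead
  would let planted local effects modulate the global noise floor and leak
  into every channel's relative power -- a group confound, not noise.
  Between-subject variability is a log-normal amplitude factor per source
  (SD 0.4), which sets realistic effect sizes: with the default
  multiplier, the theta relative-power Cohen's d at Pz is about 1.0--1.1
  at n = 28/27, in the range a well-powered clinical EEG study reports.

**What the generator does not emulate.** Realistic leadfields (signed
dipole topographies), ocular/muscle artifacts, bad channels, line noise,
non-stationarity across the session, and electrode-position error.  One
consequence deserves emphasis: because the mixing weights are all
positive, common-average re-referencing redistributes a fraction of the
boosted centroparietal theta into *every* channel, so the planted "local"
power effect acquires a global component (d about 0.6 at Fp1 versus 1.05
at Pz).  That spread is a genuine property of average-referenced data, not
a bug, but it means power clusters are broader than the source layout.
Passing recovery tests therefore demonstrates that the chain detects
planted effects through zero-lag mixing and realistic subject variability;
it does not certify performance on artifact-laden clinical recordings.

## Recovery scoring

`summarize_recovery()` counts a planted power effect as detected when a
significant cluster (p < 0.05) of the correct direction contains a planted
electrode, and a planted edge as detected when a significant FDR-corrected
edge of the correct direction connects the adjacency neighbourhoods of its
two anchors -- spatial leakage makes electrode-exact localization too
strict a criterion.  Edges inside those neighbourhood pairs are excluded
from the false-positive-rate denominator; everything else that reaches
significance counts against the pipeline.  Note that under leakage plus
average referencing some "false" edges carry genuinely lagged signal
(remixed copies of the planted coupling), so the measured edge FPR is an
honest upper bound on estimator false positives.

## Numerical choices and degenerate inputs

* ciPLV guard $\varepsilon = 10^{-12}$ on $1-(\mathrm{Re}\,C)^2$;
  perfectly zero-lag pairs return 0, not NaN.
* Permutation p-values: exhaustive enumeration when feasible (p exactly
  $\#\{|t_{perm}| \ge |t_{obs}|\}/B$), otherwise the $+1$ convention; a
  degenerate sample with all values identical returns p = 1; zero-variance
  relabelings give t = 0 when means agree and $\pm\infty$ otherwise.
* Epoch rejection uses three metrics (variance, amplitude range, deviation
  of epoch channel means from channel grand means), each averaged over
  channels, two-sided at |z| > 2; an epoch fails if *any* metric does.
  Constant metrics produce no evidence (z set to 0), and rejecting all
  epochs is a hard error.
* The EDF writer uses the symmetric digital range $-32767..32767$ so that
  digital 0 is exactly physical 0 on round trip.
* Quartiles use R's default type-7 linear interpolation.

## Problem sizes used in validation

The test suite and the acceptance script validate calibration with 500
null datasets for the scalar permutation test and 200 null map datasets
for the cluster test (999 permutations each), and recovery with 20 (suite)
or 10 (script) independent simulated studies of 55 subjects at 60 s per
subject, analysed in the theta band.  These sizes give binomial standard
errors of about 1% on the null rejection rate and 9--13% on detection
rates, which is adequate to distinguish "works as designed" from "broken"
without overnight runs.

## Known limitations

Sensor-space inference: nothing here localizes sources, and ciPLV, while
robust to zero-lag leakage, still reflects remixed lagged signal (see the
recovery scoring note).  Directed metrics, source modelling, and graph
statistics beyond node strength are out of scope.  EDF support covers the
original 16-bit continuous variant only.
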