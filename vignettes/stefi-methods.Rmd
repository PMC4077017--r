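---
title: "Data-driven IC selection for single-trial EEG-informed fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven IC selection for single-trial EEG-informed fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Simultaneous EEG/fMRI recordings of a Go/Nogo response-inhibition task carry
two complementary signals: millisecond-resolved electrophysiology and
hemodynamic maps. Trial-to-trial variability of the inhibition-related EEG
response can be used as a regressor in the fMRI general linear model (GLM),
revealing which voxels co-fluctuate with the strength of single-trial neural
inhibition. The classical approach extracts single-trial amplitudes from
fixed group-level ERP windows (Nogo-N2 at 280--340 ms, Nogo-P3 at 350--570 ms,
at Cz). `stefi` implements instead a fully data-driven alternative: for each
participant and run, independent components (ICs) of the continuous EEG are
classified by a pointwise reliability statistic, and only components with
reliably larger Nogo amplitude inside participant-specific latency windows
contribute to the regressor.

# The selection model

## Epochs and condition statistics

IC activation time courses (rows of $W\,x(t)$ for the per-run unmixing matrix
$W$) are cut into 1200 ms epochs starting 200 ms before each stimulus, at the
100 Hz working rate (120 samples). The 200 ms pre-stimulus mean is subtracted
per trial and component. Trials are partitioned into correct Go, correct
Nogo, omissions and commissions; pointwise means and unbiased variances are
accumulated per condition.

## The reliability statistic

For the Nogo-related path the package computes, at every component and time
point, the unpooled (Welch) two-sample statistic

$$ t = \frac{\bar{x}_{\mathrm{Nogo}} - \bar{x}_{\mathrm{Go}}}
          {\sqrt{s^2_{\mathrm{Nogo}}/n_{\mathrm{Nogo}} +
                 s^2_{\mathrm{Go}}/n_{\mathrm{Go}}}} , $$

and standardizes it to a per-trial signal-to-noise scale,

$$ Z = t / \sqrt{n_{\mathrm{ref}}}, \qquad
   n_{\mathrm{ref}} = \min(n_{\mathrm{Nogo}}, n_{\mathrm{Go}}), $$

recording the degrees of freedom conservatively as $n_{\mathrm{ref}} - 1$.
This standardization is calibrated against the published anchor of the
method: with 300 trials per run of which 90 are Nogo, the selection threshold
$|Z| > 0.275$ corresponds to $t = 0.275\sqrt{90} \approx 2.61$, a two-sided
$p$ of $0.01$ at $df = 89$. The exact $t \to Z$ map is not uniquely
determined by that anchor (a pooled-variance effect size would behave
similarly); we adopt $t/\sqrt{n_{\mathrm{ref}}}$ because it reproduces the
anchor exactly and reads naturally as a per-trial SNR. The visual-component
path pools correct Go and Nogo epochs and uses the one-sample statistic
against the baseline-corrected zero level.

Degenerate points are handled explicitly: zero variance with zero mean
difference gives $Z = 0$; zero variance with a nonzero difference gives
$\pm\infty$ and the series is flagged.

## Latency ranges, polarity, dominance

Maximal contiguous runs of $|Z|$ above threshold become half-open latency
ranges $[t_{\mathrm{on}}, t_{\mathrm{off}})$: the range opens at the first
above-threshold sample and closes at the first below-threshold sample.
Crossings are evaluated on the 100 Hz grid without sub-sample interpolation.
Because IC polarity is arbitrary, each range receives a direction: the
condition average with the larger absolute mean over the range is the
dominant condition, and the polarity is its sign. Ranges dominated by the Go
average are discarded — only components with larger absolute Nogo amplitude
are accepted. There is no minimum range duration beyond one sample; the
containment rule below is the only duration constraint.

## Window containment

Analysis windows are anchored on each participant's median correct-Go
response time (RT): *early* spans 200 ms post-stimulus to the median RT,
*late* spans RT $-$ 100 ms to RT $+$ 300 ms, and the *visual* window is fixed
at 90--140 ms. A latency range is selected for a window only when it rises
above threshold at or after the window start **and** falls below threshold at
or before the window end. The early and late windows deliberately overlap; a
range wholly inside the overlap is tagged with both windows (whether the
original procedure fed such ranges to both regressors is not documented; a
single-window assignment can be obtained by filtering the selection table).
Participants with no selected range for a window are excluded from that
window's group analysis, and the exclusion is reported, never silent.

## Single-trial amplitudes

For every selected (IC, range) pair and **every** trial — Go, Nogo and errors
alike, since the regressor must cover the whole run — the mean IC amplitude
over the range is taken and multiplied by the polarity, so reliable Nogo
activity is positive-going. Amplitude vectors of all ranges selected for the
same window and run are summed into one vector per window. The fixed-window
ERP path (N2/P3 at Cz on artifact-corrected, TP9/TP10-re-referenced channel
data) keeps raw signs; whether to invert the negative-going N2 is exposed as
an option and off by default, since signed regressors admit both positive
and negative BOLD correlations.

# From amplitudes to fMRI regressors

The per-trial amplitude series (1 Hz at the default paradigm) is carried to
the scan grid (1/2.25 Hz) in a fixed order: cubic-smoothing-spline
resampling at volume acquisition times, normalization to median 0 and
inter-quartile range 1, convolution with the canonical double-gamma HRF
(main lobe peaking near 5 s, undershoot at 16 s with 1:6 ratio, 32 s support,
zero at lag 0, sampled 16$\times$ oversampled and decimated), and
orthogonalization of the task regressors against the Go/Nogo/Errors onset
regressors (the visual regressor is not orthogonalized). Orthogonalization
is an exact least-squares residual including an intercept; by the
Frisch--Waugh property the onset-regressor betas in the subsequent GLM are
identical to a model without the EEG regressor, which the test suite asserts
numerically.

**Spline smoothing.** The smoothing parameter defaults to the
near-interpolating limit ($\lambda = 10^{-8}$), not to generalized
cross-validation. The choice is forced by the statistic being modeled: a
per-trial amplitude sequence is serially almost uncorrelated, so GCV
correctly concludes that the smooth trend is nearly constant and smooths the
series flat — destroying precisely the trial-to-trial variability the
regressor exists to carry (in simulation the GCV-smoothed regressor retains
about 4% of the planted amplitude variance). The spline's role here is
resampling between mismatched clocks, and the interpolating limit preserves
the signal; GCV remains available through `lambda = NULL`. Evaluation
outside the covered trial span is clamped to boundary values, and
median-centering inside the IQR step stabilizes convolution edge effects.

# First-level and group analysis

The first-level design contains the onset regressors, one EEG regressor, a
discrete-cosine high-pass set spanning periods above 128 s (equivalent to
filtering both data and model while keeping OLS exact; for 152 volumes at
TR = 2.25 s that is 5 cosines), and an intercept. Per-voxel OLS gives beta,
t and Z images for the EEG contrast; the two run-level contrast images of a
participant are voxel-averaged into one subject image. Group maps are
one-sample or paired t maps (the paired map is computed, exactly, as the
one-sample map of difference images). Cluster-extent thresholding converts
the map at an uncorrected voxelwise $p$ (one-sided $p = 0.005$ for
directional contrasts) into 26-connected clusters and removes clusters below
$k = 20$ voxels. No random-field or FWE correction is applied at this stage.

# EEG preprocessing

* **Gradient artifact**: sliding template subtraction. Each inter-scan-trigger
  epoch has the mean of the surrounding 21 volume epochs (centered window
  including itself, truncated at run edges) subtracted. The window width
  trades drift tracking against template noise; note the intrinsic floor —
  subtracting a 21-epoch template of signal-free data distorts by
  $1/\sqrt{21} \approx 22\%$ RMS, which is why the method is applied before,
  not after, artifact-free segments exist. Trigger spacing must be constant
  to within one sample.
* **Bandpass and rate**: zero-phase Butterworth filtering, 0.2--48 Hz, then
  decimation to 100 Hz. The low-pass leg (order 4) runs at the input rate as
  the anti-alias filter; the high-pass leg (order 2) runs at the output rate
  where its normalized corner frequency is well conditioned.
* **ICA**: a square unmixing matrix per participant and run by extended
  infomax (sub- and super-Gaussian sources, kurtosis-sign switching) after
  PCA sphering. Training is a deterministic full-batch natural-gradient
  iteration on an evenly spaced subsample (default cap
  $\max(25000, 50\,n_{\mathrm{ch}}^2)$ samples — continuous EEG is heavily
  oversampled relative to the number of mixing parameters). At the contrast's
  fixed point the batch gradient vanishes exactly, so convergence is declared
  on the relative weight change per iteration; a stochastic mini-batch
  variant was rejected because its weight-change floor scales with the
  learning rate, making any fixed tolerance arbitrary. Stability guards: a
  dead zone ($|\kappa| < 0.05$) keeps near-Gaussian components from flapping
  between sub- and super-Gaussian classes; if the gradient norm grows to
  three times its running minimum (a slowly amplifying mode under a too-large
  step) the iteration restarts from the best iterate at half the step; when
  the gradient stalls in a limit cycle the step is annealed. Near-singular
  covariance eigenvalues are floored with a warning. Non-convergence is an
  error carrying diagnostics, never a silent result.
* **Artifact ICs**: heartbeats (and blinks) are detected on the ECG (EOG)
  channel by template matching — provisional robust peaks, an averaged
  waveform template, then normalized cross-correlation maxima above
  $0.6 \times$ the global maximum with refractory periods of 0.4 s
  (heartbeat) and 0.25 s (blink). An IC is flagged as artifactual when the
  RMS of its event-locked average exceeds the 99th percentile of the same
  statistic over circularly shifted surrogate event sets (at least 50,
  default 200), a nominal 1% false-flag rate per IC. The published
  description of "ICs loading on the average" is qualitative; the surrogate
  test is this package's operationalization. Flagged ICs are excluded from
  every candidate list downstream; channel-space back-projection without
  them is produced only for the ERP comparison path.

# The synthetic-data generator

Because no public dataset accompanies the method, the package ships a
generator whose defaults are the study conditions: two runs of 300 stimuli
at a 1 s SOA (500 ms letter + 500 ms blank), Nogo probability 29% under the
constraint that every Nogo is followed by at least one Go (realized by a
two-state Markov chain with $P(\mathrm{Nogo}\mid\mathrm{Go}) = p/(1-p)$,
whose stationary Nogo fraction is exactly $p$; feasible only for
$p \le 0.5$), log-normal correct-Go RTs with median 0.4 s (inside the
published 323--488 ms range of individual medians), commission/omission
rates of 15%/2%, 64 EEG channels (62 scalp named after the 10--20 system
plus EOG and ECG) at 100 Hz, and BOLD runs of 157 volumes at TR = 2.25 s.

Planted structure: an inhibition source (smooth Hann bump confined to
0.25--0.35 s, full log-normal amplitude on Nogo trials, a 0.2 leak fraction
on Go trials so that Nogo-dominance is informative rather than trivial), a
visual source in 90--140 ms on every stimulus, a quasi-periodic
ballistocardiogram (1.1 s $\pm$ 0.05 s inter-beat interval) with matching
QRS deflections on the ECG channel, blinks with matching EOG deflections,
and an optional gradient artifact — a fixed high-amplitude pattern repeated
exactly every TR at scan triggers. Topographies are random smooth unit-norm
vectors, deliberately not dipole-forward solutions. BOLD signal in a
compact 30-voxel region is baseline plus HRF-convolved condition responses
plus a coupling gain times the median-centered per-trial amplitude, with
AR(1) noise ($\rho = 0.3$, unit SD) elsewhere and everywhere.

**Default SNR.** Source scale 30 (bump peaks of roughly 8--10 µV on the
strongest channels), channel noise 0.5 µV and log-amplitude SD 0.6 were
fixed once, from a forward power analysis, as the operating point at which
the planted component is recoverable by the full procedure — the regime the
method is designed for. They are deliberately cleaner than raw scalp EEG:
the generator's white channel noise stands for the residual that ICA cannot
concentrate, not for the full structured EEG background, which a linear
mixture of a handful of sources cannot emulate. Consequently, passing
recovery suites demonstrate the correctness of the machinery under the
model's own assumptions — linear stationary mixing, event-locked stereotyped
sources — and not performance on real recordings, where IC splitting,
non-stationarity and residual gradient artifacts make selection harder (in
the original application only about half the participants showed selectable
Nogo-specific ICs).

# Problem sizes in the test suite

The validation suites run the full study-size paradigm (300 trials per run)
but a reduced 8-channel cap for most ICA-bearing tests, with a 12,000-sample
training subsample and a $3\times10^{-4}$ convergence tolerance; one
acceptance check fits the full 64-channel decomposition. Cohort-level GLM
checks use 8 subjects $\times$ 2 runs on a $10^3$ voxel grid with a 30-voxel
coupled region, and null calibrations use $10^4$ independent time points
(pointwise Z) and three 8-subject null cohorts (group GLM). These sizes were
chosen so that each property is measured with meaningful Monte-Carlo
precision while the whole suite stays comfortably repeatable on one CPU.

# Known limitations

* The trigger code scheme for scans vs stimuli is not standardized; the
  readers accept a user-supplied code map (defaults: `S  1`/`S  2` stimuli,
  `R128` scan onsets).
* EDF input is not implemented; BrainVision triplets and the internal cache
  cover the supported acquisition path.
* Scan timestamps are volume onsets; no slice-timing offset is modeled, and
  no spatial preprocessing (realignment, normalization, distortion
  correction) is provided — inputs are assumed spatially preprocessed.
* The repeated-measures ERP contrast utility operates on whatever amplitudes
  are supplied; published real-data effect sizes are not reproducible from
  synthetic cohorts and are not targets of the test suite.
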