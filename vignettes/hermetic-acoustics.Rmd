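---
title: "Acoustic monitoring of insect activity under hermetic grain storage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic monitoring of insect activity under hermetic grain storage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainAcoustics)
```

# The problem

Hermetic storage seals grain so tightly that the respiration of the insects
(and the grain itself) depletes the oxygen in the enclosure, suppressing and
eventually killing pests such as the rice weevil *Sitophilus oryzae*.
Because the insects cannot be seen inside the grain mass, two indirect
monitoring channels are used: residual-oxygen sensors, and acoustic sensors
coupled to the grain through a waveguide. This package implements the full
analysis chain for such experiments: detecting insect sound impulses in
recordings, classifying them against spectral profiles of verified insect
sounds, grouping them into bursts, computing activity statistics, and
relating those statistics to oxygen depletion, grain damage and seed
viability. A synthetic-data module generates ground-truthed recordings and
experiment tables so every stage is testable without access to raw
recordings.

# The acoustic model

Feeding and movement sounds of stored-product insects occur as **trains of
brief impulses**: individual transients 1–10 ms long, separated within a
train by gaps of less than 200 ms. The pipeline operationalizes this as:

1. **Impulse detection.** The segment is high-pass filtered (4th-order
   Butterworth, default cutoff 200 Hz — well below the insect impulse band,
   suppressing room rumble), rectified and smoothed with a 0.5 ms moving
   average. Samples where this envelope exceeds
   `median + thresholdK * MAD` (default `thresholdK = 8`) mark candidate
   events; events closer than a 20 ms dead time merge, and events outside
   0.5–20 ms are discarded (impulses are 1–10 ms; a 2x margin is allowed
   before an event is treated as noise). All constants live in
   `detectionConfig()`. The median/MAD floor makes the threshold robust to
   the sparse, high-amplitude impulses themselves; a small relative floor
   (0.5 % of the envelope peak) keeps the threshold meaningful on
   noise-free signals, where median and MAD collapse to zero.
2. **Spectrum extraction.** Each impulse's one-sided power spectrum is a
   Hann-windowed average over 256-point frames with 50 % overlap covering
   the impulse (padded symmetrically to at least 256 samples), normalized
   to unit total power so that classification is invariant to recording
   gain.
3. **Profile matching.** A *spectral profile* is the bin-wise mean of the
   normalized spectra of verified insect impulses, renormalized to unit
   power. A new impulse is classified by least squares: the sum of squared
   bin differences (SSE) against each profile, argmin wins, and the impulse
   counts as an insect signal iff the minimum SSE is at or below a
   threshold. Two bundled profiles mirror the averaging depths used in
   practice (139 impulses over 62 s; 33 impulses over 20 s); they are
   synthetic, built by the shipped `scripts/build_default_profiles.R` from
   simulated verified impulses, and any number of user profiles (>= 1) is
   supported.
4. **Burst grouping.** Maximal runs of insect-matched impulses with
   consecutive gaps strictly below 0.2 s that contain at least 3 impulses
   are *bursts*. A gap of exactly 200 ms splits: the published criterion is
   "separated by < 200 ms", quoted strictly.
5. **Activity measures.** For a segment of duration $T$ with bursts
   $b_1..b_k$ holding $n_i$ impulses: the burst rate $R_b = k/T$, the mean
   impulses per burst $N_b = \sum n_i / k$, and the burst-impulse rate
   $R_{bimp} = \sum n_i / T$. With no bursts, $R_b = R_{bimp} = 0$ and
   $N_b$ is *missing*, never 0 — zero-burst files must not drag the
   impulses-per-burst regression toward zero.
6. **Infestation threshold.** A sample with $R_b \ge 0.02$ bursts/s is
   flagged as likely infested. The comparison is inclusive because the
   published figure is a *minimum* detectable rate. Activity *cessation*
   (`timeToQuiescence()`) requires the rate to fall below threshold and
   stay below it at all later observations, because day-to-day rates are
   non-monotone (a silent day can be followed by renewed activity).

Analysis operates on a 77–300 s window selected uniformly at random from
each recording (`selectAnalysisWindow()`); recordings shorter than 77 s are
analyzed whole with a warning so small fixtures remain usable. Timestamps
are reported to 0.1 ms.

## Calibration of the match threshold

No numeric match criterion is published for profile matching, so the
default is calibrated on synthetic fixtures
(`scripts/calibrate_sse_threshold.R`): at a signal-to-noise ratio of 10
(impulse peak over noise RMS), the 99th percentile of true insect impulse
SSE against the bundled profiles is about 0.028, while the smallest SSE of
the low-frequency distractor transients is about 0.48. The shipped default
of 0.05 sits above the former with close to a 2x margin and keeps the
distractor false-match rate at 0. Matching on dB spectra
(`scale = "db"`) is available for conventions that weight low-power bins
more heavily, but power-scale SSE — the most direct reading of
"least-squares matching of spectra" — is the default, and the default
threshold applies to the power scale only.

# The hermetic-storage model

## Oxygen budgets and depletion statistics

The air volume of a wheat-filled jar (headspace plus intergranular space)
is 260 ml for 500-ml jars and 480 ml for 1000-ml jars, and oxygen makes up
about 21 % of air. `oxygenBudget()` converts percentages to volumes and
reports consumption per insect; `oxygenBudgetVolumes()` accepts measured
volumes directly (the mode used to reproduce published per-jar budgets).
Volume is conserved exactly: initial = final + n * consumedPerInsect.

Times to the 5 % and 2 % residual-oxygen levels are located by **linear
interpolation** between the bracketing observations — published times are
fractional days and linear interpolation is the minimal assumption. A
series already below target at its first reading gets time 0. The
depletion-rate statistic is population divided by days to 2 %, reported to
2 decimal places (insects/day).

## Activity-on-depletion regressions

Across treatments, activity declines with **depletion** $d$ = initial minus
residual O$_2$ percentage. The burst rate and burst-impulse rate span wide
magnitudes across treatments, so they are normalized per insect ($N_t$ =
insects in the treatment) and transformed:

$$\log_{10}(R_b/N_t + 1) = a + b\,d, \qquad
  N_b = a + b\,d, \qquad
  \log_{10}(R_{bimp}/N_t + 1) = a + b\,d$$

$N_b$ is already confined to a narrow 3–6 band and is fitted on the
identity scale. Fits are ordinary least squares (`stats::lm`);
`fitActivityRegression()` reports intercept, slope (with standard errors),
$R^2$, $F$, degrees of freedom and $p$. The published coefficient set (all
values x 1e-3: burst-rate intercept 2.26, slope -0.156; impulses-per-burst
4132 and -50.87; burst-impulse rate 10.8 and -0.818) is stored with an
explicit scale field (`defaultActivityCoefficients()`) to avoid magnitude
bugs. Per-record depletion uses **each replicate's own first reading** as
its initial level, not the nominal 21 % — measured day-one readings spread
around 20 %. Within a single treatment, `fitTreatmentRegression()` fits the
untransformed metric against residual O$_2$ (or depletion) and additionally
reports the error variance $s^2$ and $s$. Fits against residual O$_2$ and
against depletion are sign-flipped twins: equal $|$slope$|$ and identical
$R^2$.

## Grain quality

The count-and-weigh weight-loss estimator on a subsample with undamaged
weight/count $W_U, N_U$ and damaged $W_D, N_D$:

$$\mathrm{loss\ (\%)} = 100\,\frac{N_D W_U - N_U W_D}{W_U (N_U + N_D)}$$

Equal per-kernel weights give exactly 0; inputs where damaged kernels are
*heavier* per grain return a negative value with a warning rather than an
error, since subsampling noise can produce them. Germination capacity is
the pooled percentage germinating across dishes (default 25 seeds/dish).

# The synthetic-data generators

## Recordings

`generateRecording()` emulates a jar recording: insect sound bursts placed
by a homogeneous point process at `burstRate`, each holding $k$ impulses
($k$ uniform on 3–6, matching the narrow observed band of impulses per
burst) with intra-burst gaps uniform on 30–180 ms; inter-burst gaps are
kept above 0.2 s so the generated trains satisfy the burst criterion by
construction (burst counts stay Poisson — placement distributes the bursts
over the free time left after reserving the spans and minimum gaps).
Impulse *kernels* are exponentially damped sinusoids with a raised-cosine
onset — the published record constrains only duration (1–10 ms) and train
structure, not waveform shape, so the kernel shape is this package's
choice. Sample counts round ties-to-even (`round(duration * rate)`). The
default insect kernel is a 4 kHz, 5 ms, 1000/s-decay transient; the
default distractor is a low-frequency (600 Hz) broadband 8 ms thud, typical
of incidental room noise, spectrally distinct from the insect kernel
(construction rejects kernel pairs with cosine similarity >= 0.9 so that
profile rejection is genuinely exercised). Background noise is Gaussian
with RMS one tenth of the kernel peak by default (SNR 10) — a fixture
engineering choice, since no amplitude calibration of real recordings is
published. Everything is bit-reproducible given `rngSeed`, and the caller's
RNG stream is left untouched.

What the generator does *not* emulate: amplitude variation between
individuals, overlapping bursts from many simultaneous insects, reverberant
or non-Gaussian noise, sensor/waveguide transfer functions, and long-range
nonstationarity. Passing round-trip tests therefore demonstrate the
internal consistency of the pipeline at a stated SNR, not field
performance on real recordings.

## Experiments

`generateExperiment()` produces (treatment, replicate, day) records.
Residual oxygen follows exponential decay toward a floor,
$O_2(t) = f + (21-f)e^{-rt}$ with $f = 0.2\,\%$ and
$r = c \cdot n_{insects}/V_{air}$: the published series are not
parameterized, and this shape reproduces the qualitative record that most
of the reduction happens early (by day 11) while making depletion strictly
faster at higher insect density per ml of air. The constant $c = 2.0$ per
day per (insect/ml) was fixed so the geometric-mean density reaches 2 % at
the geometric mean of the published times-to-2 % (about 8.6 d); the
resulting per-treatment times span 3.2–23.5 d. No single exponential
constant can match the full published 5–13 d spread (the real decline is
sigmoid — slow on day one even in the densest jars), which is why published
times are treated as *inputs* to the depletion-rate arithmetic, never as
generator outputs to be reproduced.

Activity is generated by inverting the regression models at each
timepoint: $y = a + b\,d + \varepsilon$ on the transformed scale with
Gaussian $\varepsilon$, then back-transformed and floored at 0 (a rate
cannot be negative), with $N_b$ set missing whenever no bursts occurred.
The default noise SDs (0.25e-3 for the burst-rate model, 0.35 for
impulses-per-burst, 1.2e-3 for the burst-impulse model, all on the model
scales) keep the simulated response above its zero floor over the
early-storage window, where the linear model is valid; they are deliberate
benchmark conditions for parameter recovery, not estimates of field
variance (published $R^2$ values bundle treatment-by-time interaction and
flooring effects and are not reproduction targets).

## Grain counts

`generateGrainCounts()` constructs a subsample realizing a target
weight-loss percentage exactly: the damaged-kernel count is set from a
typical 40 % per-kernel weight loss of weevil-bored wheat, then the exact
per-kernel loss is back-solved so the count-and-weigh formula returns the
target. Mean kernel weight is jittered around 40 mg by the seed; the loss
value is invariant to it.

# Problem sizes and numerical choices

The validation studies shipped in the tests and the acceptance script use:
1000 random onset lists against a brute-force $O(n^2)$ burst scanner; 20
synthetic 100-s recordings (burst rate 0.1/s, SNR 10, distractors present)
for the detection round trip, requiring >= 90 % burst recall and <= 10 %
spurious bursts; and 200 replicate experiments of 36 records each (6
treatments x 2 replicates x days 0, 0.5, 1) for regression recovery,
requiring the 95 % CI to cover the generating slope in >= 90 % of
replicates. The recovery design includes a day-0 reading (physically, the
oxygen sensor is read at sealing) so the fit's own-first-reading depletion
convention coincides with the generator's nominal-21 % inversion; without
day 0 the noise-free residuals would not vanish.

Other conventions, stated once: WAV I/O is 16-bit PCM with quantization
`round(x * 32767)` and its exact inverse on read (a write/read round trip
is bit-identical); multi-channel files use the first channel with a
warning; truncated or compressed files fail with an error naming the file
and byte offset. Ties in profile matching break toward the first profile in
list order. Degenerate detector inputs: an all-zero segment yields an empty
impulse set (not an error); an all-zero spectrum window is an error, since
a unit-power spectrum is undefined.

# Known limitations

* The detector and its constants are this package's design; only the
  impulse/burst definitions and the spectrum parameters (256-point frames,
  50 % overlap) follow the published analysis. Constants are all exposed
  in `detectionConfig()` and should be re-tuned for other sensors.
* The oxygen model is a single exponential per jar; real series flatten
  early and steepen before the floor.
* Inference beyond the regression $F$/$p$ (ANOVA/ANCOVA tables with
  multiple-comparison letters) is out of scope; `summarizeTreatments()`
  stops at means and SEMs.
* Mortality is only proxied by activity and oxygen levels; no survival
  model is fitted. Grain respiration, humidity and temperature dynamics,
  and immature life stages are not simulated.
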