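---
title: "Models and methods in cppreserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cppreserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`cppreserve` implements an analysis chain for visual response-speed cohorts
in which single-trial EEG decision signals explain, and are moderated by,
between-subject factors such as lifetime environmental enrichment (EE,
measured by the Cognitive Reserve Index questionnaire's Leisure subscale):

1. a **synthetic cohort generator** producing behaviour and epoched EEG
   with the statistical structure the downstream analysis assumes;
2. **preprocessing**: FIR filtering, epoching, baselining, and trial
   exclusion;
3. **metric extraction**: N2c latency/amplitude (target selection), CPP
   onset/build-up rate/amplitude (evidence accumulation), and
   left-hemisphere beta (LHB) latency/slope/amplitude (motor preparation);
4. a per-subject **detection drift-diffusion model** fitted by G-square
   minimisation over RT quantile bins;
5. **cohort statistics**: hierarchical regression with R-squared change,
   moderation with conditional effects, bootstrapped mediation, one-way
   ANOVAs with partial eta-squared, JZS Bayes-factor t tests;
6. **trial-subsampling reliability** and a task-time budget calculator.

Because raw data from the motivating study cannot be shared, every stage is
exercised end-to-end on the generator. This vignette records the models,
the tunable parameters, and the design decisions taken where the published
description was silent or internally inconsistent.

# The behavioural model

A single-accumulator (detection) diffusion with unit within-trial noise:
evidence starts at 0, drifts at rate $v$ (evidence/s), and a response is
triggered when it reaches the bound $a$ (response caution); the observed RT
adds a nondecision time $t_0$. First-passage times then follow the
shifted-Wald (inverse-Gaussian) law with mean $a/v$ and shape $a^2$:

$$f(t \mid a, v, t_0) \;=\; \frac{a}{\sqrt{2\pi (t-t_0)^3}}
  \exp\!\left(-\frac{(a - v\,(t-t_0))^2}{2\,(t-t_0)}\right),\qquad t > t_0 .$$

Trials whose passage time exceeds the 1800 ms deadline are misses. The
diffusion scale is fixed at $s = 1$, which makes the published magnitudes
($a \approx 2\text{–}3$, $v \approx 7\text{–}8$, $t_0 \approx 0.1$ s)
produce realistic RTs. Trial-to-trial parameter variability is not
modelled; the source description of bin-wise parameter variation is
ambiguous and was deliberately left out of scope.

`simulate_ddm()` provides the independent oracle: Euler–Maruyama paths
with a Brownian-bridge within-step crossing correction
($p_\text{cross} = e^{-2(a-x_i)(a-x_{i+1})/\Delta t}$). Without the bridge
term the naive scheme has an $O(\sqrt{\Delta t})$ first-passage bias that
would fail the package's own Kolmogorov-distance check (~0.07 at
$\Delta t = 0.5$ ms); with it the distance at $10^5$ paths is ~0.003.

# The G-square fit

Responded RTs are split at their 0.1/0.3/0.5/0.7/0.9 quantiles. Five
cutpoints delimit **six** response intervals with observed proportions
0.1, 0.2, 0.2, 0.2, 0.2, 0.1 of responders; a miss bin is appended.
Descriptions of this layout sometimes count "five response bins plus a
miss bin": that count contradicts both the printed proportions and
frequency conservation ($\sum O_i = \sum E_i = n$), so the package keeps
all seven cells. Expected frequencies integrate the shifted-Wald CDF
between cutpoints (with 0 and the deadline as outer edges; the miss cell
gets $1 - F(\text{deadline})$, floored at $10^{-10}$ so the objective is
finite everywhere), and

$$G^2 = 2 \sum_i O_i \ln(O_i / E_i)$$

is minimised over $(a, v, t_0)$ with a direction-set **Powell** minimiser
(authored in `R/powell.R`, Brent line searches via `optimize()`), from a
3×3×3 multi-start grid with $t_0$ capped below the fastest observed RT.

**Known information floor.** At the published older-group means and
$n = 2000$ trials, the binned-multinomial Fisher information bounds the
sampling SDs at roughly 23% ($a$), 8% ($v$) and 50% ($t_0$) — the
$(a, t_0)$ trade-off along the RT mean $t_0 + a/v$ is only weakly broken
by seven cells. Median recovered values are nearly unbiased (the
acceptance report emits them alongside the error statistics), but a
"median absolute error below 10%" criterion is unattainable for $a$ and
$t_0$ with this estimator; the corresponding acceptance expectations are
deliberately left failing rather than loosened.

# The synthetic cohort: a stated world

Each subject carries true metric values that the EEG synthesis plants and
the extractors must recover:

* **CPP** at Pz: zero until `cpp_onset_true`, then a linear ramp at
  `cpp_slope_true` (µV/ms) topping out 50 ms after the response and
  decaying over 300 ms. The peak sits at RT+50 ms — the upper edge of the
  −150..+50 ms build-up-rate window — because a peak exactly at RT would
  put the window astride the decay and make exact noiseless slope
  recovery impossible. On unusually fast trials the ramp start is pulled
  forward to keep 200 ms of build-up before the response.
* **N2c** at P7/P8: a Gaussian negativity (SD 42.5 ms ≈ 100 ms FWHM) of
  amplitude `n2c_amp_true` at `n2c_latency_true`, planted contralateral
  to the target hemifield.
* **LHB** at C3: a 25 Hz carrier whose envelope declines linearly from
  1.5 µV at target onset to `1.5 − lhb_depth_true` at RT, recovering over
  300 ms; misses keep a flat envelope.

White Gaussian noise (default SD 15 µV, a realistic single-trial EEG
scale) is added per sample; a 1/f option exists (`pink = TRUE`) because
the real noise spectrum is unspecified. Epochs span −200..1500 ms at
500 Hz and are baselined over −100..0 ms.

**Onset/RT coherence.** A fixed stimulus-locked CPP onset and a
response-locked slope window are jointly recoverable only when
essentially no trial responds earlier than onset + 150 ms. The generator
therefore caps each subject's onset 150 ms below the $10^{-4}$ quantile
of their Wald RT distribution (floor 50 ms). This makes planted onsets
earlier than typical empirical CPP onsets — the price of the exact
round-trip the package's tests demand; subjects fast enough to hit the
floor fall outside the recoverable regime. Empirical studies face the
same geometry, which is why their single-trial windows tolerate partial
overlap instead of demanding exact recovery.

**Cohort-level coupling.** Subject mean RT follows the moderation
equation $\mathrm{RT} = i_1 + b_1\,\text{slope} + b_2\,\mathrm{EE} +
b_3\,\text{slope} \times \mathrm{EE} + \varepsilon$ with the published
estimates (1259.45, −5420.91, −4.34, 32.00) as defaults and
$\sigma_\varepsilon = 90$ ms (the published model's residual MSE of
8102 ms² gives ≈ 90 ms). Drift is drawn from the published group
distributions (older 7.38 ± 2.05, younger 8.49 ± 1.99) and caution then
absorbs the subject's mean decision time, $a = v\,(\mathrm{RT}/1000 -
t_0)$, so the equation holds in expectation while the older < younger
drift ordering is preserved. Consequently $a$ runs somewhat higher than
the published group means — the published fits let parameters vary with
response bins, which this package does not model. Means are clamped to
[250, 1400] ms; distributional parameters not stated anywhere (CRI
Leisure ≈ 138 ± 20, centred on the published median; slope SD 0.069 from
the published moderation probes 0.0034/0.0724/0.1405) were fixed once
from the printed anchors and are configurable, not calibrated.

# Preprocessing decisions

* Filters are Hamming windowed-sinc FIR, zero-phase (symmetric kernels,
  mirror-padded FFT convolution), in the order detrend → notch
  (50/100/150 Hz) → 0.1 Hz high-pass → 35 Hz low-pass. Kernel order is
  3.3/(transition bandwidth) samples; only the window family was stated,
  so transition widths are library-style defaults exposed as arguments.
* Exclusion: RT ≤ 150 ms or ≥ 1800 ms; absolute amplitude strictly
  greater than 100 µV between −100 ms and RT+100 ms ("exceeded" read as a
  strict inequality, applied symmetrically); misses carry their own
  reason. Whether the threshold applies to CSD-transformed units is
  unstated, so it is an argument. Exclusion is idempotent and conserves
  counts per reason.
* The current-source-density transform itself is out of scope: the
  pipeline accepts either raw-µV or pre-transformed data.
* Response-locked epochs are re-sliced from stimulus-locked data at RT;
  trials whose window would leave the epoch are dropped and logged. Two
  windows are used: −200..+100 ms for CPP measures (almost lossless) and
  −600..+300 ms for beta (its −450..−350 ms baseline needs more
  pre-response signal; trials faster than 400 ms are lost there).
* IQR outliers use type-7 (linear-interpolation) quartiles with a 3×IQR
  fence; the original analysis used a statistics package whose default
  this matches.

# Metric extraction decisions

* **CPP onset**: two-sided running t tests of 25 ms window means against
  zero across trials; onset is the first of 90 consecutive samples (180 ms
  at 500 Hz) with p < 0.05, searched over 0–1000 ms. Sidedness, window
  centring and the sample interpretation of "90 points" are documented
  choices. Zero-variance windows count as significant iff their mean is
  nonzero, which makes the noiseless world well defined.
* **N2c**: latency is the window minimum over 150–400 ms (earliest tie);
  amplitude is the mean over ±50 ms around the cohort grand-average peak.
  Hemifield collapse is an unweighted average of the two contralateral
  per-hemifield averages.
* **TSE/beta**: band-pass 20–35 Hz, rectify, smooth with a 100 ms window
  stepped by 50 ms. Windows are half-open ([c−50, c+50)) so each holds
  exactly five rectified-carrier periods at 25 Hz, removing smoothing
  ripple; remaining carrier-phase and sampling ripple is ≈ 2%. The trace
  is baselined by subtraction (matching ERP baselining) *before* the
  200 ms edge trim, because the stimulus-locked baseline window lies
  inside the trimmed region. Latency is the argmin of the baselined
  average over 0–1000 ms (earliest tie); slope is OLS over −300..−50 ms;
  amplitude is the mean over ±50 ms.

# Statistics decisions

* Moderation enters variables raw (uncentred) — the published intercept
  magnitude (1259.45) indicates raw units — with a `center` flag.
  Conditional effects of the predictor are reported at moderator
  mean ± 1 SD (the published probes are consistent with that convention),
  with SEs from the coefficient covariance; the identity
  $b_2 + b_3 m$ is exact.
* Mediation uses the percentile bootstrap (the toolbox the study used
  reports percentile intervals), resampling subjects with replacement;
  degenerate resamples are redrawn and counted. The indirect effect is
  the product of the x→m slope and the m→y slope controlling x; when x
  and m are exactly collinear the m→y slope falls back to the simple
  regression (the deterministic-chain limit).
* The JZS Bayes factor integrates the noncentral-t likelihood over a
  Cauchy(0, 0.707) effect-size prior; for |t| beyond the reliable range
  of R's noncentral t the implementation switches to the numerically
  stable inverse-gamma mixture form on the log scale (the two agree to
  4+ significant digits where both work, and the test suite checks the
  primary route against an independent quadrature oracle). Directional
  tests renormalise the half-line prior.
* Standardised betas come from refitting on z-scored variables; raw-scale
  CIs are reported alongside. Bonferroni thresholds (α/3 moderations,
  α/8 EEG group tests) are applied as reported, not re-derived.

# Trial-subsampling reliability

For each subject with ≥ 129 valid response-locked trials, 1000 random
subsamples per bin size (20–120) yield distributions of mean RT and CPP
build-up rate. The slope of a subsample is computed as the mean of the
drawn trials' single-trial OLS slopes — algebraically identical to
fitting the averaged waveform, since OLS is linear in the data.
SNR = mean/SD across permutations; exhausted pools (SD = 0) are flagged
and excluded from trend tests. Cross-subject Pearson correlations between
slope and RT are computed per permutation, with one-sample JZS Bayes
factors against a threshold effect size (default −0.55; the source states
−0.5 in one place and −0.55 in another, and the threshold is an
argument). Adjacent-bin Kolmogorov–Smirnov tests pool subject-centred
estimates, a pooling the source does not specify.

The task-time calculator inflates the required valid-trial count for
misses and then for artifact rejection, rounding to the nearest integer
at each step — the one rule that reproduces all four printed trial counts
(42, 48, 52, 75) — and allocates presented trials over the ITI set as
evenly as possible, remainder to the shortest ITIs. The printed
average-case total (277.6 s) contains an arithmetic slip (1.8×16
transcribed as 28 instead of 28.8); the calculator returns the correct
278.4 s, and the worst case reproduces 435 s exactly.

# What a green test establishes — and what it does not

The generator emulates component shapes, additive noise, and the
between-subject moderation structure. It does **not** emulate volume
conduction, artifacts other than amplitude excursions, eye movements,
1/f-plus-oscillation spectra (unless `pink = TRUE`), trial-to-trial
parameter variability, or CRIq item-level structure. Green tests
therefore establish that the pipeline's operations are correct on data
satisfying their assumptions, and that printed worked examples are
reproduced — not that the study's cohort-level tables would be recovered
from real recordings.

# Numerical conventions

All times are ms relative to the lock event, windows closed on both ends
(the TSE smoothing window is half-open, see above); sample 0 sits at the
lock event. Quantiles are type-7 throughout. Every stochastic operation
takes an explicit seed, and the pipeline stamps outputs with the MD5 of
the config that produced them. Persistence is plain TSV + JSON (no HDF5/
YAML bindings are available in the supported environment); the epoch
container writes a wide TSV plus a JSON sidecar and round-trips losslessly
to 8 significant digits.
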