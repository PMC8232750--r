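---
title: "Directed EEG connectivity with lag-optimized transfer entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG connectivity with lag-optimized transfer entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teflow)
```

## The problem

Given multichannel EEG recorded while subjects listen to narrated stories
under crossed odor (neuter, androstenol-like, estratetraenol-like) and
narrator-voice (male, female) conditions, we ask which channels *send*
information to the rest of the scalp over and above the voice-matched
neutral condition, whether those channels' outgoing-flow profiles differ
between settings, and whether the profiles are specific enough to identify
the setting they came from. The primary quantity is transfer entropy (TE),
a directed, model-free measure of information flow.

## Transfer entropy and its estimator

For a source $X$ and target $Y$, TE is the conditional mutual information

$$\mathrm{TE}_{X \to Y}(\mu) = I\!\left(Y_t ;\, X_{t-\mu} \mid Y_{t-1}, \dots, Y_{t-h_y}\right),$$

the information the source carries about the target's next sample beyond
what the target's own past provides — the deviation from the target's
generalized Markov property. It is strictly non-symmetric: `ksg_te(x, y)`
and `ksg_te(y, x)` are independent quantities. Units are nats throughout
(`nats_to_bits()` converts).

**Lag convention.** `delay = mu` pairs the target future $Y_t$ with the
source sample $X_{t-\mu}$, so a generative coupling $y_t \leftarrow c\,
x_{t-d}$ attains its maximal TE at $\mu = d$ and the delay-scan argmax
estimates the physical transfer delay directly. Consequently $\mu = 0$
means "no lag" in the sense of a source sample simultaneous with the
target future. An alternative convention aligns $\mu = 0$ with the end of
the target history; we rejected it because it shifts every recovered delay
by one sample relative to the generative delay.

**Estimation** uses the Kraskov–Stögbauer–Grassberger (KSG)
nearest-neighbour construction extended to conditional mutual information
(Frenzel–Pompe counting): with $\epsilon_i$ the max-norm distance of joint
sample $i$ to its $k$-th nearest neighbour,

$$\hat I = \psi(k) - \left\langle \psi(n_{fz}+1) + \psi(n_{sz}+1) -
\psi(n_z+1) \right\rangle,$$

where the $n$'s count neighbours strictly inside $\epsilon_i$ in the
marginal subspaces. The kernel width adapts to the local sample density,
which is what makes the estimator effectively parameter-free *in its
smoothing*; the embedding is not, so the defaults are explicit and fixed:
$k = 4$ neighbours, source and target history lengths 1/1. Series are
standardized internally (TE is invariant to linear rescaling).

Numerical choices:

* **Tie-breaking jitter** (`noise_jitter_sd`, default $10^{-8}$) is added
  deterministically, seeded from each series' own content, so repeated
  calls are bit-identical. Seeding per series (rather than per call) has a
  second purpose: when the target is an exact copy of the source — full
  synchronization — the source embedding and the target history become
  exactly tied coordinates, their neighbour counts cancel, and the
  estimate collapses to the theoretical zero. With independent jitters the
  tie is broken arbitrarily and the estimator acquires a finite negative
  offset ($\approx -0.06$ nats at $k = 4$) in this degenerate case.
  Doubling the jitter changes estimates by well under 1%.
* **Theiler (dynamic-correlation) exclusion** (`theiler`, default 0):
  temporally adjacent embedding vectors of an autocorrelated series are
  close in state space for trivial reasons and inflate weak-coupling
  estimates by a few percent. For our AR(0.5) surrogates the
  autocorrelation drops below 0.01 within 7 samples, so the estimator
  calibration analyses use `theiler = 10`; the default stays 0 to match
  the plain estimator.
* Neighbour search is a kd-tree under the max-norm; marginal counts use a
  sort on the conditioning coordinate. Estimates are exact (identical to
  the brute-force double loop), only faster.

**Gaussian oracle.** For a linear-Gaussian VAR, TE has the closed form
$\tfrac12 \ln \big(\mathrm{Var}(Y_t \mid Y_\text{past}) /
\mathrm{Var}(Y_t \mid Y_\text{past}, X_\text{past})\big)$, which
`gaussian_te_oracle()` computes analytically from the stationary
covariance (discrete Lyapunov equation on the VAR companion form). On the
reference pair ($x_t = 0.5x_{t-1} + \varepsilon$, $y_t = 0.5y_{t-1} +
0.5x_{t-1} + \eta$, unit innovations) the closed form gives 0.13483 nats,
confirmed against regression residual variances on $10^6$ simulated
samples. The KSG estimator is validated against this oracle over coupling
strengths 0.1–0.5; at strength 0.1 the true TE is only ~0.0066 nats while
a single length-20,000 estimate has standard deviation ~0.004 nats, so
oracle-agreement checks average 30–40 independent replicates and compare
the mean.

## Signal conditioning

The conditioning chain is `bandpass()` → `reject_artifacts()` →
`downsample_tenth()` → `detrend_linear()`:

* 0.5–50 Hz Butterworth band-pass, order 4 (≈24 dB/octave), applied as
  separate high- and low-pass sections for numerical stability at the very
  low normalized high-pass edge, each forward–backward (zero phase) so
  filtering cannot bias the lag estimates.
* Amplitude artifact rejection at 125 µV on contiguous 1-s segments,
  excised jointly across channels so time-locking is preserved. The
  segment length is our choice; only the amplitude rule is inherited.
* Tenth-length decimation (anti-alias low-pass at 80% of the new Nyquist,
  then every 10th sample), mapping 120,000 samples at 1,000 Hz to 12,000
  points at 100 Hz; `antialias = FALSE` gives naive subsampling for
  sensitivity checks. A delay of $d$ samples before decimation appears at
  $d/10$ after it.
* Per-channel least-squares detrending.

## The channel-of-interest procedure

Per subject and setting, `pairwise_te()` scans delays 0–50 samples
(0–500 ms at 100 Hz) for every ordered channel pair and stores the maximal
TE and its lag. Then, per odorized setting:

1. **Neutral contrast** — subtract the voice-matched neutral matrix
   (AM−NM, EM−NM, AF−NF, EF−NF). Negative residuals are retained; the
   threshold removes them later.
2. **Grand average** over subjects.
3. **Bootstrap upper-CI threshold** — resample the pooled off-diagonal
   entries (B = 10,000), take the mean of each resample, threshold at the
   97.5th percentile of the bootstrap mean distribution (one-tailed
   p < 0.025 against the average); entries strictly below are zeroed,
   entries equal to the threshold survive (relevant only in the degenerate
   all-equal case).
4. **Out-degree selection** — count non-zero entries per source row,
   bootstrap the mean of the degree vector, and keep channels whose degree
   strictly exceeds its upper 95% CI bound. "At or below the average
   bound" is discarded; the comparator is our choice where the procedure's
   verbal description lacks one.
5. **Common channels** — intersect selections across settings; settings
   with empty selections are dropped and reported.

The CI is computed over the pooled entries, not per entry, matching the
one-tailed-average reading of the procedure. Note what this construction
is: a *ranking* device that retains the upper tail of the flow
distribution, not a calibrated null-hypothesis test. On coupling-free
data roughly 40–50% of contrast entries exceed the mean's upper CI and
the degree selection keeps the top ~25–30% of channels at any montage
size, so the per-setting selection is almost never empty under the null.
Even the cross-setting intersection retains a false channel in a
meaningful fraction of null replicates (~20% in our 8-channel validation
studies), partly because voice-matched settings share their neutral
recording, which correlates their null contrasts at $\rho = 0.5$. Users
should read the selected sets as a relative ranking of information
sources whose evidential weight comes from the planted-truth recovery and
the group statistics, not as a false-positive-controlled detection.

## Synthetic ground truth

`synth_design()`/`generate_recording()` simulate each channel as an AR(1)
process (coefficient 0.5, innovation SD in nominal µV) plus
condition-active directed couplings at stated delays — a linear VAR whose
TE is known through the Gaussian oracle, with an optional `tanh`
source nonlinearity to exercise the estimator's model-free claim, and an
optional artifact-injection flag (~1% of samples above 100 µV) for the
rejection rule. Designs are checked for stationarity via the spectral
radius of the VAR companion matrix; a burn-in of at least
`10 x max delay` (and ≥500) samples is discarded. Seeding is
counter-based per (subject, condition), so subjects are exchangeable yet
every recording is reproducible bit-for-bit.

What the generator emulates: montage geometry (10-10 labels, 62 channels,
1,000 Hz), directed couplings with known delays, condition structure with
voice-matched neutrals, amplitude scale, artifacts. What it does not:
volume conduction, 1/f spectra, oscillatory rhythms, nonstationarity,
ocular artifacts with realistic topography. Passing recovery tests
therefore show the *procedure* is sound on data satisfying its
assumptions, not that real-EEG conclusions are automatic.

The reference validation study (`scaled_study_design()`) uses 8 channels,
6 subjects, and 600–800 samples at the 100 Hz analysis rate, with sources
F3 and C2 each driving three targets (strength 0.6, delays 2–4 samples)
in the odorized settings EM/AM/AF. The recording length is scaled down
from the full 12,000-point series so a replicate study runs in seconds;
at these sizes the true-edge TE (~0.15 nats) stands far above the
estimation noise of the 6-subject grand average (~0.005 nats), which is
the regime the procedure assumes. The EF setting is declared an exact
re-labeling of its neutral partner (`condition_alias = c(EF = "NF")`):
the odor manipulation with literally no effect. Its contrast is then
identically zero, the degenerate path in which every degree ties and the
selection is empty, so the setting is dropped from the intersection — a
deterministic analogue of the empirically-dropped setting in the original
analysis, chosen because a stochastic near-null almost never produces a
strictly empty selection under the ranking construction above.

## Group statistics and effect sizes

Normality is checked by a Lilliefors test whose p-value comes from seeded
Monte-Carlo replicates of the KS distance with re-estimated parameters
(the classical KS null does not apply when mean and SD are estimated).
Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`) carries the
effect size $r = \sqrt{H/N}$; Wilcoxon tests report the *standardized*
statistic $W$ (normal approximation with tie and continuity corrections) —
the only form dimensionally consistent with printed values like
$W = -7.99$ on hundreds of observations — and $r = W/\sqrt{N}$ with $N =
n_1 + n_2$ for the rank-sum and the number of protocol runs for the
signed-rank. Magnitudes classify as small ($|r| \le 0.3$), medium
($0.3 < |r| < 0.5$), large ($|r| \ge 0.5$). Degrees of freedom print in
the $(k-1, N-1)$ / $(N-2)$ style of the source tables. Two-sided
p-values; `p = 0.00` renders as `p < 0.001`.

## Specificity protocol

`build_dataset()` forms one row per (setting, common channel) from the
channel's outgoing TE profile (62 features). Per run, one channel per
setting is held out (15 × 62 train, 3 × 62 test), features are
standardized on the training rows only, and a multinomial (softmax)
logistic regression with fixed L2 penalty 1.0 (`nnet::multinom`, `decay`)
is fit; accuracy and macro-averaged precision/recall/F1 are scored on the
3 held-out rows and aggregated over 1,000 runs. Chance is $100/3\%$ for
the balanced 3-class design. Per-class weight maps are the softmax
coefficients recentred across classes and averaged over runs. The
regularization strength, the standardization, and weight averaging are
our fixed choices where the protocol's description is silent; they are
recorded in the report object. Three-row test sets make single-run
metrics coarse (0/33/67/100%), so only aggregates over runs are
meaningful — hence the large SDs such a protocol reports.

## Sensitivity analysis

`min_detectable_f()` root-finds the Cohen's $f$ at which a
repeated-measures design attains target power, under the within-factors
noncentrality convention $\lambda = f^2 n m / (1-\rho)$ with numerator df
$m-1$ and error df $(n - g)(m - 1)$, no nonsphericity correction. For
$\alpha = .05$, power $.8$, $n = 20$, $g = 2$, $m = 6$, $\rho = .4$ it
returns $f \approx 0.253$, bracketing the conventional software value
0.258 (whose exact dialog choices are not recoverable); the conversion
chain $\eta^2 = f^2/(1+f^2)$, $d = 2f$, $r = d/\sqrt{d^2+4}$ is exact.
The $r$ corresponding to $f = 0.258$ is 0.2498 at full precision; we do
not truncate.

## Problem sizes used in validation

Validation suites run at deliberately scaled sizes chosen to keep each
property in its asymptotic regime while a full run stays fast: estimator
checks at series lengths 4,096–20,000; delay recovery over 100 seeded
pairs of length 2,000 (scan 0–15); end-to-end recovery over 10 replicate
studies (8 channels × 6 subjects × 600 samples, B = 1,000); null
calibration over 20 coupling-free replicates (400 samples) plus 1,000
rank-sum type-I simulations; chance calibration of the specificity
protocol over 1,000 label-shuffled runs.

## Known limitations

* Single-source TE with scalar histories: no multivariate or conditional
  TE between channel groups, no spectral/symbolic variants.
* The bootstrap selection is a ranking construction (see above); its
  per-setting output on null data is not an error-controlled set.
* The Gaussian oracle covers the linear generator only; for the `tanh`
  variant the oracle is an approximation and only qualitative recovery is
  asserted.
* BrainVision support covers the multiplexed IEEE-float/INT16 core needed
  for round-trips, not the full format zoo (segmented files, markers).
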