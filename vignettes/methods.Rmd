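---
title: "Models and methods behind ercal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ercal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercal)
```

ercal implements four analysis pipelines used to study how luminal
Ca²⁺ regulates the InsP₃ receptor (InsP₃R), the main Ca²⁺-release
channel of the endoplasmic reticulum: differential-binding inference for
affinity-enrichment proteomics, single-channel gating statistics,
dose-inhibition curve fitting, and single-cell Ca²⁺-imaging
classification. Each pipeline ships with a seeded generator that emits
data with exactly the statistical structure the analysis assumes, so
every stage can be exercised, tested and calibrated without external
data. This vignette records the models, the tunable parameters, and the
design decisions taken where a published description leaves the
implementation open.

## 1. The spike-and-slab Poisson model for spectral counts

An affinity-enrichment experiment compares pull-downs with a bait
peptide against pull-downs with a scrambled control peptide, in several
biological blocks (here individual animals, historically "cows"). For
protein $g = 1,\dots,p$, block $c = 1,\dots,C$ and condition
$t \in \{0, 1\}$ (0 control, 1 bait), the observed MS/MS spectral count
$y_{gct}$ is modelled as

$$
y_{gct} + 1 \sim \mathrm{Poisson}(\lambda_{gct}), \qquad
\log \lambda_{gct} = \log \mu_c + \alpha_{gc} + t\,\beta_g,
$$

with $\alpha_{gc} \sim N(0, \sigma_c^2)$ a protein-by-block random
effect, and a spike-and-slab prior on the binding effect:
$\beta_g \sim \pi_0\,\delta_0 + (1 - \pi_0)\,N(0, \tau^2)$. The
hyperpriors are $\pi_0 \sim \mathrm{Beta}(0.5, 0.5)$ and
$\sigma_c^{-2}, \tau^{-2} \sim \mathrm{Gamma}(1, 1)$. The per-block
scale is a fixed plug-in, never resampled:

$$
\mu_c = \frac{1}{p} \sum_{g=1}^{p} \frac{y_{gc0} + y_{gc1} + 2}{2},
$$

the across-protein mean of the pseudo-count-shifted average count. The
pseudo count of 1 avoids $\log 0$ and is deliberately conservative: it
shrinks fold changes toward 1, so it can only make enrichment harder to
detect. Raw tables are stored unshifted; the offset lives inside the
likelihood (`count_model_spec(pseudo_count = 1)`).

Inference for protein $g$ is summarized by the local false sign rate,

$$
\mathrm{lfsr}_g = P(\beta_g \le 0 \mid Y),
$$

the posterior probability that the protein did *not* preferentially bind
the bait. Spike draws ($\beta_g = 0$) count toward the event. Proteins
with $\mathrm{lfsr}_g \le 0.2$ are selected (ties at the threshold are
selected), and the global false sign rate of the selected set is
estimated by the mean lfsr among selections.

### Sampler architecture

The posterior is explored by Metropolis-within-Gibbs
(`fit_count_model()`):

* $(\pi_0, \tau^2, \sigma_c^2)$ — exact conjugate draws.
  $\pi_0 \mid z \sim \mathrm{Beta}(0.5 + \#\{z_g{=}0\},\; 0.5 +
  \#\{z_g{=}1\})$; $\tau^{-2}$ and each $\sigma_c^{-2}$ from their Gamma
  closed forms.
* $(z_g, \beta_g)$ — exact gridded Gibbs. The $\beta$-conditional
  depends on the data only through $A_g = \sum_c (y_{gc1} + 1)$ and
  $B_g = \sum_c \mu_c e^{\alpha_{gc}}$, giving log-likelihood
  $A_g\beta - B_g e^{\beta}$. The slab marginal
  $\int L(\beta)\,N(\beta; 0, \tau^2)\,d\beta$ is computed by
  deterministic trapezoid quadrature on a 401-node grid spanning
  $\pm 8\max(\tau, 1)$ beyond 0 and the likelihood mode
  $\log(A_g/B_g)$; if the integrand mass touches the grid edge the grid
  is widened once, then the update aborts. Given $z_g = 1$, $\beta_g$ is
  drawn from the gridded conditional by inverse CDF with within-bin
  jitter; given $z_g = 0$, $\beta_g = 0$ exactly.
* $\alpha_{gc}$ — one simultaneous vectorized random-walk Metropolis
  proposal per sweep, per-block step size adapted toward roughly 40%
  acceptance during burn-in only and frozen afterwards, so the
  post-burn-in chain is a fixed Markov kernel.

Exactness was preferred wherever a conditional admits it because every
such update has a brute-force oracle: the test suite checks the
conjugate moments against their closed forms, the gridded slab
probability against fine-grid integration (agreement below $10^{-4}$),
and the Metropolis kernel's stationary law against a gridded density
(Kolmogorov–Smirnov distance below 0.02).

Defaults are 4,000 iterations with 2,000 burn-in, thin 1, one chain, an
explicit integer seed (runs are bit-reproducible), all overridable.
Log-rates are clamped to $[-30, 30]$ before exponentiation as a
numerical floor. Incomplete designs are rejected by default; an explicit
`impute_missing = TRUE` fills absent cells with zero and flags them. No
sum-to-zero constraint is imposed on $\alpha_{gc}$ versus $\beta_g$:
with small $C$ the priors regularize the decomposition, and imposing a
constraint would change the model.

### Calibration and the shifted scale

The generator (`simulate_counts()`) draws from the model above. In
`shifted` mode it emits $u \sim \mathrm{Poisson}(\lambda)$ directly — the
law the model assumes for $y + 1$ — so a fit with `pseudo_count = 0`
makes the fitted and generative models *identical*. This is what
simulation-based calibration requires: with hyperparameters drawn from
their priors and data from the prior predictive, the rank of each true
$\beta_g$ among its posterior draws must be uniform. The suite runs 200
such replicates at $p = 40$, $C = 3$ (1,100 iterations, thin 8, fixed
plug-in $\mu_c = 3$ shared by generator and fit) and requires a
chi-square uniformity test not to reject at $\alpha = 0.01$; spike ties
are broken by randomized ranks. Raw-count emulation
($y = \max(u - 1, 0)$) is available for end-to-end demonstrations. The
generator applies the same $\pm 30$ log-rate clamp as the likelihood and
switches to a Gaussian approximation for Poisson rates above $10^7$
(error negligible there), so extreme prior draws cannot overflow.

The paper-scale preset is $p = 486$, $C = 3$. The remaining generator
defaults — $\pi_0 = 0.95$, $\tau = 1$, $\sigma_c = 0.6$, $\mu_c$
lognormal around 3 — are this package's choices for a realistic sparse
regime (a few dozen spectral counts per protein, a handful of genuine
binders); no published effect magnitudes exist to copy. What passing
calibration shows is that the sampler is correct *for data from this
model*; real eluates carry over-dispersion and correlated contaminants
beyond the block random effect, which the lfsr does not automatically
absorb.

## 2. Single-channel gating statistics

Records are assumed acquired at 5 kHz and anti-aliasing filtered at
1 kHz (both configurable). The reduction chain is:

1. **Idealization** (`idealize()`): each sample is assigned the nearest
   occupancy level $\mathrm{round}((i - i_{\text{closed}})/\Delta i)$,
   clamped at zero — thresholds sit halfway between levels. A
   Schmitt-trigger refinement commits a level transition only when the
   run of samples overshoots the half-amplitude boundary by 10% of the
   unitary increment, suppressing noise chatter at thresholds. Events
   briefer than the dead time are merged into their neighbors, shortest
   first, durations conserved exactly. The dead time follows the
   Gaussian-filter rise-time convention $t_d = 0.179/f_c$ (≈179 µs at
   1 kHz), with a floor of 1.5 samples because a single-sample run has
   no measurable duration. Idealization refuses traces whose increment
   is below 4 noise standard deviations. When levels are unknown they
   are estimated from a Gaussian-mixture fit to the amplitude histogram
   (`estimate_levels()`, requires mclust), with explicit override.
2. **Open probability** (`open_probability()`):
   $P_o = \sum_k k\,T_k / (N \cdot T)$, occupied channel-time over total
   channel-time — the multichannel convention, dividing by the assumed
   channel count.
3. **Dwell times** (`dwell_times()`): arithmetic means of open and
   closed sojourns for single-channel records, excluding the
   boundary-censored first and last events. Aggregated multichannel
   dwell analysis is out of scope. Dwell means are accurate when true
   dwells are long relative to the dead time; near it, merging biases
   means upward (the tests exercise the regime $\tau \gg t_d$).
4. **Channel counting** (`channel_count_confidence()`): the active
   channel count $N_A$ is the maximum observed level, which can
   undercount. With per-channel $\hat P_o$ estimated under $N_A$
   channels, a hypothetical $N_A + 1$-channel patch would show occupancy
   $\le N_A$ at a random instant with probability
   $q = 1 - \hat P_o^{\,N_A+1}$. Treating the record as
   $m = T / (\bar t_{\text{open}} + \bar t_{\text{closed}})$ independent
   looks, the undercount confidence is $1 - q^m$; records are accepted
   at confidence > 0.99. This rule is a documented stand-in with the
   same contract as the published acceptance criterion (whose exact
   procedure is described elsewhere); simulations over $N \in \{1,2,3\}$
   verify that accepted records undercount in under 1% of cases.
5. **Ramp fits** (`iv_ramp_fit()`): closed-channel (leak) current is
   estimated by a linear fit over level-0 samples and subtracted;
   open-channel points are fitted with an order-1 (ohmic) or order-4
   (permeant-ion-block regime) polynomial; slope conductance at 0 mV is
   the linear coefficient.
6. **Group comparisons** (`normalize_po()`): $P_o$ divided by the
   reference-group mean, the reference-mean uncertainty propagated into
   the normalized standard error, percent reduction reported.

The simulator (`simulate_trace()`) draws $N$ independent two-state
Markov channels with exact exponential sojourns, sums them, scales to
current, adds Gaussian noise and applies a Gaussian FIR filter with
−3 dB at the cutoff (a true Bessel response is not needed for these
tests). The uninhibited preset has $P_o = 0.65$ with 10 ms mean open
time, a 5 pA unitary current and 0.8 pA rms noise — the plateau open
probability of the maximally stimulated channel; the dwell scale is this
package's choice where no value is published. Supplying `ca_er_uM` sets
the target $P_o$ through the Hill relation below, holding the mean open
time fixed (the inhibitor's dominant effect being on closed durations).

## 3. The inhibitory Hill dose-response

Luminal Ca²⁺ suppression of open probability follows

$$
P_o = P_{\max}\left[1 + \left(\frac{[\mathrm{Ca}^{2+}]_{ER}}{K_{inh}}
  \right)^{H_{inh}}\right]^{-1},
$$

with defaults $P_{\max} = 0.65$, $K_{inh} = 260$ µM, $H_{inh} = 2.3$ —
the published fit values for the ANXA1-mediated mechanism.
`fit_hill()` minimizes squared error on the *mean* $P_o$ per
concentration (unweighted by default, matching a fit to averages;
$1/\mathrm{sem}^2$ weighting by flag) using Levenberg–Marquardt from a
deterministic multi-start: $P_{\max}$ at the observed maximum, $K_{inh}$
at the first concentration below half-maximum, $H_{inh} \in \{1,2,4\}$.
$P_{\max}$ floats by default with a `fix_p_max` option, since whether
the published fit fixed the plateau is not stated. Flat datasets are
rejected as unidentifiable; datasets not sampling the descent are
flagged. Standard errors come from the local curvature. Concentrations
are µM throughout; the reader converts an `ca_er_nM` column.

The generator (`simulate_po_dataset()`) simulates, for each of 8
log-spaced concentrations over 0.07–600 µM, 10 event-level gating
records of 30 s whose true $P_o$ follows the relation above; each record
contributes its occupied-time fraction. Round-trip recovery over 25
seeds reproduces $K_{inh}$ and $H_{inh}$ to well within the ±15%/±20%
bands used in the acceptance checks, and the median absolute $K_{inh}$
error over 100 seeds stays inside the ±14 µM scale of the published
standard error.

## 4. Single-cell Ca²⁺-imaging classification

Ratiometric (Fura-2, 340/380 nm) traces sampled every 2 s are
normalized per cell to $R/R_0$, the mean over the first 30 s
(`normalize_ratio()`). The logic tests (`classify_cell()`) are:

* **Inclusion**: every baseline frame within $[0.75, 1.25]$ *and* every
  frame of the last 30 s of washout below 1.5. The strict every-frame
  reading is the default for both tests; `washout_all_frames = FALSE`
  relaxes the washout test to the window mean.
* **Responder**: post-stimulus maximum $R/R_0 \ge 2.0$.
* **Oscillating**: coefficient of variation
  ($100 \cdot \mathrm{sd}/\mathrm{mean}$) above 15% over the analysis
  window, which runs from the end of the initial Ca²⁺ signal to the end
  of stimulation. The end of the initial signal is not defined in the
  published rule; here it is the first time after the first
  post-stimulus peak at which $R/R_0$ falls below baseline + 50% of the
  peak excess, or peak time + 20 s if it never does. The choice is
  recorded in the per-cell output (`analysis_window_s`).
* **Pattern**: the published oscillating/spiking distinction was
  qualitative; it is made quantitative here — "periodic oscillation"
  when the dominant positive-lag autocorrelation peak of the window
  exceeds 0.4, else "random spiking". This is an extension of a
  qualitative rule, not a published criterion.

Population responses (`fit_rise()`) use a 90 s pre-agonist baseline;
$\Delta R(t) = \Delta R_{\max}(1 - e^{-(t - t_0)/\tau})$ is fitted over
the rising phase (stimulus to first maximum) with $t_0$ fixed at the
stimulus, so the fitted curve passes $(1 - 1/e)\Delta R_{\max}$ at
$t_0 + \tau$. Group effects on $\Delta R_{\max}$ and $1/\tau$ are
normalized to the control mean with Welch t-tests
(`normalize_to_control()`).

The cell generator (`simulate_cells()`) mixes four archetypes with
known labels: non-responders, smooth single transients (5 s rise, 8 s
decay — fast enough that the decay tail keeps the window CV safely below
the 15% criterion), periodic spike trains (40 s period) and
uniformly-jittered (±18 s) random trains, over a 3% multiplicative
baseline noise and a random per-cell gain that must cancel in $R/R_0$.
Classification of generated fields reproduces the archetype labels
exactly across seeds; real recordings with drift, partial washout or
photobleaching will exercise the exclusion branches far more often.

## 5. Problem sizes and reproducibility

Every generator takes an explicit integer seed and returns its ground
truth; identical (config, seed) pairs are bit-identical. The shipped
test suite uses reduced but honest problem sizes chosen for a laptop:
SBC at $p = 40$ with 200 replicates, lfsr calibration pooled over 15
replicates at $p = 60$, 60-trace ensembles for the channel-count rule,
and 25/20-seed recoveries for the Hill and gating pipelines. The
acceptance script (`scripts/acceptance.R`) recomputes the Hill and
gating recoveries and the paper-scale design conformance from scratch at
any seed.

## Known limitations

* The count model treats runs as conditionally Poisson given the block
  random effect; residual over-dispersion beyond that (digestion
  efficiency, shared contaminants) is not modelled.
* Idealization is threshold-based, not hidden-Markov; it will
  under-resolve flickery gating near the dead time, and dwell means are
  biased upward in that regime.
* The channel-count confidence rule treats looks as independent and
  identical channels as exchangeable; cooperative gating would violate
  both.
* The oscillation classifier sees only the sampled $R/R_0$; oscillations
  faster than the 2 s frame interval alias.
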