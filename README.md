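# ercal

Analysis pipelines for studying how **luminal Ca²⁺ regulates the InsP₃
receptor (InsP₃R)**, the principal Ca²⁺-release channel of the
endoplasmic reticulum. The package is aimed at groups combining
affinity-enrichment proteomics, nuclear patch-clamp electrophysiology
and ratiometric Ca²⁺ imaging to dissect ER-luminal regulation of Ca²⁺
release — the workflow that identified annexin A1 (ANXA1) as an
ER-luminal inhibitor of the channel.

Four pipelines, each paired with a seeded synthetic-data generator that
emits data with exactly the statistical structure the analysis assumes:

1. **Spectral-count enrichment** (`fit_count_model`, `compute_lfsr`).
   Bait-versus-scrambled-control pull-down counts $y_{gct}$ (protein
   $g$, block $c$, condition $t$) are modelled as

   $$y_{gct} + 1 \sim \mathrm{Poisson}(\lambda_{gct}), \quad
     \log \lambda_{gct} = \log\mu_c + \alpha_{gc} + t\beta_g,$$

   with $\alpha_{gc} \sim N(0, \sigma_c^2)$,
   $\beta_g \sim \pi_0\delta_0 + (1-\pi_0)N(0, \tau^2)$,
   $\pi_0 \sim \mathrm{Beta}(0.5, 0.5)$,
   $\sigma_c^{-2}, \tau^{-2} \sim \mathrm{Gamma}(1, 1)$ and $\mu_c$ a
   fixed plug-in. MCMC (exact conjugate + exact gridded Gibbs +
   adaptive Metropolis) yields the local false sign rate
   $\mathrm{lfsr}_g = P(\beta_g \le 0 \mid Y)$; proteins with
   $\mathrm{lfsr} \le 0.2$ are called enriched.
2. **Single-channel gating** (`idealize`, `open_probability`,
   `dwell_times`, `channel_count_confidence`, `iv_ramp_fit`).
   Half-amplitude multilevel idealization with hysteresis and dead-time
   merging; occupancy-time open probability; dwell-time means;
   active-channel counting with an explicit >99%-confidence undercount
   rule; linear and 4th-order polynomial current–voltage ramp fits.
3. **Dose inhibition** (`hill_po`, `fit_hill`). Nonlinear
   least-squares fit of the inhibitory Hill equation
   $P_o = P_{\max}[1 + ([\mathrm{Ca}^{2+}]_{ER}/K_{inh})^{H_{inh}}]^{-1}$
   to mean open-probability data across luminal Ca²⁺ concentrations.
4. **Ca²⁺-imaging classification** (`classify_cell`, `fit_rise`,
   `normalize_to_control`). The baseline/washout/responder/%CV logic
   tests for Fura-2 $R/R_0$ traces, and single-exponential rise fits
   ($\Delta R_{\max}$, $\tau$) for population responses.

## Worked example

Simulate a dose-inhibition experiment at the package defaults
($P_{\max} = 0.65$, $K_{inh} = 260$ µM, $H_{inh} = 2.3$; 8 log-spaced
concentrations over 0.07–600 µM, 10 simulated 30 s gating records per
concentration) and refit the Hill equation:

```r
library(ercal)
d <- simulate_po_dataset(seed = 20260923)
fit <- fit_hill(d$data)
print(fit)
#> Inhibitory Hill fit
#>   P_max = 0.651
#>   K_inh = 259.2 uM
#>   H_inh = 2.35
#>   RSS   = 2.33e-05
```

The fitted half-maximal inhibitory concentration (259.2 µM) and Hill
coefficient (2.35) recover the generator truth (260 µM, 2.3): the
steep, cooperative suppression of channel opening that sets in above
physiological resting $[\mathrm{Ca}^{2+}]_{ER}$.

The full workflow lives in `analysis/` as numbered stages, each writing
its tables under `results/`:

```sh
Rscript analysis/01_count_enrichment.R    # enrichment.tsv, run_summary.json
Rscript analysis/02_gating_statistics.R   # gating_stats.tsv, gating_normalized.tsv
Rscript analysis/03_dose_response.R       # po_dataset.tsv, hill_fit.json
Rscript analysis/04_cell_signals.R        # cell_classification.tsv, population_rise.tsv
```

Stage 1, for example, simulates a paper-scale pull-down (486 proteins,
3 blocks), fits the spike-and-slab model and reports the selection —
on the shipped seed it selects 6 proteins at lfsr ≤ 0.2, all of them
true binders, with an estimated global false sign rate of 0.017.

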