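# burstepi

Quantitative analysis of transcriptional bursting and its chromatin
determinants, for researchers studying how nucleosome remodeling, histone
levels and preinitiation-complex assembly shape the activity of an
inducible gene — the *GAL10*-style single-allele, single-transcription-site
setting in budding yeast.

The package covers four linked analyses:

1. **Live-cell bursting.** Time-lapse stacks of a PP7/MS2-labelled
   transcription site (TS) are drift-corrected, segmented (Otsu +
   watershed) and quantified by iterative Gaussian-mask photometry with a
   6σ/4σ/carry-over detection cascade. Traces are binarized at five times a
   Lorentzian-fitted background width, cleaned (single-frame bursts
   deleted, then single-frame gaps merged), and reduced to per-cell burst
   parameters: active fraction, induction time, burst duration, time
   between bursts, burst intensity. Populations are summarized by a
   1,000-repetition bootstrap over cells.
2. **Dynamic epistasis.** The fractional change of each parameter under a
   perturbation is the ratio of bootstrap means,
   `f = m_perturbed / m_reference`, with errors propagated assuming
   independent conditions. A double perturbation is compared with the
   multiplicative expectation `f_A·f_B` through
   `z = (f_obs − f_A f_B)/√(sd_obs² + sd_exp²)`: `z > 2` synergistic
   (redundant processes), `z < −2` buffered (same pathway/opposing),
   otherwise independent.
3. **Rate-limiting steps and subpopulations.** Induction-time histograms
   (1-min bins) are fit by constrained least squares with
   `A·Γ⁻¹(k) θ⁻ᵏ x^{k−1} e^{−x/θ}`; the shape `k` estimates the number of
   sequential rate-limiting activation steps. Interval distributions use
   the same fit with `A = 1, k ≥ 1`; burst intensities use a log-normal.
   Conditions with `R² < 0.8` are flagged as candidate mixtures.
4. **smFISH and MNase-seq.** Nascent RNA counts from 3D spot tables
   (median-cytoplasmic normalization, ≥ 5-RNA activity rule), cell-cycle
   staging from a 2-component DAPI Gaussian mixture, and promoter
   nucleosome analysis from MNase fragments: 95–225 bp filter,
   per-chromosome normalized coverage, −1/+1 calling around the smoothed
   coverage minimum, metagene profiles, NDR-sorted log2 fold-change maps,
   +1 shifts and 8-bp TATA-window occupancy.

A synthetic-data module (`simulate_traces()`, `render_movie()`,
`simulate_smfish()`, `simulate_mnase()`) generates every input with known
ground truth, so the entire chain is testable offline.

## Worked example

Simulate a reference and a "depleted" population (the depletion doubles the
mean OFF time), run the measurement chain, and fit the induction-time
distribution:

```r
library(burstepi)

p <- burst_sim_params(n_steps = 3, step_rate = 0.5, mean_on = 2, mean_off = 8,
                      active_prob = 0.8, mean_intensity = 1000, bg_sd = 20,
                      seed = 1)
sim  <- simulate_traces(p, 200)
recs <- burst_records(sim$traces, bg_width = 20)
s    <- summarize_population(recs, n_boot = 1000, seed = 1, condition = "reference")
s
#> population_summary [reference]: 163 active / 37 inactive (fraction 0.815 +/- 0.027)
#>   induction_time        7.984 +/- 0.522 (bootstrap, n = 163)
#>   burst_duration        2.415 +/- 0.066 (bootstrap, n = 765)
#>   inter_burst_time      8.320 +/- 0.278 (bootstrap, n = 631)
#>   burst_intensity     996.445 +/- 2.618 (bootstrap, n = 163)

p2 <- p; p2$mean_off <- 16; p2$seed <- 2L
s2 <- summarize_population(burst_records(simulate_traces(p2, 200)$traces, 20),
                           n_boot = 1000, seed = 2, condition = "depleted")
fractional_change(s2, s, "inter_burst_time")
#> effect_estimate [inter_burst_time] depleted vs reference: f = 1.611 +/- 0.095

fit_gamma_induction(s$parameters$induction_time$values)
#> gamma_fit: A = 1.000, k = 2.598, theta = 2.666, R^2 = 0.9184
```

Reading the output: 163 of 200 cells burst within the hour
(0.815 ± √n-propagated error); bursts last ~2.4 min with ~8.3 min between
them (bootstrap mean ± s.d.; the slight excess over the generative 2 and
8 min is the documented frame-discretization effect of the cleanup rules).
The depletion raises the time between bursts by a factor 1.61 ± 0.10
(generatively 2.0; a 60-min movie right-censors the longest OFF intervals,
see the vignette's censoring discussion). The Gamma fit estimates ~2.6–3
rate-limiting steps from the induction delays of 163 cells
(generative truth: 3).

Two such fractional changes combine into an epistasis call with
`expected_double()` and `classify_interaction()`; smFISH tables and MNase
fragment sets flow through `quantify_cells()`/`classify_cell_cycle()` and
`make_coverage()`/`call_plus_one()` the same way (see the vignette
`vignettes/bursting-methods.Rmd` for the models, parameter meanings and
design choices).

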