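# ilextract

Quantitative analytics for ionic-liquid depletion of heme/hemoglobin from
serum and its effect on downstream immunoassays.

Hemolysed serum interferes with clinical assays twice over: free
heme/hemoglobin dominates the visible spectrum through the Soret band at
410 nm, and it binds nonspecifically in immunoassays, inflating apparent
analyte levels. Shaking serum with a hydrophobic imidazolium ionic liquid
(IL) forms a biphasic system that selectively extracts heme/hemoglobin
within minutes. `ilextract` is for analytical chemists and assay developers
who need the numbers around that workflow:

* **spectra** — Beer–Lambert quantification at the Soret band
  (`A = s·c`, default `s = 1/0.15` per mg/mL at 410 nm) and extraction
  efficiency `100·(A_before − A_after)/A_before`;
* **kinetics** — the reversible first-order biphasic model
  `dC_aq/dt = −k1·C_aq + k2·(q − C_aq·V_aq)/V_IL`, its closed-form solution
  `C_aq(t) = C∞ + (C0 − C∞)·exp(−a·t)` with `a = k1 + k2·V_aq/V_IL`,
  least-squares estimation of `(k1, k2)` and equilibration times;
* **partition** — equilibrium models `C_IL = S0·C_aq` (constant separation
  ratio) and the saturating `C_IL = S0·C_aq/(1 + C_aq/K)`, isotherm fitting
  with automatic regime selection, and depletion prediction by mass balance;
* **elisa** — four-parameter logistic calibration
  `A(c) = A_bot + (A_top − A_bot)/(1 + (c/IC50)^h)` for competitive
  cotinine ELISA, its analytic inverse, and replicate accuracy/precision
  statistics (mean, sample SD, CV%, signed relative error);
* **freeenergy** — Bennett Acceptance Ratio estimation from forward/reverse
  work samples and water→IL transfer free energies with propagated
  uncertainty;
* **synthetic data** — a deterministic generator for every input the
  pipeline consumes, plus a CLI (`inst/exec/ilextract`) over all of it.

## Worked example

Fit extraction kinetics to a simulated shaking-time experiment, predict
equilibrium depletion, and quantify what removing hemoglobin does to a
cotinine determination:

```r
library(ilextract)

## 3 mL serum + 0.7 g ionic liquid (density 1.12 g/mL), 0.125 mg/mL hemoglobin
sys <- extraction_system(v_aq = 3, q = 0.375, il_mass = 0.7)
fit <- fit_kinetics(make_kinetic_trace(scenario_config(seed = 7)), sys)
fit
#> Reversible first-order extraction fit (n = 8)
#>   k1 = 0.848111 +/- 0.0352 1/min
#>   k2 = 0.00958762 +/- 0.00275 1/min
#>   RSS = 4.44553e-05, converged: TRUE
equilibration_time(fit$model, 0.99)   # 5.15 min: shake at least ~5 min

predict_depletion(partition_model("hyperbolic", s0 = 90, k = 0.1), sys)
#> $c_aq_eq  0.00673   $c_il_eq  0.568   $efficiency_percent  94.6
```

The fitted rate constants say the aqueous phase relaxes with
`a = k1 + k2·V_aq/V_IL ≈ 0.89` per minute, so 99% of the approach to
equilibrium takes about 5 minutes; the partition model then predicts ~95%
of the hemoglobin ends up in the IL phase at this loading.

The bundled replicate panel (`cotinine_replicates()`) carries triplicate
cotinine determinations at a 20 ng/mL spike across hemoglobin levels,
before and after IL extraction. At 0.2 mg/mL hemoglobin:

```r
panel  <- cotinine_replicates()
before <- subset(panel, hb_mg_per_ml == 0.2 & !extracted)
after  <- subset(panel, hb_mg_per_ml == 0.2 & extracted)
rb <- replicate_stats(replicate_set(before$concentration_ng_per_ml, nominal = 20))
ra <- replicate_stats(replicate_set(after$concentration_ng_per_ml, nominal = 20))
rb
#> mean 26.436  sd 1.548  CV% 5.856  RE% +32.18
ra
#> mean 19.982  sd 0.630  CV% 3.153  RE% -0.09
accuracy_comparison(rb, ra)$decrease_points
#> 32.27
```

Hemoglobin at 0.2 mg/mL inflates the apparent cotinine by 32% of the
nominal value; after extraction the determination is accurate to −0.09%
and more precise (CV 3.2% vs 5.9%) — a 32.27-point accuracy improvement.

On the modeling side, the BAR estimator and cycle arithmetic:

```r
w <- make_work_samples(scenario_config(seed = 7))   # Crooks-consistent Gaussians
bar_estimate(w)
#> BAR estimate: dG = 10.0042 +/- 0.0045 kJ/mol (n_F = 100000, n_R = 100000, T = 298 K)

tr <- transfer_free_energy(transfer_cycle(
  free_energy_leg("decouple-in-water", -100.0, 3.0, "heme"),
  free_energy_leg("decouple-in-IL",      27.3, 4.1, "heme")))
tr                        #> transfer water->IL (heme): dG = -127.3 +/- 5.1 kJ/mol
classify_preference(tr)   #> "IL-preferring"
```

A transfer free energy significantly below zero means the solute prefers
the ionic liquid over water — the thermodynamic driving force behind the
depletion.

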