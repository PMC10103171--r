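# hdxensemble

Quantify conformational-state populations from hydrogen-deuterium
exchange mass spectrometry (HDX-MS) data by maximum-entropy
reweighting of a candidate structural ensemble.

HDX-MS measures peptide-level deuterium uptake that averages over a
protein's conformational equilibrium. For proteins that interconvert
between structurally distinct states -- e.g. the outward-facing (OF)
and inward-facing (IF) states of an alternating-access transporter --
this package turns that averaged signal into fractional populations:

1. **Forward model.** Per-residue protection factors are predicted
   from each frame's amide heavy-atom contacts and hydrogen bonds,
   `ln PF_i = < beta_C N_C(i) + beta_H N_H(i) >_w` (defaults
   `beta_C = 0.35`, `beta_H = 2.0`), combined with Bai-Englander
   intrinsic exchange rates under EX2 kinetics,
   `D_i(t) = 1 - exp(-k_int,i t / PF_i)`, and averaged over each
   peptide's exchange-competent residues.
2. **Absolute data.** Raw uptake (Da) is normalized against a
   maximally deuterated (MaxD) control, which cancels static
   back-exchange; peptides outside the structurally resolved span or
   with negative mean deuteration are excluded.
3. **Reweighting.** Frame weights minimize
   `gamma/2 * sum (D_pred - D_exp)^2 + KL(w || w0)` on the simplex.
   A gamma scan selects the fit whose apparent work
   `W_app = kB T KL(w || w0)` best approaches a budget (default
   5 kJ/mol) without exceeding it, guarding against overfitting.
   State populations are summed frame weights, with uncertainty from
   three systematic-subsampling reruns, per-peptide RMSE and
   peptide-exclusion robustness checks, and optional re-optimization
   of `(beta_C, beta_H)` against the data.

A hybrid significance test for differential HDX between two states
(global 99%-CI threshold plus per-cell Welch's t-test) and a
synthetic two-state data generator (so everything runs without
external data) are included. Intended users are structural mass
spectrometrists and simulators integrating HDX-MS with MD ensembles.

## Worked example

Recover a known 80% OF / 20% IF mixture from synthetic uptake data,
starting from a 50:50 candidate ensemble:

```r
library(hdxensemble)

spec   <- synthetic_spec(seed = 1)          # truth: 80% OF / 20% IF
syn    <- make_target_uptake(spec)          # raw Da + MaxD control
target <- filter_peptides(normalize_to_maxd(syn$raw, syn$maxd), c(1, 60))
rates  <- intrinsic_rates(spec$sequence)    # pD 7.4, 298 K

scan <- gamma_scan(syn$ensemble$features, rates, beta_params(), target,
                   state = syn$ensemble$state)
scan
#> hdx_reweight: 200 frames, gamma = 1000, W_app = 0.7882 kJ/mol,
#>   MSE 0.02082 -> 2.523e-05
populations(scan$weights, syn$ensemble$state)
#>   state  fraction sd
#> 1    IF 0.2080102 NA
#> 2    OF 0.7919898 NA
```

The scan reduces the misfit by three orders of magnitude while
spending only ~0.8 kJ/mol of apparent work, and the summed OF weight
(79.2%) recovers the generating mixture to within a percentage point.
`subsample_uncertainty()` on the same inputs reports 79.0 +/- 0.8%
(n = 3), bracketing the truth.

The `analysis/` directory holds the full narrative workflow as
numbered scripts -- simulate a WT-like (IF-rich) and a mutant-like
(OF-rich) state, map significant differential HDX, reweight both,
refit the scaling parameters, and run robustness checks -- each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_differential_hdx.R
Rscript analysis/03_reweight_populations.R
Rscript analysis/04_beta_refit.R
Rscript analysis/05_robustness.R
```

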