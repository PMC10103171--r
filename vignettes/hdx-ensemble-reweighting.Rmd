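---
title: "Quantifying conformational populations from HDX-MS by maximum-entropy ensemble reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational populations from HDX-MS by maximum-entropy ensemble reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxensemble)
```

## The problem

Hydrogen-deuterium exchange mass spectrometry (HDX-MS) reports, at
proteolytic-peptide resolution, how fast backbone amides exchange
their hydrogens in deuterated buffer. For a protein interconverting
between conformational states -- the canonical example being an
alternating-access transporter cycling between outward-facing (OF)
and inward-facing (IF) states -- the measured uptake is an
equilibrium-weighted average over the whole conformational ensemble.
Differential HDX can say *which* regions become more or less
protected between conditions, but not *how much* of each state is
present.

`hdxensemble` closes that gap. Given (i) absolute (MaxD-normalized)
uptake tables and (ii) a candidate ensemble of structural frames with
state labels (for example a 50:50 pool of OF and IF conformers from
molecular-dynamics sampling), it adjusts the frames' statistical
weights by maximum-entropy reweighting until the forward-modelled
uptake fits the data, then reads off each state's fractional
population as the summed weight of its frames.

## The forward model

Per-residue protection is modelled phenomenologically from two amide
features counted in every frame: heavy-atom contacts around the amide
nitrogen ($N_C$, within 6.5 Å, excluding residues $i-2 \dots i+2$)
and hydrogen bonds at the amide hydrogen ($N_H$, oxygen acceptors
within 2.4 Å). Under frame weights $w$,

$$\ln \mathrm{PF}_i \;=\; \Big\langle \beta_C\, N_C(i) + \beta_H\, N_H(i) \Big\rangle_w ,$$

with $\beta_C = 0.35$ and $\beta_H = 2.0$ by default, the values of
the original empirical calibration against soluble-protein HDX data.
The ensemble average is taken over the exponent (the per-frame linear
combination), matching the convention of the established
reweighting-oriented implementations of this model; averaging
per-frame deuteration instead is deliberately not offered.

Exchange kinetics follow the EX2 limit. Intrinsic rates $k^{int}_i$
come from the poly-DL-alanine reference rates with side-chain,
neighbor and terminal corrections (D2O constants; reference
$\log_{10} k_A = 2.04$, $\log_{10} k_B = 10.36$,
$\log_{10} k_W = -1.5$ at 293 K; activation energies 14/17/19
kcal/mol; $pK_D = 15.05$). Aspartate and glutamate are treated as
deprotonated and histidine as protonated; the labeling conditions
default to pD 7.4 and 298 K and are configurable, since real studies
must supply their own buffer conditions. Then

$$D_i(t) = 1 - \exp\!\big(-k^{int}_i\, t\, / \mathrm{PF}_i\big),$$

and a peptide's deuterated fraction is the unweighted mean of
$D_i(t)$ over its exchange-competent residues. Residue 1 of the
protein, prolines, and the first residue of each peptide are excluded
(no exchange-relevant amide or near-instant back-exchange; the
per-peptide skip count is configurable 0-2).

Predictions are compared directly with experimental fractions
normalized against a maximally deuterated (MaxD) control. Static
back-exchange losses are multiplicative per peptide, so the MaxD
ratio cancels them; no further back-exchange correction is applied.
Normalized values may fall outside $[0,1]$ through noise and are
preserved; peptides with negative mean deuteration at any exposure,
or extending beyond the residues resolved in the candidate
structures, are excluded before fitting (`filter_peptides()`), with
every exclusion logged.

## Differential HDX

`hybrid_test()` implements the hybrid significance criterion used for
peptide-level difference maps: an uptake difference is significant
only if it exceeds a global 99%-confidence threshold
$t_{\mathrm{crit}}(\alpha, \mathrm{df})\sqrt{s_A^2/n_A + s_B^2/n_B}$
built from pooled replicate variances *and* a per-cell Welch's
$t$-test gives $p < \alpha$ (default $\alpha = 0.01$). Pooling is
global by default, with a per-exposure mode, since either choice is
defensible; no further multiple-testing correction is applied beyond
the conjunction, with the conjunction itself strictly more
conservative than either criterion alone. `woods_summary()` projects
significant peptides onto residues (protected / deprotected /
nonsignificant / no-coverage, majority vote, ties nonsignificant).

## Maximum-entropy reweighting

Weights are fitted by minimizing

$$G(w) \;=\; \frac{\gamma}{2} \sum_{\mathrm{peptide},\,t}
  \big(D^{\mathrm{pred}}_{p,t}(w) - D^{\mathrm{exp}}_{p,t}\big)^2
  \;+\; \sum_j w_j \ln \frac{w_j}{w^0_j}$$

over the simplex. The relative-entropy term keeps the solution as
close as possible to the prior (candidate) weights for a given fit
quality; $k_B T$ times its value is the *apparent work*
$W_{\mathrm{app}}$, the thermodynamic cost of biasing the ensemble.
The tightness-of-fit coefficient $\gamma$ is scanned over a log grid
(default $10^{-2}$ to $10^3$, 6 points per decade) and the selected
solution is the one whose $W_{\mathrm{app}}$ comes closest to a work
budget (default 5 kJ/mol) without exceeding it -- the standard
decision-plot guard against overfitting. When even the largest
$\gamma$ stays below the budget (common when the target is nearly
noiseless and the candidate pool contains the truth), the
largest-$\gamma$ result is returned with a warning.

Numerically, the objective is minimized by BFGS on log-weights under
a softmax parameterization (iterates stay on the simplex exactly),
with an analytic gradient. Three safeguards matter in practice:

* **Gamma continuation.** A cold start at large $\gamma$ can
  overshoot into the flat region of the softmax where gradients
  vanish; each cold solve therefore warms up through
  $\gamma/10^3, \gamma/10^2, \gamma/10$.
* **Warm starts and candidate exchange.** Along the scan each
  $\gamma$ starts from the previous solution; afterwards every
  solution is re-polished from any other $\gamma$'s solution that
  lowers its objective. Besides being a cheap multi-start, this
  enforces the pairwise optimality relations that imply
  $W_{\mathrm{app}}$ non-decreasing and misfit non-increasing in
  $\gamma$, so decision plots are clean.
* **Monotone acceptance.** A solve never returns a point with higher
  objective than its start, which guarantees
  `mse_final <= mse_initial`. Convergence is declared when the
  maximum relative weight change falls below $10^{-8}$ (or the
  objective is stationary to $10^{-13}$ relative); $\gamma = 0$
  short-circuits to the prior weights exactly.

`populations()` sums final weights per state label.
`subsample_uncertainty()` repeats the whole scan on $k = 3$
interleaved (stride-$k$) frame subsets -- a deterministic reading of
"systematic subsampling"; a seeded random partition is available --
and reports the mean and SD over subsets. `peptide_rmse()` and
`exclusion_robustness()` flag error-prone peptides and show how much
the populations depend on them, and `reweighted_distribution()`
re-histograms any per-frame scalar (e.g. an interdomain centroid
distance) under the final weights.

## Re-optimizing the scaling parameters

Long-timescale ensembles sample more structural fluctuation than the
simulations the original $\beta$ calibration used, so `fit_betas()`
re-optimizes $(\beta_C, \beta_H)$ against a dataset with weights held
fixed: mean-squared-deviation objective on deuterated fractions, a
21×21 grid pre-scan over $[0,2] \times [0,10]$ to avoid local minima,
then restarted Nelder-Mead refinement from both the best grid point
and the caller's start, keeping the better optimum. The protocol
details are the package's own reconstruction (grid density, local
search, fixed-weight objective) and are configurable. Degenerate
directions are detected rather than papered over: if a feature is
identically zero across frames, its $\beta$ is reported
non-identifiable at its initial value with a warning, and solutions
on the box boundary are flagged.

## The synthetic study

Because a real benchmark requires microsecond MD trajectories and
deposited HDX-MS raw data, the package ships a generator that
reproduces the *statistical* structure of a two-state transporter
study at desk scale, and the whole test suite runs against it:

* 60 residues (a fixed default sequence with one proline), three
  blocks: an extracellular face, a core, an intracellular face.
* Two states, 100 frames each. In OF the extracellular face is open
  (Poisson contact mean $\lambda_C = 6$, per-bond H-bond probability
  $p_H = 0.4$, two bonds maximum) and the intracellular face closed
  ($\lambda_C = 13$, $p_H = 0.85$); IF mirrors this; the core
  ($\lambda_C = 10$, $p_H = 0.7$) is state-independent. A mild
  deterministic per-residue modulation avoids identical residues.
  With the default betas these profiles put peptide deuteration in
  the informative part of its range across exposures of 30, 300 and
  3600 s at the default intrinsic-rate scale.
* An overlapping peptide map (18 peptides, lengths 6-12), 3
  replicates, Gaussian replicate noise of SD 0.01 on the normalized
  scale, a per-peptide static back-exchange retention drawn once from
  U(0.6, 0.9), and a consistent MaxD control -- so MaxD normalization
  cancels the back-exchange exactly at zero noise.
* A known ground-truth mixture, 80% OF / 20% IF by default, while the
  candidate ensemble used for reweighting is the uniform 50:50 pool.

Everything is a pure function of the spec and its seed. What passing
tests on this generator show is that the estimator recovers known
mixtures from data with the assumed noise structure; what they cannot
show is robustness to forward-model misspecification against real
structures (real $N_C$/$N_H$ are correlated along the chain and
between frames, back-exchange is not exactly static, and EX1-like
kinetics are outside the model). Those caveats are inherent to the
approach, not to the implementation, and motivate the RMSE /
exclusion / $\beta$-sensitivity checks above.

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)            # truth: 80% OF / 20% IF
syn <- make_target_uptake(spec)
target <- filter_peptides(normalize_to_maxd(syn$raw, syn$maxd), c(1, 60))
rates <- intrinsic_rates(spec$sequence)

scan <- gamma_scan(syn$ensemble$features, rates, beta_params(), target,
                   state = syn$ensemble$state)
populations(scan$weights, syn$ensemble$state)
```

## Numerical choices and limitations

* Distance cutoffs use closed comparisons (`<=`); counts are then
  non-decreasing in the cutoff, which is property-tested.
* A missing amide hydrogen is rebuilt 1.01 Å from N opposite the
  bisector of its bonded heavy atoms (CA and the preceding C); this
  is adequate for counting 2.4 Å acceptor contacts but is not a
  force-field placement.
* Waters and non-oxygen acceptors are ignored by default; both are
  deliberate simplifications of the published feature definitions.
* The problem sizes used throughout (60 residues, 200 frames, 18
  peptides, 3 exposures) are the package's desk-scale defaults chosen
  so the complete analysis reruns in minutes; all of them scale up
  through the spec and function arguments.
* Fit cells are equally weighted; replicate-SD weighting of cells is
  a possible extension, currently not implemented.
* The entropy-regularized objective is not convex in $w$ because the
  forward model is nonlinear; the continuation/multi-start scheme has
  been reliable on every tested ensemble, and 2-3-frame solutions are
  verified against exhaustive simplex grid search in the test suite.
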