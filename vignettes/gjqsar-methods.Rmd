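---
title: "Methods: potency modeling of Cx43 gap-junction inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: potency modeling of Cx43 gap-junction inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjqsar)
```

## The scientific problem

Gap junctions (GJs) built of connexin-43 (Cx43) couple adjacent cardiac
myocytes electrically; pharmacological modulation of their conductance is
of interest for arrhythmia and other communication-dependent conditions,
but known GJ inhibitors are non-specific and computational screening
pipelines are needed to prioritize candidates. `gjqsar` implements such a
pipeline for a panel of 17 compounds spanning terpenes, anthranilic acid
derivatives, quinolines, anticoagulants, triterpenoids, a glycoside, a
pyranoxanthone, an organoboron compound and a fatty alcohol, each with a
measured half-maximal inhibitory concentration (eIC50) against Cx43 GJ
conductance determined by patch clamp or metabolic-communication assays.

Potency is handled internally on a single scale, $-\log_{10}$ of the molar
IC50; micromolar concentrations appear only at I/O boundaries
(`neg_log_to_micromolar()`, `micromolar_to_neg_log()`). All modeling
equations operate on the log scale, which is why the data model stores
nothing in concentration units.

Three in-silico estimates of potency are covered, in increasing order of
structural detail, plus the experimental stage that validates them:

1. **Docking calibration** — an affine map from a docking program's best
   binding-affinity score (DMA, kcal/mol) to potency.
2. **Descriptor QSAR** — a three-descriptor multiple linear regression
   found by exhaustive best-subset search.
3. **Grid-field 3D-QSAR** — steric and electrostatic molecular
   interaction fields (MIFs) on a lattice around aligned molecules,
   regressed on activity by partial least squares (PLS).
4. **Dose–response** — junctional conductance from dual patch-clamp
   voltage ramps, and a three-parameter Hill fit yielding IC50 and the
   Hill coefficient.

## The compound table

The packaged dataset (`cx43_dataset()`) carries, per compound: PubChem
CID, species tag (human/rat Cx43), assay method, measured
$-\log(\mathrm{eIC}_{50})$, the three descriptors used by the packaged
QSAR model, the three per-compound model predictions, an alignment score,
and docking-eligibility flags. Species and assay tags are metadata only;
they enter no model. Exclusion flags are explicit data rather than
inferred from structure: digoxin and dihydrogambogic acid lack reliable
3D structures and 2-APB contains boron, for which the docking force field
has no parameters. `filter_docking_eligible()` removes these three,
leaving the 14 compounds available to docking-dependent and field-based
stages.

## Descriptor QSAR

The model form is
$$-\log(p\mathrm{IC}_{50}) = a_1 x_1 + \dots + a_k x_k + b,$$
fitted by QR-based ordinary least squares (`fit_ols()`); normal equations
are avoided because molecular descriptors are often strongly correlated.
Descriptors constant across the dataset are uninformative and removed
first (`drop_constant_descriptors()`).

`exhaustive_subset_search()` evaluates **every** size-$k$ subset; the
branch-and-bound tricks used by specialized packages are an optimization,
not a definition — correctness here is defined by enumeration, and the
suite cross-checks the search against an independent brute-force oracle.
The ranking key is training $R^2$ (equivalently $|R|$); adjusted $R^2$ is
reported but deliberately not used for ranking, matching the practice of
selecting the most significant correlation. Ties are broken
lexicographically by the descriptor-name tuple so results are
deterministic. The default subset size $k = 3$ is an overfitting guard
appropriate to a 17-compound dataset and is configurable.

The packaged model (`cx43_qsar_model()`) is
$$-\log(p\mathrm{IC}_{50}) = -4.87\,\mathrm{SpMin5\_Bhm}
 + 5.67\,\mathrm{SpMax3\_Bhi} - 5.70\,\mathrm{minHBd} - 7.24.$$

Two reproducibility caveats are worth stating precisely:

* The descriptor values in the table are printed to two decimals, while
  the published per-compound predictions were evidently computed from
  unrounded descriptors. Re-evaluating the model on 2-dp descriptors
  reproduces 16 of 17 printed predictions within ±0.05; the quinidine row
  differs by 0.057. This is a rounding artifact of the source table, not
  of the implementation, and the corresponding acceptance check is left
  failing rather than widening the band.
* Adjusted $R^2$ uses the standard formula
  $1 - (1 - R^2)(n-1)/(n-k-1)$. For the QSAR fit ($R^2 = 0.79$, $n = 17$,
  $k = 3$) this gives 0.74, whereas the source reports 0.77; the
  convention behind the published value is unclear and the standard
  formula is kept. For the printed 3D-QSAR column the package reports
  adjusted $R^2$ with $k = 1$, since a single latent component is the
  only count consistent with the published adjusted value.

## Docking calibration

Affinity and potency are related affinely,
$-\log(p\mathrm{IC}_{50}) = m\,\mathrm{DMA} + n$, fitted by simple least
squares (`fit_calibration()`). The fitted panel coefficients
$m = -0.18$, $n = 0.75$ ship as `paper_docking_calibration()`. Docking
runs themselves are out of scope — DMA values arrive as CSV — and the
source table prints only the mapped predictions, never the raw DMAs, so
the preset can only be validated through its intercept property
(prediction at DMA = 0 equals $n$) and by simulation with
`gen_dma_scores()`, which inverts the calibration.

## Grid-field 3D-QSAR

`build_grid()` spans the joint bounding box of all aligned molecules,
expanded by an output gap of 5.0 Å on every side and discretized at a
1.0 Å step (both configurable; these are the stated modeling settings).
Node order is x-fastest and coordinates are absolute, in the shared
alignment frame — molecular alignment itself is out of scope and inputs
are assumed pre-aligned (SDF V2000 via `read_sdf_v2000()`, with partial
charges in a data field or sidecar CSV; no charge model is computed
internally).

Two probes are implemented in `compute_mif()`:

* **Steric**: 12-6 Lennard-Jones energy summed over atoms, with an
  sp³-carbon-like probe (minimum-energy distance 4.0 Å, well depth
  0.107 kcal/mol), arithmetic-mean combination for distances and
  geometric-mean for depths. At the combined minimum-energy distance the
  pair energy is exactly $-\epsilon$.
* **Electrostatic**: Coulomb energy of a unit positive probe charge in
  vacuum (dielectric 1), $k \sum_i q_i/r_i$ with
  $k = 332.0637$ kcal·Å·mol⁻¹·e⁻².

Probe parameters were not stated by the modeling software's users and are
package choices, all configurable via `probe_params()`.

**Degenerate geometry.** A grid node exactly on an atom center would make
either sum singular. Such nodes are assigned the positive clamp value
with a warning — except under the electrostatic probe for an atom of zero
charge, whose contribution is zero everywhere, so that a fully uncharged
molecule yields an identically zero electrostatic field.

**Truncation.** Extreme values are clamped, not deleted, so field vectors
stay length-aligned across molecules (`truncate_extremes()`). The bounds
are not stated in the source (they defer to a software manual), so
conventional CoMFA-style defaults are used: steric clamped above at
+30 kcal/mol (the attractive well needs no lower clamp), electrostatic
clamped symmetrically at ±10 kcal/mol. Both are configurable, and a mask
records exactly which nodes were clamped.

**Regression.** `fit_pls()` is mean-centered PLS1 by NIPALS: successive
weight/score/loading triples maximize covariance with the deflated
response; coefficients are folded back to the original predictor scale as
$B = W (P^\top W)^{-1} q$. With as many components as the predictor rank
on a full-rank problem PLS reproduces OLS, which the suite checks against
`lm()` to 1e−8. Note that a *one*-component fit is exact only when the
response lies in the span of the first score — being a linear functional
of a single grid column does **not** guarantee this, so exact-recovery
tests use $n-1$ components. The component count is not stated in the
source; the default chooser (`select_pls_components()`) takes the
smallest count in 1–5 maximizing leave-one-out $q^2$.

**Maps.** Coefficient maps are thresholded at ±0.0002 (the stated
rendering cutoff — without it the clouds would fill the whole box) and
exported per probe and sign in OpenDX scalar-grid format
(`export_coefficient_map()`), with the data block emitted z-fastest as
the format requires.

**Far-field behavior.** Both fields vanish with distance, but at
different rates: the steric field decays as $r^{-6}$ and is below
10⁻³ kcal/mol at a 10 Å-padded box corner, while the electrostatic field
of even a *neutral* molecule decays only as the dipole $r^{-2}$ —
roughly 0.03 kcal/mol at a 20 Å-padded corner for a ±0.1 e pair. A
sub-10⁻³ electrostatic far-field bound is therefore physically
unattainable with the real Coulomb constant, and the test suite asserts
the steric bound at 10⁻³ and, for electrostatics, smallness (< 0.05) plus
strict decay with padding.

Because the original training structures (alignments and charges) are not
available, the published 3D-QSAR model itself cannot be re-trained; its
printed prediction column is validated as data (correlation with the
measured potencies) while the engine is validated by the properties above
and by parameter recovery on synthetic molecules.

## Dose–response

In the dual whole-cell patch-clamp protocol, both cells of a pair are
held at the same potential and a ramp $\Delta V_1$ (−10 mV, 20 ms,
repeated every 10 s) is applied to Cell-1 while the junctional current is
read in Cell-2 ($I_j = \Delta I_2$). Junctional conductance is
$g_j = -I_j/\Delta V_1$; with $I_j$ in nA and $\Delta V_1$ in mV the
ratio is in µS and `compute_gj()` returns nS. A negative value flags a
non-junctional artifact rather than being silently clipped.

`normalize_timecourse()` divides the plateau conductance after drug
application by the mean baseline before it. The stationary-segment rule
(mean of the final window, length configurable, default equal to the
baseline window) is a documented package choice; the exact plateau rule
used for the published recordings is unstated.

The dose–response curve is the three-parameter Hill inhibition form
$$y(C) = \frac{y_{\max}}{1 + (C/\mathrm{IC}_{50})^{h}},$$
chosen to match the sigmoidal-inhibition convention of the plotting
software cited for the original fit (the source names "a three-parameter
Hill equation" without printing it); the zero-dose baseline anchors
$y_{\max}$, and $y(\mathrm{IC}_{50}) = y_{\max}/2$ for every $h$.
`fit_hill()` minimizes the sum of squares over
$(y_{\max}, \log \mathrm{IC}_{50}, \log h)$ by multistart L-BFGS-B
($h_0 \in \{1, 2, 4\}$; IC50 started at the dose bracketing half-maximal
response and at the geometric mean of the positive doses; $y_{\max}$ at
the largest observed response) followed by a Nelder-Mead polish at
relative tolerance 1e−14; the best SSE wins. Bounds:
$y_{\max} \in (0, 1.5]$, $h \in [10^{-3}, 50]$. On noiseless data the
fit recovers generative parameters to better than 1e−6; the fitter is
scale-equivariant in concentration. Non-convergence after all starts
returns best-effort parameters with `converged = FALSE` and a warning
rather than an error.

With the experimentally determined parameters (IC50 = 30 µM, $h$ = 2.8)
the fitted curve leaves under 4% residual response at 100 µM, consistent
with the observation of complete block at that dose.

## The synthetic world

Every stage has a seeded generator producing data with exactly the
structure the stage assumes, so the pipeline is testable end to end with
no downloads:

* `gen_descriptor_dataset()` — equicorrelated Gaussian descriptors
  (pairwise correlation 0.2 by default — descriptors are correlated in
  real panels but the exact structure is irrelevant to the tests), with
  a planted three-descriptor linear activity model. Defaults mirror the
  study scale (17 compounds; planted coefficients equal to the packaged
  model's) with activity noise SD 0.3, about 10% of the observed potency
  range; the recovery tests also use a larger 40 × 30 regime where
  subset search is non-trivial.
* `gen_dma_scores()` — inverts the docking calibration with Gaussian
  affinity noise (0.3 kcal/mol in the noisy regime).
* `gen_dose_response()` — Hill responses at the experimental doses
  (0, 10, 30, 50, 100 µM) from the experimentally determined parameters
  (1, 30 µM, 2.8), times lognormal multiplicative noise with 5%
  coefficient of variation, `meanlog = 0` (median-unbiased; at 5% CV the
  mean/median distinction is ~0.1% and immaterial to the medians
  reported).
* `gen_aligned_molecules()` — random 3–10-atom point molecules with
  charges in [−0.5, 0.5] e; activity is a planted weighted sum of true
  field values at hotspot grid columns.

Each generator draws from its own stream, derived from the master seed by
a fixed per-generator offset, so adding one generator call never perturbs
another's output; generation is byte-identical under a fixed seed and
restores the caller's random state.

What the synthetic world does **not** emulate: the marginal distributions
of real computed descriptors, alignment error, conformational variability,
or the spatial autocorrelation structure of fields of real chemistry. A
green recovery test therefore establishes that the estimators are
implemented correctly (unbiased recovery of planted truth under the
stated noise), not that the published models would re-derive from raw
structures.

## In-source inconsistencies, recorded not repaired

* The discussion section quotes the d-limonene docking prediction as
  4.17 where the data table prints 4.18; the packaged fixture follows
  the table.
* The stated micromolar conversions of the d-limonene predictions are
  66, 14 and 42 µM; the first two match $10^{-4.18}$ and $10^{-4.84}$
  (66.1, 14.5 µM) but $10^{-4.35}$ is 44.7 µM, not 42. The package
  reports the computed 44.7 and documents the discrepancy.
* The QSAR adjusted-$R^2$ convention (0.77 printed vs 0.74 standard), as
  discussed above.

## Limitations

Docking itself, descriptor computation from structure, molecular
alignment, and homology-model preparation are all out of scope by design:
their outputs (scores, descriptor tables, aligned SDFs) are this
package's inputs. The packaged 3D-QSAR and docking prediction columns are
fixture data from those upstream runs and are validated statistically,
not regenerated.
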