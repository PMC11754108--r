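---
title: "Models and methods behind foldstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foldstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

foldstab analyses growth-rate-based deep mutational scans of protein
domains: selection assays in which a domain variant's cellular abundance
sets the growth rate of the cell carrying it, so that destabilizing
mutations read out as growth defects. This vignette describes the models
the package implements, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## The two-state thermodynamic model

The central model treats each domain as a two-state folder. A sequence
with folding free energy $\Delta G$ (in units of RT; negative = stable)
occupies the folded state with Boltzmann probability

$$p_f = \frac{1}{1 + e^{\Delta G}},$$

and its measured fitness (growth rate, h^-1^) is an affine function of the
fraction folded: $f = \gamma_0 + \gamma_1\, p_f$ with $\gamma_1 > 0$.
Within a family of homologous domains aligned to shared columns, the free
energy of a variant decomposes additively:

$$\Delta G = b_0 \;+\; \sum_{c\,\in\,\text{non-gap}} U[c,\, wt_h(c)] \;+\; D[c_{\text{mut}},\, aa_{\text{mut}}],$$

where $U$ holds per-(column, residue) wild-type composition energies,
$D$ holds mutation energies ($\Delta\Delta G$) shared by *all* homologues
regardless of their wild-type residue at that column, and $b_0$ is a
family intercept. The key scientific assumption is that a mutation causes
the same change in folding energy in every homologous background — i.e.
no specific epistasis; deviations from this assumption are exactly what
the epistasis module detects afterwards.

### Fitting

`fit_energy_model()` minimizes the error-weighted least squares
$\sum_i w_i\,(f_i - \gamma_0 - \gamma_1 p_f(\Delta G_i))^2 +
\lambda(\lVert U\rVert^2 + \lVert D\rVert^2)$ with analytic gradients
under L-BFGS-B. Numerical choices that matter:

* **Weight moderation.** Per-variant errors estimated from three
  replicates have heavy-tailed reciprocals (a variance estimate with two
  degrees of freedom can be nearly zero), so raw inverse-variance weights
  let single variants dominate the loss. Each variance is therefore
  shrunk halfway toward the family median variance before weighting
  (`moderation = 0.5`), the usual empirical-Bayes stabilization for deep
  mutational scanning errors. Doubling all declared errors leaves the
  optimum unchanged.
* **Warm start.** Random initialization can strand whole homologues on a
  plateau of the Boltzmann curve, where gradients vanish (a saturation
  local optimum). The fit instead inverts the affine and Boltzmann maps
  per variant (with $p_f$ clipped away from the plateaus), estimates each
  homologue's baseline from its least-destabilized variants, seeds $U$
  with the minimum-norm composition solution and $D$ with per-feature
  mean excess energies, then adds seeded jitter on restarts.
* **Robust refit.** One Huber-type pass downweights residuals beyond
  three standard errors and refits warm-started, so isolated epistatic
  outliers cannot distort the shared energies they sit on. This is what
  lets the downstream epistasis caller see planted outliers as residuals
  rather than absorbing them into $D$.
* **Gauge fixing.** Adding a constant to all residues of a column of $U$
  and subtracting it from $b_0$ changes nothing; after fitting, each
  column covered by every training homologue is centred on its observed
  residues, with the shift absorbed into $b_0$. Centring is restricted to
  fully covered columns so the step is exactly prediction-preserving even
  in gapped alignments. Features never observed in training are zeroed
  and masked.
* **Convergence** is L-BFGS-B's relative-reduction criterion
  (`factr = 1e7`, about 2e-9 relative) with up to 20,000 iterations and
  five seeded restarts; a fit that still fails, or whose $\gamma_1$
  collapses to the bound, is flagged and refused by downstream callers.

Mutation energies are reported on a comparative scale
(`rescale_energies()`): the wild type at 0 and the 2.5th percentile of
the fitness-oriented energy distribution at magnitude 1, with the
destabilizing-positive orientation, so "scaled $\Delta\Delta G$ > 0.3"
marks strong predicted destabilization. Standard errors for predictions
on unseen homologues come from the Gauss–Newton curvature of the weighted
loss at the optimum.

## Quality control and normalization

Four per-domain metrics (wild-type position in the fitness distribution,
replicate correlation for missense variants, fitness–rSASA correlation,
fitness–hydrophobicity correlation) are standardized and combined by PCA;
domains are ranked by the first component, oriented so that higher scores
track higher replicate correlation. Retention requires rank within the
cutoff, replicate correlation strictly above 0.485 and more than half of
the designed variants covered. Fitness is then normalized per domain by
the affine map sending the wild type to 0 and the 2.5th percentile of
missense-plus-wild-type growth rates to −1 (linear interpolation between
order statistics; the quantile rule is recorded because no convention is
canonical). The hydrophobicity scale only feeds a QC correlation; any
named 20-value scale can be supplied, with a standard hydropathy scale as
default. The correlation uses the mutant residue's value — the natural
reading for substitution effects — and is configurable.

## Destabilization and clinical variants

Destabilization is a one-tailed z-test ($z = f_{\text{norm}}/\sigma_{\text{norm}}$,
only fitness below the wild type can be significant) with
Benjamini–Hochberg correction applied over the whole analysis set in one
batch — matching dataset-wide statements of the form "x of y pathogenic
variants" — rather than per domain; the caller takes whatever set it is
given, so either family is available. Destabilizing means FDR < 0.1 and
negative normalized fitness; strongly destabilizing additionally requires
fitness below −0.3. Enrichments use a two-tailed Fisher's exact test with
the *sample* (cross-product) odds ratio and a Haldane–Anscombe 0.5
correction only when a cell is zero; the exact p-value sums hypergeometric
probabilities no larger than the observed table's. Classifier evaluation
uses the MCC with the strong-destabilization rule as the default positive
prediction (the class cut is configurable, since per-domain usage could
defensibly use either), population variants above an allele frequency of
1e-5 count as benign, and MCC uncertainty comes from re-drawing each
variant's fitness from its measurement error ten times.

## Functional sites

Stability explains much of a variant's evolutionary fitness, but
mutations in binding interfaces and active sites hurt fitness beyond
their stability effect. Per eligible domain, normalized stability fitness
is modelled as a sigmoid of the evolutionary score with fixed asymptotes
0 and −1, weighted by $w_i = (\max f - \min f - (f_i + 1))^2$ to
prioritize the low-stability variants that pin down the curve. Domain
eligibility requires (1) the wild type within the top 30% of the domain's
fitness distribution — the stated condition has two readings and this one
is implemented, flagged as an interpretation — and (2) a 5th-to-95th
percentile evolutionary-score range above 10. Residuals are *positive*
when a variant is more stable than its evolutionary fitness predicts;
functional mutations require a two-tailed z-test FDR < 0.1 (per domain,
because the residual null is domain-specific) *and* residual > 0.3.
Functional sites are residues whose inverse-variance-weighted mean
residual exceeds 0.3; the weighting form is not canonical and
$1/\sigma^2$ is used. The disattenuated variance explained divides the
observed correlation by the square root of the replicate reliability,
with the Pearson version reported by default and the fraction clipped at
1 with a warning when the correction overshoots.

## Epistasis

Residuals to the family energy model, in raw growth-rate units, are
z-tested (two-tailed, BH within family); epistatic variants need FDR
< 0.1 and |residual| > 0.05 h^-1^ — the magnitude gate is interpreted in
growth-rate units as printed, and a normalized-unit mode exists but
requires the per-domain scale factors explicitly (units are declared,
never guessed). Alignment columns are core when buried (rSASA < 25%) in
at least 75% of their homologues, surface when exposed in at least 75%,
changing otherwise. Per-column enrichment is Fisher's exact over
(epistatic vs not) × (at column vs elsewhere) with BH over columns;
epistatic sites need log2(OR) > 1.5 and FDR < 0.05. Enrichment operates
within one family (pooling across families would mix column coordinate
systems).

## The synthetic-data generator

`simulate_family()` runs the two-state model forwards with planted,
losslessly recorded truth, so every downstream stage has a recovery
benchmark. What it emulates, and the settings it fixes:

* **Families**: 12 homologues × 40 columns by default — large enough for
  stable energy estimation, small enough that a full fit takes seconds
  and tenfold cross-validation about a minute on one CPU. Wild types are
  sampled per column from a softmax over the negated composition
  energies (`u_sd = 0.1`, `temperature = 0.03`), giving consensus-like
  sequences with ~40–60% pairwise identity — typical of a domain family —
  and wild-type stabilities spread over a few tenths of RT around a mean
  of −2.5 RT, so wild types are folded but not so deep in the plateau
  that mutations become invisible.
* **Energies**: mutation energies are Normal with mean 3.5 RT at core
  columns and 1.5 RT at surface columns (sd 1.5), placing most variants
  in the assay's responsive range while strongly destabilizing core
  mutations saturate, as in real scans.
* **Measurement**: replicate growth rates are
  $\gamma_0 + \gamma_1 p_f + \varepsilon$ with $\gamma_0 = 0.05$,
  $\gamma_1 = 0.4$ h^-1^ (a realistic yeast growth-rate range) and noise
  chosen so the three-replicate mean has sd 0.05 h^-1^; the reported
  per-variant error is the replicate standard error, floored at 1e-4,
  reproducing the heavy-tailed error estimates real pipelines face.
  Read counts are Poisson (mean 100).
* **Function**: four surface columns (binding interfaces are exposed)
  carry a planted evolutionary-score penalty of 6 score units; the score
  itself tracks the stability signal between configurable bounds. It is a
  synthetic stand-in for a protein-language-model score — it reproduces
  the one feature the analysis needs (function beyond stability at
  specific sites), not the scale or error structure of any real
  predictor.
* **Epistasis**: `inject_epistasis()` shifts a chosen fraction of
  variants' energies by a set magnitude before measurement, sampled with
  a core bias by default. Shifts are oriented toward the responsive side
  of the curve (destabilizing on folded backgrounds, stabilizing on
  unfolded ones) with probability 0.9, because a shift deeper into either
  plateau produces no measurable fitness change in a saturating assay —
  symmetric planting would bury part of the ground truth by construction.
* **Divergence**: per-homologue `divergence` switches a fraction of
  columns to alternative plausible residues (the softmax with the
  consensus excluded), changing sequence identity without grossly
  destabilizing the homologue. Because the generator is additive by
  construction, held-out prediction for divergent homologues only decays
  through composition coverage; the divergence studies therefore plant
  context-dependent energy deviations in the same proportion as the
  divergence, emulating epistasis that grows with sequence distance —
  the mechanism the family-model literature holds responsible for the
  real decay.

What the generator does **not** emulate: insertions and deletions (the
synthetic alignment is gap-free; the encoders nevertheless handle gapped
alignments), codon-level effects and sequencing-count noise beyond
Poisson input counts, domains incompatible with two-state folding,
correlated replicate artefacts, and realistic evolutionary-score error
structure. Passing the recovery suites therefore demonstrates that the
estimators are correct and calibrated under the stated model — not that
real scans satisfy that model.

## Reference problem sizes

The test and acceptance workloads use the default family (12 × 40 ≈
9,100 variants; one fit in a few seconds), tenfold cross-validation on
it, three single-fit divergence studies, pure-null calibrations at
10,000 variants, and sigmoid fits per domain. These sizes were chosen so
a full validation run completes in a few minutes on one CPU while leaving
comfortable statistical margins.

## Known limitations

* Strongly destabilizing energies beyond the assay's dynamic range are
  only bounded, not identified; their fitted values rest on the L2
  penalty and should not be interpreted quantitatively.
* Baseline prediction for unseen homologues degrades with the number of
  wild-type residues never observed in training (reported as a coverage
  count); with few homologues this is the dominant error source.
* The per-variant z-tests trust the declared measurement errors; with
  few replicates those are noisy, and the callers' false-call rates on
  real data will exceed the nominal FDR to the extent the errors are
  misdeclared.
* The linear and homologue-specific-output model variants discussed in
  the field are not part of the supported surface; the package fits the
  shared-output Boltzmann model only.
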