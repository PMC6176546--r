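---
title: "Methods: cross-species DIA quantification with crossdia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species DIA quantification with crossdia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdia)
```

## The problem and the procedure

Label-free intensities are comparable *between samples* for the same peptide,
but not *between peptides*: ionization efficiency varies by orders of
magnitude with sequence. In a cross-species comparison an ortholog's sequence
differences therefore confound abundance with response factor. `crossdia`
implements the standard remedy: quantify only tryptic peptides whose sequence
is identical in every species of the comparison, established by in-silico
digestion of each species' protein database, and compare relative abundances
of those shared peptides.

The pipeline (`run_pipeline()`) for a two-group contrast is:

1. digest every proteome (trypsin, minimum length 6, up to 2 missed
   cleavages) and build the conserved-peptide index;
2. keep precursors confidently detected (Q ≤ 10⁻⁴, one outlier sample
   allowed per species) in *either* comparison group, drop precursors mapping
   to more than one gene, drop precursors whose sequence is not in every
   species' digest;
3. normalize total peak areas per run, sum peptides to gene-level proteins,
   then remove intensity-dependent bias with fast cyclic loess
   (10 iterations);
4. fit the empirical-Bayes moderated t-test on log2 abundances, adjust
   p-values by Benjamini–Hochberg, call significance at adjusted p ≤ 0.005;
5. optionally test a gene set for enrichment among the significant proteins
   (2×2 chi-square), and report QC: per-species CoV, pairwise R², and
   average-linkage clustering on correlation distance.

Assumptions worth stating: targeted extraction yields a *complete* matrix (a
precursor observed in some but not all samples is treated as a data error,
not silently dropped — silent drops would bias the rollup); precursor
identity is (sequence, modifications, charge), and modifications are ignored
only for the conservation test, where bare sequence identity is what makes
response factors cancel; all samples of a kept precursor enter
quantification, including the allowed low-confidence outliers.

## The moderated test

Per protein, a two-group linear model gives means, pooled variance
$s_g^2$ with $d = n_A + n_B - 2$ df, and $\log_2\!FC_g$. The prior
$(d_0, s_0^2)$ is estimated by method of moments on $z_g = \log s_g^2$ using
$E[z] = \psi(d/2) - \log(d/2) + \log\sigma^2$ and
$\mathrm{Var}[z] = \psi'(d/2)$, solving $\psi'(d_0/2) = \widehat{\mathrm{Var}}$
by Newton inversion of the trigamma function (`trigamma_inverse()`). Then
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and
$t_g = \log_2\!FC_g / (\tilde s_g \sqrt{1/n_A + 1/n_B})$ on $d + d_0$ df.

Degenerate cases are handled explicitly: when the observed spread of
$z$ is no larger than its sampling variance, $d_0 = \infty$ and the test
becomes a z-test with variance $s_0^2$; `prior_df = 0` recovers the
classical pooled t-test; a zero standard error yields $t = 0$ when the fold
change is zero (equal groups) and $\pm\infty$ otherwise, so noise-free data
behave correctly rather than producing 0/0. The implementation is checked in
the tests against an independent direct-formula oracle (trigamma inversion
by `uniroot`, a different numerical route) and against `limma::eBayes`.

The group contrast pools species within each group (e.g. mouse + rat as
"rodent"); species is deliberately not modeled as a nested random effect —
the comparisons this package targets are two-group contrasts on a handful of
species, where a species-level variance component is not identifiable with
two species per group.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `digest_params()` enzyme | `trypsin_blocked_by_proline` | K/R–P bonds resist tryptic cleavage; the blocked rule is the convention of the MaxQuant-era search workflow. `trypsin_p` is selectable. |
| `max_missed_cleavages` | 2 | matches the identification search settings, so any reported peptide can be tested for membership in every species' digest |
| `min_length` | 6 residues | identification-search minimum |
| `ibaq_params()` | 7–30 residues, 0 missed | "theoretically observable" peptides for the iBAQ denominator; the method's customary bounds, configurable since sources vary. Zero observable peptides gives an explicit undefined (`NA`) iBAQ, never a division by zero. |
| `filter_policy()` thresholds | 10⁻³ strict / 10⁻⁴ grouped | fragment-group Q-value cutoffs for the replicate-QC and comparison workflows |
| `outliers_allowed_per_species` | 1 | one sample per species may exceed the grouped threshold; qualification is evaluated per group and OR-combined (`group_mode = "either"`) |
| loess | span 0.7, 10 iterations, `fast` | the named normalization function's documented defaults; see below |
| `alpha` | 0.005 | FDR-adjusted significance threshold, boundary-inclusive |

Logs are base 2 throughout, so fitted coefficients read directly as log2
fold changes; linear fold changes are reported as `2^|log2fc|` with a
direction label. CoV is computed on linear-scale values with the unbiased
standard deviation and reported in percent; pairwise R² and clustering use
log2 values (linear-scale correlations would be dominated by the top decade
of abundance).

## Numerical choices

* **Cyclic loess, fast variant.** The implementation delegates to
  `limma::normalizeCyclicLoess(method = "fast")`: per iteration, each
  column's deviation M from the mean log profile is loess-smoothed *against
  that mean profile* and subtracted. On columns that differ by constant
  offsets the fixed point is exact (offsets are removed to machine
  precision and re-running changes nothing); on noisy data the per-column
  median M is driven well below 0.01 log2 units while within-column rank
  order is preserved.
* **Total-area normalization** targets the *mean* of the original column
  totals (the target is arbitrary up to a global constant; mean keeps the
  overall intensity scale). Scaling commutes with the summation rollup, so
  the order of these two steps does not matter.
* **Chi-square enrichment** defaults to no continuity correction, with Yates
  available by flag; for the table sizes involved (hundreds per margin) the
  two differ in the third decimal of p. Both variants are reported by the
  acceptance script. The odds ratio uses the Haldane 0.5 correction when a
  cell is empty.
* **Clustering determinism.** Samples are sorted by id before clustering, so
  the dendrogram (exported as Newick) is invariant to input column order.
* **Conservation is exact string equality** — isoleucine and leucine are
  distinct letters. Isobaric I/L collapsing would merge peptides that a
  fragment-based extraction can in fact distinguish only partially; exact
  identity is the conservative choice and keeps the index a pure set
  operation.

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure of a
targeted-extraction report, not its biochemistry:

* gene base abundances are log-normal (log10 sd 0.8), spanning roughly six
  orders of magnitude over thousands of genes, as iBAQ surveys of synaptic
  proteomes show;
* each gene contributes 2–8 tryptic "blocks" (length 6–20, ending in K/R, no
  internal K/R/P, so tryptic boundaries align across species); a block is
  identical in all species with probability `conserved_fraction` (default
  0.7) or carries ≥1 internal substitution in ≥1 species; block sequences
  are unique across the library, as precursor keys in a spectral library
  are;
* peptide response factors are log-normal (log10 sd 1.0) and fixed per
  peptide — the dominant peptide of a protein therefore dominates its rolled
  up intensity, as in real summation rollup;
* a fraction `de_fraction` (default 0.1) of genes receives a true group
  effect, split symmetrically between the groups (±fc/2 per side), magnitude
  uniform on 0.2–2.0 log2 units by default; an optional per-gene
  per-species offset (`species_effect_sd`, default 0) adds species-level
  divergence beyond the group effect — zero by default so the two-group
  null is exact for FDR studies, and set above the noise level when
  species-resolved structure (e.g. clustering) is the object of study;
* observation noise is a mean-one log-normal multiplier with configured CV
  (default 10%, the regime of the biological comparisons; 4% for technical
  replicates);
* 2% of observations receive a low-confidence Q-value (above 10⁻⁴),
  placed preferentially at low intensities; confident observations draw
  Q ≤ 10⁻⁵. The Q-value model is a stand-in: real extraction software's
  Q-value distribution is not characterized here, so only the *rates* and
  the intensity bias are meaningful, not the shape.
* Every generator stage draws from its own seed-derived stream, so e.g.
  regenerating a report does not perturb the proteome sequences. The same
  configuration reproduces byte-identical outputs.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: retention-time structure, fragment-level
interference, missing rows, between-sample response-factor drift,
isolation-efficiency differences between species preparations, and
correlated biological variation between proteins. Ground-truth-recovery
results on this generator validate the pipeline's statistics, not the
upstream extraction.

## Study conditions used in the validation suite

The tests and `scripts/acceptance.R` use the four-species design (5/5/6/5
samples, rodent vs primate contrast, 2000 genes, ~10⁴ peptides). The null
FDR study runs 20 replicate simulations with no true effects at 10%
observation CV. The sensitivity study fixes all true fold changes at 1.25
and sets observation CV to 12%, which yields protein-level median CoV of
~8.7% per species — chosen to match the 8–9% medians typical of the
biological replicate comparisons this workflow targets — and detection
power is then ≥0.8 at adjusted p ≤ 0.005 with 10-vs-11 samples. Technical
replication is emulated at 4% observation CV with 3 runs, giving median
peptide CoV ≈ 3.4% (the expected small-sample attenuation of a 4% CV) and
lower protein CoV after rollup. Unit tests run smaller configurations
(8–11 samples, 150–400 genes) of the same structure.

## Known limitations

* Two-group contrasts only; no moderated F-tests over more than two groups
  and no intensity-dependent variance trend in the prior.
* The conserved-peptide test requires the species' protein databases to be
  of comparable completeness; a peptide missing from one database because
  of annotation gaps (not sequence divergence) is discarded.
* iBAQ values are within-sample relative abundances; they are not accurate
  absolute copy numbers, and the package makes no cross-species claims from
  iBAQ.
* Gene symbols are the protein identity unit throughout; protein groups are
  collapsed to genes (multi-gene groups dropped) before comparison.
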