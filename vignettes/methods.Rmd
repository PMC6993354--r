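---
title: "Models and methods in spectraQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spectraQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model it
fits, the conventions it fixes where the underlying methodology leaves
room, the design of the synthetic-data generator, and what a green test
does and does not establish. It states no empirical result that the test
suite does not itself compute.

## The repeatability model

Milk transmittance at one selected wavenumber, for record $ijkl$ (parity
$i$, season $j$, herd $k$, cow $l$), is modelled as

$$
y_{ijkl} = \mu + \mathrm{Parity}_i + \mathrm{Season}_j
  + \beta_1\,\mathrm{DIM}_{ijkl} + \beta_2\,e^{-0.05\,\mathrm{DIM}_{ijkl}}
  + \mathrm{Herd}_k + \mathrm{CowA}_l + \mathrm{CowPE}_l + E_{ijkl},
$$

with $\mathrm{DIM} = \mathrm{dim}/365$ for days in milk
$\mathrm{dim} \in [1, 400]$. Herd, permanent-environment and residual
terms are normal with variances $\sigma^2_{Herd}$, $\sigma^2_{PE}$,
$\sigma^2_E$. The additive genetic value is parameterised through SNP
effects on centred allele dosages, $\mathrm{CowA}_l = \sum_m g_{lm} a_m$,
with $a_m \sim N(0, \sigma^2_a)$ sharing one variance — the ridge /
SNP-BLUP prior.

**The Wilmink term as printed.** The lactation-stage exponential uses the
*scaled* covariate, $e^{-0.05\,\mathrm{dim}/365}$, which is nearly linear
over a lactation — unlike the conventional per-day form
$e^{-0.05\,\mathrm{dim}}$. We implement the scaled form as the default
because it is what the methodology prescribes, and expose the
conventional form via `build_design(wilmink = "per_day")`. A side effect
of the scaled form is near-collinearity of intercept, DIM and the
exponential; see "Sampler" below.

**Heritability** is computed per posterior draw as
$h^2 = \sigma^2_A / (\sigma^2_{Herd} + \sigma^2_A + \sigma^2_{PE} +
\sigma^2_E)$, where $\sigma^2_A$ is the variance across cows of that
draw's $\mathrm{CowA}$ vector (the realised genomic variance), not a
sampled scalar. This matches the hierarchical definition of the breeding
value and makes the heritability numerator consistent with the
window-variance denominator. Wavenumbers with posterior mean $h^2 < 0.05$
are excluded from the GWAS stage.

## Priors and their numerical realisation

* Fixed effects: flat (improper uniform) priors. The source methodology
  prints UNI(0, +∞) for "all fixed effects and regressors", which taken
  literally would force positive contrasts; transmittance contrasts can
  have either sign, so we read it as an unbounded flat prior.
* Variances: UNI(0, +∞) realised as uniform on $(0, b]$ with
  $b = 10^6 \times$ phenotypic variance (configurable,
  `mcmc_config(variance_bound_factor=)`). Conditional draws are scaled
  inverse-chi-square, $SS/\chi^2_{q-2}$, truncated at $b$ by redraw (100
  attempts, then set to $b$). A fit in which more than half the variance
  draws hit the bound carries a warning flag.

## Sampler

The sampler is single-site Gibbs — the Metropolis–Hastings special case
with acceptance probability one, which is the standard realisation for
this conditionally conjugate model class. Implementation choices:

* **Fixed effects are drawn as one multivariate block** from
  $N((X'X)^{-1}X'(e + Xb),\ \sigma^2_E (X'X)^{-1})$. Because the printed
  Wilmink covariate is nearly collinear with intercept + DIM, single-site
  updates would random-walk along the collinear ridge for thousands of
  iterations; the block draw mixes in one step. A jitter of
  $10^{-10}\,\mathrm{tr}(X'X)/q$ on the diagonal guards exact
  singularity (e.g. a constant-DIM design); the extra variance lies in
  the null space of $X$ and never touches the fitted values.
* Herd and permanent-environment effects use per-group residual sums
  (groups are disjoint across records, so one pass suffices).
* SNP effects use cow-level sufficient statistics: with $s_l$ the sum of
  residuals over cow $l$'s records and $c_m = \sum_l n_l g_{lm}^2$, the
  conditional is $N((\sum_l g_{lm} s_l + a_m c_m)/(c_m + \lambda),\
  \sigma^2_E/(c_m+\lambda))$ with $\lambda = \sigma^2_E/\sigma^2_a$, so a
  full sweep costs $O(p \cdot n_{cows})$ rather than
  $O(p \cdot n_{records})$.
* Record-level residuals are rebuilt exactly after each update family,
  which also eliminates floating-point drift over long chains.
* Initialisation: fixed effects at least squares, random effects at
  zero, variances at equal quarters of the phenotypic variance (the
  per-SNP variance divided by $p$). Deterministic, fast burn-in.
* All randomness comes from R's RNG, so a chain is bit-reproducible
  under `set.seed()`. Permuting record order changes floating-point
  summation order, so chains from permuted data are statistically — not
  bitwise — identical; the tests assert equality within Monte-Carlo
  error.
* Chain bookkeeping: saved draws are exactly
  $\lfloor(\text{iterations} - \text{burn-in})/\text{thinning}\rfloor$.
  The default 7,000/3,000/10 chain is the full-scale analysis chain
  (70,000/30,000) divided by ten, for desk-scale runtime; the full values
  are one `mcmc_config()` call away.
* Missing dosages are mean-imputed per SNP before centring (imputation
  proper is out of scope); this keeps the dosage matrix dense as the
  SNP-effect parameterisation requires.

## Wavenumber selection conventions

The selection stage fixes three conventions that the underlying
methodology leaves informal:

* **Water boundary.** Exclude wavenumbers strictly above 3008 cm⁻¹ and
  the closed band [1623, 1669] cm⁻¹ — 3008 itself is retained. On a
  uniform 1060-point grid spanning 925–5008 cm⁻¹ this leaves exactly 530
  wavenumbers, the documented count.
* **Blocks.** "Visual inspection of the heatmap" is replaced by a
  deterministic rule: scanning the retained grid left to right, a block
  grows while every pairwise residual correlation within the extended
  block exceeds 0.95 (strict); singletons are allowed. Blocks therefore
  partition the retained grid, which is asserted as an invariant.
* **Representative and ties.** Within a block, the member with the
  highest within-block correlation sum (diagonal included) is selected;
  exact ties break toward the lower index and are flagged. Correlations
  are computed on OLS residuals after parity, season, the two Wilmink
  terms, and herd as a fixed categorical term (the correction step
  predates the random-herd model, so a fixed herd term is the simplest
  faithful reading).
* Selection runs independently per input population, so representatives
  may differ between populations for the same block.

## The window GWAS

Groups of 100 consecutive SNPs are tiled per chromosome at offsets 1, 21,
41, 61 and 81; truncated trailing groups with fewer than 80 SNPs are
dropped. For group $j$ of wavenumber $i$,

$$ \%\sigma^2_{A,ij} = 100 \cdot \sigma^2_{gEBV,ij} / \sigma^2_{A,i}, $$

with the numerator the across-cow variance of the group breeding value
per draw. We report the **ratio of draw-averaged variances** (mean
numerator over mean denominator), which is stable when individual
additive-variance draws are small; `per_draw_ratio = TRUE` switches to
the mean of per-draw ratios. Thresholds are strict as printed
(> 0.35 %, > 0.95, < 80, < 0.05). QTL merge transitively by closed
base-pair interval overlap (equivalent to SNP-ordinal overlap on a
sorted map); coordinates are 1-based and closed throughout. The Manhattan
orientation point of a group is its middle SNP, ordinal
$\lceil n/2 \rceil$ within the group. Cross-population overlap counts
connected components of the bipartite interval-intersection graph that
contain calls from both sets — symmetric, and a QTL matched by several
partners counts once. Peak regions are labelled by chromosome and rank of
start position; no attempt is made to reproduce ad-hoc letter suffixes.

## The synthetic-data generator

The generator emulates the structure of a national milk-recording study:
cows assigned uniformly to herds; ~9 % of cows in second parity; record
dates uniform over a one-year recording window (2015-10-01 to 2016-09-30)
with season "summer" from April 1 through September 30; days in milk
uniform on 1–400 (the observed range; the true distribution is not
documented, so uniform is the least informative choice); one to twelve
records per cow by default (the documented range is 1–20 with roughly six
records per cow on average; the distribution is exposed as a config knob
rather than fixed). Genotypes are biallelic SNPs in Hardy–Weinberg and
linkage equilibrium with per-SNP allele frequencies uniform on the
configured MAF range; SNPs whose realised MAF falls below the 0.01 QC
floor are resampled. Linkage equilibrium is the default because it makes
the window-variance additivity property exactly testable; real data have
LD, which *helps* window attribution (local SNPs tag a causal variant)
— see "What a green test establishes" below.

Planted QTL effects are sized on the realised centred-dosage variance so
each carries exactly its configured fraction of $\sigma^2_A$; background
effects are i.i.d. normal, then rescaled once so the background carries
exactly its complementary share (up to sampling covariance between SNPs).
Wavenumbers inside a configured block share the systematic signal plus a
common noise component with weight $\sqrt{\rho}$, so within-block
phenotypic correlations exceed $\rho$; fat and protein percentages are
simulated without genetic signal purely to exercise record QC.

Default variance components are $(\sigma^2_A, \sigma^2_{Herd},
\sigma^2_{PE}, \sigma^2_E) = (0.3, 0.1, 0.2, 0.4)$ in squared
transmittance units, giving true $h^2 = 0.30$ — a typical value for a
strongly heritable wavenumber. Defaults were fixed before the tests were
run and are not tuned.

## Test-scale power analysis for QTL recovery

The parameter-recovery criterion plants a QTL carrying 5 % of additive
variance and requires the top-ranked QTL to cover it in ≥ 9/10
replicates. Choosing the test-scale world required a power analysis,
done before freezing the test:

* Under the shared-variance (ridge) prior, a lone large effect at a
  low-MAF SNP is differentially shrunk (its per-SNP information
  $c_m \propto$ dosage variance is small relative to $\lambda$), and its
  window can lose the top rank to background noise. Major milk QTL are
  common variants, so the recovery world draws MAF from [0.25, 0.5].
* With $p$ SNPs and $n$ cows, the null SNPs jointly reconstruct roughly
  $p/n$ of the causal dosage in-sample (sampling LD), smearing the
  planted excess genome-wide. The world therefore uses
  $n_{cows} = 5000 \gg p = 1500$.
* Background group shares are themselves random (i.i.d. effects):
  relative SD $\sqrt{2/100} \approx 14\%$ per 100-SNP group. With three
  chromosomes of 500 SNPs the planted group's true share (≈ 11 %)
  reliably exceeds the background maximum (≈ 9 %).
* At this density every group carries percent-scale polygenic variance,
  so all groups clear the 0.35 % threshold and merge chromosome-wide;
  three chromosomes keep the coverage check non-vacuous (the planted
  chromosome must win the peak).

## What a green test establishes — and what it does not

The suite establishes: exact agreement of the deterministic stages with
brute-force oracles (grouping, block detection, interval merging, window
arithmetic to 1e-12); agreement of the sampler's conditional mode with
the closed-form ridge solution and of its fixed effects with an REML
oracle; recovery of simulated heritability and planted QTL at the stated
tolerances; and bit-reproducibility of the pipeline under a fixed seed.

It does not establish performance on real spectra: real wavenumber
correlations are not exactly block-structured, real genotypes have LD
(which changes both the leak geometry and the interpretation of a window
hit), herds are unbalanced, and lactation-stage effects are not exactly
Wilmink. The motivating study's real-data results are not reproducible
here because its raw data are not public.

## Known limitations

* The scaled Wilmink exponential is retained as printed even though it is
  nearly linear in DIM; the conventional per-day form is a switch, and
  the near-collinearity it induces is handled in the sampler rather than
  by reparameterisation.
* The shared SNP-effect variance under-ranks lone large effects at low
  MAF (BayesA/B-style per-SNP variances would preserve them, but are a
  different model class than the one specified).
* Convergence diagnostics are limited to a stationarity smoke test;
  long-run users should inspect traces.
* `overlap_qtl` assumes both call sets share a genome build and map
  convention; no liftover is attempted.
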