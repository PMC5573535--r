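---
title: "Models and methods in codonsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in codonsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

codonsel detects natural selection on a protein-coding gene from three
complementary kinds of evidence: between-species codon substitution
patterns (site models, counting methods, episodic tests,
fingerprinting), the joint pattern of within-species polymorphism and
between-species divergence (a Poisson-random-field mapper of
population-scaled selection coefficients), and a phenotype-level
resampling test (age trends in expression). This vignette explains the
models, the defaults, and the reasoning behind the choices that were
genuinely open.

## Codon substitution machinery

All phylogenetic computations share one engine. The instantaneous rate
from codon *i* to codon *j* is zero unless the codons differ at exactly
one nucleotide position, and otherwise

    q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous],

over the 61 sense codons of the standard genetic code; stop codons are
excluded everywhere. `kappa` is the transition/transversion rate ratio,
`omega` (dN/dS) the nonsynonymous/synonymous rate ratio, and `pi` the
equilibrium codon frequencies (`equal`, `F3X4` from position-specific
nucleotide frequencies, or `F61` from empirical codon counts; both
empirical schemes carry a 0.5 pseudocount because a zero frequency
breaks the reversibility scaling). The matrix satisfies detailed
balance, so likelihoods are invariant to root placement, and is
normalised so branch lengths are expected substitutions per codon.

Per-site likelihoods come from Felsenstein's pruning algorithm,
implemented in C++ and vectorised over sites; transition matrices use
the symmetrised eigendecomposition of the reversible generator. Codons
containing gaps or ambiguity codes are treated as missing data for that
taxon (the likelihood sums over all 61 states), preserving the site
count rather than dropping columns. Site-class mixtures (M1a, M2a, M7,
M8, the episodic test) share `kappa` across classes and are normalised
so the *mixture-averaged* substitution rate is 1; this keeps branch
lengths comparable across models. One consequence worth stating: when
site posteriors are computed after a fit, all classes are scaled by the
same fitted normaliser, so a positively selected class really does
evolve faster than the average site — normalising each class separately
would erase most of the detectable signal.

Maximum-likelihood fitting uses bounded L-BFGS-B on transformed
parameters (`omega` in [1e-4, 50], `kappa` in [0.1, 20], proportions by
stick-breaking logits), with a deterministic multi-start (default 5
dispersed starting points) and a convergence tolerance of about 1e-8 on
the log-likelihood (`factr` is exposed for cheaper exploratory fits).
Branch lengths are estimated under M0 — jointly (`"full"`), as a single
scale factor on least-squares initial lengths (`"scale"`), or taken as
given — and then held fixed for the site models, the common and much
cheaper convention. Alternative models can be warm-started from their
nested null (`warm_start`), which also guarantees the nesting
inequality numerically. The M7/M8 beta distribution is discretised into
10 equal-weight classes represented by the conditional bin mean (lower
discretisation bias than the bin median; the median is a documented
switch).

## Tests and site detection

Both standard comparisons (M1a vs M2a, M7 vs M8) are referred to a
chi-square distribution with 2 degrees of freedom, the standard choice,
with the statistic clamped at zero. Under null simulations the test is
calibrated or conservative (the boundary problem pushes it below the
nominal level), which the test suite checks empirically.

Site detection offers three methods with a consensus rule:

* **BEB** integrates the M8 (or M2a) distribution parameters over a
  uniform grid of 10 values per free parameter — for M8, `p0` on
  midpoints of (0,1), the beta shapes on midpoints of (0,2), and the
  selection-class `omega` on midpoints of (1,11) — with `kappa`,
  frequencies, and branch lengths fixed at their MLEs. Flag at
  posterior ≥ 0.90.
* **REL** fits a 3-class general discrete distribution over per-site
  synonymous (`alpha`) and nonsynonymous (`beta`) rates (mean rate
  normalised to 1) and reports empirical-Bayes posteriors of
  `beta > alpha`; the Bayes factor is posterior odds over prior odds,
  flagged at BF ≥ 50. The class count and cutoff are configurable; 50
  is the conventional default for this kind of analysis.
* **FUBAR-style** detection precomputes site likelihoods on a 20 × 20
  lattice of (`alpha`, `beta`) values, quadratically spaced on [0, 50]
  (denser near zero), places a symmetric Dirichlet(0.5) prior on the
  lattice weights, and Gibbs-samples the weights (site allocations by
  Gumbel-max categorical draws — with `ties.method = "first"`, since
  base R's "random" tie handling corrupts draws when some cells carry
  essentially zero likelihood — and conjugate Dirichlet weight
  updates). The per-site posterior of `beta > alpha` is the
  Rao-Blackwellised average over retained weight draws, flagged at
  ≥ 0.90. The sampler was validated against exact quadrature over the
  weight simplex on small instances.

A site is a **consensus** target when flagged by at least 2 methods
(configurable); the strict set requires all supplied methods. A
practical note on power: with a 400-cell lattice the Dirichlet(0.5)
prior contributes 200 pseudo-counts, so when only a few dozen sites in
a gene are truly under selection the weight available to
positive-selection cells is diluted and FUBAR posteriors for true
targets often settle around 0.8 — real signal, below the 0.9 flag. BEB
and REL are noticeably more powerful at the same false-positive rate in
this regime, which is itself an argument for the multi-method consensus.

The **episodic test** fits a 3-class omega distribution
(`omega1 <= omega2 <= 1 <= omega3`, all branches foreground) against a
null with `omega3 = 1`. Because the null lies on the boundary, the
default p-value uses an equal-weights mixture of chi-square(0), (1) and
(2); a plain chi-square(2) option is provided as a conservative
alternative.

**Fingerprinting** fits general discrete (`alpha`, `beta`) mixtures for
k = 1..5 and selects k by small-sample AIC (AICc with n = number of
codons; 3k − 2 free parameters after the rate normalisation); classes
with negligible weight are pruned.

## Counting-based dN/dS

The counting route uses a single joint maximum-likelihood ancestral
reconstruction (max-product dynamic programming under the M0 matrix;
ties broken deterministically toward the lowest codon index in the
alphabetical codon ordering). Per codon state, the 3 mutable sites are
split into expected synonymous and nonsynonymous parts by
single-nucleotide neighbor enumeration with stops excluded
(`ES + EN = 3` exactly), averaged over the states assigned to all
nodes; substitutions are tallied along every branch, with
multi-position changes averaged over all minimal mutational paths that
avoid stop codons (falling back to all minimal paths in the rare case
none avoids a stop). The global ratio is
`(sum ON / sum EN) / (sum OS / sum ES)`; its 95% interval is a
nonparametric percentile bootstrap over codon sites (default 1000
replicates) — method-agnostic and directly testable, which is why it
was chosen over analytic approximations. Per-site evidence is a
two-sided binomial test of the nonsynonymous substitution fraction
against the neutral expectation `EN/(EN+ES)`. Unweighted neighbor
counting is the default; `kappa`-weighted opportunities would be a
straightforward variant but are deliberately not the default so that
the counting route stays independent of the ML fit beyond the
reconstruction.

## Selection-coefficient mapping

For within-species data the package maps population-scaled selection
coefficients `gamma` along the gene on the fixed 12-value grid
{100, 50, 10, 5, 1, 0, −1, −5, −10, −50, −100, −500}. Per codon, four
counts enter — lineage-specific fixed synonymous/nonsynonymous
differences versus a parsimony ancestor (from the fixed
((ingroup1, ingroup2), outgroup1, outgroup2) topology; 2-vs-2 splits
are ambiguous and excluded) and segregating synonymous/nonsynonymous
sites — modelled as independent Poissons with the standard
Poisson-random-field means:

    lambda_Ds = (theta/2) T
    lambda_Dn = (theta/2) T Z_n h(gamma)
    lambda_Ps = (theta/2) a_n
    lambda_Pn = (theta/2) a_n Z_n G_rel(gamma, n)

with `h(gamma) = gamma / (1 − exp(−gamma))` (continuous at 0), the
relative polymorphism factor `G_rel` from adaptive quadrature of the
diffusion sojourn density (evaluated in an overflow-safe
parameterisation so `gamma = −500` is exact), `a_n` the harmonic
number of the sample size, and `Z_n` the codon's
nonsynonymous/synonymous opportunity ratio from neighbor enumeration
(the synonymous part floored at 1/3 site so codons like ATG with no
synonymous neighbor keep a finite ratio). `gamma` here is the value
entering `h` directly; no extra factor of 2 is applied. This
independent-Poisson skeleton deliberately drops the full codon-path
mutation model and `kappa`: it preserves the inferential structure
(counts in, per-codon posterior over the grid out) with a likelihood
every part of which is unit-testable.

The sampler is Metropolis-within-Gibbs: per-codon `gamma` assignments
are drawn exactly by forward-filtering backward-sampling under a
first-order persistence chain (adjacent codons share their class with
probability `p`, else redraw from the Dirichlet weights); copy/fresh
auxiliary indicators make `p` (uniform prior) and the 12 class weights
(uniform Dirichlet) conjugate; `theta` and `T` take lognormal
random-walk Metropolis steps under lognormal hyperpriors (defaults
`LogNormal(log 1e-3, 1)` and `LogNormal(0, 1)` — weakly informative at
a per-site mutation-rate scale, and configurable; analyses of
informative synthetic counts should pass matched priors). Two chains of
100,000 iterations with thinning 10 are the analysis default; 10% of
each chain is discarded as burn-in (a declared choice), chains are
compared by split R-hat on `theta`, `T`, `p` (warning status above
1.1) and merged. A codon is called positively selected when its
cumulative posterior mass on classes with `gamma >= 1` exceeds 0.80.
Both this and the `gamma > 0` spelling (`criterion = "gt0"`) are seen
in practice, and both are exposed — though on this particular grid,
where the smallest beneficial class is exactly 1, the two select the
same five classes and give identical calls. The single-codon posterior was
validated against direct quadrature over the hyperpriors.

## Expression envelopes

Age trends are fit by lowess on a transformed age axis
`x = log2(age_years + offset)` with a default offset of 0.75 years
(about a human gestation, so age 0 maps to a finite value;
species-specific offsets are configurable). The default span is 0.5
with 3 robustness iterations — a mid-range smoother choice, exposed in
the interface. The null of constant expression over the lifespan is
made operational by permuting expression values against ages within a
species × region series (each series gets its own envelope; per-series
permutation is exactly the stated null). For each of B = 1000
permutations the curve is refit on the same grid, and the pointwise
2.5%/97.5% percentiles form the envelope; percentiles use the
order-statistic convention (quantile type 6), the standard
finite-sample choice for permutation distributions. Observed-curve
exceedances are flagged with their direction, and `deviation_report()`
summarises fractions and age intervals across series. Average pointwise
null coverage is ~95% by construction, which the test suite verifies.

## Synthetic data and what passing tests mean

The generators produce exactly the inputs the analyses consume, each
with a truth table and a mandatory seed: codon alignments evolved by
exact matrix-exponential sampling under site-class omega mixtures on a
tree (the same normalisation convention as the fitting engine);
per-codon PRF counts drawn from the likelihood's own Poisson means,
with optional persistence-structured gamma profiles; and age-expression
series as trend plus Gaussian noise. Benchmark problem sizes used by
the validation suite, chosen once: an 8-taxon tree of root-to-tip depth
1.0 for null-calibration experiments (200 simulations x 200 codons), a
12-taxon near-balanced tree of depth 1.2 (total length ~6.6
substitutions/codon — the mid-divergence regime of the site-model power
literature) for recovery (500 codons) and detection (300 codons, 10% of
sites at omega = 5) experiments, PRF counts at `theta = 0.05`/codon and
`T = 2` with n = 20 chromosomes (scaled so per-codon counts are O(1)),
and expression series of 25/31/12 individuals with noise SD 0.3.

What the passing tests do **not** show: the generators evolve sites
independently (no recombination, no indels, no alignment error), codon
frequencies are stationary along the tree, the PRF counts are drawn
from the same independent-Poisson skeleton the mapper assumes (real
data add demography, linkage and mutation-model misfit), and real
single-gene polymorphism data at primate scales are far sparser than
the benchmark scaling. Power numbers from these benchmarks are
best-case statements about the machinery, not about any particular
gene.

## Numerical notes

Log-space pruning with per-node rescaling keeps 61-state likelihoods
stable to at least ~20 taxa; per-class site log-likelihoods of exactly
zero (a zero-rate class with a variable column) are clamped to a large
negative constant so mixture weights handle them. `h` and `G_rel` use
`expm1`-based forms stable across the whole grid. Bootstrap replicates
whose resample contains no synonymous substitution are dropped from
the percentile interval (and counted); a data set with no synonymous
substitutions at all is an explicit error, not an NA. Reported codon
coordinates are always 1-based positions in the unmasked gene: masking
removes columns from computation but the site-index map keeps the
original numbering, so the same codon index means the same column in
every stage's output.
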