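---
title: "Multi-breed genetic evaluation for synthetic hexaploid wheat: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed genetic evaluation for synthetic hexaploid wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synwheat)
```

## The problem

Synthetic hexaploid wheat (SHW) is produced by hybridizing tetraploid
*Triticum turgidum* (genomes AABB) with diploid *Aegilops tauschii*
(genome DD) and doubling the chromosomes of the triploid hybrid.  Crossing
and backcrossing synthetics to elite bread wheat *T. aestivum* (AABBDD)
yields synthetic derivative lines that re-introduce wild diversity into
the elite gene pool.  Because the three source populations have very
different evolutionary histories, a single additive genetic variance is a
poor description of such material: the variance contributed by an allele
depends on which population it came from, and crosses between populations
with diverged allele frequencies release *segregation variance* —
additional additive variance in an F2 or backcross relative to the F1.

`synwheat` implements a pedigree-based evaluation that partitions the
additive variance of every individual by breed of origin.  The machinery
has three layers:

1. **Breed fractions and partial relationship matrices** — deterministic
   pedigree algebra (`breed_fractions()`, `partial_kinship()`).
2. **A hierarchical Bayesian mixed model** estimated by Gibbs sampling
   (`fit_multibreed()`), giving posterior distributions for seven
   variance components and breeding values by origin.
3. **Derived summaries** — per-cross-type variance decompositions,
   narrow-sense heritability and line-mean repeatability
   (`group_variances()`, `narrow_sense_h2()`,
   `line_mean_repeatability()`).

A synthetic-data generator (`simulate_pedigree()`,
`simulate_phenotypes()`) and a gene-dropping Monte-Carlo oracle
(`gene_drop()`) make every layer testable without external data.

## Genotypic variance with variable parental ploidy

Breed groups are `D` (diploid *Ae. tauschii*), `T` (tetraploid
*T. turgidum*), `V` (hexaploid *T. aestivum*), `S` (the doubled D x T
synthetic) and `SD` (synthetic derivatives).  Allopolyploid subgenomes
pair independently at meiosis, so each subgenome is treated as an
independent diploid.  With additive variances scaled by ploidy
(sigma2_D = 2 Var(alpha_D), sigma2_T = 4 Var(alpha_T),
sigma2_V = 6 Var(alpha_V)), a non-inbred pure line of breed PB has
genotypic variance (1 + F) sigma2_PB, where F is the within-breed
probability of identity by descent between the two homologous alleles of
a subgenome.

The doubled synthetic carries a full complement of both parental
subgenome sets, so its variance is the sum of the D and T pure-breed
terms and its composition coefficients are f_D = f_T = 1.  For every
other non-founder the coefficients average the parents,
f_i = (f_sire + f_dam)/2; `100 * f_D` reproduces the familiar
"percent synthetic genome" labels (50, 25, 12.5, 6.25) of the F1 and the
successive backcrosses to V.

The variance of a derivative individual is

    f_D sigma2_D + f_T sigma2_T + f_V sigma2_V
      + a_DV sigma2_DV + a_TV sigma2_TV

with segregation weights accumulated from both parents,
a_DV = 2 (f_s^D f_s^V + f_d^D f_d^V) (+ carry-over), and the
`4 (...)` analogue for TV.  Two remarks on deliberate design choices:

* **Both parents contribute to the segregation weight.**  In the
  backcrossing scheme the recurrent parent is always a pure V line whose
  product f^D f^V vanishes, so the symmetric form reduces exactly to the
  familiar single-parent rule on every cross of the scheme, while
  removing an arbitrary dependence on which parent is listed as sire.
* **A carry-over term `a_seg(sire, dam)/2`** keeps the parent-averaging
  covariance recursion exact component-wise when the two parents are
  themselves related; it is zero for all crosses between unrelated
  parents.

`partial_kinship()` builds the five partial numerator relationship
matrices A_D, A_T, A_V, A_DV, A_TV (and the classical one-breed A) in a
single tabular-method pass: off-diagonals follow the purebred recursion
a_Q(i, j) = (a_Q(sire_i, j) + a_Q(dam_i, j))/2 applied component-wise,
and diagonals follow the rules above.  The total covariance between
breeding values is then `sum_Q a_Q(i,j) sigma2_Q`.

### The synthetic-doubling ambiguity

Chromosome doubling copies the gametic alleles of the D x T hybrid, so
the two within-subgenome copies in an S individual are literally
identical by descent.  Scored that way, the S variance would be
2 sigma2_D + 2 sigma2_T and all D/T covariances of the synthetic with
other individuals double.  The standard tabular rules instead score the
copies at the purebred rate, (1 + F^D) sigma2_D + (1 + F^T) sigma2_T.
`partial_kinship()` implements the standard rule as the default and the
literal rule as `s_diag = "doubled"`.  The gene-dropping oracle, which
implements doubling literally, reproduces the `"doubled"` variant at
every affected pair and the default everywhere else; `gene_drop()`
therefore reports both predictions with a flag rather than silently
reconciling them.  Since phenotyped material in practice consists of
derivatives rather than the synthetics themselves, the choice has little
influence on variance-component estimates, but it matters for the
synthetics' own predicted variances.

## The hierarchical model and its sampler

Records are modeled as

    y = X b + Z_D a_D + Z_T a_T + Z_V a_V + Z_DV a_DV + Z_TV a_TV
        + Z_GE ge + e

* `b`: fixed environment (location-by-cycle) effects with proper prior
  N(0, K), K = 1e8 on every coordinate.  X keeps an intercept plus all
  environment columns; the proper prior regularizes the resulting
  aliasing instead of dropping a column.  The consequence is that
  individual `b` coordinates are identified only up to the aliased
  direction (their posterior along it is the prior), while every linear
  combination that the data see — and all fitted values — are identified.
* `a_Q ~ N(0, A_Q sigma2_Q)` on the support of each component (the
  individuals with nonzero diagonal).  Individuals outside the support
  are excluded rather than stored as zero rows, keeping each block
  factorizable.
* `ge ~ N(0, I sigma2_GE)` over observed genotype-by-environment cells,
  and `e ~ N(0, I sigma2_e)`.
* Every variance has a scaled inverse chi-squared prior.  Defaults:
  nu = 5 for all components; the scale S2 is set so that the prior mode
  nu S2/(nu + 2) equals an equal share of the phenotypic variance across
  the model's variance components.  This is a documented reconstruction
  of "weakly informative by default"; it is user-overridable and the
  exact published posterior values are not claimed to be reproducible
  without the original trial data.

All full conditionals are conjugate and the sampler is a standard
blocked Gibbs: each location block (b, each a_Q, ge) is drawn jointly
from the Normal full conditional given by its mixed-model-equations
system, and each variance from its scaled inverse chi-squared full
conditional, e.g.

    sigma2_Q | . ~ ScInvChi2(nu + q_Q,
                   (a_Q' A_Q^-1 a_Q + nu S2_Q) / (nu + q_Q)).

Two implementation details, both algebraically neutral:

* **Marginalization of unphenotyped relatives.**  Support members
  without records do not enter the likelihood, so the chain samples only
  the phenotyped subset of each support (whose prior is the
  corresponding submatrix of A_Q); their breeding values are recovered
  as conditional expectations given the sampled relatives.  This keeps
  the per-iteration systems at the number of phenotyped genotypes.
* **One-time eigendecomposition.**  For each block the only
  iteration-varying quantities in the conditional precision are the two
  scalars sigma2_e and sigma2_Q, so
  D^-1/2 A_Q^-1 D^-1/2 is eigendecomposed once and each draw costs two
  dense matrix-vector products instead of a fresh Cholesky.

Chains are reproducible given `seed`.  Defaults follow common practice
for this model class: 10,000 retained draws after 10,000 burn-in
iterations, thinning 1.  Convergence checking is left to trace
inspection (`autoplot(fit)`) plus the effective-sample-size report in
`glance()`.  A variance draw that overflows aborts the chain with
diagnostics rather than continuing silently.  Missing phenotypes are
dropped with a logged count, never imputed.

The one-breed comparison model is the same sampler with a single genetic
component on the classical numerator relationship matrix; on an all-V
pedigree the two code paths are identical draw for draw.

## Derived quantities

`group_variances()` evaluates the decomposition for a canonical
non-inbred individual of each cross type (F1, BC1, BC2, BC3) with
unrelated parents.  With the published posterior means of the seven
components it reproduces the published per-cross additive (0.705, 0.444,
0.313, 0.247), segregation (0, 0.408, 0.306, 0.178) and total (0.705,
0.852, 0.619, 0.425) variances at full precision before rounding.

Narrow-sense heritability is computed on a single-plot basis,

    h2 = sigma2_A_total / (sigma2_A_total + sigma2_GE + sigma2_e),

deliberately without replication divisors: only this reading reproduces
the published per-cross values (0.47, 0.52, 0.44, 0.35) and the
one-breed value 0.13.  The replication-adjusted divisors belong to the
line-mean repeatability,

    H2_LM = sigma2_A / (sigma2_A + sigma2_GE/yl + sigma2_e/(yl b)),

with `yl` (cells per genotype) and `b` (replicates per cell) taken from
`replication_summary()`.  Per-group repeatabilities require per-group
cell counts that are not recoverable from the published summary, so they
are reported only when the user supplies the replication structure.

## What the generator emulates — and what it does not

`simulate_pedigree()` reproduces the structure of a long-running
semi-arid wheat yield trial series: by default 10 D, 21 T and 105 V
founders, 16 synthetics, and 88 terminal crosses split 12/45/24/7 across
the four depths, each terminal with its own chain of intermediate
crosses.  `simulate_phenotypes()` draws breeding values from
N(0, A_Q sigma2_Q), iid cell-level G x E, and Gaussian residuals over an
unbalanced trial grid: 20 locations x 5 cycles by default, each genotype
observed in 25 randomly chosen environments with 2 replicates, giving
about 4,400 records for 88 genotypes — the scale of the motivating
data.  Environment means are drawn once from N(4, 1) t/ha, typical of
dryland wheat yield.

The generator deliberately omits features of real trial data: selection
(parents are drawn at random, records are never censored on phenotype),
non-random mating, linkage and epistasis, spatial/block effects within
trials, heteroscedastic residuals across environments, and the temporal
drift of a breeding program.  Passing recovery tests therefore
demonstrates internal consistency of model and sampler, not robustness
to these real-data departures.

The gene-dropping oracle simulates unlinked biallelic loci per subgenome
with breed-specific allele frequencies; its analytic component variances
are sigma2_D = 2 sum a^2 p_D q_D (and ploidy analogues) with segregation
variances sigma2_DV = sigma2_TV-style halves of the squared frequency
gaps, `0.5 sum a^2 (p_D - p_V)^2`.  At one million replicates the
Monte-Carlo standard error of a covariance is about 0.3% of the signal,
sharp enough to separate the two synthetic-scoring rules cleanly.

## Numerical choices and problem sizes

* Topological ordering uses a stable Kahn queue with ties broken by
  input order, so matrix layouts are reproducible across runs.
* Unknown parents are allowed only for founders; an individual with
  exactly one known parent is rejected (the averaging recursion would
  need an arbitrary convention for the missing half).
* Selfing is permitted and handled by the unmodified recursions.
* Matrices are stored dense; the intended pedigree scale (hundreds of
  individuals) makes sparse storage unnecessary.
* A support block that fails Cholesky receives a logged ridge of
  1e-8 x mean diagonal before inversion.
* HPD intervals are the shortest empirical window containing 95% of the
  retained draws.
* The test suite runs its recovery experiment at 300 terminal genotypes
  x 20 environments x 2 replicates with 2,000-iteration chains (500
  burn-in) over 20 replicates, and the oracle comparison at 1e6
  replicates on an 11-individual pedigree; both sizes were chosen so the
  Monte-Carlo error is well below the effects being checked.

## Identifiability of the segregation split

A structural property of the backcrossing grammar deserves emphasis:
every derivative has `f_D = f_T` (the D and T genomes travel together
after doubling), which makes `A_TV` exactly `2 A_DV` on any set of
phenotyped derivatives.  The likelihood then depends on the segregation
components only through `sigma2_DV + 2 sigma2_TV`; how the posterior
splits that sum between DV and TV is driven by the prior.  The same
aliasing is present in any real data set with this crossing structure.
Consequently, posterior summaries of the identified combination are
well calibrated (the package's recovery experiment checks this
directly), while the individual DV and TV marginals should be read as
prior-informed decompositions rather than data-identified estimates.
The D/T split, by contrast, is partially identified through crosses
that share a D founder but not a T founder (and vice versa).

## Known limitations

* REML estimation, factor-analytic G x E structures, multi-trait models
  and marker-based relationship matrices are out of scope.
* Dominance and epistasis are not modeled; published evidence suggests
  epistatic variance in wheat is non-negligible.
* The synthetic-doubling ambiguity above is surfaced, not resolved.
* Exact reproduction of published posterior summaries would require the
  original trial records, which the package does not ship; the
  closed-form per-cross tables are reproduced exactly from the published
  posterior means instead.
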