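---
title: "Estimating additive genetic variance with pedigree and genomic relatedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating additive genetic variance with pedigree and genomic relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In wild populations of socially monogamous birds, the pedigree assembled
from field observations records *social* parentage. Extra-pair paternity
(EPP) — offspring sired by a male other than the social mate — makes a
fraction of the paternal links wrong. An animal model fitted with such a
pedigree misattributes part of the additive genetic variance: misassigned
offspring resemble their social "relatives" less than the relationship
matrix claims, which deflates the additive genetic variance Va and pushes
the unexplained repeatable among-individual variance into the
permanent-environment component Vpe. Relatedness estimated directly from
SNP genotypes does not depend on observed parentage and so provides both a
way to measure the EPP rate and an alternative relatedness matrix for the
model. `pedgenvar` implements that full comparison.

## The model

For repeated measurements `y` of a trait (think tarsus length on a 0.1 mm
scale, population mean ~174.8 units, phenotypic variance ~25 units²):

$$y = Xb + Z a + Z u + e$$

with fixed effects `b` (by default the measurer, reference-coded so the
first measurer is the baseline), additive genetic effects
`a ~ N(0, K σ²_a)` for a relatedness matrix `K`, permanent-environment
effects `u ~ N(0, I σ²_pe)` at the individual level, optionally an
among-year effect, and residuals `e ~ N(0, I σ²_res)`. Repeated
measurements are what separate σ²_pe from σ²_res; with a single record per
individual only their sum is identified (the fit proceeds with a warning
and the posterior of the sum remains stable while the split follows the
prior — this is tested). Heritability is summarised per draw as
`h² = σ²_a / (σ²_a + σ²_pe + σ²_res [+ σ²_year])` and reported as the
posterior mean of the ratio (the ratio of posterior means is attached for
transparency); the additive genetic coefficient is `σ²_a / trait mean` per
draw, meaningful only when the mean is expressed on the same measurement
scale as the variances.

### Sampler

All full conditionals are conjugate: Gaussian for the location effects and
scaled-inverse-chi-square for each variance (prior degrees of freedom
0.002, prior scale the variance of the fixed-effect residuals — weakly
informative on the scale of the data; the default `n_iter = 20000`,
`n_burnin = 4000`, 4 chains). Two one-time symmetric eigendecompositions —
of `K` (jittered to positive definiteness by diagonal increments escalating
from 1e-8 to at most 1e-4 of the mean diagonal, then refused) and of
`N^{-1/2} K^{-1} N^{-1/2}` with `N` the diagonal of per-individual record
counts — give bases in which both the genetic and the permanent-environment
full conditionals are *diagonal*, so one sweep costs a handful of
matrix–vector products (O(n²)) rather than a dense Cholesky (O(n³)).
Because `a` and `u` are strongly anticorrelated given the data, the blocked
updates are followed by an interweaving step that redraws the split of
`t = a + u` from its exact conditional given `t` (diagonal in the
eigenbasis of `K`); this restores the mixing of a joint update. Validity
is established in the test suite by parameter recovery on data with known
variance components and by agreement of `va + vpe` and `vres` with REML
(`lme4`) on the individual-level model. Chain seeds derive deterministically from the user seed, and
phenotype rows are sorted into a canonical order before sampling, so
posterior draws are byte-reproducible and invariant to row permutations.

## Relatedness matrices

- `build_a_matrix()` uses the tabular method, exact for any acyclic
  pedigree (verified against a gene-dropping Monte-Carlo oracle). Dummy
  parents inserted for broods with unidentified parents
  (`insert_dummy_parents()`) participate in the recursion — preserving
  within-brood covariance — but are excluded from parentage counts and
  phenotype joins. `trim_to_common()` keeps ancestors of the target set so
  that coefficients passing through removed intermediates survive the
  projection.
- `build_grm_ibs()` is the identity-by-state similarity
  (mean over loci of `(2 − |g_i − g_j|)/2`, pairwise-complete): entries in
  [0, 1] with a high baseline (around 0.7) for unrelated individuals of
  the same population, since most loci match by chance alone. This is the matrix used for the Mantel comparison; the
  Pearson-based Mantel statistic is invariant to affine rescaling, so the
  choice of scale is inert there.
- `build_grm_vanraden()` is the allele-frequency-weighted GRM
  (`ZZ'/2Σp(1−p)` with column-centred dosages): unrelated pairs near 0,
  parent–offspring near 0.5, diagonal near 1. **Variance estimation and
  paternity classification need this relatedness scale.** A raw-IBS `K`
  would inflate σ²_a by the inverse of its shallow slope against true
  relatedness (far below one), and against its high baseline no
  father–offspring pair could ever fall below an absolute threshold of
  0.1. The published variance components this package's worked examples
  reproduce are mutually consistent only on the relatedness scale, which is
  why `run_config(grm_fit = "vanraden")` is the default; `grm_fit = "ibs"`
  remains available.

## Paternity classification

`classify_paternity()` labels a social father–offspring pair *within-pair*
when similarity exceeds 0.3 and *extra-pair* below 0.1; intermediate values
are counted as *unresolved* and kept in the rate denominator by default
(`drop_unresolved = FALSE`). On relatedness-scale similarity these
thresholds sit far from both the parent–offspring distribution (0.5 ± ~0.03
at thousands of loci) and the unrelated distribution (0 ± ~0.03).
Intermediate values are not an artifact: an extra-pair sire that is itself
a relative of the social male (likely in small closed populations) yields
genuinely intermediate similarity, and such pairs should be rare in large
outbred study systems.

## SNP quality control

Filters are applied in a fixed, logged order: excluded (sex) chromosomes;
per-SNP missing rate (> 0.1 removed, boundary kept); per-individual missing
rate (> 0.05 removed, exactly 5% kept — "no more than 5%"); then, with
statistics recomputed on the remaining individuals, minor-allele frequency
(< 0.05 removed, strict) and the exact Hardy–Weinberg test (p < 0.001
removed, strict). The HWE p-value is the two-sided conditional exact test
computed in log space and verified against brute-force enumeration; the
exact test is conservative, so the realized rejection rate under
equilibrium stays below the nominal level. The order of individual- versus
locus-level filtering is a convention, not an inference; it is fixed so
reports are deterministic, and `apply_qc()` is idempotent.

## The synthetic-data generator

`sim_config()` defaults describe the emulated study population: 80 founders
and four discrete non-overlapping generations of strictly monogamous social
pairs with 3 offspring each (~650 individuals, near the ~700 genotyped
birds of the motivating system); a 20% per-offspring EPP rate (field
estimates 17–21%), the extra-pair sire drawn uniformly from the other males
of the parental generation; 1,000 unlinked biallelic loci with founder
minor-allele frequencies uniform in [0.05, 0.5], gene-dropped through the
*genetic* links; variance components Va = 13.5, Vpe = 8.2, Vres = 3.9
(the published pedigree-fit posterior means, total ~25.6 on the 0.1 mm
scale); five measurers with offsets up to ±0.5 units; and 1–3 measurements
per individual (the motivating data average ~1.7 per bird; the
within-population distribution of repeats is not published, so the uniform
1–3 default is a modelling choice). All randomness flows from the single
seed through fixed per-stage offsets; identical configurations give
byte-identical data.

Deliberate simplifications (documented limits of what passing tests show
about real data): no overlapping generations, immigration, selection or
assortative mating; no dominance or epistasis; no linkage — and breeding
values follow the pedigree recursion (founders N(0, Va); offspring =
midparent + Mendelian deviation N(0, Va/2), ignoring parental inbreeding,
adequate for pedigrees a few generations deep). Two consequences matter.
First, EPP replaces sires independently per offspring; brood-correlated EPP
is not modelled. Second, because breeding values derive from the pedigree
rather than from the simulated genomes, marker-based relatedness is a
*noisy proxy* for the breeding-value covariance even at high marker counts:
finite panels attenuate the genomic-matrix Va estimate, shrinking roughly
inversely with panel size (material at 1,000 loci, minor at 16,000),
whereas in real data the genome is the causal substrate and genomic
relatedness can capture *more* variance than pedigree expectations. Synthetic experiments therefore understate, never overstate,
the advantage of the genomic matrix.

## The pedigree-error experiment

The acceptance experiments run the deflation design at a scale a desk
machine handles: 44 founders, three generations, clutch-size-5 broods
(~430 individuals; large broods weight the information toward sibling
pairs, exactly the pairs EPP corrupts — and match the study species'
5–7-egg clutches), true h² = 0.5 with components Va = 12.8, Vpe = 9.0,
Vres = 3.8 (the published component proportions rescaled to h² = 0.5), a
16,000-locus panel so marker noise is small relative to the pedigree-error
effect (the motivating study used ~188,000 SNPs), and short single chains
(1,600 iterations, 500 burn-in) across ≥20 replicate seeds. Under those
conditions the social-pedigree fit's mean posterior Va falls below the
genomic fit's and Vpe moves the opposite way, while with EPP switched off
the two heritability credible intervals overlap in at least 18 of 20
replicates and the 95% interval covers the generating h² in ≥85 of 100
replicates. Credible-interval overlap is the declaration rule for a
difference between the two fits, mirroring standard practice in this
literature; the pipeline also reports `P(va_G > va_P)` from paired draws
as a finer-grained (clearly labelled) extension.

## Numerical choices and degenerate inputs

- PSD repair of `K`: diagonal jitter 1e-8×(trace/n), escalating tenfold to
  at most 1e-4, then a decomposition error; the VanRaden GRM of a
  population is singular along the all-ones direction by construction, and
  the jitter handles it.
- Monomorphic loci: HWE p-value 1 (single outcome); MAF 0, so the MAF
  filter removes them.
- Mantel test: undefined (error) when either off-diagonal vector is
  constant; permutation p-values use the add-one correction
  `(1 + #[r* ≥ r])/(n_perm + 1)`; bootstrap resamples individuals and drops
  pairs formed by duplicated copies of one individual.
- Empty id sets trim to empty objects with a warning; an individual with
  every genotype missing is a named coverage error.
- Priors: only the conjugate scaled-inverse-chi-square family is
  implemented. Fits in this conjugate family and the motivating study's
  half-Student-t setup agree qualitatively; prior sensitivity beyond that
  is the user's responsibility to check by varying `prior`.

## Known limitations

The sampler's intercept mixes more slowly than the variance components
(it is confounded with the mean breeding value, and with a genomic `K`
also with the matrix's singular direction); variance-component inference
is unaffected, but intercept Rhat benefits from the full default chain
length. The generator cannot demonstrate the genomic matrix *outperforming*
a correct pedigree (see above). Pedigree reconstruction from markers,
maternal and common-environment variance, multi-trait models and
cross-validation are out of scope.
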