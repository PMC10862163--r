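# pedgenvar

Quantitative geneticists working on wild populations estimate the additive
genetic variance (Va) and heritability (h²) of traits with the **animal
model**: a mixed model in which each individual's additive genetic merit is a
random effect whose covariance among individuals is proportional to a
relatedness matrix. In socially monogamous but genetically polygamous birds,
the field pedigree records the *social* father, so extra-pair paternity (EPP)
corrupts the paternal links; relatedness can instead be measured directly
from SNP genotypes. `pedgenvar` implements both routes and the machinery to
compare them:

- **Relatedness**: the additive (numerator) relationship matrix **A** from a
  pedigree by the tabular method (`A[i,i] = 1 + 0.5·A(sire,dam)`,
  `A[j,i] = 0.5·(A[j,sire] + A[j,dam])`), with dummy-parent insertion for
  broods with unidentified parents and trimming/projection to genotyped
  individuals; identity-by-state genomic similarity
  `G[i,j] = mean over loci of (2 − |g_i − g_j|)/2` and an
  allele-frequency-weighted (VanRaden) GRM on the relatedness scale.
- **SNP QC**: exact Hardy–Weinberg test (log-space conditional enumeration),
  minor-allele-frequency, per-SNP and per-individual missingness filters,
  sex-chromosome exclusion, with per-locus reports.
- **Matrix comparison & paternity**: Mantel permutation test with a
  bootstrap-over-individuals confidence interval; classification of social
  father–offspring pairs as within-pair (similarity > 0.3) or extra-pair
  (< 0.1).
- **Animal model**: Bayesian variance decomposition
  `y = Xb + Za + Zu + e`, `a ~ N(0, K·σ²a)`, `u ~ N(0, I·σ²pe)`, fitted by a
  conjugate Gibbs sampler (scaled-inverse-chi-square full conditionals,
  one-time eigendecompositions so each sweep is O(n²)), returning per-draw
  heritability `h² = σ²a/(σ²a+σ²pe+σ²res)`, the additive genetic coefficient
  `Va / trait mean`, and split-chain Gelman–Rubin diagnostics.
- **Synthetic data**: dual social/genetic pedigrees with controlled EPP,
  gene-dropped genotypes, and polygenic repeated-measure phenotypes with
  known variance components, so every stage has a parameter-recovery test.

## Worked example

```r
library(pedgenvar)

cfg <- sim_config(n_founders = 40, n_generations = 4, n_snps = 800, seed = 5)
run <- run_config(mode = "synthetic", sim = cfg,
                  mantel = list(n_perm = 99, n_boot = 50),
                  mcmc = list(n_iter = 1500, n_burnin = 500, n_chains = 2),
                  seed = 42)
report <- run_pipeline(run)
report
```

```
Pedigree (P) vs genomic (G) relatedness comparison

Component                P                      G
(Intercept)              175.00 (174.03, 175.88) 175.11 (174.53, 175.66)
measurerM2               1.18 (0.55, 1.81)      1.18 (0.55, 1.80)
...
Additive genetic         5.69 (2.15, 11.82)     5.61 (2.73, 10.38)
Permanent environment    12.75 (8.49, 16.79)    12.57 (9.41, 15.94)
Residual                 4.11 (3.53, 4.77)      4.12 (3.55, 4.82)
Heritability             0.25 (0.10, 0.47)      0.25 (0.13, 0.42)
Genetic coefficient      0.03 (0.01, 0.07)      0.03 (0.02, 0.06)

Mantel r = 0.678 (CI 0.639-0.711), p = 0.01
EPP: 23.51% (67 of 285 classified father-offspring pairs)
95% CrIs for h2 overlap; P(va_G > va_P) = 0.523
```

The two columns decompose the same phenotype data with the social-pedigree
matrix (P) versus the genomic matrix (G); "EPP" is the fraction of social
father–offspring pairs whose genetic similarity falls below 0.1 (here the
generator planted a 20% per-offspring EPP rate, and extra-pair sires that
are relatives of the social male are additionally reported as unresolved);
the final line applies the credible-interval overlap rule for declaring the
two heritabilities different. At this small demonstration size (~325
individuals, short chains) the posterior means sit well below the
generating values — the vignette discusses the panel sizes and chain
lengths at which the estimates are reliable.

Individual stages are plain functions: `simulate_pedigree()`,
`apply_qc()`, `build_a_matrix()`, `build_grm_ibs()`,
`mantel_correlation()`, `classify_paternity()`, `fit_animal_model()`
(returning a classed object with `print`, `summary`, `coef`, `plot`,
`fitted`, `residuals` methods), `summarize_heritability()`,
`genetic_coefficient()`.

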