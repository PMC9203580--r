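# eqtlatlas

Species-wide expression-QTL mapping and mediation analysis for panels of
inbred wild strains.

In selfing species such as *Caenorhabditis elegans*, hundreds of genetically
distinct wild strains (isotypes) can be grown as isogenic populations and
profiled by bulk RNA-seq in biological replicates. Treating each
transcript's abundance as a quantitative trait, genome-wide association
against biallelic SNVs reveals the regulatory architecture of expression:
**local eQTL** near the genes they regulate, **distant eQTL** elsewhere in
the genome, and **hotspots** where distant eQTL for many transcripts pile up
— the signature of variation in a shared regulator. Connecting this map to
organism-level traits, **mediation analysis** asks how much of a variant's
effect on a phenotype flows through the expression of a candidate gene,
which prioritizes causal genes even when allelic heterogeneity defeats
single-marker tests.

`eqtlatlas` implements the full pipeline as composable, pipe-friendly
functions returning tibbles:

* **Expression QC** — DESeq-style median-of-ratios normalization
  (`norm_factors()`), reliable-transcript filtering ("≥ 5 normalized counts
  in all replicates of ≥ 10 strains", `filter_reliable()`), per-strain
  hyper-divergent-region masking (`apply_divergent_mask()`), iterative
  removal of badly clustered replicate samples (`select_samples()`), and
  strain-mean trait construction on the `log2(TPM + 0.5)` scale.
* **Genotype relatedness** — missingness/MAF filtering, windowed LD pruning
  (50-marker windows, step 10, r² ≤ 0.8), kinship
  `K = MMᵀ / Σ p(1−p)` from centered dosages, Euclidean distance matrices
  and neighbor-joining trees (`nj_tree()`, via ape).
* **Mixed-model association** — EMMA-style REML variance components under
  the kinship covariance (`reml_null()`), P3D/EMMAX generalized
  least-squares scans (`gls_scan()`): per marker,
  `y = μ + xβ + g + e`, `g ~ (0, σ²_g K)`, tested by an F statistic in the
  whitened basis.
* **Thresholds** — eigenvalue-based effective number of independent tests
  (`meff_li_ji()`), EIGEN `−log10(0.05/Meff)` and Bonferroni thresholds,
  and a permutation-calibrated 5% FDR cutoff: map label-permuted traits,
  pool the peak significances of detected QTL, take their 95th percentile
  (`permutation_fdr()`).
* **QTL calling** — peak/interval extraction (±100 markers beyond the
  outermost significant markers), variance explained as squared
  peak-dosage/trait correlation, local/distant classification (±1 Mb from
  the TSS), inter-QTL LD, and fine-mapping candidate filters (top 5%
  significance ∧ outside common divergent regions ∧ negative BLOSUM score).
* **Hotspots** — distant eQTL binned in 0.5 cM windows; a bin is a hotspot
  iff its count exceeds the 99th percentile of a Poisson fit (MLE rate over
  all bins); adjacent hotspot bins merge (`detect_hotspots()`).
* **Heritability** — broad-sense H² from replicate variance
  (`value ~ 1 + (1|strain)`, lme4) and narrow-sense h² from kinship REML.
* **Mediation** — `med_test()` scores mediators by `|a·b|` on standardized
  variables with family-wise adjusted p-values from joint permutation of
  the mediator matrix; `estimate_proportion()` returns total/direct/indirect
  effects and the proportion mediated by the difference method;
  `make_pseudo_marker()` collapses allelic series;
  `regression_drop_scan()` re-tests a trait after regressing out each
  transcript's expression.
* **Synthetic studies** — `sim_config()` / `sim_study()` generate genotypes
  with LD blocks and population structure, expression with planted local,
  distant and hotspot eQTL at exact target heritabilities, divergent masks,
  and a mediated organismal trait, all with a ground-truth table; used
  throughout the tests and the acceptance script.

## Worked example

```r
library(eqtlatlas)

cfg <- sim_config(n_strains = 150, n_chrom = 5, markers_per_chrom = 200,
                  n_transcripts = 200, n_local_eqtl = 25, n_distant_eqtl = 25,
                  hotspot_spec = list(marker = NULL, n_targets = 20, h2 = 0.3),
                  seed = 42)
study <- sim_study(cfg)
res <- run_eqtl_study(study, fdr = "none")
res
#> <eqtl_study> 199 traits x 954 pruned markers; threshold 3.637
#>   eQTL: 90 (25 local / 65 distant); hotspots: 1
res$thresholds
#> <threshold_spec> Meff = 217 of 954 markers; EIGEN = 3.637 BF = 4.281
dplyr::select(res$eqtl, trait, chrom, peak_marker, neglog10p, ve, classification) |> head(4)
#> # A tibble: 4 × 6
#>   trait  chrom peak_marker neglog10p    ve classification
#> 1 T00004 I     M00040           4.08 0.174 distant
#> 2 T00007 V     M00989          14.9  0.438 local
#> 3 T00008 I     M00021           6.35 0.226 distant
#> 4 T00012 IV    M00643           9.61 0.419 local
glance(res$hotspots)
#> # A tibble: 1 × 4
#>   lambda_hat   q99 n_bins n_hotspots
#> 1     0.0421     1    499          1
```

One simulated study of 150 strains: 199 transcripts survive QC, 954 pruned
markers give an effective test count of 217 and hence an EIGEN threshold of
3.64 on the −log10 p scale. Ninety eQTL are called; local peaks explain more
trait variance (`ve`) than distant ones, and the distant eQTL pile into one
hotspot bin whose count exceeds the Poisson 99th-percentile threshold
(`q99 = 1` at the genome-wide rate of 0.042 eQTL per 0.5 cM bin).
`plot_eqtl_map(res$eqtl, study$annotation)` draws the classic
peak-vs-transcript diagonal map; `plot_hotspots(res$hotspots)` the hotspot
histogram; `autoplot()` on a `gls_scan()` result a Manhattan plot; `tidy()`
and `glance()` give broom-style summaries of fits.

Mediation of an organism-level trait:

```r
tm <- res$traits                                     # strain-mean expression
st <- colnames(tm)                                   # strains surviving QC
X <- setNames(study$genotypes$dosage[st, study$exposure_marker], st)
Y <- setNames(study$phenotype$value, study$phenotype$strain)[st]
med_test(X, t(tm[study$mediator, , drop = FALSE]), Y, n_perm = 1000, seed = 1)
#> # A tibble: 1 × 5
#>   mediator estimate    p_adj collinear n_used
#> 1 T00033      0.296 0.000999 FALSE        144
estimate_proportion(X, tm[study$mediator, st], Y)
#> # A tibble: 1 × 6
#>   total direct indirect proportion interpretable n_used
#> 1 0.982  0.536    0.446      0.454 TRUE             144
```

The planted mediator transcript (`T00033`) is recovered with the minimal
adjusted p-value at 1000 permutations; the difference-method decomposition
attributes 45% of the genotype's total effect on the trait to the mediated
path in this draw (144 strains carry all three data types after divergent
masking).

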