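---
title: "Species-wide eQTL mapping and mediation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-wide eQTL mapping and mediation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlatlas)
```

`eqtlatlas` implements a complete expression-QTL study for panels of inbred
wild strains — the design used for species-wide association mapping in
selfing nematodes such as *Caenorhabditis elegans*, where each genotype is a
fully homozygous isotype measured in two to three biological replicates.
This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the bundled synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## The data model

All stages work from four inputs:

* **Genotypes** (`geno_matrix`): strains × biallelic SNV dosages coded 0/1.
  Strains are inbred, so no heterozygotes are modelled; heterozygous or
  missing VCF calls become `NA` and are removed by `filter_markers()`
  together with markers below 5% minor allele frequency (strictly below —
  MAF exactly 0.05 is kept).
* **Expression** (`expr_matrix`): transcripts × samples, as raw counts and
  TPM, with `(strain, replicate)` metadata and a missingness mask.
* **Transcript annotation**: transcript, gene, chromosome, TSS, strand.
  Strand is carried but deliberately unused: the local/distant window is
  centred on the TSS regardless of orientation.
* **Per-strain hyper-divergent masks** (BED, 0-based half-open):
  genomic segments where a wild strain's sequence diverges so strongly from
  the reference that short-read quantification is unreliable; expression of
  transcripts whose TSS falls inside a strain's masked interval is treated
  as missing for that strain.

## Expression QC

**Normalization.** `norm_factors()` computes DESeq-style median-of-ratios
factors: for every reference transcript positive in all samples, the ratio
of each sample's value to the transcript's geometric mean is formed, and the
per-sample factor is the *median of those ratios in linear space*. (For an
even number of reference transcripts the linear-space median differs from
the exponentiated log-space median; the linear-space definition is used.)
Factors are computed before divergent masking — a masked cell is data
removed downstream, not evidence about the sample's scale.

**Reliable transcripts.** A transcript is kept iff at least 10 strains have
normalized counts ≥ 5 in *all* of their replicates (`filter_reliable()`,
both cutoffs tunable). A strain with one failing replicate does not count.

**Well-clustered samples.** `select_samples()` iterates: summarize counts to
gene level (sum of member transcripts), normalize, transform
`log2(x + 1)`, compute all-pairs Euclidean distances, and per strain compare
every intra-strain replicate-pair distance to the median of that strain's
pooled inter-strain distances. All pairs pass → keep all replicates; none
pass → remove the strain; a 3-replicate strain with one or two passing pairs
keeps its minimum-distance pair. The loop repeats on the reduced sample set
until a fixed point (cap 20 iterations). Two interpretations were open:

* *Ties.* "Smaller than" is read strictly — an intra-strain distance equal
  to the median inter-strain distance fails.
* *Pooling.* The inter-strain median pools all distances from any of the
  strain's samples to other strains' samples, rather than being computed per
  replicate.

The gene-level `log2(x + 1)` transform stands in for a variance-stabilizing
transform; the sample-selection rule depends only on relative distances, and
the property suite (contraction, idempotence at the fixed point, planted
outlier removal) validates the behaviour rather than numeric equality to any
particular VST.

**Strain means.** Mapping uses `log2(normalized TPM + 0.5)`; replicates are
averaged *after* the transform (the mapped scale is the transformed one, so
averaging on it keeps the trait linear-Gaussian). Masked replicates are
excluded; strains with no unmasked replicate are `NA` for that transcript,
and transcripts retaining fewer than 100 strains are dropped entirely.

## The mixed model

Association runs per strain-mean trait under

$$y = \mu + g + e,\qquad g \sim (0, \sigma_g^2 K),\quad e \sim (0, \sigma_e^2 I)$$

with kinship $K = M M^\top / \sum_j p_j(1-p_j)$ from column-centred pruned
dosages ($p_j$ the allele frequency). `reml_null()` eigendecomposes $K$
once, then maximizes the restricted likelihood over
$\delta = \sigma_e^2/\sigma_g^2$ on a 100-point log grid spanning
$[10^{-5}, 10^5]$, refined locally with Brent search; the refinement is only
accepted when it genuinely improves the likelihood. Two numerical choices
matter:

* With $K = I$ the profile is *exactly flat* in $\delta$ (the model is
  unidentifiable); ties within $10^{-6}$ resolve to the largest $\delta$,
  i.e. the no-genetic-variance end. This is the conservative choice: pure
  noise reports $h^2 \approx 0$ rather than $\approx 1$.
* Negative eigenvalues of $K$ within tolerance are clipped at zero, so
  variance components are non-negative and $h^2 = 1/(1+\delta) \in [0,1]$
  by construction.

`gls_scan()` uses the population-parameters-previously-determined (P3D /
EMMAX) scheme: variance components are estimated once per trait under the
null and held fixed across markers. Each marker is tested by generalized
least squares in the whitened eigenbasis with an F statistic on
$(1, n-2)$ degrees of freedom; p-values are floored at $10^{-300}$ and
monomorphic markers are recorded with $p = 1$ and flagged. Under $K = I$
the scan reduces exactly to the OLS F test, which the tests assert to
$10^{-8}$.

## Thresholds and permutation FDR

The effective number of independent tests (`meff_li_ji()`) comes from the
eigenvalues $\lambda_i$ of the marker correlation matrix (computed on the
strain side of the standardized dosage matrix, which shares the nonzero
spectrum): $M_\mathrm{eff} = \sum_i [\,\mathbb{1}(\lambda_i \ge 1) +
(\lambda_i - \lfloor \lambda_i \rfloor)\,]$. Eigenvalues are rounded at
$10^{-8}$ before flooring (a duplicated marker pair gives
$\lambda = 2 - \varepsilon$, and naive flooring would leak a spurious
fractional part), and the sum is capped at $m$. Whether the original study
used this particular eigenvalue estimator is not asserted; it is this
package's documented choice. Note the estimator is conservative when the
marker count approaches the strain count: for truly independent markers the
sampling spread of the correlation eigenvalues pushes
$M_\mathrm{eff}/m$ below 1 (about 0.76 at $m = n = 500$), so it should be
read as an effective count for the *pruned* marker set, which is much
smaller than the strain panel in this design.

Significance uses $-\log_{10}(0.05/M_\mathrm{eff})$ (EIGEN) or
$-\log_{10}(0.05/m)$ (Bonferroni). To correct additionally for the number of
*traits*, `permutation_fdr()` samples 200 traits, permutes each one's strain
labels 200 times (genotypes and kinship are never recomputed — only the
trait is permuted), maps every permuted trait at the raw threshold, pools
the peak significances of all detected QTL, and takes their 95th percentile
(type-7 linear interpolation) as the 5% FDR cutoff. If no permuted trait
yields a QTL the raw threshold is returned with a warning. The FDR cutoff is
used both for calling QTL and for the interval rule below; the spec left
open which threshold defines interval endpoints, and using one threshold for
both is the simpler, internally consistent reading.

## QTL calling, intervals, classification

Markers above threshold on one chromosome are grouped into a single QTL when
separated by at most 1000 pruned-marker indices (configurable; the original
pipeline does not state its grouping rule). The peak is the most significant
marker, ties going to the leftmost; the interval extends 100 markers beyond
the outermost significant members, clamped at chromosome ends. Variance
explained is the squared Pearson correlation between peak dosage and the
mapped trait (strain means on the transformed scale).

A QTL is **local** iff its peak lies on the transcript's chromosome within
1 Mb of the TSS (inclusive: exactly 1 Mb is local; 1 Mb + 1 bp is distant);
everything else, including other chromosomes, is **distant**.

## Hotspots

Distant eQTL whose peaks fall in *common* hyper-divergent regions are
excluded first. Common regions are 1 kb bins covered (≥ 1 bp overlap; the
overlap fraction is not specified upstream, so the most inclusive reading is
used) by masks of at least 5% of strains, merged when adjacent; the strain
denominator is a parameter defaulting to the number of masked strains
supplied. Remaining peaks are assigned to half-open 0.5 cM bins anchored at
each chromosome's minimum map position, keeping zero-count bins. The Poisson
rate $\hat\lambda$ is the maximum-likelihood estimate — the mean count over
*all* bins, empty included (exposed as a choice; the alternative of
non-empty bins only would inflate the threshold). A bin is a hotspot iff its
count strictly exceeds $q_{99}$, the smallest integer with Poisson CDF
≥ 0.99 at $\hat\lambda$; adjacent qualifying bins merge. Markers without a
genetic-map position (mitochondrial) never enter the binning.

## Heritability

Broad-sense $H^2$ fits the one-way random-intercept model
`value ~ 1 + (1|strain)` by REML on replicate-level expression
(`lme4::lmer`), unbalanced designs handled natively;
$H^2 = \sigma^2_\mathrm{strain}/(\sigma^2_\mathrm{strain} +
\sigma^2_\mathrm{resid})$, which matches the balanced ANOVA closed form to
$10^{-6}$ wherever the latter is in $[0,1]$. Narrow-sense $h^2$ is
$\sigma_g^2/(\sigma_g^2+\sigma_e^2)$ from the kinship REML fit on strain
means. Both lie in $[0,1]$ by construction because variance components are
truncated at zero.

## Mediation

For an organism-level trait with a mapped QTL, candidate mediators are
transcripts whose eQTL interval overlaps the trait QTL interval (closed
intervals, one shared base pair suffices). Strains are intersected across
genotype, expression and phenotype per analysis, and zero-variance triples
are dropped — so the number of performed analyses can be smaller than the
number of overlapping eQTL.

`med_test()` scores each mediator by $S = |a b|$ on standardized variables
($a$ the slope of $M \sim X$, $b$ the slope of $M$ in $Y \sim X + M$).
Family-wise adjusted p-values come from permuting the strain labels of the
mediator matrix jointly across mediators — the exposure–outcome pairing is
preserved, so the null hypothesis is "no mediation" while any direct
genotype–phenotype association remains intact. With the add-one correction,
$p_i = (1 + \#\{\text{perm}: \max_j S^*_j \ge S_i\})/(n_\mathrm{perm}+1)$.
Which variable the original analysis permuted is not recoverable from its
description; this scheme is the package's choice and its calibration is
enforced by tests rather than asserted as fidelity. A mediator exactly
collinear with the exposure ($|r_{XM}| = 1$) makes $b$ unidentifiable; such
mediators are flagged `collinear` and scored through the degenerate path
$b = r_{MY}$ (so a perfect exposure–mediator–outcome chain still scores
$S = 1$ with the minimal adjusted p) instead of being silently dropped.

`estimate_proportion()` uses the analytic difference method — total effect
$c$ from $Y \sim X$, direct $c'$ from $Y \sim X + M$, indirect $c - c'$,
proportion mediated $(c - c')/c$ — which for linear least squares on one
sample equals the product $a\,b$ identically (asserted to $10^{-10}$), and
is deterministic where a quasi-Bayesian simulation would not be. Proportions
outside $[0,1]$ are flagged uninterpretable; a total effect below
$10^{-12}$ leaves the proportion undefined. `call_significant()` flags
mediators with adjusted $p < 0.05$ *or* an estimate strictly above the 99th
percentile of the estimates in the same analysis (per analysis, not pooled
across traits), and the reported set additionally requires interpretability.

For genes whose causal variation is allelically heterogeneous,
`make_pseudo_marker()` collapses all qualifying variants of a gene into a
presence/absence dosage, and `regression_drop_scan()` residualizes the
outcome on each transcript's expression (OLS) and re-tests the residual at
the pseudo marker with the mixed model: a true mediator produces a large
drop in significance relative to the unregressed baseline, while unrelated
transcripts leave it essentially unchanged.

## The synthetic-data generator

`sim_study()` produces genotypes, expression (counts + TPM), divergent
masks, a mediated organismal trait, and a ground-truth table. Its defaults
are the study conditions the pipeline is tested under: 200 strains in 3
population groups (Balding–Nichols allele-frequency divergence 0.1), 6
chromosomes × 200 markers in 10-marker LD blocks (block-founder copying with
5% per-site mutation flips, so within-block $r^2$ is high and decays across
blocks), ancestral MAF uniform on [0.05, 0.5], 400 transcripts with 50
planted local eQTL at $h^2 = 0.45$ and 50 distant at $0.25$ (local effects
larger, matching the observed asymmetry between local and distant regulatory
variation), one 30-target master-regulator hotspot at $h^2 = 0.3$, 3
replicates with replicate noise SD 0.3 on the log2 scale, 5% of
(strain, region) pairs masked as hyper-divergent, and one organismal trait
whose exposure-marker effect is 26% mediated by a planted transcript. Where
the source study states no value (per-eQTL effect sizes, replicate noise,
masking rate, trait noise), values were chosen once as what a quantitative
geneticist would call realistic for this design and are exposed as
configuration, not revisited.

The per-transcript latent trait is built so the strain-level genetic
variance fraction equals the target $h^2$ *exactly* (empirical rescaling of
the genetic and environmental parts); TPM is $2^{\text{latent}}$ — a
positive monotone transform chosen so the downstream
$\log_2(\mathrm{TPM}+0.5)$ recovers an approximately linear-Gaussian trait
and the mixed model's assumptions hold by construction. Counts rescale TPM
by a lognormal per-sample library factor. All randomness flows from one
seed; sub-generators use fixed offsets of it, so identical configurations
give byte-identical studies.

What the generator does **not** emulate: coalescent demography and
selection, read-level RNA-seq noise (counts are a rescaled transform of
TPM, not a sampling process), batch effects, shared-gene transcript
structure (transcripts map 1:1 to genes), and real hyper-divergent regions'
sequence properties (masks are random intervals on a fixed 10-regions-per-
chromosome grid). Passing tests therefore demonstrate the pipeline's
statistical behaviour under its stated model, not robustness to alignment
artefacts or batch structure in real data.

## Problem sizes used in the test suite

The packaged checks run the calibration experiments at desk scale, chosen as
the smallest sizes at which the distributional claims are meaningful: type-I
error on ~20,000 marker tests at 200 strains; heritability recovery over 100
traits; permutation FDR at 50 traits × 50 permutations validated on 2,000
fresh null traits; hotspot detection over 20 simulated studies; mediation
recovery at 167 strains over 20 seeds; and one end-to-end study with 150
strains × 500 transcripts × 2,000 markers. Binomial checks (FDR exceedance,
family-wise error) are asserted through interval or one-sided binomial
tests at the simulated sample size rather than as point equalities.

## Known limitations

* The P3D approximation fixes variance components across markers; per-marker
  exact REML is not implemented (the approximation is standard and its
  calibration is tested, but strong single-marker effects slightly deflate
  the null components).
* `meff_li_ji()` is one member of the eigenvalue-based family of effective-
  test estimators; others (e.g. tail-probability corrections) would shift
  the EIGEN threshold by a few percent.
* The mediation machinery is linear-Gaussian only: no logistic outcomes, no
  joint multi-mediator path models, no sensitivity analysis for unmeasured
  confounding.
* Fine-mapping filters candidates (top 5% significance, outside common
  divergent regions, negative BLOSUM score) but does not model LD between
  candidates within the region of interest.
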