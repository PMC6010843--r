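---
title: "Methods: linking chemodiversity, population genetics, and disease in natural tree populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chemodiversity, population genetics, and disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`chemodivgwa` implements an integrative analysis for natural plant
populations profiled in two layers: an untargeted LC-MS metabolome
(aligned peaks characterized by m/z, retention time, and per-sample
intensity) and a reduced-representation SNP panel (biallelic SNPs on
short GBS tags, here 90 bp), together with sample metadata (collection
site, ecoregion, planar coordinates, a 1-5 canopy health score, and the
environmental covariates Tcol — temperature at the day of collection,
degrees C — and Bio14 — precipitation of the driest month, mm). The
motivating system is a disease-threatened understory tree sampled from
six collection sites in three ecoregions, roughly 30 trees per site, with
about 2,785 aligned LC-MS features collapsing to roughly 377 metabolites.

The pipeline runs in a fixed order: feature processing, chemodiversity,
population genetics, multivariate structure, mixed-model association,
graphical-model networks, and health biomarkers. Every stage is also
exposed as ordinary functions, and a synthetic-cohort generator with
recorded ground truth makes each stage testable by parameter recovery.

# Feature processing

**Outlier screening (DModX).** Samples are screened against a PCA model
of the autoscaled feature table. With K features, A components, and
per-sample residual sum of squares SS_i, DModX_i = sqrt(SS_i / (K - A)) /
s0, where s0 pools the residual variance over samples. A sample is
flagged when DModX_i^2 exceeds the upper-alpha quantile of an
F(K - A, (n - A - 1)(K - A)) distribution. The component count defaults
to 2 and alpha to 0.05; both are pipeline parameters.

**Redundant-peak grouping.** One metabolite typically produces several
aligned peaks (isotopes, adducts, in-source fragments) that share
retention time and are nearly perfectly correlated across samples.
Features are joined by an edge when |dRT| <= `rt_tol` (default 5 s, the
scale of the alignment bandwidth) and Pearson correlation >= `cor_min`
(default 0.75); groups are connected components, represented by the
member with the largest median intensity (median rather than a single
maximal value so that one aberrant sample cannot change the
representative; ties fall back to the larger mean, then the
lexicographically first id). Pearson is used because redundant peaks are
proportional on the intensity scale; the threshold is exposed. Values of
`cor_min` above 1 degenerate to all-singleton groupings and are allowed.
Note an identifiability limit: two *distinct* metabolites that both
co-elute within `rt_tol` and correlate above `cor_min` (e.g. members of
the same tightly co-regulated pathway) are merged by construction — no
correlation-and-RT rule can separate them. The exact-recovery property
therefore holds on cohorts where truth is identifiable, and recovery is
reported as an adjusted Rand index otherwise.

**Annotation.** Negative-ion mode with deprotonated molecules is assumed:
candidate neutral mass = m/z + 1.007276. All database compounds within
10 ppm (inclusive) are reported, ordered by ppm error. Other adducts are
out of scope.

**Log transformation.** Association and network stages use ln(intensity +
1); the offset handles not-detected zeros and is configurable. Diversity
indices are computed on raw intensities, because relative abundances on
the log scale are not compositional.

# Chemodiversity

Indices are computed per sample over the detected set (intensity strictly
above a detection threshold, default 0): richness S; Shannon entropy H in
nats; Hill numbers D1 = exp(H) and D2 = 1/sum(p^2) (effective metabolite
counts); Pielou evenness E = H / ln S, undefined (NA) at S <= 1; and
Berger-Parker dominance BP = max p, the relative abundance of the single
most abundant metabolite. Alpha richness is the within-site mean of S
(with a t-interval over samples); gamma richness is the number of
metabolites detected at least once in the site. Pielou's H/ln S is used
for evenness as the standard form; it is configurable because evenness
has competing definitions. All indices are scale-invariant and satisfy
D2 <= D1 <= S; these identities are asserted in the test suite.

The same indices can be recomputed within a metabolite subset (relative
abundances renormalized inside the subset), which is how dominance within
a biosynthetically related compound group — e.g. an iridoid-glucoside
family — enters the health models.

# Population genetics

* **Hardy-Weinberg**: exact two-sided p from the Levene-Haldane
  conditional distribution of the heterozygote count given allele counts,
  summing all outcomes no more probable than the observed one.
* **SNP filters**: minor allele frequency >= 0.05 over non-missing calls,
  call rate >= 0.80, and Hardy-Weinberg p >= 0.05 in strictly more than
  half of the subpopulations with at least 5 genotyped individuals (a SNP
  with no testable subpopulation passes; the alpha and the floor are
  exposed, since only the "over half of the subpopulations" rule is fixed
  by the protocol).
* **One SNP per tag**: neutral tags keep the SNP closest to the
  restriction cut site (minimal within-tag position); tags with any
  evidence of selection keep the SNP with the highest per-SNP F_ST. A tag
  carrying both class labels is treated as outlier. The output is split
  into the full association panel and the neutral reference panel.
* **Diversity statistics**: unbiased expected heterozygosity
  2pq * 2n/(2n-1) throughout; nucleotide diversity divides the summed
  site heterozygosity by tag count x tag length (the only sequence length
  GBS tags carry); rarefied allelic richness uses the exact
  hypergeometric form sum(1 - C(N - N_i, g)/C(N, g)) with g defaulting to
  the smallest number of gene copies seen anywhere.
* **Inbreeding F**: method of moments per individual against
  total-sample allele frequencies (pooled, PLINK-style); individuals with
  fewer than 20 genotyped loci are flagged unreliable.
* **Kinship**: identity-by-state similarity, (2 - |d_i - d_j|)/2 averaged
  over shared non-missing loci. Missing dosages are excluded pairwise
  here but mean-imputed in the association scan — an intentional
  asymmetry matching the respective conventions of the two estimators.
* **F_ST**: Weir-Cockerham (1984) variance components with the
  ratio-of-sums multilocus estimator, linearized as theta/(1 - theta) for
  distance-based analyses. Negative multilocus estimates truncate to 0;
  complete fixation maps to a configurable cap (default 100) with a
  warning.

# Multivariate structure

**DAPC.** Variables are autoscaled; PCA scores feed a linear discriminant
analysis. With site priors the retained PC count defaults to the smallest
number explaining 90% of variance, capped at n/3 against overfitting.
Without priors, cluster number is chosen by k-means over K = 1..K_max on
the full PC score matrix with BIC(K) = n ln(WSS_K/n) + K d ln(n), where d
is the score dimension. Two numerical points matter here and were
verified empirically: (i) cluster *identification* must use (nearly) all
PCs — in low dimension the best k-means split of pure noise removes a
large fraction of WSS, so truncated scores make every K look better than
K - 1; (ii) the penalty must count the K x d cluster-mean parameters — a
penalty of K ln(n) alone is smaller than the WSS reduction from splitting
noise at any n and d, so its argmin never selects K = 1 on unstructured
data.

**ANOSIM.** For each pair of subpopulations, pooled intersample distances
are ranked (mean ranks on ties) and R = (mean between-group rank - mean
within-group rank) / (M/2), M the number of pooled pairs, so R = 1 at
complete separation. Significance is by label permutation with the
(count + 1)/(n_perm + 1) estimator. The matrix of pairwise R serves as
the metabolic "distance" between subpopulations; because R can be
slightly negative under the null it is shifted by its minimum before use
in Mantel tests.

**Mantel tests.** Pearson r between upper-triangle distance vectors;
one-tailed p by simultaneous row/column permutation (9,999 by default,
with +1 smoothing so p is never 0); confidence intervals by bootstrap
over entities (500 by default, self-pairs dropped). The partial test
correlates the residuals of both vectors after linear regression on the
conditioning vector, which equals the closed-form first-order partial
correlation; conditioning on a matrix (nearly) identical to one argument
is degenerate (0/0) and should not be interpreted.

# Mixed-model association

The variance model is y = Xb + u + e with u ~ N(0, sigma_g^2 K) and
e ~ N(0, sigma_e^2 I), K the IBS kinship from the neutral panel
(symmetrized, eigenvalues floored at zero). REML estimation profiles the
likelihood in delta = sigma_e^2/sigma_g^2 using the one-time
eigendecomposition of the projected kinship; the profile is evaluated on
a 100-point grid of ln(delta) in [-10, 10], refined by Brent search in
every derivative sign-change interval, and the global optimum is
returned with a boundary flag. Pseudo-heritability is 1/(1 + delta).

The scan reuses the null-model variance components for every SNP (the
EMMAX approximation; exact per-SNP REML is available through the same
REML routine for testing): V^(-1/2) whitens the trait, covariates, and
dosages, and the dosage coefficient's t statistic gives the p-value.
Missing dosages are mean-imputed per SNP; SNPs monomorphic after
imputation are skipped. Four covariate configurations are run: none,
Bio14, Tcol, and both. Bonferroni control is per trait across SNPs
(alpha 0.05 / n_SNPs, the convention of single-trait scans; a global
denominator is a parameter away). Each trait/configuration is screened by
lambda_gc (the median chi-square inflation factor, accepted in
[0.8, 1.2]) plus a Kolmogorov-Smirnov uniformity test at 0.01 of the
p-values above the significance threshold; `significant` requires both
the Bonferroni pass and a clean screen. Whole traits are excluded by the
screen, not individual SNP results. One behavior worth knowing: a single
very large planted QTL inflates the null model's sigma_g^2 (its dosage is
partially aligned with kinship), which deflates the whole scan — the
screen then flags the trait as deflated. That is a faithful property of
the approximation, not a bug, and it is why power is assessed on the
Bonferroni p-value rather than the screened flag.

# Gaussian graphical model

With more metabolites than samples the sample covariance is singular, so
classical full-order partial correlations do not exist; this regime
dictated the estimator. The correlation matrix is shrunk toward the
identity with the analytic Ledoit-Wolf/Schafer-Strimmer intensity
lambda* = sum of estimated variances of off-diagonal correlations over
the sum of their squares (clamped to [0, 1]); partial correlations come
from the inverse of the shrunk matrix. Edge significance transforms the
partial correlations by Fisher's z and fits an empirical null scale as
the MAD of the (mostly null) z values when at least 50 pairs are
available; smaller problems fall back to the analytic standard error
1/sqrt(n - (p - 2) - 3). Benjamini-Hochberg q-values gate edges at
q <= 0.05; a fixed |pcor| threshold is available as an alternative.

The integrated network joins the GGM (metabolite-metabolite edges
weighted by partial correlation) with the association results (SNP-
metabolite edges weighted by -log10 p, annotated with the set of
covariate configurations under which they are significant). Nodes are the
metabolites with at least one retained GGM edge plus SNPs significantly
associated with those metabolites; SNPs with two or more metabolite
partners are flagged multi-associated. Output formats are GraphML plus
two edge-list TSVs.

# Health biomarkers

The 1-5 canopy score recodes to binary health (4-5 healthy, 1-3
diseased). Per-metabolite models are random-intercept logistic
regressions (Laplace-approximate ML via lme4) of health on the metabolite
abundance, controlling inbreeding F and Tcol with a site random
intercept; interactions are deliberately omitted (they were tested and
removed in the motivating analysis). Significance is the Wald z on the
focal term. Complete separation and constant predictors are detected and
refused. Random-forest ranking uses 1,000 trees, sqrt(p) features per
split, and OOB permutation importance (mean decrease in accuracy), with
the top 12 selected by default; the forest parameters are not fixed by
any protocol and are exposed. Subset-chemodiversity models recompute the
six indices within a metabolite group (by default, the GGM neighborhood
of the top-ranked biomarker) and substitute each index as the focal
predictor; an index constant across samples — richness under zero
dropout — is skipped with a reason.

# Synthetic cohorts

The generator emulates the study design rather than any particular
dataset: 6 subpopulations in 3 ecoregions, 30 trees each, 377 metabolites
expanding to about 2,785 features through a 1 + Poisson(6.39) redundancy
draw, and tagged SNP panels with neutral and outlier loci.

* **Genotypes** follow a Balding-Nichols model: subpopulation allele
  frequencies drawn Beta((1-F)/F p, (1-F)/F (1-p)) around ancestral
  frequencies. The draw is hierarchical — half of the target F_ST acts
  between ecoregions and half within (configurable) — so genetic
  structure mirrors geography, as in a transect design; region centers
  sit along the transect and the environmental covariates follow it
  (Tcol rises, Bio14 falls), giving realistic genotype-environment
  confounding. Per-individual inbreeding draws the second gamete
  identical by descent with probability f ~ Beta(1, 19) (mean 0.05).
* **Metabolites** are log-normal: baseline U(8, 14) on the ln scale (peak
  areas from ~3e3 to ~1e6), latent-pathway factors with loadings
  U(0.9, 1.1) and member residual SD 0.3 — within-pathway marginal
  correlations near 0.9, the regime of tightly co-regulated biosynthetic
  families — plus planted SNP effects, environmental slopes on centered
  covariates, and independent residuals (SD 0.5) elsewhere. Pathways are
  disjoint, so the true partial-correlation support is the union of
  within-pathway cliques. Redundant peaks scale the representative by
  U(0.1, 0.85) with ln-scale noise SD 0.05, share RT up to jitter, and
  take isotope/adduct m/z offsets.
* **Health** is logistic on true biomarker log abundances, F, Tcol, and
  site intercepts (SD 0.5). The non-intercept part is centered so the
  intercept logit(0.81) targets the observed healthy fraction of the
  motivating cohort; the realized marginal fraction is somewhat closer to
  one half because averaging the logistic over the linear predictor's
  variance shrinks it. The ordinal score quantile-bins the linear
  predictor within each binary class, so recoding the score reproduces
  the binary state exactly, by construction.

What passing tests do and do not show: the generator draws independent
individuals within sites, uncorrelated loci, disjoint pathways, Gaussian
residuals, and missingness/dropout completely at random. Real cohorts
have LD between tags, overlapping pathways, intensity-dependent detection
limits, batch effects, and spatial autocorrelation within sites — none of
which are emulated, so recovery results here bound what the methods can
do under clean conditions, not under field conditions.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at a "demo" scale
chosen so a complete run stays comfortably interactive on one core: 180
samples, 200 tags x 2 SNPs, 50 metabolites (about 370 features), with
permutation counts reduced to 99-999 where a calibration loops hundreds
of replicates. The paper-scale generator defaults (377 metabolites, 1,000
tags) are used where only a single cohort is needed. All randomness runs
through one global seed with per-stage derived substreams, so stages can
be regenerated independently; the same seed gives bit-identical cohorts.
Pipeline stages write JSON manifests with input hashes and parameters and
are skipped when still current, so corrupting an intermediate re-executes
exactly its consumers.

# Known limitations

Only [M-H]- annotation is supported; the GGM estimator assumes
approximately Gaussian log abundances and reports undirected conditional
dependence, not causality; the EMMAX approximation understates
single-SNP effects that contribute substantially to trait variance (see
the Q-Q note above); ANOSIM-as-distance is a pragmatic convention, not a
metric; and the ordinal health response is analyzed only through its
binary recode.
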