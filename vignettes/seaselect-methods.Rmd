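---
title: "Methods: models, defaults and design choices in seaselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in seaselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seaselect)
```

This vignette is the package's own account of the statistics it implements:
what each model assumes, which knobs matter, what the simulator does and
does not emulate, and where the design was genuinely open.

## The data model

Everything operates on a `geno_matrix`: samples × loci integer calls with
0/1/2 counting the alternate allele and `NA` as the missing sentinel. `NA`
was chosen over a magic integer because R's arithmetic propagates it loudly:
no statistic in the package can silently absorb a missing call. Missing data
are handled by pairwise deletion in all frequency-based statistics; only the
ordinations (RDA, PCA, DAPC, the latent-factor scan) mean-impute per locus,
which is the common practice for constrained ordinations of genotype
matrices and is logged whenever it happens. VCF positions are 1-based on
disk and 0-based half-open internally; the conversion happens only at the
I/O boundary.

## Candidate detection

**RDA.** With the centered genotype matrix $Y$ ($n \times L$) and centered
predictors $X$, the constrained ordination is the eigendecomposition of
$\hat Y = Q Q^\top Y$ where $Q$ spans $X$'s column space. Because
$\mathrm{svd}(\hat Y)$ and $\mathrm{svd}(Q^\top Y)$ share singular values
and right singular vectors, the scan computes the small $q \times L$
cross-product instead — this is what makes 1,000 permutations cheap. The
full-model test uses the pseudo-F on fitted versus residual sums of squares;
per-axis p-values compare the $k$-th permuted eigenvalue against the $k$-th
observed one. The outlier rule is the field's: on every constrained axis
with permutation $p \le 0.01$, flag loadings more than 3 SD from the axis
mean. Individuals inherit their locality's predictor values, since
environmental data are per-locality.

**Latent-factor scan.** The estimator is deliberately not an MCMC: one round
of regressing the predictor out of $Y$, a truncated SVD for the top-$K$
factors, then per-SNP OLS of genotype on predictor plus factors. With
$K = 0$ the z-scores are exactly the per-SNP OLS t-statistics, which the
tests assert. The genomic-inflation step is kept verbatim:
$\lambda = \mathrm{median}(z^2)/0.454936$ (the $\chi^2_1$ median), adjusted
$p = P(\chi^2_1 \ge z^2/\lambda)$, significance at $\alpha = 0.01$. The
rescaled statistic is invariant to a common scaling of the z-scores, which
is the point of the median correction. $K$ is chosen once per dataset by
masked-entry cross-validation of the truncated SVD (10% of entries masked,
reconstruction error on the mask, arg-min over $K = 0..k_{max}$) — a
deliberate simplification of per-$K$ scans whose merging rule would
otherwise be unspecified.

**FST-outlier scan.** Per-locus Weir–Cockerham $\theta$ with a null from
permuting individuals across localities (the same permutations for all
loci), empirical $p = (1 + \#\{\theta^{perm} \ge \theta\})/(n_{perm}+1)$,
Benjamini–Hochberg at FDR 5%. This is a frequency-based stand-in for a
Bayesian genome scan, and its null hypothesis is *no differentiation at
all*: under strong global structure every differentiated locus is "an
outlier", so the channel is liberal there by construction. The package
keeps it because the consensus rule only needs a third, frequency-only
channel; the calibration that matters — near-zero discoveries under
panmixia, recovery of strongly differentiated planted loci against a weak
background — is what the tests pin down.

**Consensus.** Candidates are loci flagged by at least two of the three
channels; the union (≥ 1) and the neutral complement (0) are reported
alongside Venn counts. The partition identities (consensus ⊆ union,
union ∪ neutral = universe, monotonicity in the inputs) are asserted as
properties.

## Diversity and structure

Per locus with $k$ non-missing gene copies and $x$ alternate copies:
unbiased $H_E = \frac{k}{k-1}(1 - p^2 - q^2)$ and
$\pi = \frac{2x(k-x)}{k(k-1)}$ are algebraically identical, an identity the
tests assert on random fixtures. $\theta_\pi$ is reported as the **sum**
over SNP loci — the mean pairwise difference between multilocus genotypes —
because that is the convention that produces the familiar >1 magnitudes in
per-population diversity tables of SNP panels; `per_site = TRUE` normalises
by the locus count. $F_{IS} = 1 - \Sigma H_O / \Sigma H_E$ uses the
ratio-of-sums (multilocus) convention over loci polymorphic in the
population, with significance from shuffling gene copies among individuals
within the population — a permutation that preserves allele frequencies and
destroys only the within-individual pairing.

Weir–Cockerham components $a$, $b$, $c$ follow the 1984 moment equations
with per-locus sample sizes (pairwise deletion); the multilocus
$\theta = \Sigma a / \Sigma(a+b+c)$ includes monomorphic loci (they
contribute zeros to both sums). An independently transcribed loop
implementation is the test oracle at $10^{-12}$.

AMOVA builds squared Euclidean distances between individual allele-count
vectors, rescaled by $L / L_{observed}$ per pair, and decomposes sums of
squares among regions / among localities within regions / within
localities with the standard unequal-size coefficients. Negative variance
components are reported as estimated and flagged, never truncated:
truncation would silently bias the percentage decomposition that users
read. Permutations are stratified per statistic ($\Phi_{ST}$: individuals
everywhere; $\Phi_{SC}$: individuals within regions; $\Phi_{CT}$: whole
localities among regions).

## Coding effects and rank enrichment

ORF prediction scans the three forward frames for leftmost-ATG-to-stop
spans of at least `min_codons` (default 100) translated codons —
transcripts are used in assembly orientation, so reverse-strand ORFs are
out of scope. Transcripts with more than one qualifying ORF are dropped
(ambiguous annotation); transcripts with none are excluded from the
classification universe rather than having their SNPs called oCDS, since
"outside CDS" is only meaningful relative to a CDS. Classification
substitutes the alternate base into its codon under the standard code:
premature stops and stop losses are a separate `nonsense` class excluded
from kN (the count ratio is conservative about protein-changing variants),
and stop-to-stop changes count as synonymous. kN/kS is a **count ratio**,
not a site-normalised rate: no attempt is made to correct for the differing
mutational opportunity of synonymous and non-synonymous sites, so it should
be compared between SNP sets, not against 1.

The enrichment walk ranks SNPs by percent contribution
($100 v_j^2$ for PCA; $100 b_{jf}^2/\Sigma b^2$ with
$b_f = P a_f$ for DAPC discriminant $f$) in descending order, ties broken
by locus id for determinism. At each depth $m$ from 10 to 200 a one-tailed
Wilcoxon rank-sum test asks whether kN SNPs rank higher than kS ∪ oCDS
SNPs within the top $m$; the exact distribution is used when both groups
are ≤ 25 (ranks are distinct, so ties never arise). Ranks are re-indexed
within the top-$m$ set; because the rank-sum test depends only on the
ordering, using global ranks restricted to the set would give identical
p-values. No multiplicity correction is applied across depths — the output
is the per-depth series, and the report never aggregates it into a single
p, because the minimum over the walk is not uniform under the null.

DAPC retains `n_pca` PCs then solves $B a = \lambda W a$; each discriminant
eigenvalue is the between/within variance ratio along the function. The
reported null behaviour of that ratio is the sampling noise floor of LDA
(it is not 0 in finite samples), so model assessment relies on the a-score:
observed nearest-centroid reassignment minus its mean over random-label
refits, arg-max over the candidate grid (plain arg-max, no spline
smoothing). The cluster search scores k-means solutions with
$BIC(k) = n \ln(W_k/n) + k \ln n$; this criterion behaves when many PCs
are retained (the per-split reduction of $W$ is then small relative to the
penalty), so `find_clusters_bic()` is meant to be run with a generous
`n_pca`, as is standard for cluster identification.

## The simulator: what it emulates, what it does not

`simulate_genotypes()` draws population allele frequencies from the
Balding–Nichols model — Beta with mean $p$ and variance $F p(1-p)$ — which
gives an analytic $F_{ST}$ target that the estimator-recovery tests use.
Adaptive loci shift the logit of the population frequency by $\beta$ per SD
of one designated predictor (one predictor per locus, assigned
round-robin); genotypes are binomial within populations (Hardy–Weinberg),
and missingness is uniform (MCAR). Defaults are the package's reference
study design: 8 localities × 30 diploids, 1,000 loci with 20 adaptive,
$F = 0.10$, $\beta = 2$, 5% missingness — sizes representative of a
reduced-representation study of a high-dispersal coastal invertebrate, kept
small enough that the full suite runs in minutes.

What the simulator does **not** emulate: linkage disequilibrium between
loci (all loci independent), demographic history and isolation by distance
(all populations exchangeable around one ancestral pool), population-biased
missingness, genotyping error, and multi-predictor architectures at a
locus. Tests passing on these simulations therefore demonstrate estimator
correctness and calibration under the stated model, not robustness to the
full messiness of empirical call sets.

`simulate_transcriptome()` builds UTR + ATG·(sense codons)·stop + UTR
transcripts, rejection-sampling away secondary reading frames of qualifying
length — including those that codon planting itself can open — so the
single-ORF guarantee holds by construction. Planted SNPs draw from
hard-coded substitution templates whose class is guaranteed by the code
table (for example third positions of 4-fold degenerate codons for
synonymous changes), giving the classifier an exact ground truth.

## Numerical and reproducibility choices

Permutation p-values always use the +1 correction, so they live in
$[1/(n_{perm}+1), 1]$ and can never be zero. Eigenvalues below
$10^{-12} \times$ the leading one are treated as null axes. The ridge added
to a singular within-cluster covariance in DAPC is $10^{-8}$ of its mean
diagonal and is logged. Every stochastic function takes an explicit seed;
the pipeline derives per-stage child seeds deterministically from one root
seed, and reruns are byte-identical (asserted in the tests). Reference
problem sizes used by the test-suite calibrations: $F$-recovery at
4 × 50 × 500 loci; scan calibration at 8 × 30 with 1,000–2,000 loci;
classification agreement on 10,000 planted SNPs; enrichment power on 250
transcript SNPs across 8 localities with the 30 non-synonymous SNPs tied to
a single predictor gradient.

## Known limitations

* The FST-outlier channel tests differentiation, not outlier-ness relative
  to a genome-wide background; under strong global structure its
  discoveries approach the locus count, and only the consensus rule keeps
  the candidate set selective.
* RDA's full-model permutation test is calibrated under the global null (no
  structure, no association). When population structure exists but is
  environment-independent, locality-constant predictors can still explain
  among-population variance, and the full-model p is anticonservative —
  an inherent property of ordinating structured genotypes on group-level
  predictors, worth remembering when reading empirical RDAs.
* kN/kS counts are not mutational-opportunity corrected (above).
* ORF prediction is forward-strand and one-ORF-per-(frame, stop); it does
  not model alternative initiation or frameshifts.
* AMOVA assumes the squared-Euclidean genotype distance; sequence-aware
  distances are out of scope.
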