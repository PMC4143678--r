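---
title: "Estimated genetic values in extended pedigrees: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimated genetic values in extended pedigrees: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egvkit)
```

This vignette is the package's account of its science: the models it fits,
the numerical routes it takes, the parameters that matter, what the synthetic
data generator does and does not emulate, and where genuinely open design
choices were resolved.

## 1. Relatedness

Two routes to the n×n relatedness matrix **R** = 2Φ (twice the kinship
coefficient) are provided.

**Expected (pedigree) relatedness** uses the recursive tabular algorithm in
generation order: founders have self-kinship ½ and mutual kinship 0; for a
non-founder *i* with parents *f*, *m*, φ(i,i) = ½(1 + φ(f,m)) and
φ(i,j) = ½(φ(f,j) + φ(m,j)) for every *j* processed earlier. The method is
exact (it reproduces textbook values — parent–offspring 2φ = 0.5, half-sibs
0.25, an offspring of full-sib mating has diagonal 1.25 — and agrees with
single-locus gene-drop Monte Carlo within sampling error) and costs O(n²)
memory. The diagonal is 1 + F with F the inbreeding coefficient. Pedigree
validation is deliberately strict: duplicate ids, cycles and half-specified
parentage (one parent named, the other missing) are errors rather than
silently repaired, because malformed pedigrees corrupt every downstream
matrix.

**Empirical relatedness** uses the KING-robust estimator,

$$\hat\varphi_{ij} = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)},$$

over SNPs non-missing in both samples. It is robust to allele-frequency
misspecification, which matters in structured samples; the cost is that a
pair with no heterozygous sites has an undefined estimate (reported as an
error naming the pair). Choices made here, configurable but defaulted:

* `variant_set = "common"` applies a MAF ≥ 0.05 filter (the "SNP" flavour);
  `"all"` uses every polymorphic site (the "sequence" flavour).
* SNPs with > 10% missingness are dropped globally; remaining missing
  genotypes are handled pairwise-complete.
* The diagonal is fixed at 1: no marker-based inbreeding estimate is
  attempted, since the downstream model only requires a valid correlation
  structure and marker-based self-kinship is noisy at realistic SNP counts.
* Between-family and within-family pairs use the same estimator. How the
  original KING software's family-specific substructure correction was
  configured in the motivating analysis is not documented anywhere we can
  recover, so the homogeneous-population form is used and stated openly; the
  simulator generates homogeneous populations, for which the two coincide.

**Nearest-correlation repair.** Raw KING matrices are generally not positive
semidefinite, and the EGV equation needs an invertible R. The repair is
Higham's alternating projections between the PSD cone (eigenvalue clipping)
and the unit-diagonal set, with Dykstra's correction so the iteration
converges to the Frobenius-nearest point of the intersection. Convergence
tolerance 1e-8 on the successive-iterate max-norm, cap 500 iterations,
non-convergence is an error carrying the last residual. The output has an
exactly-unit diagonal and smallest eigenvalue ≥ −1e-8; tests verify
Frobenius optimality against an independent brute-force minimiser (and
`Matrix::nearPD`) and idempotence. Empirical matrices additionally receive a
1e-8 diagonal ridge wherever they are inverted.

## 2. Covariates: genotype PCA with parental-mean projection

Population-structure covariates are computed the family-aware way: principal
components are fitted on a mutually unrelated subset only (greedy selection
by sorted id with pairwise R < 0.05 — deterministic, since the historical
pre-designated unrelated panels cannot be reconstructed), on an LD-pruned
marker set; all founders are then scored with the fitted loadings and each
non-founder receives the mean of its two parents' scores, recursively in
generation order. Projection by parental means (rather than by SNP loadings)
is the rule implemented; it is exact for the expectation of an additive score
under Mendelian transmission and requires founders to be genotyped, which the
simulator guarantees.

LD pruning is the standard greedy sliding window (defaults: window 50 SNPs,
step 5, r² ≤ 0.2). The drop rule within a violating pair — remove the member
with the larger summed r² against the other survivors, ties to the later
position — is chosen for determinism; no published default exists for the
historical marker panel, so these values are configuration, not doctrine.
Genotypes are standardised by √(2p(1−p)) by default (`scaling = "center"`
disables it).

## 3. The polygenic model

The variance-component model is y = Xβ + g + e, Var(g) = σ²_g R,
Var(e) = σ²_e I. One spectral decomposition R = UDUᵀ turns the covariance
into a diagonal family σ²_p (h²D + (1−h²)I) in the rotated basis; for fixed
h², β and σ²_p have closed-form GLS/profile solutions, leaving a 1-D
maximisation of h² on [0, 1] (golden-section via `optimize`, tolerance 1e-8,
endpoints checked explicitly). ML is the default — matching the convention
of the variance-component software this workflow descends from — with REML
available. Numerical conventions:

* boundary optima are returned as exact 0 or 1 with `boundary = TRUE`;
* a likelihood flat in h² (R = I makes σ²_g and σ²_e unidentifiable) returns
  the h² = 0 boundary with a warning;
* eigenvalue clipping at 0 guards tiny negative eigenvalues after repair;
  matrices with eigenvalues below −1e-6 are rejected as non-PSD.

Tests verify the spectral likelihood against a directly-coded dense
multivariate-normal log-density to 1e-8, affine invariance of ĥ², GLS
orthogonality of residuals, and parameter recovery (|mean ĥ² − h²| < 0.05
at h² ∈ {0.2, 0.5, 0.8}, n = 847, 50 replicates).

## 4. Estimated genetic values

The EGV is the BLUP of g given the residualised phenotype:

$$\mathrm{EGV} = (I + R^{-1}\lambda)^{-1}(y - X\hat\beta), \qquad
  \lambda = \hat\sigma^2_e/\hat\sigma^2_g.$$

The implementation never forms R⁻¹: the algebraically identical form
R(R + λI)⁻¹(y − Xβ̂) is computed by Cholesky factorisation of R + λI, which
is defined even for singular R and numerically safer. λ = 0 returns the
residual unchanged; λ → ∞ shrinks to zero; tests check agreement with an
explicit-inverse Henderson mixed-model-equations solve to 1e-8.

**The error-variance matrix E.** The workflow that motivated this package
incorporated a "pairwise error variance matrix" into the association model
without ever defining it. Here E is the standard BLUP prediction-error
variance,

$$E = \mathrm{Var}(\widehat g - g) = \sigma^2_g R - \sigma^2_g R (R+\lambda I)^{-1} R
    = \sigma^2_g \lambda\, R (R+\lambda I)^{-1},$$

which is the natural candidate (it is what the mixed-model-equations inverse
yields), vanishes as σ²_e → 0 and reduces to the scalar shrinkage variance
σ²_g λ/(1+λ) at R = I. This is an implementer's interpretation and is
documented as such.

Per-replicate pipelines (`egv_pipeline`) re-fit the polygenic model for every
phenotype replicate — covariate values are fixed, their effects re-estimated —
and use that replicate's own λ. Replicates whose ĥ² hits the zero boundary
yield skip records: without additive variance the EGV is undefined. When an
EGV is computed from an empirical R, the same R is used in the polygenic fit
that supplies its variance components; the historical analysis is ambiguous
on this point, and using one matrix throughout keeps λ internally consistent.

A property worth knowing when interpreting results: re-fitting the polygenic
model on EGVs roughly doubles (or more) the fitted heritability relative to
the raw trait, because the BLUP is by construction smooth in the R-metric.
The acceptance suite asserts the ratio exceeds 1.5 at designed h² = 0.3; a
fitted h² near 1 for an EGV trait is expected behaviour, not a bug.

## 5. Measured-genotype association

Each SNP is tested by a likelihood-ratio test of one additive fixed effect
added to the polygenic null model, with all variance parameters re-optimised
in both models; the statistic 2Δlog L is clamped at zero and referred to
χ²(1). The null model is fitted once per (trait, replicate) and reused across
SNPs. Missing dosages are mean-imputed per SNP; monomorphic SNPs yield skip
records; per-SNP failures never abort a scan.

The family covariance is printed in the source workflow as
Ω = σ²_p(2Φh² + Iσ²_e + Eε), which mixes scaled and unscaled terms. The
implementation reads it as a variance-shares model:

$$\Omega = \sigma^2_p\,(2\Phi\,h^2 + I\,e^2 + E_n\,\varepsilon),
  \qquad h^2 + e^2 + \varepsilon = 1,\; h^2, e^2, \varepsilon \ge 0,$$

with E normalised to unit mean diagonal so ε is a proportion comparable to
h². At ε = 0 this is exactly the standard polygenic covariance (unit-tested:
supplying an identity-proportional E reproduces the no-E likelihood).
Expected kinship 2Φ is used in Ω for *all* traits, including empirically
derived EGVs; E is included for EGV traits and omitted for the raw
phenotype. Computationally, when E shares eigenvectors with 2Φ — true
whenever E is the prediction-error variance built from the same pedigree
matrix — the whole optimisation stays in the eigenbasis (weights
h²dᵢ + e² + εuᵢ, simplex-parameterised Nelder-Mead); otherwise a dense
Cholesky path is used. The two paths agree to 1e-4 on commuting fixtures.

Calibration is a first-class requirement: on ~2,000 null SNPs at n ≈ 420 the
empirical type-I error at α = 0.05 must sit inside the exact binomial 99%
interval and the median-based inflation λ inside [0.9, 1.1]; the calibration
fixture uses LD-free SNPs so the binomial reference is honest.

Two thresholds are carried deliberately: genome-wide significance 5e-8
drives the summary tables, while a looser evaluation-inclusion threshold
5e-7 bounds which SNPs are LD-classified at all, mirroring the two printed
conventions of the motivating workflow.

## 6. Evaluation against a known architecture

A significant SNP is a true positive iff its r² (squared Pearson correlation
of dosages) with any causal SNP of some gene on the same chromosome reaches
`r2_block` = 0.2. This max-r²-to-causal-SNP rule operationalises "falls
within an LD block surrounding a causal gene" without a haplotype
block-segmentation algorithm — the simplest faithful and fully testable
reading. One hit may vouch for several genes (regions of extended LD
genuinely do implicate neighbouring genes); the per-gene table counts a hit
for every gene clearing the threshold, while the single best gene (max r²,
ties by genomic distance then name) labels the hit. Monomorphic hits are
unclassifiable and conservatively counted as false positives. FDR is pooled
across replicates (false positives / total significant); a per-replicate
mean is also computable, and with zero significant hits the FDR is reported
as not applicable rather than 0. Conservation (TP + FP = total) and
monotonicity (raising r2_block never increases TPs) are asserted property
tests.

## 7. The synthetic study generator

The generator emulates the study conditions of a workshop-style family
design, and its defaults *are* those conditions: 20 extended families
totalling 847 individuals over 4 generations (sibships 1 + Poisson(1.8),
spouses married in as founders; after the random draw, youngest-generation
leaves are added or removed deterministically to hit the target size
exactly); 100 phenotype replicates over fixed genotypes, covariates and
effect sizes; four causal genes of 15/14/16/8 SNPs designed to explain
7.79%/4.67%/3.87%/2.06% of total variance; a causal-site MAF quota of 10/53
below 1% and 18/53 between 1% and 5%; background polygenic h² 0.2; an
age/sex covariate share of 0.1; total variance 400 (sd 20 mm Hg) around a
mean of 120. Where the historical design left values unstated (sibship
distribution, LD strength ρ = 0.7, 4 chromosomes × 500 SNPs at desk scale,
per-SNP effect shapes), values were fixed once at field-plausible levels and
exposed as configuration.

Implementation choices that matter:

* **Founder haplotypes** come from a latent Gaussian AR(1) process
  thresholded at the per-site frequency quantile. A naive "copy the previous
  allele with probability ρ" chain would smear marginal frequencies toward
  their neighbours' (q_k = ρq_{k−1} + (1−ρ)p_k) and destroy the rare-variant
  quota; the thresholded-copula construction preserves marginals exactly
  while giving monotone LD decay in ρ, with ρ = 0 yielding independence.
  Both properties are tested.
* **Gene drop** transmits recombined parental haplotypes (crossovers
  Poisson(1) per chromosome per meiosis, uniform breakpoints). Mendelian
  consistency and realised kinship (KING on the dropped genomes recovers
  0.5/0.5/0 for parent–offspring/sib/between-family within 0.02 at 20,000
  SNPs) are tested.
* **Effect calibration.** Per-gene SNP effects are drawn once
  (standard-normal weights scaled by 1/√(2p(1−p)), so rare variants get
  larger per-allele effects) and rescaled against the *realised* dosage
  covariance so each gene's in-sample contribution variance equals its
  designed fraction of total variance exactly — under LD among a gene's
  SNPs, calibrating against theoretical 2p(1−p) would not achieve this, and
  parameter-recovery targets would be ill-posed.
* **Randomness** flows from one master seed through named substreams
  (pedigree, haplotypes, gene drop, per-replicate draws), so any stage can
  be regenerated in isolation; reproducibility is tested byte-for-byte.

What the generator does **not** emulate: coalescent-accurate haplotype
diversity, demographic history, genotyping error, ascertainment, household
environment, dominance or X-linkage. Passing tests therefore demonstrate
correctness of the estimators under a clean additive family model — not that
real blood-pressure GWA would behave identically. In particular the exact
hit counts and FDR values of any real study are data-dependent and are not
reproduction targets; the package reproduces the *report formats* and the
*recovery properties*.

## 8. Measuring realised variance fractions

`gene_variance_share` estimates the share of phenotypic variance a causal
gene explains, the quantity the acceptance script reports. A naive
regression of y on the gene's dosages is badly behaved here for three
reasons: overfitting bias of order p/n; fixed in-sample covariance between
the gene's dosage span and the other genes' and covariates' contributions
(in family data, rare-variant dosage columns are nearly family indicators,
so spans of different chromosomes correlate); and polygenic variance
absorbed by the gene's span in excess of the iid degrees-of-freedom
correction. The estimator therefore regresses the phenotype on covariates
plus *all* causal dosages jointly under the fitted polygenic mixed model
(GLS, so family-structured noise is whitened) and reports

$$\widehat{f}_g = \frac{\operatorname{var}(G_g\hat\beta_g) -
  \operatorname{tr}\!\big(\widehat{\mathrm{Var}}(\hat\beta_g)\,
  \widehat{\mathrm{Cov}}(G_g)\big)}{\operatorname{var}(y)},$$

averaged over replicates; the trace term removes the estimation-noise
inflation of var(G_g β̂_g). Monomorphic causal sites (possible for designed
frequencies near 0.1% at n ≈ 850) drop out of the regression.

## 9. Problem sizes and limitations

The test suite runs the full 847-member design where the property demands it
(heritability recovery, variance-fraction recovery, EGV amplification, KING
at 20,000 SNPs) and scaled-down fixtures (40–420 members, hundreds of SNPs)
elsewhere; these sizes are the package's chosen desk-scale study points and
keep the whole suite under a minute of compute. Known limitations: the MGA
dense path (non-commuting E) costs one Cholesky per likelihood evaluation
and is not meant for genome-scale scans; the greedy unrelated-subset and
LD-pruning rules are deterministic stand-ins for historical panel choices;
no household or dominance variance components; EGVs are computed only for
phenotyped individuals.
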