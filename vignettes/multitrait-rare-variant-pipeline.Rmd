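---
title: "Multi-trait rare-variant gene-based association with a shared genetic impact trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait rare-variant gene-based association with a shared genetic impact trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Back-pain-related phenotypes — chronic back pain (CBP), dorsalgia, and
intervertebral disc disorder (IDD) — are binary, heritable, and
genetically very similar to one another (pairwise genetic correlations
around 0.9), yet each on its own gives an under-powered rare-variant
scan: liability-scale SNP heritabilities are modest (on the order of
0.08–0.12) and prevalences range from ~18% down to below 2%.  The
strategy implemented here pools the three traits into a single *shared
genetic impact trait* (SGIT), a linear combination whose coefficients
maximize the proportion of the genetic background common to all traits,
and then runs summary-statistics gene-based rare-variant tests — under
nested functional annotation masks and with ultra-rare-variant
collapsing — on the original traits and on the combination.  Genes that
cross the significance threshold are re-scored conditionally on nearby
external association signals.

Because the motivating cohort data are access-restricted, the package
ships a synthetic cohort generator that reproduces the *statistical
structure* of such a study (prevalences, heritabilities, a single
shared genetic factor, rare and ultra-rare exonic variants with
consequence labels).  Every claim the package makes about itself —
calibration, oracle agreement, parameter recovery, the multi-trait
power advantage — is demonstrated on that generator by the test suite
and the acceptance script, never asserted from outside numbers.

## The generative model

Each binary trait $k$ arises from a liability threshold model.  The
liability is

$$
\ell_k \;=\; \sqrt{h^2_k}\,\bigl(\lambda_k\, g_{\mathrm{sh}}
      + \sqrt{1-\lambda_k^2}\; g_{\mathrm{sp},k}\bigr) \;+\; e_k ,
$$

where $g_{\mathrm{sh}}$ is a standardized genetic score shared by all
traits, $g_{\mathrm{sp},k}$ a trait-specific score, $\lambda_k$ the
shared-factor loading, $h^2_k$ the liability-scale heritability, and
$e_k$ the non-genetic component (covariate effects plus correlated
residual noise, scaled so the total liability has unit variance).  An
individual is a case when $\ell_k$ exceeds the empirical
$(1-\text{prevalence}_k)$ quantile of the realized liability
distribution; using the empirical quantile rather than the theoretical
normal one pins realized prevalences to their targets to within $1/n$
in every finite sample.

Genetic scores are built from causal rare variants: per-variant effect
magnitudes scale with $|\log_{10}\mathrm{MAF}|$ (the rarer the variant,
the larger its effect — the usual rare-variant convention), with the
sign fixed deleterious for loss-of-function (LoF) consequences with
probability 0.95 and random otherwise.  Under this construction the
pairwise *genetic* correlation between traits is
$\lambda_i\lambda_j$ (plus a vanishing specific-component term), so the
default loadings $\lambda_k=\sqrt{0.9}$ give the genetic correlations
of about 0.9 that motivate pooling the traits.

Default study conditions: $n = 20{,}000$ individuals; prevalences
17.97%, 3.48%, 1.76%; $h^2 = (0.12, 0.114, 0.08)$; rare-variant MAF
spectrum log-uniform on $(1/2n,\,0.01]$; VEP-style consequence labels
drawn with realistic exome proportions (~4% LoF, ~32% missense-class,
~19% synonymous-class, the rest intronic/UTR).  The liability-scale
cross-trait correlations of the non-genetic component are solved from
target total liability correlations of 0.45–0.55, a range consistent
with the substantial observed comorbidity among these phenotypes; the
solver fails loudly if the targets are unattainable given $h^2$ and
$\lambda$.  The *observed-scale* phenotypic correlation matrix is
never an input: it emerges from thresholding and is estimated
downstream from summary statistics, exactly as in a real analysis.

What the generator deliberately does not emulate: linkage
disequilibrium beyond an optional first-order autoregressive haplotype
copula (`ld_rho`; used by the conditional-analysis tests), relatedness
and population structure (covariate "principal components" are noise
columns, so the mixed-model random effect of large-biobank scans is
unnecessary and a plain logistic score test is the correct analogue),
sex chromosomes, and any realistic effect-size architecture — the
effect sizes of real genes in such cohorts are not publicly knowable,
so power statements are relative comparisons at a planted effect, not
absolute predictions for real data.

## Stage 1: the association scan

Each variant is tested with a covariate-adjusted logistic **score
test**: one null model `status ~ sex + age + batch + PC1..PC10` per
trait, then per variant $U = g'(y-\hat\mu)$,
$V = g'Wg - g'WX(X'WX)^{-1}X'Wg$, $z = U/\sqrt V$.  Score tests remain
stable down to a handful of carriers, which Wald statistics do not; an
optional saddlepoint correction (`spa = TRUE`) guards the extreme
case-control imbalance of the rarest trait.  Variant QC keeps MAF
$\ge 5\times10^{-6}$ (boundary included) and missingness $\le 0.02$;
missing dosages are dropped per variant (complete-case), because mean
imputation distorts minor-allele counts exactly where they matter most
(ultra-rare variants).

**Ultra-rare collapsing.** Within each gene and annotation mask,
variants with MAC $\le 10$ are recoded into one pseudo-variant per
individual: 2 if homozygous for a rare allele at any collapsing
variant, 1 if heterozygous at any, 0 otherwise.  The pseudo-variant is
then scored by the same single-variant test and enters the gene test
alongside the individually testable (MAC $> 10$, MAF $\le 0.01$)
variants.

## Stage 1b: the shared genetic impact trait

With $\gamma_k = \lambda_k\sqrt{h^2_k}$ (the standardized genetic
covariance of trait $k$ with the shared factor), the combination
$a'T$ maximizing the proportion of shared genetic background,
$(a'\gamma)^2 / (a'Pa)$, is $a \propto P^{-1}\gamma$ — a generalized
Rayleigh quotient with a rank-one numerator, so the closed form is
exact.  Rather than trusting the derivation, the closed form is
*validated against brute-force maximization* on random panels in the
tests.

Three design choices were genuinely open:

* **Normalization.** We impose $a'Pa = 1$, giving the combination unit
  phenotypic variance so that its z-score is simply $z_S = a'z$ with no
  rescaling; the sign is fixed so the largest-|a| trait enters
  positively.  Published coefficient values for this kind of analysis
  depend on an unstated normalization, so only the qualitative ordering
  of coefficients (traits with more shared signal and less redundancy
  get larger weights) is asserted.
* **Factor loadings.** For three traits the one-factor loadings have
  the closed triad form $\lambda_i=\sqrt{g_{ij}g_{ik}/g_{jk}}$; more
  traits use least squares on the off-diagonals.  Heywood cases are
  clipped to $[0,1]$ with a warning.  Heritabilities and genetic
  correlations are *inputs* (or simulation truth); LD-score regression
  is out of scope.
* **Phenotypic correlations from summary data.** Under the null the
  per-variant z-vector is $N(0,P)$, so $P$ is estimated from the
  correlation of z-scores over putatively null variants (all
  $|z| < 2$).  Restricting to a box attenuates correlations in a known
  way; the estimator inverts the exact truncated bivariate-normal
  attenuation curve (computed by Simpson quadrature and solved by
  root-finding), which removes the bias that a naive truncated
  correlation would carry even for genuinely null variants.

## Stage 2: gene-based tests from summary statistics

Inputs per gene: the aligned z-vector, Beta(1,25)-density MAF weights
$w$ (the rare-variant convention; the collapsed pseudo-variant receives
the maximum weight of its members), and the genotype correlation matrix
$R$ estimated from the cohort (filters: MAC $\ge 3$, missingness
$\le 0.02$; the pseudo-variant column is always retained).  $R$ is
regularized by an eigenvalue floor at $10^{-8}$ of the leading
eigenvalue — collapsed columns and tight LD otherwise make it
numerically singular.

* **Burden**: $z_b = w'z/\sqrt{w'Rw}$, two-sided normal.
* **SKAT**: $Q_\rho = (1-\rho)\sum(w_jz_j)^2 + \rho(\sum w_jz_j)^2$;
  under the null $Q_\rho$ is a quadratic form in $N(0,R)$, scored
  through the eigenvalues of the induced kernel.  $\rho=0$ is classic
  SKAT; $\rho=1$ reduces algebraically to the squared burden statistic
  (asserted in the tests).
* **SKAT-O**: minimum p over the canonical eight-point grid
  $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ with the
  one-dimensional-integration null of the minimum (the decomposition
  over the burden direction with a variance-adjusted remainder term).
  If the integration fails the package falls back to Bonferroni over
  the grid, with a warning — never silently.
* **PCA test**: project $Wz$ onto the leading eigenvectors of the
  kernel $WRW$, keeping the smallest $k$ whose eigenvalues reach 85% of
  the total variance; $T=\sum_{l\le k}(u_l'Wz)^2/\lambda_l\sim\chi^2_k$
  under the null.
* **ACAT-O**: the Cauchy combination
  $T=\sum w_i\tan((0.5-p_i)\pi)/\sum w_i$,
  $p = 0.5-\arctan(T)/\pi$, combining the SKAT-O and PCA p-values per
  mask.  Inputs at 0/1 are clamped to $[10^{-15}, 1-10^{-15}]$ with a
  warning, and the numerically stable expansion $1/(p\pi)$ is used for
  tiny inputs.

Annotation masks are nested vocabularies of VEP-style consequence
terms: **LoF** (frameshift, splice acceptor/donor, start loss, stop
gain/loss, transcript ablation), **LoF+missense** (adding transcript
amplification, inframe insertion/deletion, missense, protein
altering), **LoF+protein-coding** (adding synonymous, start/stop
retained, coding sequence, incomplete terminal codon), and **all
intragenic** (every within-gene term including UTRs and introns).
Genes need at least two testable variants (the collapsed pseudo-variant
counts as one); single-variant genes report only the single-variant
burden p.  A separate **LoF burden** collapses *all* of a gene's LoF
variants (regardless of MAC) into one pseudo-variant and single-variant
tests it.

**Quadratic-form tail probabilities** are computed by Imhof's exact
characteristic-function inversion on an adaptively truncated range
(the truncation point chosen so the envelope tail is a small fraction
of the p-value itself), switching to the Kuonen saddlepoint
approximation below $p \approx 5\times10^{-4}$, where the saddlepoint's
relative accuracy does not degrade; the Liu moment-matching
approximation serves as last-resort fallback and as the fast inner CDF
of the SKAT-O omnibus integration (the reported per-$\rho$ p-values
stay on the exact path).  The Imhof route is validated against
million-draw Monte-Carlo sampling in the tests.

Significance uses the fixed-gene-count Bonferroni convention:
$0.05/20{,}000 = 2.5\times10^{-6}$, with a suggestive level ten times
larger; a configuration switch substitutes the observed gene count.

## Stage 3: approximate conditional analysis

For each significant gene, index variants are selected stepwise in a
window extending 1 Mb beyond the gene borders, with the selection
threshold set to the minimum p-value inside the gene (so the gene's own
top signal always seeds the search).  Candidates with $r^2 > 0.9$ to an
already selected variant are skipped; ties break by position, then id.
Selected variants *outside* the gene form the conditioning set, and
in-gene variants are re-scored on the standardized scale
($b^* = z/\sqrt{2f(1-f)(n+z^2)}$):

$$
z_{\mathrm{cond}} = \frac{z_t - R_{tc}R_{cc}^{-1}z_c}
                         {\sqrt{1 - R_{tc}R_{cc}^{-1}R_{ct}}},
$$

which equals the target's coefficient z in the joint model containing
the conditioning set (verified against full joint logistic fits in the
tests).  An empty conditioning set returns the marginal statistics
bit-for-bit; conditioning a variant on itself returns zero.  The
conditional z-vector re-enters the same gene-test battery with the
gene's own LD matrix (the de-correlation of residual z is second-order
at the $r^2$ values the collinearity guard admits, a standard
approximation in summary-statistic conditional gene tests).  One LD
panel serves both the gene tests and the window search; the original
two-panel design (exome plus imputed genotypes) collapses to a single
synthetic panel here.

## Study sizes and what the tests show

The suite exercises the pipeline at sizes chosen to make every check
statistically meaningful while completing in minutes: calibration uses
2,000 independent null genes on a 20,000-individual cohort (binomial
standard error ~0.005 at $\alpha=0.05$); the power study plants a
shared-only effect diluted over 20 causal genes — which puts the SGIT
gene test's per-seed detection probability near the informative middle
of the power curve — and compares paired per-seed detections at
$2.5\times10^{-6}$ over 60 replicates with exact sign tests; oracle
comparisons use 6–10-variant genes where full joint logistic fits and
million-draw Monte-Carlo nulls are cheap.  Passing these tests shows
the machinery is correct and calibrated *under the generator's
assumptions*; it does not certify behaviour under real-data phenomena
the generator omits (LD structure, relatedness, phenotype
misclassification, genuine effect-size architectures).

## Known limitations

* The score test's normal approximation degrades for ultra-rare
  variants combined with very low prevalence; the saddlepoint option
  mitigates but the default calibration study deliberately tests the
  MAC-above-collapsing regime the gene tests actually consume.
* The SKAT-O omnibus null is itself an approximation (as in its
  original formulation); its accuracy is asserted empirically at
  conventional $\alpha$ and by dominance bounds, not proven in the far
  tail.
* Conditional re-scoring keeps the marginal LD matrix for the
  conditional z-vector rather than re-deriving the conditional
  correlation structure.
* The one-factor genetic model is an assumption, not an inference: with
  three traits it is exactly identified, so model misfit is invisible
  at $K=3$.
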