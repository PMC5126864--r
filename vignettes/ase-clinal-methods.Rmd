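---
title: "Methods: allele-specific expression and latitudinal cline analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and latitudinal cline analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

When a wild-derived haploid *Drosophila* genome is crossed onto the sequenced
reference strain, every F1 individual is heterozygous with a known phase: one
haplotype is always the reference. RNA-seq reads overlapping exonic SNPs can
then be assigned to the wild or the reference allele, and a departure of the
wild/reference read ratio from 1:1 within a genotype indicates a
*cis*-regulatory difference between the two alleles (allele-specific
expression, ASE). Aggregated over panels of lines from temperate and
tropical populations on two continents, ASE lets one ask whether the
frequencies of *cis*-regulatory alleles change with latitude in parallel on
both continents — the signature expected from spatially varying selection or
parallel admixture.

`clinase` implements that full analysis as a reusable, tested pipeline:
probabilistic SNP filtering, per-gene allele counting, a binomial mixed-model
ASE test, maximum-likelihood high/low-allele grouping, and the clinal
concordance and enrichment statistics, driven by a synthetic-data generator
that emulates the study design so that every stage can be validated against
known ground truth without any sequencing data.

# The core model

For one gene, let $w_{i}$ be the wild-allele read count of observation $i$
(one library of one genotype) out of $n_{i}$ allele-informative reads. The
model is a binomial logit GLMM,

$$
w_i \sim \mathrm{Binomial}\!\left(n_i,\ \mathrm{logit}^{-1}(x_i^\top\beta +
u_{g(i)} + v_i)\right),\qquad
u_g \sim N(0, \sigma_g^2),\qquad v_i \sim N(0, \sigma_r^2),
$$

with a genotype-level random effect $u_g$ and an observation-level random
effect $v_i$ that absorbs extra-binomial variation between biological
replicates (overdispersion). Because *cis*-regulatory variation makes
different genotypes carry different CRE alleles, genotype-level heterogeneity
in the allelic ratio *is* the ASE signal: the test for ASE is a likelihood
ratio test of $\sigma_g = 0$, i.e. twice the difference in maximized marginal
log-likelihood between the full model and the model with the genotype effect
removed. p-values use the $\chi^2_1$ reference by default; since the null
value lies on the boundary of the parameter space this is conservative, and
the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture is available via
`null_dist = "mixture"`. Genome-wide significance is controlled by
Benjamini–Hochberg FDR at 0.20.

## Fitting: nested adaptive Gauss–Hermite quadrature

The marginal likelihood integrates over both random effects. The package
exploits the genotype → replicate nesting: the observation-level integral is
a one-dimensional function of the linear predictor, evaluated by adaptive
Gauss–Hermite quadrature centred at its conditional mode (found by Newton's
method; the integrand is strictly log-concave), and the genotype integral is
handled the same way one level up. Cost is therefore linear in the number of
genotypes. Defaults are 9 nodes per dimension; the accuracy contract —
checked in the tests — is that the fitted log-likelihood moves by less than
$10^{-4}$ when the node count is doubled. Maximization is bounded
quasi-Newton (`optim(method = "L-BFGS-B")`) over the fixed effects and
log-SDs, with starting values from the no-random-effect binomial regression,
a relative objective tolerance near $10^{-9}$, and an analytic gradient
computed with the adaptive centres held fixed (exact to quadrature
accuracy). Either variance can be constrained to exactly zero, which is used
both for the reduced model of the LRT and for the unit test that the
constrained fit reproduces `glm()` coefficients. `lme4::glmer` (Laplace,
with an explicit observation-level factor) serves as an independent
cross-check in the test suite, not as the fitting engine: it cannot
constrain a variance to zero, cannot combine two random effects with
multi-node quadrature, and is several-fold slower than needed for the
Monte-Carlo validation studies.

Non-convergence is reported through a flag and propagates to an `NA`
p-value; it is never silent.

## Gene inclusion

Only genes where enough genotypes have biological replicates support the
observation-level variance. The rule — at least 12 genotypes with counts in
two replicates for the gene (configurable) — resolves the ambiguity of
"samples with biological replicates" toward the interpretation that matches
the design's 12–16 replicated genotypes per analysable gene.

# SNP filtering and allele counting

SNP support thresholds guard against a worst-case systematic sequencing
error in which every error at a site produces the same wrong base at phred
20 ($p = 0.01$). `min_supporting_reads(depth)` returns the smallest $m$ with
$P(X \ge m) < 10^{-4}$ for $X \sim \mathrm{Bin}(depth, 0.01)$ — e.g. 4
supporting reads at depth 15, 7 at depth 100 — and is verified against an
exact tail-sum oracle for all depths 0–1000. Site filters then require depth
≥ 15, exactly two allele states, overlap with a gene interval (BED
convention: 0-based half-open input, converted internally to 1-based), and
membership in a biallelic whitelist VCF (position and allele pair).
Reads assigned the wild allele at one SNP and the reference allele at
another are dropped by default (smallest information loss); alternatively
SNPs whose observations are conflicted at a rate above a threshold are
removed first. Per-gene counting then tallies one call per read, so row
totals always equal the number of retained allele-informative reads.

Residual reference-mapping bias is summarised as per-sample and per-gene
(pooled) reference-allele proportions; genes are stratified at < 0.45 /
\> 0.55 for the robustness re-analyses.

# Allele grouping

For each ASE gene, lines are sorted by the log2 wild/reference ratio of
replicate-summed counts (a 0.5 pseudocount on both alleles only when a
count is zero, and only for ordering/display — model fits always use raw
counts). Every ordered split into a top and bottom group is scored by the
full mixed model plus a two-level Group fixed effect, and the
maximum-likelihood split wins. The split enumeration runs over all $L-1$
ordered splits of the $L$ lines with data; the alternative reading of the
source procedure (enumerating only up to the number of non-replicated lines
minus one) is available through `max_top_size`. Ties (within $10^{-4}$ log
units, which also defines the degeneracy flag for exchangeable data) break
toward the more balanced split. The group whose mean ratio is nearest 0 is
the reference-CRE group; the sign of the other group's mean decides whether
the wild allele is the high- or low-expression allele, and per-line
high/low calls follow group membership. ASE magnitude is the difference of
group mean log2 ratios.

# Clinal statistics

* **cpm and filtering** — counts per million with the non-strict "≥ 1 cpm in
  ≥ 10 samples" retention rule; per-sample cpm sums to $10^6$ by
  construction.
* **Down-sampling** — multivariate hypergeometric draws per sample to a
  fixed total, applied to count tables (alignment being out of scope);
  column sums match the target exactly and proportions are unbiased.
* **Latitudinal DE** — a pluggable per-gene two-group test; the default is
  Welch's comparison of log2(cpm + 0.5), tropical minus temperate, per
  continent. Downstream statistics use only signs and p-values, so a
  moderated-dispersion test can be slotted in without touching anything
  else.
* **Concordance** — among genes significant on either continent, the
  proportion with the same direction of change on both, with 95% binomial
  intervals by Wilson (score inversion, no continuity correction) and
  Clopper–Pearson (exact beta quantiles). Both are reported because no
  single method reproduces every printed interval in the source analyses:
  Wilson reproduces the 53/59 interval (80–95%) and Clopper–Pearson the
  159/192 interval (77–88%). Interval endpoints are rounded half away from
  zero to whole percent for reporting.
* **Latitudinal ASE** — per-population mean ASE from a Population
  fixed-effect (cell-means) fit of the same mixed model; the latitudinal
  difference is tropical minus temperate per continent; significance of
  latitude by an LRT dropping Latitude and Latitude×Continent jointly (2 df
  default, 1-df interaction-only variant available). Cross-continent
  agreement is a tie-corrected Spearman correlation (t approximation;
  exact permutation p for small tie-free samples).
* **Enrichment** — Fisher's exact test of ASE membership against
  latitudinal-differentiation membership ("p < 0.05 on ≥ 1 continent and
  concordant direction", the figure-legend rule, as default); a
  power-matched variant thins the higher-coverage gene set's allele counts
  hypergeometrically to quantile-match total-count distributions before
  re-testing, which removes enrichment that is purely a coverage artefact.
* **Allele effects on expression** — log2 ratio of mean cpm between high-
  and low-allele lines correlated with ASE magnitude, and the major/minor
  comparison restricted to genes with MAF < 0.30, with a one-sample t test
  of the mean log2 major/minor ratio.
* **QC** — PCA outlier flagging on standardized log2 cpm at 3 SD on PC1/PC2
  (the outlier rule in the source analysis is unstated; this is the
  package's own definition).

# The synthetic-data generator

`simulate_ase_dataset()` inverts the analysis model exactly: per gene a CRE
effect $\delta \sim N(0, \texttt{cre\_effect\_sd})$ (or a fixed planted
value), per-genotype carrier status of the alternate CRE allele drawn from
the population's allele frequency (the wild chromosome is haploid in the
cross design), genotype and replicate noise, negative-binomial depths, and
binomial wild counts with an additive logit mapping-bias shift toward the
reference allele. Identical `(config, seed)` reproduce byte-identical
output; per-gene random streams are derived deterministically from the
master seed and gene index.

Default study conditions, chosen once to mirror the design: 2 continents ×
2 latitude classes, 13 genotypes per population with 4 replicated (52
lines, 68 libraries), negative-binomial depth with mean 100 and dispersion
size 5 (per-gene depth distributions are unknowable without raw reads, so
these remain configurable), balanced baseline, CRE effect SD 0.5 logits,
residual genotype SD 0.1 (kept small because genotype-level variance is
itself the ASE signal; CRE effects, not residual noise, should dominate),
replicate SD 0.2, and a mapping-bias shift of 0.004 logits, which
reproduces a mean reference fraction of ~50.1%. Alternate-allele
frequencies default to 0.5 everywhere; latitude-structured clines (e.g. 0.8
tropical / 0.2 temperate) are set per latitude class or per population.
`total_expression_coupling` (default 1.3) multiplies expected total counts
of high-allele carriers, giving the ASE→expression coupling the analysis is
meant to detect.

What the generator does **not** emulate: read-level artefacts (alignment,
base quality, positional error structure), linkage between genes, shared
library-size factors, batch structure, and trans-acting variation. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery under the model's assumptions, not robustness to
every artefact of real RNA-seq data.

For workflow demonstrations and the acceptance script,
`simulate_study_mixture()` composes three gene classes under one design:
cline genes (latitude-structured alternate-allele frequencies, expression
coupling), spectrum genes (per-gene Beta(0.6, 0.6) allele frequencies — a
U-shaped spectrum reminiscent of a site-frequency spectrum — with coupling
but no cline, and with 80% of effects oriented so the minority allele is the
lower-expressed one, emulating low-frequency expression-reducing variants),
and null genes (no CRE variation, no coupling). The
CRE-variable classes use effect SD 0.8 logits so that skewed-frequency
polymorphisms remain detectable at the default depth, which is what makes
the major/minor-allele analysis (restricted to MAF < 30%) non-empty at desk
scale. Latitudinal differentiation in total expression arises only through
the cline genes, so ASE enrichment among latitudinally differentiated genes
is a genuine end-to-end signal rather than an artefact of the class sizes.

# Validation studies and problem sizes

The test suite validates each stage against independent oracles: exact
binomial tail sums for the SNP threshold, hand-computed and enumerated
values for BH, Spearman, Fisher and both binomial CIs, `glm()` for
constrained fits, `glmer` for the mixed model, and ground-truth recovery
for the generator-driven studies. Monte-Carlo sizes were chosen to keep the
standard error of each checked property well below its margin: 1000 null
genes for the type-I error of the ASE LRT (16 genotypes, depth 100,
$\sigma_r = 0.2$), 200 genes for $\sigma_g$ recovery (52 genotypes, depth
200, $\sigma_g = 1$; mean absolute error ≤ 30%), 200 genes for exact
planted-partition recovery (13 lines, separation 1.5 log2 units, depth
~200, ≥ 95% exact), and 20 replicate datasets of 500 genes for the
end-to-end clinal recovery (alternate-allele frequency 0.8 tropical / 0.2
temperate on both continents; the cross-continent Spearman correlation of
latitudinal ASE differences must be positive at p < 0.01 in ≥ 95% of runs,
with a one-continent-cline control centred on zero; the control uses 10
runs).

# Numerical choices and degenerate inputs

Zero-total rows are dropped before fitting; a gene with all totals zero is
an error. Variance components are optimized on the log scale with a lower
bound of $10^{-4}$ on the SD, so the boundary is approached smoothly; the
reduced model of the LRT fixes $\sigma_g$ at exactly zero and the statistic
is clamped at 0 (tolerance $10^{-6}$). Rank-deficient fixed-effect designs
raise a classed error rather than silently aliasing. Fisher tests with a
degenerate margin return p = 1; Spearman with a constant vector returns
`NA` with a note; exact ties in the grouping's |group mean| comparison make
the larger group the reference and flag the gene.

# Known limitations

The LRT's $\chi^2_1$ default is conservative at the boundary, matching the
source analysis rather than optimal power. The Welch DE default is less
powerful than moderated negative-binomial tests at small $n$. The grouping
procedure considers exactly two allele classes; genes segregating more than
two functional CRE haplotypes will be forced into the best two-group
approximation. Mapping bias is modelled as a single additive logit shift,
not an allele-specific alignment process.
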