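---
title: "Methods: RNA-editing discovery, quantification and QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-editing discovery, quantification and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editqtl)
```

# Overview

`editqtl` implements an analysis pipeline for adenosine-to-inosine (A-to-I)
RNA editing in outbred mammalian populations, built around paired DNA and
RNA sequencing of a discovery cohort and RNA sequencing of a larger
quantification cohort. Inosine is read as guanosine by sequencers, so edits
appear as A>G mismatches present in RNA-derived variant calls but absent
from the same animals' DNA-derived calls. The pipeline covers:

1. **Discovery** — subtraction of DNA variants from RNA variants, quality
   filters, positional artifact filters, cohort-level curation, and
   strand-resolved classification and genic annotation of surviving sites.
2. **Quantification** — per-animal editing proportions (Φ, the fraction of
   reads carrying the edited base), logit mapping phenotypes, neighbor-base
   context analyses and sequence-logo information content.
3. **Structure** — prediction of double-stranded pre-mRNA regions by
   dot-plot scanning for inverted repeats, and location of each edit site's
   predicted opposite base.
4. **Association** — generalized least squares (GLS) mapping of editing,
   expression and trait phenotypes under a pedigree covariance, with an
   inflation diagnostic and cis/trans classification.
5. **Integration** — read-pair phase tests, the allele-complementarity
   sign test, Φ–expression correlations, and edQTL/eQTL cosegregation by
   rank correlation of association profiles.

A synthetic-data generator (`sim_config()` and the `simulate_*` functions)
provides inputs with the statistical structure the analysis assumes, so
every stage is testable without sequencing data.

# The association model

For each phenotype vector $y$ (logit-Φ for editing, variance-stabilized
exonic counts for expression, trait measurements for lactation phenotypes)
and each variant dosage $x \in \{0,1,2\}$, the model is

$$ y = X\beta + \varepsilon,\qquad X = [\,1, x\,],\qquad
   \mathrm{Var}(\varepsilon) = W = \sigma_P^2\,(0.3\,A + 0.7\,I), $$

where $A$ is the pedigree numerator relationship matrix (built by the
recursive tabular method in `a_matrix()`) and $\sigma_P^2$ the phenotypic
variance. The fixed 0.3/0.7 mixture is treated as a given constant of the
method, with a configurable override in `gls_fit()`/`gls_scan()`. The Wald
statistic $\chi^2 = (\hat\beta/\mathrm{se}(\hat\beta))^2$ is referred to a
1-df chi-square distribution. Per phenotype, the inflation statistic is the
observed median $\chi^2$ divided by 0.4549, the median of $\chi^2_1$; values
near 1 indicate that the pedigree covariance is adequately absorbing
relatedness.

Numerical route: $V = 0.3A + 0.7I$ is Cholesky-factorized once per
phenotype; each variant is then an ordinary regression on whitened data.
The result is contractually identical (to 1e-8 relative, tested) to the
direct formula $\hat\beta = (X^\top W^{-1}X)^{-1}X^\top W^{-1}y$ with
$\mathrm{Var}(\hat\beta) = (X^\top W^{-1}X)^{-1}$.

Choices the method description leaves open, resolved here:

* **$\sigma_P^2$ estimator** — the sample variance of the analyzed
  phenotype vector, re-estimated per phenotype. $W$ enters the statistic
  only through scale and structure; this convention fixes the scale and
  makes $\chi^2$ invariant to affine rescaling of $y$ (tested).
* **Missing genotypes** — animals are dropped pairwise per variant.
  Imputation inside the statistics engine is deliberately avoided; cohorts
  genotyped on imputed (complete) panels are unaffected.
* **Reference distribution** — a 1-df chi-square (identical to a squared
  standard normal).
* **Genotype screening** — variants with minor allele frequency below 1%
  or an exact Hardy–Weinberg test P below 1e-30 are dropped
  (`genotype_screen()`); the exact test is implemented in-package because
  no installed dependency provides one.

# Discovery filters

Candidate sites are RNA-called variants with no DNA-called variant at the
same position with the same alleles. The quality filter retains candidates
with call quality ≥ 30, at most one missing genotype, and at least six
observed alternate alleles (boundary semantics: "five or fewer" removed).
The positional filter removes sites:

* within **W = 4 bp** of an annotated splice junction, on the intronic
  side. "Adjacent to a splice site" has no canonical distance; 4 bp
  intronic of each junction follows established RNA-editing filtering
  practice, and W is configurable.
* inside, or immediately adjacent to, a **homopolymer** run of ≥ 5
  identical bases — a deliberately conservative reading of "adjacent to"
  that also removes sites inside the run.
* whose edited reads occur only in the **first or last six bases** of
  reads. Because alignment parsing is out of scope, this predicate
  consumes a per-site table of edited-read offsets produced upstream
  (or by the simulator), keeping the filter testable without BAMs.
* inside the **repeat/low-complexity mask** (consumed as BED).

Cohort curation keeps sites where at least $\lceil 2N/3\rceil$ of $N$
animals have an edited read and at least $\lceil 2N/3\rceil$ have depth
≥ 5. The depth rule is implemented as "at least two-thirds of animals
have ≥ 5 reads", the reading consistent with its purpose of requiring
broadly quantifiable sites. Manual appraisal of alignments, sometimes used
as a final curation step, is inherently not implementable and is replaced
by the automated predicates plus a per-site report
(`curate_cohort()$stats`) to support external review.

Classification complements alleles on minus-strand genes before naming the
substitution, reporting A>G on the transcript strand as A-to-I. Region
assignment reassigns sites upstream/downstream of a gene to 5'/3'-UTR
respectively (annotated UTRs are frequently shorter than the transcribed
region evident in RNA data), bounded at a configurable 5 kbp so distant
intergenic sites are not absorbed; coding impact is computed from the codon
substitution inside annotated CDS.

# Editing proportions and context

Φ = edited/total reads per site and animal, missing when no reads cover the
site. Mapping phenotypes use the Haldane–Anscombe logit
$y = \log\{(e+0.5)/(t-e+0.5)\}$, which keeps boundary proportions finite
while remaining strictly monotone in the edited count — the standard
resolution for boundary proportions Φ ∈ {0, 1}.

Sequence-logo columns report $2 - H - e(n)$ bits with $H$ the Shannon
entropy of the column's base frequencies and $e(n) = 3/(2\ln 2\, n)$ the
small-sample correction; negative corrected values are clipped to 0
(the presentation convention of the logo method). The edit-site column uses
the unedited reference base: with all 2380 A-to-I sites carrying adenosine
the column height is 1.999 bits.

Neighbor-base enrichment is a two-sided exact binomial test of each base's
count at offsets −1/+1 against background frequencies estimated from the
±10 bp flanks of the same sites (excluding offsets −1, 0, +1) — a
self-contained background requiring no genome-wide pass. The Φ–context
association is a one-way ANOVA of site-level mean Φ (one value per site,
not animal-level, to avoid pseudo-replication) by upstream base, downstream
base, and the joint 16-level grouping.

# Double-stranded structure prediction

Within each gene, sequence spanning the outermost edit sites ±1.5 kbp is
extracted; regions over 15 kbp are split into chunks with 1.5 kbp overlap
so helices spanning a cut are seen whole in one chunk (the chunking rule is
otherwise unspecified; overlap prevents systematic misses). The dot-plot
places a dot at position pair $(i, j)$ when at least 11 of the 15 base
pairs centered on the pair are Watson–Crick complementary (A:U, C:G only;
G:U wobble is excluded from the scan criterion and handled only in
interpretation of opposite bases). The scan is computed per anti-diagonal
with a running window sum (O($n^2$) rather than O($n^2 w$)) and is tested
for exact agreement with a brute-force oracle.

Helix calls from dot-plots are traditionally visual. Here they are
automated as anti-diagonal runs of ≥ 25 consecutive dots with zero gap tolerance
(bulges split helices) — a deterministic, conservative stand-in. The
pairing map follows run geometry ($i \leftrightarrow d-i$ on diagonal $d$)
and is self-inverse by construction. Thermodynamic refinement of helix
geometry is out of scope; the dot-plot is the defining computation.

# The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is
tested under:

* **Cohort**: 355 animals from 50 founders over three generations —
  the scale of the quantification herd.
* **Genotypes**: 400 variants on one 4 Mbp synthetic chromosome (so
  500 kbp cis windows are meaningful). Founder haplotypes follow a
  Gaussian-copula AR(1) model: marginal allele frequencies are exactly as
  drawn (Hardy–Weinberg at each variant) and LD decays with distance at
  rate 2e-6/bp (~0.4 correlation at 500 kbp). Descendants receive one
  whole parental haplotype per parent (no within-chromosome
  recombination); LD beyond the founder structure arises only from
  cosegregation. A per-variant independent-transmission mode destroys LD
  for null tests.
* **Editing model**: per site, logit-Φ is
  $\mu + \beta x + g + e$ with $g \sim \mathrm{MVN}(0, \sigma_g^2 A)$ and
  $e \sim N(0, \sigma_e^2)$; read totals are Poisson and edited counts
  binomial. $\mu = \mathrm{logit}(0.165)$ (the observed median site Φ of
  16.5%); $\sigma_g^2{:}\sigma_e^2 = 0.3{:}0.7$ so the generative polygenic
  fraction equals the mixture the GLS model assumes — the natural null for
  calibration; depth 50 reads/site (a free choice at high-depth
  RNA-seq scale); $\beta = 1.0$ logit units per allele, the strong-cis regime of
  clearly mapped edQTL (top $\chi^2$ ~100 at a few hundred animals) —
  required for the generator to produce genuinely cosegregating
  edQTL/eQTL pairs, one of its design goals; weaker effects are a
  parameter away.
* **Pre-mRNA**: one planted inverted repeat, stem 100 nt and loop 30 nt —
  the scale of inverted SINE pairs, the dominant editing substrate in
  non-primate mammals — with edit positions at adenosines inside the stem
  and a truth table of paired positions for oracle tests. The dot-plot's
  15-nt window cannot call the outer ~3 positions of a stem, so the
  planted stem length keeps deterministic recovery above 90%.
* **Expression**: negative-binomial counts with mean
  $\exp(a + s\,\ell)$ linked to latent logit editing $\ell$
  (slope −0.3, dispersion 0.1, mean depth 500), giving the negative
  Φ–expression coupling the integration stage tests for; a pleiotropy flag
  reuses the edit site's causal variant to create true cosegregating
  pairs.
* **Read pairs**: 2×2 edited-by-allele tables drawn from a Plackett
  construction whose odds ratio equals the configured phase odds ratio at
  the configured margins.

What the generator does **not** emulate: sequencing error, alignment and
mapping artifacts, real bovine sequence content, recombination within the
chromosome, hyper-edited read clusters, and empirical depth distributions.
Passing tests therefore demonstrate correctness of the statistical
machinery under the model's assumptions, not robustness to upstream
bioinformatic artifacts.

# Calibration and problem sizes

The test suite verifies, among others:

* GLS estimates against the direct matrix-formula oracle (1e-8 relative)
  and exact dot-plot agreement with a brute-force oracle on sequences up
  to 2 kb.
* Type-I error (0.05 ± 0.01) and inflation (λ = 1.00 ± 0.02) under the
  generative polygenic null, measured over 1e5 variant tests
  (10 phenotypes × 1e4 LD-free variants) — a problem size chosen so the
  Monte-Carlo standard error of the median-based λ (~0.007) is well inside
  the acceptance band.
* Recovery of the planted causal effect on logit-Φ with |bias| < 5% over
  200 replicate sites at 355 animals and depth 50.
* End-to-end truth-table performance: sensitivity and specificity ≥ 0.9
  for cis-edQTL calls (10 true, 10 null sites) and for cosegregation
  calls (10 pleiotropic pairs, 10 pairs driven by unlinked variants
  > 1.5 Mbp away).

# Numerical and degenerate-input conventions

* Internal coordinates are 1-based closed (the Bioconductor convention);
  BED input/output is converted at the boundary. All coordinate
  conversions are tested as exact bijections.
* Zero-depth site/animal combinations are missing, excluded from site
  means and from model fits.
* Monomorphic variants are flagged untestable rather than fitted.
* Context ANOVA with no between-group variance reports F = 0, p = 1.
* Degenerate t-tests (constant inputs) return the limiting p-value
  rather than erroring.
* Cosegregation uses Spearman correlation with average ranks for ties;
  classification threshold r > 0.707 (r² > 0.5).
* The expression VST is the closed form
  $f(x) = (2/\sqrt\alpha)\,\mathrm{asinh}(\sqrt{\alpha x})/\ln 2$ for a
  common method-of-moments dispersion — an approximation to
  spline-fitted VSTs, monotone and variance-stabilizing, which is all the
  downstream correlation analysis requires.
* The phase test is a plain Pearson chi-square without continuity
  correction: the ≥ 6 observed-and-expected cell filter already guards
  small counts.
* The correlation-significance threshold feeding the sign-concordance
  test is computed as 0.05 divided by the number of correlated pairs at
  run time, generalizing any fixed printed constant.

# Known limitations

* Variant calling, alignment, imputation and repeat masking are consumed,
  not reproduced; FreeBayes-internal thresholds enter only through the
  VCF fields.
* The automated helix caller cannot see paired strands more than 1.5 kbp
  from any edit site of the gene, so some true double-stranded context is
  unobservable by construction.
* Effect-sign orientation across edQTL/eQTL/trait QTL uses the alternate
  allele as the common frame; sign comparisons are meaningless without a
  fixed frame, and any consistent frame gives the same test.
* The A matrix assumes correct pedigree records; genomic relationship
  alternatives are out of scope.
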