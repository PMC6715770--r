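---
title: "From tag SNP to target gene: methods and design notes"
author: "snp2target"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tag SNP to target gene: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snp2target)
```

# The problem

Most GWAS risk variants are noncoding tags: the reported SNP marks a
linkage-disequilibrium (LD) neighborhood in which some other variant may do
the actual regulatory work, possibly in a cell type other than the disease
tissue — for breast cancer, for instance, in the tumor-infiltrating
lymphocytes whose transcripts appear in bulk tumor RNA-seq.  snp2target
implements the standard evidence chain used to walk from a tag SNP to a
candidate functional variant and its target gene:

1. **Pleiotropy ranking** — rank disease-category GWAS SNPs by the density of
   nearby GWAS signals from a second trait category (e.g. immunoinflammatory
   traits), `rankByProximity()`.
2. **cis-eQTL scan** — regress each nearby gene's expression on risk-allele
   dosage with the gene's copy number as covariate, `eqtlScan()`.
3. **Survival** — split patients at the median expression of the candidate
   gene and compare survival with the log-rank test, `medianSplit()`,
   `logrankTest()`.
4. **LD expansion** — find all common proxies in high LD with the tag from
   phased haplotypes, `ldExpand()`.
5. **Evidence overlay** — flag proxies in open chromatin (DHS), under
   enhancer marks (H3K4me1), and inside chromatin-interaction anchors looping
   to the target gene, `buildEvidenceTable()`.
6. **Motif disruption** — score both alleles of each gated proxy against TF
   position weight matrices and test allele-specific binding change against a
   null-mutation ensemble, `disruptionSignificance()`.

`runPipeline()` chains all six stages and writes one TSV per stage.

# Models and statistics

## LD from phased haplotypes

All LD quantities derive from the 2x2 joint haplotype count table
(`haplotypeBiasTable()`).  With focal-allele frequencies $p_A$, $p_B$ and
joint focal frequency $p_{AB} = n_{11}/N$,

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
  D' = \frac{|D|}{D_{\max}},$$

where $D_{\max} = \min\{p_A(1-p_B), (1-p_A)p_B\}$ for $D > 0$ and
$\min\{p_A p_B, (1-p_A)(1-p_B)\}$ for $D < 0$.  Design choices: $D'$ is
reported unsigned (the convention used when a locus is described as "low
$r^2$ but high $D'$" — a rare allele riding almost exclusively on one allele
of a common SNP); the signed $D$ is kept alongside.  The focal allele
defaults to the alternate allele and is always labeled in output.
Monomorphic sites raise an error rather than returning 0 or NaN, because
silent zeros silently corrupt LD-expansion lists.  `ldExpand()` gates proxies
at $r^2 \ge 0.8$ and MAF $\ge 0.05$ within 1 Mb by default — the standard
common-proxy definition — and always includes the tag itself ($r^2 = 1$).

## Copy-number-adjusted eQTL

`eqtlFit()` is ordinary least squares of expression on (intercept, dosage,
copy number), dosage coded additively 0/1/2 in risk-allele copies — no
dominance term, matching how genotype effects at GWAS loci are routinely
summarized.  Copy number enters linearly as supplied; the simulator stores
it as log2 copy ratio so the model it fits is exactly the model that
generated the data.  The reported `r_genotype` is the standardized effect
$\hat\beta_g \cdot \mathrm{sd}(g)/\mathrm{sd}(y)$.  P-values are reported raw
(a Benjamini-Hochberg column is provided but never used for gating), because
the pilot-scan reporting convention this mirrors is per-gene unadjusted.
When the copy-number covariate is constant the model reduces exactly to
simple regression; collinear covariates abort with the condition number.

The conditional test `conditionalEqtl()` asks whether the primary SNP keeps
an effect inside one genotype stratum of a second variant: samples are
restricted to the conditioning genotype, then carriers of the primary risk
allele (dosage $\ge 1$) are Welch-tested (two-sided, Satterthwaite df)
against non-carriers.  The carrier-vs-noncarrier dichotomization is a design
choice — the obvious alternatives (0 vs 2 homozygotes, or an additive trend
test within the stratum) are not distinguishable from the published use of a
two-group Welch test; carrier status keeps both groups populated at small
stratum sizes.

## Survival

`medianSplit()` labels values at or above the median "high" (ties go high —
arbitrary but fixed; both the split and the log-rank statistic are
label-symmetric, so any directional claim must be read from the KM curves).
Kaplan-Meier estimation and the log-rank statistic are delegated to the
survival package (`survfit`, `survdiff`) behind this interface, with deaths
processed before censorings at tied times (the standard convention).  The
test suite checks both against closed-form product-limit and
$(O-E)^2/V$ hand oracles on small fixtures.

## Motif scanning and the null-mutation test

`scanAlleles()` is a FIMO-style scanner: position probabilities are
pseudocount-smoothed at load ($p_{bj} \propto m_{bj} + 0.1\,\pi_b$, uniform
background $\pi$ by default — configurable, since published scans rarely
state their background), k-mers are scored by summed natural-log odds
$\sum_j \log(p_{b_j j}/\pi_{b_j})$, and every offset of the 51-bp
SNP-centered window is scored on both strands.  A window is a hit when its
exact score p-value — the probability that a background-drawn k-mer scores
at least as high — is below $10^{-3}$.  That p-value is computed by dynamic
programming over the per-position score distribution discretized at bin
width 0.001 (scores scaled by 1000 and rounded, FIMO's convention); the test
suite verifies the DP against exhaustive enumeration of all $4^L$ k-mers for
$L \le 6$.  Scores above the achievable maximum report the smallest positive
representable mass, keeping p in (0, 1].

`disruptionSignificance()` quantifies allele-specific binding change.  The
observed statistic is $|\Delta|$, the difference between the best
center-covering window scores of the two alleles — best taken over offsets
and strands *without* the hit threshold, which only decides whether a motif
is present at all (a properly disrupted allele usually has no thresholded
hit left, yet its score at the motif window is precisely what the null
models).  The null ensemble "simulates null mutations in motif sequences": a
motif-length sequence is drawn from the PWM, one uniformly chosen position is
mutated to a uniformly chosen different base, and the score change is
recorded.  Because that change depends only on the position and the two
bases involved, the implementation samples those directly — distributionally
identical and O(1) per draw.  With $n$ draws,
$p = (1 + \#\{|\Delta_0| \ge |\Delta|\})/(1 + n)$ (add-one convention, so
$p \in (0,1]$ and identical alleles give exactly 1).  Disruption versus
creation is the sign of $\Delta$; significance is two-sided since both are
of interest.  The precise null of the prior art this phrase describes is not
published in detail; the definition above is this package's own, chosen
because it is exactly calibratable — the acceptance suite verifies that when
the central SNP is itself generated by the null process, the empirical
p-value is uniform.

## Evidence integration

`buildEvidenceTable()` keeps a per-peak-set flag plus the union flag
(`in_dhs`), so per-cell-type statements remain reproducible.  Motif scanning
is gated on the open-chromatin flag by default, mirroring staged
prioritization (scan only where a TF could plausibly bind); `motif_gate =
FALSE` disables the gate.  The interaction flag requires one anchor to
contain the SNP and the mate anchor to overlap a configurable target region
— typically the 3'-most few kb of the candidate gene; no default gene model
is assumed.  Rows are ordered by (interacts_target, number of true flags,
r2), all descending, with position as the final deterministic tie-break.

# The synthetic-data module

Controlled-access cohort and reference-panel data cannot ship with a
package, so `simConfig()` + the `simulate*()` generators produce every input
with the generative structure the analysis assumes.  All generators are pure
functions of (config, seed): same seed, byte-identical output, caller's RNG
untouched.

**Haplotypes** use a founder-copying block model: within a block all
variants share an allele frequency $p$ (drawn once from U(0.1, 0.9) unless
specified); each haplotype draws a founder state $z \sim \mathrm{Bern}(p)$
and with probability $\kappa$ carries $z$ at every block variant, otherwise
independent $\mathrm{Bern}(p)$ draws.  Pairwise allelic correlation within a
block is then exactly $\kappa$ (so $E[r^2] \approx \kappa^2$), $\kappa = 1$
gives perfect LD and $\kappa = 0$ independence.  The shared within-block
frequency is not a simplification but a mathematical necessity: $r^2 \to 1$
forces matched allele frequencies.  What this model does *not* emulate:
recombination-distance decay, allele-frequency/LD coupling from genealogy,
population structure.  A green test therefore establishes that the LD
machinery is correct on block-structured data, not that the generator is a
coalescent.

**Cohorts** pair consecutive haplotypes into diploids (dosage = risk-allele
count), draw per-gene log2 copy ratios N(0, 0.25), and build expression as
$\mu + \sum \beta_g \cdot \mathrm{dosage} + \beta_{cn} \cdot \mathrm{lr} +
N(0, \sigma)$ truncated at 0 — additive Gaussian rather than lognormal so
that OLS is exactly well-specified and parameter-recovery tests are clean
(with the default $\mu = 10$ the truncation is never active).  Survival
times are exponential with hazard $h_0 \exp(\gamma z)$, $z$ the z-scored
expression of the designated gene, so the log-rank direction check has a
closed-form expectation; censoring hits each subject with the configured
probability at a uniform fraction of its event time.  Defaults ($n = 500$
samples, $\sigma = 1$, effects a fraction of an expression SD, ~30%
censoring) are sized like a single-cancer-cohort analysis.

**GWAS catalogs** place cluster members uniformly in a window around a
center with log-uniform p-values in [1e-12, 1e-5], giving exact bookkeeping
for proximity-count tests.  **plantMotifSnp()** embeds a PWM consensus in a
random 51-mer so it covers the central base, with the alternate allele set
to the consensus column's worst base — the canonical "motif disrupted by the
SNP" configuration.

# Numerical and convention notes

- Intervals live as GRanges (1-based closed) internally; BED/BEDPE 0-based
  half-open coordinates are converted at the I/O boundary, preserving the
  half-open overlap semantics (a SNP at 0-based p overlaps [start, end) iff
  start <= p < end — verified at the boundaries in the tests).
- Chromosome names are taken literally; no "chr" normalization.  Mixed
  naming surfaces as zero overlaps, which the evidence table makes visible.
- Multiallelic VCF records are rejected by default; an opt-in flag splits
  them into biallelic pseudo-variants with suffixed ids.
- Proximity windows are inclusive at both boundaries ("within 100 kb"
  published usage does not state inclusivity; inclusive is chosen and
  tested).  Neighbor counting deduplicates by SNP id, so one variant
  associated with several traits of a category is one signal; the query
  never counts itself.
- Best-hit ties in motif scans break by (smaller offset, then + strand).
- Empirical allele-frequency convergence, eQTL null calibration
  (Kolmogorov-Smirnov on uniform p), log-rank type-I error, DP-vs-
  enumeration equality, and planted-locus recovery are asserted in
  `tests/testthat/test-acceptance.R` at the sample sizes stated there; the
  vignette makes no empirical claim the tests do not compute.

# Worked example

```{r example}
cfg <- simConfig(seed = 7, nHaplotypes = 400, nSamples = 150,
                 blocks = list(list(ids = c("v1", "v2", "v3"), kappa = 0.95,
                                    freq = 0.5)),
                 eqtlEffects = data.frame(gene = "g1", variant = "v1",
                                          beta = -0.8),
                 survGene = "g1", survLogHR = -0.5)
panel <- simulateHaplotypes(cfg)
cohort <- simulateCohort(panel, cfg)

ldPair(panel, "v1", "v2")$r2

fit <- eqtlFit(exprMatrix(cohort)["g1", ], dosageMatrix(cohort)["v1", ],
               cnMatrix(cohort)["g1", ])
c(beta = fit$beta_genotype, p = fit$p_genotype)

st <- survivalTable(cohort)
st$group <- medianSplit(exprMatrix(cohort)["g1", st$sample])
logrankTest(st)[c("chi2", "p")]
```

# Known limitations

- LD generation is block-wise exchangeable; no recombination maps or
  admixture.  Counts published for a real locus (numbers of high-LD proxies
  or of SNP-containing regulatory elements) depend on reference-panel and
  peak-atlas downloads and are not reproducible offline.
- The eQTL model ignores tumor purity and latent expression factors
  (PEER-style correction is out of scope).
- The motif null is this package's definition (above); published empirical
  motif p-values obtained with other matrix collections and null choices are
  not comparable number-for-number.
- Genotype-based (unphased) LD via EM, Cox regression, and trans-eQTL are
  deliberately out of scope.
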