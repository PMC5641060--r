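---
title: "Methods: dosage sensitivity and regulatory networks of SCNA lncRNAs"
author: "lncSCNA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage sensitivity and regulatory networks of SCNA lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncSCNA)
```

# Scope and model

`lncSCNA` analyzes long non-coding RNAs that sit inside recurrently
gained or lost genomic fragments of a tumor cohort. The guiding model is
that copy number acts on phenotype only through expression: a fragment
resident whose expression tracks its gene-level copy number (a
*dosage-sensitive* lncRNA) is a candidate driver, and its downstream
reach is mapped through three regulatory lenses — genomic neighborhood
(cis), transcription-factor intermediaries (trans), and shared-miRNA
competition (ceRNA) — before prognostic value is assessed on survival
data.

All containers are Bioconductor-native: gene annotation is a `GRanges`
(1-based closed coordinates, conversions handled by `rtracklayer` at the
BED/GTF boundary), and every assay is an `OmicsMatrix`, a
`SummarizedExperiment` subclass carrying a role tag (`expression`,
`copy_number`, `discrete_cn`, `beta`) whose validity method enforces the
role's value domain. Missing cells are `NA` throughout and are never
conflated with zero — the missingness filter (drop genes missing in
strictly more than 30% of samples) and the methylation imputation rule
both depend on that distinction.

# The dosage sensitivity score

For copy number $c$ and expression $e$ over tumor samples,

$$\mathrm{DSS} = w\, r(c, e) + (1 - w)\, \kappa_n(e \mid c),$$

where $r$ is the Pearson correlation and $\kappa_n$ is a concordance
statistic: samples are sorted by $c$ (stable sort, ties broken by sample
name), split into $n$ equal-size bins — the last $m \bmod n$ bins take
one extra sample, so no bin is empty — and the per-bin mean expressions
$m_1 \le \dots \le m_n$ are scored as
$(\#\{m_l > m_k\} - \#\{m_l < m_k\}) / \binom{n}{2}$ over ordered pairs
$k < l$. Both components live in $[-1, 1]$, so the score does too, and
it inherits two useful invariances verified in the tests: monotone
affine maps of expression leave it unchanged, and negating expression
negates it.

Samples with $|c| \le 0.3$ are treated as copy-number normal; the score
is reported only for genes whose continuous copy number leaves that
window in strictly more than 20% of samples (the alteration-frequency
flag, by contrast, uses at least 20% on the discretized matrix — the two
gates are deliberately different). Defaults are $n = 6$ and $w = 0.5$;
`dssRobustness()` recomputes the score at $n \in \{5, 6, 7, 15\}$ and
reports pairwise Spearman correlations, which exceed 0.95 on the default
synthetic cohort.

**A calibration caveat worth stating plainly.** The concordance
component compares bin means by sign only, so its null distribution does
not tighten as samples accumulate: for $n = 6$ exchangeable bin means it
has standard deviation $\approx 0.355$ however large the cohort. Under
independence of $c$ and $e$ the full score therefore has a null spread
of roughly $0.18$, and about 30% of null genes land outside
$[-0.2, 0.2]$. The DSS separates planted dosage-sensitive genes from
null genes very well (ranking, grouping), but a small absolute score
should not be read as evidence of absence, and thresholds on raw DSS
values inherit this floor. Raising $n$ shrinks the floor (at $n = 15$
the null sd roughly halves) at the cost of noisier bin means.

# Differential expression

The SAM-style statistic is $d = (\bar e_T - \bar e_N)/(s + s_0)$ with
the pooled two-class standard deviation $s$ and the exchangeability
constant $s_0$ set to the median of all per-gene $s$ — a deterministic
rendering of SAM's variance moderation. P-values come from the
pooled-across-genes permutation null of the class labels (default 200
permutations, add-one smoothed), are BH-corrected, and a call
additionally requires a linear fold change (ratio of linear-scale class
means, the same ratio convention the methylation module uses) above 2 or
below 1/2. Percentiles everywhere use linear interpolation between
closest ranks; BH ties are broken by input index, so results are
deterministic.

# Methylation

Promoters are the 2 kb immediately upstream of the TSS,
strand-aware by default (`strandAware = FALSE` gives the strand-agnostic
variant) and clipped at the chromosome start. Probes mapping to zero or
multiple promoters are discarded; probe-level missing values are imputed
with the probe's across-sample mean *before* per-gene averaging (the
order matters and is idempotent). Calls use Welch t-tests — class sizes
in methylation arrays are typically very unbalanced — with a beta-ratio
fold change above 2 (hyper) or below 1/2 (hypo) at FDR < 0.01. The
methylation–expression correlation step deliberately uses raw p < 0.05
with no multiplicity correction, mirroring how such screens are usually
reported; it is a flag, not an inference.

# Networks

Cis pairs require the PCG partner (not the lncRNA) to be differentially
expressed, the pair to survive the co-expression screen (r > 0.5,
FDR < 0.05, positive sign), and the gene bodies to lie within 300 kb on
the same chromosome (gap distance; overlapping bodies count as 0). The
trans test takes each co-expressed (lncRNA, TF) link — TF screen at the
stricter r > 0.6 — and asks whether the lncRNA's co-expressed PCGs
over-represent the TF's target list, by the upper-tail hypergeometric
probability over the universe of differentially expressed PCGs; BH runs
over all tested links (the widest tested family), and significant links
are expanded to one triple per overlap gene.

The ceRNA stage separates two roles of the interaction tables: the
counts $x$, $M$, $L$ entering the printed hypergeometric formula come
purely from the tables, while pair eligibility requires at least one
shared miRNA that is negatively correlated (FDR < 0.05, within the
family of all miRNA–gene tests of the step) with both partners.
Retention requires both raw p < 0.05 and q < 0.05. The tail sum is
evaluated in log space (`lchoose`) and is tested against exact rational
arithmetic and against brute-force urn enumeration for all universes up
to 12.

GO enrichment is an internal hypergeometric test over a user-supplied
gene–term table (no web service); the universe is the set of PCGs that
survived expression preprocessing, and terms are tested only with at
least one hit and at least three annotated genes in the universe.

# Prognosis

Each ceRNA triple (lncRNA, surviving shared miRNAs, PCG) gets univariate
Cox coefficients per node on z-scored tumor expression (fitting
delegated to `survival::coxph`); the per-sample risk is
$\sum_k \hat\beta_k z_k$, samples split at the median risk (ties to the
low-risk group, so group sizes differ by at most one), and the groups
are compared by log-rank test. Because the $\hat\beta_k$ are estimated
on the same samples the split is tested on, the procedure is optimistic
under the null: with three noise nodes at $n = 300$ the measured
log-rank rate at 0.05 is roughly 15–20%, the familiar in-sample bias of
expression risk scores. The per-triple p-values should therefore be
read comparatively; the summary table also carries a BH column, and any
clinical claim would need a held-out cohort, which this package does not
model.

Drug nomination is a pure join with directional logic: a drug that
up-regulates a module miRNA is a candidate when both module partners are
up-regulated in tumors (boosting the shared miRNA plausibly represses
both); every other combination is reported with `rationale = "other"`
rather than silently dropped.

# The synthetic cohort

`generateCohort()` is the package's test bed: it emulates a TCGA-style
cohort at desk scale — 100 tumor / 30 normal samples, 80 lncRNAs, 150
PCGs (6 TFs), 30 miRNAs, 10 focal fragments of 500 kb holding 4 lncRNAs
each — chosen so the full pipeline runs in a few seconds while every
stage still has non-trivial multiplicity. Planted structure and the
reasoning behind the defaults:

* **Copy number.** Background values are uniform inside the normal
  window; within a fragment, exactly half the tumor samples (the
  `alteration_fraction`) are redrawn with magnitude in (0.4, 1.4] and the
  fragment's sign, so discretization at ±0.3 recovers the alteration set
  exactly. Gene-level values mirror GISTIC-style input; segmentation is
  out of scope.
* **Dosage effects.** 30 fragment lncRNAs get log2 expression
  $\mu + s\,c$ with slopes drawn from $[0.15, 1.2]$ — a graded range, so
  DSS values spread over the score's range rather than clustering, which
  is what makes the rank-based robustness comparison meaningful.
* **Expression noise** is Gaussian on the log2 scale (sd 0.3, a
  realistic per-gene residual for gene-level RNA-seq); matrices are
  emitted on the linear scale so the pipeline's own upper-quartile
  normalization and pseudocount/log2 transforms (+2 for PCGs, +0.05 for
  lncRNAs/miRNAs) are exercised, not bypassed.
* **DE genes** shift by exactly 2 on the log2 scale (4-fold), split
  between up and down. Dosage coupling and methylation coupling move
  tumor means too, but by construction less than 2-fold, so the
  fold-change gate keeps them out of the DE truth set — that is what
  makes the empirical FDR of the SAM stage measurable.
* **ceRNA triples** share a per-triple latent factor: partners load +1,
  the triple's 4 miRNAs load −0.9, giving pair correlations ≈ 0.8 and
  miRNA correlations ≈ −0.8 at default noise — comfortably inside the
  screens across seeds. Background interaction rows are random, so
  non-planted co-expressed pairs rarely share miRNAs and essentially
  never pass the negative-correlation filter.
* **Cis pairs** place a PCG 50 kb from a dosage-planted lncRNA and
  couple the PCG to the lncRNA's *expression* (loading 0.8) — cis
  regulation proper — so the pair is co-expressed whatever dosage slope
  the lncRNA drew.
* **The trans module** shares a latent factor between one fragment
  lncRNA, one TF, and 8 DE target PCGs listed in the TF-target table
  (plus 4 non-coexpressed targets, so the overlap test has a real
  contrast).
* **Methylation**: promoter probes of hypermethylated lncRNAs draw
  tumor betas from Beta(10, 10) (mean 0.5) vs Beta(3, 17) (mean 0.15)
  elsewhere, and the lncRNA's expression is coupled at −2 per unit beta —
  enough to make the hypermethylated set visibly low-expressed (the
  rank-sum comparison) without crossing the DE fold-change gate.
* **Survival**: exponential event times with hazard
  $\lambda_0 \exp(\sum \beta z)$ on the first ceRNA triple
  ($\beta = +0.7$ lncRNA, $-0.7$ per miRNA, $+0.7$ PCG),
  $\lambda_0 = 5\times10^{-4}$/day, administrative censoring at 1000
  days — roughly 40–60% observed events, typical of cohort follow-up.
* **Determinism**: one RNG stream per data layer, each derived from the
  master seed, so regenerating one layer never perturbs another, and
  identical seeds give bit-identical cohorts.

What the generator does *not* emulate: allele-specific copy number,
read-level noise, batch effects, correlated gene–gene background
structure, GO term hierarchy, or informative censoring. Passing the
planted-recovery tests therefore demonstrates that the statistical
machinery is implemented correctly and calibrated under clean
assumptions — not that real-cohort effect sizes would be recovered at
these rates.

# Numerical and design choices

* Percentile convention: linear interpolation between closest ranks,
  fixed once for normalization and expression filters.
* BH is delegated to `stats::p.adjust(method = "BH")` behind the
  `benjaminiHochberg()` surface and cross-checked in the tests against a
  hand-written step-up oracle.
* Hypergeometric tails are computed in log space; `k <= 0` returns 1 by
  convention (empty complement sum).
* Alteration-direction ties resolve to gain; bin-sort ties resolve by
  sample name; samples exactly at the median risk go to the low-risk
  group — all arbitrary but fixed and recorded in the outputs.
* The cis distance is the gap between gene bodies (the most inclusive
  reading of a "within 300 kb" neighborhood); a TSS–TSS convention would
  be stricter and can be obtained by pre-filtering the annotation.
* Whether a cis lncRNA must itself be differentially expressed is left
  open in the field's practice; here only the PCG partner must be, since
  the lncRNA's eligibility already comes from its SCNA status.
* Problem sizes in the test suite and acceptance script (20 cohort
  seeds for recovery, 1000 null replicates for DSS calibration, 50/100
  survival replicates at $n = 300$) were chosen as the smallest sizes at
  which the measured rates are stable to a few percent across seeds.

# Known limitations

The DSS null floor and the in-sample optimism of the risk score,
discussed above, are the two properties a user is most likely to
misread. Beyond those: the ceRNA test conditions on the interaction
tables as ground truth (no CLIP evidence weighting), the GO enrichment
does not propagate the term hierarchy, and the pipeline's correlation
screens use tumor samples only — co-expression driven by tumor/normal
composition is deliberately excluded, which is conservative but can
hide class-linked co-regulation.
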