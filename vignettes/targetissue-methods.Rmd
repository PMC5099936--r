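---
title: "Methods: disease-tissue association and drug-target expression confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-tissue association and drug-target expression confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetissue)
```

`targetissue` asks, for a set of gene–disease pairs (drug targets with
their indications), whether each target is detectably expressed in a
healthy tissue relevant to its disease. This vignette documents the model,
the tunable parameters, the numerical conventions, the synthetic-data
generator behind the test suite, and the design choices that were genuinely
open.

## 1. Disease–tissue association

Diseases are linked to tissues through literature co-occurrence. With
abstract counts $N_d$ (disease), $N_t$ (tissue) and $N_{dt}$ (both), the
Ochiai coefficient

$$\mathrm{OC}(d,t) = \frac{N_{dt}}{\sqrt{N_d\,N_t}}$$

is the cosine similarity of the two binary occurrence vectors; it lies in
$[0,1]$. Per disease the coefficients are normalized,

$$\mathrm{MAS}(d,t) = 100\cdot
  \frac{\mathrm{OC}(d,t)}{\sum_{t'} \mathrm{OC}(d,t')},$$

so every associable disease's scores sum to 100 and a score of 100 means
the disease's tissue literature is confined to a single tissue. The
underlying assumption is that publication co-mention frequency is a usable
proxy for biological relevance; it inherits the literature's biases (well
studied organs accumulate mentions regardless of specificity), which is why
the scores are only used comparatively within a disease.

Conventions:

* **Zero marginals.** A term never mentioned in the literature cannot be
  associated; its coefficients are defined as 0 (with a warning) rather
  than raising an error, keeping row normalization total.
* **Normalization universe.** The sum in the MAS denominator runs over the
  *entire* tissue vocabulary of the co-occurrence table, not only tissues
  present in the expression panel. Literature association and expression
  coverage are different questions; conflating them would inflate scores
  for diseases whose top tissues happen to be unprofiled. (This was an open
  choice; a curated-subset variant can be had by subsetting the table
  before scoring.)
* **All-zero rows.** Diseases with no positive coefficient are flagged
  `unassociable` and excluded from assignment and from confirmation
  denominators, mirroring the removal of organ-nonspecific disease terms
  from this kind of analysis.

**Assignment.** Each disease keeps its top $k = 3$ tissues with
$\mathrm{MAS} \ge 8$ percent. The threshold is inclusive (a tissue at
exactly 8% passes). Ties at the $k$-th rank are broken alphabetically by
tissue name so assignment is deterministic. MAS values are carried at full
precision; rounding to two decimals is a display concern only.

**Final tissue.** When a single tissue per pair is wanted, the assigned
tissue with the highest measured FPKM for the gene wins; if the gene has no
FPKM measurement in any assigned tissue, the highest-MAS assigned tissue
with an `Expressed` protein call is used; otherwise the pair has no final
tissue.

## 2. Expression evidence

**mRNA.** FPKM strictly above 1 is `Expressed` ("over 1 FPKM" is read as a
strict inequality, so 1.0 itself is `Undetected`). Negative FPKM is a
domain error. A missing value is `NotMeasured` and is excluded from
denominators — an unprofiled tissue is not evidence of absence.

**Protein.** Ordinal immunohistochemistry calls collapse as
`Medium`/`High` → `Expressed`, `Absent`/`Low` → `Undetected`. Genes whose
antibody reliability is not `supportive` are wholly excluded
(`NotMeasured`); the reliability filter applies only to the protein side —
the two evidence filters are kept independent.

**z-scores.** Per gene across tissues, on $\log_2(\mathrm{FPKM}+1)$ by
default (the log base and pseudocount are parameters, since "log-transform"
alone underdetermines them). The standard deviation uses the sample
($n-1$) convention by default, with a `population` option; tests pin the
choice. Constant rows are given all-zero z-scores and flagged, so they
contribute neutrally to tissue-vs-rest averages instead of propagating
NaNs.

**Tissue specificity.** A tissue is *enriched* for a gene when its FPKM is
at least 5-fold the mean of all other tissues **and** above the 1-FPKM
floor; the floor (not part of the classic fold rule, which is silent on
trace values) prevents a 0.05-vs-0.01 ratio from counting as specificity.
Classes: exactly one enriched tissue → `single_tissue_enriched`; 2–7 →
`group_enriched`; nothing above the floor → `undetected`; otherwise
`not_enriched`. The fold rule uses raw FPKM (an open choice; log-space
folds would compress the dynamic range the rule is meant to exploit).

**Secondary panels.** Replicate-bearing matrices are collapsed to
per-tissue medians (even replicate counts use the midpoint of the two
central values). Queries for a tissue absent from the panel follow a proxy
map (e.g. lymphoblasts for lymph node); tissues that expand into several
sampled regions (e.g. brain) return the maximum regional median and the
winning region; a missing tissue with no proxy returns `NA`.

## 3. Confirmation and rescue

A pair's mRNA (protein) flag is true when the gene is `Expressed` in at
least one assigned tissue — mode `any_assigned`, the default — or in the
single top-MAS tissue — mode `top1`. Both modes are first-class because
both accountings are scientifically interesting (the `top1` count is
necessarily ≤ the `any_assigned` count, a property the tests assert).
`NotMeasured` tissues are skipped; a pair whose every assigned tissue is
unmeasured for an evidence type gets that flag false plus an annotation
(`no mRNA data`, `no protein data`, or `gene unmeasured`), never a silent
negative. Categories partition records: `both`, `mrna_only`,
`protein_only`, `unconfirmed`.

**Alternate-indication rescue** is computed per *gene* (a gene's biology
does not change between its indications): an unconfirmed gene is rescued if
any of its other indications' records is confirmed, with the pair-level
evidence retained. Single-indication genes with no rescue are
`single_indication_weak`.

**Secondary-dataset rescue** re-tests unconfirmed pairs against an
independent panel via the proxy/multi-region lookup, rescuing a pair when
the value strictly exceeds the same 1-FPKM cutoff (rule reuse: a value
exactly at the cutoff does not rescue). The `high_confidence_filter()`
(mean assigned MAS > 70%) isolates the pairs whose literature signal makes
such a re-test worthwhile.

## 4. Statistics

* **Paired comparison.** Per record with a final tissue: the pair
  ($z$ in the disease tissue, mean $z$ over remaining tissues), then a
  two-sided paired t-test on the differences. "Remaining" excludes all
  assigned tissues by default (`exclude_final` is available; the narrower
  exclusion biases the out-group upward when secondary assigned tissues
  are also expressed). Raw-FPKM means of both sides are reported
  descriptively. Degenerate difference vectors (zero variance, including
  identical non-zero differences) return $t = 0, p = 1$ with a flag — the
  statistic is undefined there and the convention is documented rather
  than hidden. Fewer than two usable pairs is an error, not a value.
* **Enrichment.** A 2×2 chi-square frequency test (no Yates correction by
  default, matching the "frequency test" reading; correction is a toggle)
  of (gene has ≥ 2 indications) × (pair unconfirmed). A zero margin is a
  degenerate-table error.
* **Cross-tabs.** Class × tissue cells count *distinct* targets over each
  record's assigned tissues (a target under two same-class diseases in one
  tissue counts once). Ward (`ward.D2`) clustering is offered purely for
  display ordering; counts are never altered. No multiple-testing
  adjustment is applied: the pipeline runs two pre-registered tests and
  reports them raw.

## 5. The synthetic world

`generate_world()` emulates all five inputs with planted truth:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `n_diseases`, `n_tissues` | 345, 406, 32 | study-scale dimensions |
| `mean_indications` | 3.78 | zero-truncated-geometric mean indications per gene (≈ 1,300 pairs) |
| `concentration` | 10 | literature-mass ratio, planted tissue : each background tissue |
| `background_meanlog`, `background_sdlog` | −1, 2.5 | log-normal FPKM background (tail above 1 FPKM ≈ 0.34, a realistic detected fraction) |
| `boost` | 20 | expression multiplier at confirmable pairs' planted tissue |
| `confirmable_fraction` | 0.8 | probability a pair receives the boost; with the background tail this yields a confirmed fraction in the high-80s percent, echoing real studies |
| `protein_dropout` | 0.3 | probability an mRNA-expressed Medium/High call degrades to Low |
| `n_replicates` | 3 | samples per tissue in the secondary panel |

Mechanics worth knowing:

* Every disease gets exactly one planted tissue; joint counts are
  multinomial per disease with `concentration`-fold mass on it
  (`Inf` concentrates all mass, making tissue assignment noiseless).
* The boost is a multiplier, not a floor, so with `boost = 1` the
  confirmable rate collapses to the log-normal tail probability — an
  analytic identity the tests check. Ground truth records the *realized*
  state: `truly_confirmable` is whether the drawn FPKM at the planted
  tissue exceeds the cutoff, and `expected_category` is the category the
  pair would earn were its disease assigned exactly its planted tissue.
  In a noiseless-assignment world the pipeline must reproduce
  `expected_category` exactly, for any dropout.
* Protein calls are per-gene expression quartiles mapped to
  Absent/Low/Medium/High, then degraded by dropout. All tables draw from
  separate pseudo-random streams derived from the master seed, so the
  dropout uniforms are shared across configurations that differ only in
  the dropout rate — monotonicity (more dropout ⇒ fewer `both`, more
  `mrna_only`) holds *exactly* under a common seed, not just in
  expectation.
* The secondary panel expands the first panel tissue into three regions,
  withholds one tissue behind a proxy and one with no proxy, exercising
  every branch of the lookup.

What the generator does **not** emulate: correlated expression between
related tissues, cell-type heterogeneity within a tissue, antibody-specific
protein biases, literature bias toward well-studied organs, and
disease-class structure tied to biology (classes are assigned at random).
Passing tests therefore demonstrate the pipeline's correctness and
calibration under its own model assumptions, not the field-accuracy of
literature-based tissue assignment on real data.

## 6. Problem sizes and numerical tolerances

Unit tests run on 50 × 40 × 8 worlds; planted-recovery checks use a
study-scale world (406 diseases × 32 tissues) where only the MAS stage is
exercised, and 200-disease worlds for concentration grids. Calibration uses
1,000 null replicates (Kolmogorov–Smirnov uniformity of both tests'
p-values) and 200 replicates of a $d = 0.5$, $n = 500$ planted effect for
power. MAS row sums are asserted to $10^{-9}$, oracle equivalence (a
brute-force reimplementation from the two defining formulas) to
$10^{-12}$; scale invariance of OC/MAS under count rescaling to
$10^{-12}$, reflecting floating-point associativity rather than any model
looseness.

## 7. Known limitations

* Co-occurrence counts are taken as given; building them (query design,
  MeSH qualification) is upstream of this package.
* The ontology mapping of diseases to classes is an input; diseases
  without a class land in an `unclassified` bucket.
* The confirmation logic treats tissues as exchangeable labels; anatomical
  containment (e.g. a region within an organ) is only handled through the
  explicit multi-region map.
* `audit_annotation_table()` is schema-tolerant by fuzzy column matching;
  exotic column namings may need renaming before the audit.
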