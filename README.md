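# targetissue

Drug discovery teams routinely assume that a good drug target is expressed —
even in healthy people — in the tissue its indicated disease affects.
`targetissue` implements a systematic pipeline for checking that assumption
at scale: given a table of gene–disease pairs (drug targets with their
indications), literature co-occurrence counts of diseases and tissues, a
gene × tissue bulk RNA-seq FPKM matrix and an ordinal antibody-based protein
call table, it decides for every pair whether the target is detectably
expressed in a tissue relevant to the disease, and characterizes the pairs
where it is not.

## The method

**Disease → tissue.** The association of disease *d* and tissue *t* is the
Ochiai coefficient of their literature occurrence sets,

```
OC(d, t) = N_dt / sqrt(N_d * N_t)
```

where `N_d`, `N_t` and `N_dt` are abstract counts for the disease, the
tissue, and their co-occurrence. Per disease the coefficients are normalized
to sum to 100, giving the **maximal association score** (MAS, 0–100; 100
means the disease's tissue literature is confined to one tissue). Each
disease is assigned its top three tissues with MAS ≥ 8%.

**Evidence binarization.** mRNA: a gene is `Expressed` in a tissue when its
FPKM is strictly above 1. Protein: ordinal immunohistochemistry calls
`Medium`/`High` become `Expressed`, `Absent`/`Low` become `Undetected`, and
genes whose antibody reliability is not `supportive` are excluded
(`NotMeasured`).

**Confirmation.** A pair is confirmed when its target is expressed in at
least one assigned tissue (or, in the stricter `top1` mode, in the single
highest-MAS tissue); the evidence category is `both` / `mrna_only` /
`protein_only` / `unconfirmed`. Unconfirmed pairs are then triaged: genes
confirmed under an alternate indication's tissue are "rescued", and
high-confidence pairs (mean assigned MAS > 70%) can be re-tested against a
replicate-bearing secondary expression panel with multi-region expansion
(e.g. brain → sampled brain regions) and proxy tissues.

**Statistics.** A paired t-test compares each target's z-scored expression
in its disease tissue against the mean of the remaining tissues; a 2×2
chi-square frequency test asks whether multi-indication targets are
enriched among unconfirmed pairs; class × tissue cross-tabulations summarize
where each therapeutic area's targets live.

Every input can be emulated by the built-in synthetic-world generator
(`generate_world()`), which plants a known disease–tissue truth, boosts
confirmable targets' expression, and degrades protein calls with a dropout
probability — so the full pipeline is testable with no downloads.

## Worked example

Bundled curated examples (14 well-known targets with their indicated
disease, literature-assigned tissue, FPKM and protein call):

```r
library(targetissue)
rec <- curated_records()
rec[rec$gene %in% c("ACPP", "AGTR1", "HCAR2"),
    c("gene", "disease", "final_tissue", "mas_at_final",
      "fpkm_at_final", "category")]
#>   gene  disease                final_tissue mas_at_final fpkm_at_final category
#> 1 ACPP  prostatic neoplasms    prostate             71.1       1916.   both
#> 2 AGTR1 diabetic nephropathies kidney               84.7         12.0  mrna_only
#> 3 HCAR2 brain ischemia         brain                85.3          0.12 protein_only
```

ACPP (prostatic acid phosphatase) is massively expressed in prostate at both
levels; AGTR1 is seen at the mRNA but not the protein level in kidney; HCAR2
is below the 1-FPKM mRNA cutoff in brain yet detected by antibody staining.

A synthetic study end to end:

```r
w   <- generate_world(world_config(n_genes = 100, n_diseases = 80,
                                   n_tissues = 16, seed = 11))
mas <- compute_mas(w$cooccurrence)
rec <- confirm_pairs(w$pairs, mas, w$expression, w$protein)
summarize_confirmation(rec)
#> Confirmation summary over 397 gene-disease pairs (100 genes, 79 diseases)
#>   mRNA detected:        292 (74%)
#>   either evidence:      313 (79%)
#>     both:               188 (47%)
#>     mRNA only:          104 (26%)
#>     protein only:       21 (5%)
#>   unconfirmed:          84 (21%)

world_report(w, mas, rec)$planted_recovery
#> [1] 1

z <- zscore_matrix(w$expression)
paired_zscore_test(z, rec, w$expression)
#> Paired disease-tissue vs remaining-tissue comparison (n = 397 pairs)
#>   mean z in/out:    0.61 vs -0.04
#>   mean FPKM in/out: 254.7 vs 90.3
#>   paired t = 10.729, p = 9.57e-24
```

The planted disease tissues are recovered perfectly from the literature
counts at the default 10:1 concentration, and targets are — as designed —
expressed far above background in their disease tissues.

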