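# Evidence integration: per-pair confirmation, accounting, rescues.

curated_fixture <- function() curated_examples()

test_that("curated pairs reproduce their published detection calls", {
  ex <- curated_fixture()
  calls <- binarize_mrna(ex$fpkm)
  expect_equal(calls == "Expressed", ex$fpkm > 1)
  undet <- ex$gene[calls == "Undetected"]
  expect_setequal(undet, c("HCAR2", "SCN9A"))
})

test_that("curated pairs land in the published evidence categories", {
  rec <- curated_records()
  cat_of <- function(g) rec$category[rec$gene == g]
  expect_equal(cat_of("HCAR2"), "protein_only")
  expect_equal(cat_of("AGTR1"), "mrna_only")
  expect_equal(cat_of("ACPP"), "both")
  expect_equal(cat_of("SCN9A"), "protein_only")
  expect_equal(sum(rec$category == "unconfirmed"), 0)
  expect_equal(rec$fpkm_at_final[rec$gene == "SLC12A3"], 142.87)
  expect_equal(rec$final_tissue[rec$gene == "SLC12A3"], "kidney")
})

test_that("mode semantics: top1 consults only the highest-MAS tissue", {
  assignment <- tibble::tibble(disease = "d", tissue = c("a", "b"),
                               mas = c(60, 40), rank = 1:2)
  mprof <- matrix(c("Undetected", "Expressed"), 1, 2,
                  dimnames = list("G", c("a", "b")))
  pair <- tibble::tibble(gene = "G", disease = "d")
  any_mode <- confirm_pair(pair, assignment, mprof, NULL, "any_assigned")
  top1 <- confirm_pair(pair, assignment, mprof, NULL, "top1")
  expect_true(any_mode$mrna_detected)
  expect_false(top1$mrna_detected)
})

test_that("unmeasured evidence is annotated, not silently negative", {
  assignment <- tibble::tibble(disease = "d", tissue = "a", mas = 50,
                               rank = 1L)
  pair <- tibble::tibble(gene = "G", disease = "d")
  rec <- confirm_pair(pair, assignment, NULL, NULL)
  expect_false(rec$mrna_detected)
  expect_equal(rec$annotation, "gene unmeasured")
  # NotMeasured across all assigned tissues for one evidence type
  mprof <- matrix("Expressed", 1, 1, dimnames = list("G", "a"))
  pprof <- matrix("NotMeasured", 1, 1, dimnames = list("G", "a"))
  rec2 <- confirm_pair(pair, assignment, mprof, pprof)
  expect_true(rec2$mrna_detected)
  expect_match(rec2$annotation, "no protein data")
  expect_equal(rec2$category, "mrna_only")
})

test_that("pairs with no assignable tissue are excluded from denominators", {
  assignment <- tibble::tibble(disease = character(), tissue = character(),
                               mas = numeric(), rank = integer())
  pair <- tibble::tibble(gene = "G", disease = "d")
  rec <- confirm_pair(pair, assignment[0, ], NULL, NULL)
  expect_true(rec$excluded)
  expect_equal(rec$annotation, "no assignable tissue")
  s <- summarize_confirmation(dplyr::bind_rows(rec, curated_records()))
  expect_equal(s$n_excluded, 1)
  expect_equal(s$n_pairs, 14)
})

test_that("summary satisfies the partition identities on random worlds", {
  for (seed in c(5, 6)) {
    w <- small_world(seed)
    mas <- compute_mas(w$cooccurrence)
    rec <- confirm_pairs(w$pairs, mas, w$expression, w$protein)
    s <- summarize_confirmation(rec)
    expect_equal(s$n_both + s$n_mrna_only + s$n_protein_only, s$n_either)
    expect_equal(s$n_either + s$n_unconfirmed, s$n_pairs)
    expect_equal(s$n_pairs + s$n_excluded, nrow(rec))
    expect_equal(s$n_mrna, s$n_both + s$n_mrna_only)
  }
})

test_that("duplicate pairs are rejected by the summary", {
  rec <- curated_records()
  expect_error(summarize_confirmation(dplyr::bind_rows(rec, rec[1, ])),
               "duplicate")
})

test_that("any_assigned detections dominate top1 detections", {
  w <- small_world(9)
  mas <- compute_mas(w$cooccurrence)
  any_rec <- confirm_pairs(w$pairs, mas, w$expression, w$protein,
                           mode = "any_assigned")
  top_rec <- confirm_pairs(w$pairs, mas, w$expression, w$protein,
                           mode = "top1")
  expect_true(all(any_rec$mrna_detected >= top_rec$mrna_detected))
  expect_gte(sum(any_rec$mrna_detected), sum(top_rec$mrna_detected))
})

test_that("adding a protein Expressed call never unconfirms a record", {
  assignment <- tibble::tibble(disease = "d", tissue = "a", mas = 50,
                               rank = 1L)
  pair <- tibble::tibble(gene = "G", disease = "d")
  mprof <- matrix("Expressed", 1, 1, dimnames = list("G", "a"))
  pprof_neg <- matrix("Undetected", 1, 1, dimnames = list("G", "a"))
  pprof_pos <- matrix("Expressed", 1, 1, dimnames = list("G", "a"))
  before <- confirm_pair(pair, assignment, mprof, pprof_neg)
  after <- confirm_pair(pair, assignment, mprof, pprof_pos)
  confirmed <- function(r) r$category != "unconfirmed"
  expect_true(confirmed(before))
  expect_true(confirmed(after))
  expect_equal(after$category, "both")
})

test_that("alternate-indication rescue is decided per gene", {
  # PLG-style gene: 4 indications, confirmed for 3
  rec <- make_records(
    genes = c(rep("PLG", 4), "SOLO", rep("LOST", 3)),
    final_tissue = "liver",
    disease = c("conjunctivitis", "infarction", "embolism", "thrombosis",
                "rare disease", "d1", "d2", "d3"),
    category = c("both", "unconfirmed", "both", "mrna_only",
                 "unconfirmed", rep("unconfirmed", 3)))
  out <- rescue_alternate_indications(rec)
  plg <- out[out$gene == "PLG", ]
  expect_equal(plg$status, "rescued_alternate_indication")
  expect_equal(lengths(strsplit(plg$evidence, ";")), 3, ignore_attr = TRUE)
  expect_equal(out$status[out$gene == "SOLO"], "single_indication_weak")
  expect_equal(out$status[out$gene == "LOST"], "unrescued")
})

test_that("secondary-dataset rescue honors regions, proxies and strictness", {
  rec <- make_records(genes = c("G1", "G2", "G3"),
                      final_tissue = c("brain", "placenta", "lobe"),
                      category = "unconfirmed",
                      disease = c("d1", "d2", "d3"))
  sec <- matrix(c(0.2, 3, 0.1, 1.0,
                  5, 5, 5, 5,
                  0.5, 0.5, 0.5, 1.0), 3, 4, byrow = TRUE,
                dimnames = list(c("G1", "G2", "G3"),
                                c("brain_r1", "brain_r2", "lobe", "other")))
  mr <- list(brain = c("brain_r1", "brain_r2"))
  px <- c(placenta = NA)
  out <- rescue_secondary_dataset(rec, sec, px, mr)
  expect_equal(out$status[out$gene == "G1"], "rescued_secondary_dataset")
  expect_equal(out$tissue_used[out$gene == "G1"], "brain_r2")
  expect_equal(out$status[out$gene == "G2"], "unrescued") # no proxy -> NA
  expect_true(is.na(out$value[out$gene == "G2"]))
  # exactly at the cutoff is not rescued (strict rule reuse)
  rec3 <- make_records("G3", "other", category = "unconfirmed")
  out3 <- rescue_secondary_dataset(rec3, sec, px, mr)
  expect_equal(out3$status, "unrescued")
})

test_that("high-confidence filter keeps mean assigned MAS above threshold", {
  rec <- curated_records()
  kept <- high_confidence_filter(rec, min_mas = 70)
  expect_true("HCAR2" %in% kept$gene)   # MAS 85.26
  expect_false("SCN9A" %in% kept$gene)  # MAS 33.83
  expect_equal(nrow(high_confidence_filter(rec, min_mas = 0)), nrow(rec))
})

test_that("annotation-table audit re-derives flags from raw columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Gene\tDisease Name\tPredicted Tissue\tMAS Score\tmRNA Intensity (FPKM)\tProtein Detected",
    "ACPP\tProstatic Neoplasms\tprostate\t71.1\t1916.41\tY",
    "HCAR2\tBrain Ischemia\tbrain\t85.26\t0.12\tY",
    "AGTR1\tDiabetic Nephropathies\tkidney\t84.66\t11.97\tN",
    "XYZ\tSome Disease\tliver\t50\t0.5\tN"), path)
  audit <- audit_annotation_table(path)
  expect_equal(audit$summary$n_pairs, 4)
  expect_equal(audit$summary$n_both, 1)
  expect_equal(audit$summary$n_protein_only, 1)
  expect_equal(audit$summary$n_mrna_only, 1)
  expect_equal(audit$summary$n_unconfirmed, 1)
  expect_equal(audit$records$category[audit$records$gene == "HCAR2"],
               "protein_only")
})
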