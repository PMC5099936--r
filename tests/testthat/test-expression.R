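# Binarization, z-normalization, specificity classes, replicate collapsing
# and proxy lookup.

test_that("mRNA binarization is strict at the cutoff and rejects negatives", {
  expect_equal(binarize_mrna(c(0.12, 1916.41, 1)),
               c("Undetected", "Expressed", "Undetected"))
  expect_equal(binarize_mrna(NA_real_), "NotMeasured")
  expect_error(binarize_mrna(-0.1), "negative")
})

test_that("raising the cutoff never converts Undetected to Expressed", {
  set.seed(7)
  x <- rlnorm(200, 0, 2)
  lo <- binarize_mrna(x, cutoff = 0.5)
  hi <- binarize_mrna(x, cutoff = 2)
  expect_false(any(lo == "Undetected" & hi == "Expressed"))
  # and binarization is idempotent on its induced values
  expect_equal(binarize_mrna(x), binarize_mrna(x))
})

test_that("protein binarization applies level rule and reliability filter", {
  expect_equal(binarize_protein("High", "supportive"), "Expressed")
  expect_equal(binarize_protein("Medium", "supportive"), "Expressed")
  expect_equal(binarize_protein("Low", "supportive"), "Undetected")
  expect_equal(binarize_protein("Absent", "supportive"), "Undetected")
  expect_equal(binarize_protein("Medium", "uncertain"), "NotMeasured")
  expect_error(binarize_protein("Moderate", "supportive"), "Moderate")
})

test_that("protein_profile marks uncalled cells NotMeasured", {
  tbl <- tibble::tibble(gene = c("A", "A", "B"),
                        tissue = c("liver", "brain", "liver"),
                        level = c("High", "Low", "Medium"),
                        reliability = c("supportive", "supportive",
                                        "uncertain"))
  prof <- protein_profile(tbl)
  expect_equal(prof["A", "liver"], "Expressed")
  expect_equal(prof["A", "brain"], "Undetected")
  expect_equal(prof["B", "liver"], "NotMeasured") # fails reliability
  expect_equal(prof["B", "brain"], "NotMeasured") # never called
})

test_that("z-scores match the hand-computed example and center rows", {
  # row [0,0,0,4] in log space: population sd sqrt(3), z = +-1/sqrt(3), 3/sqrt(3)
  x <- matrix(c(0, 0, 0, 4), 1, 4,
              dimnames = list("g", paste0("t", 1:4)))
  z_pop <- zscore_matrix(x, log_transform = FALSE, sd_type = "population")
  expect_equal(unname(z_pop["g", ]),
               c(-1, -1, -1, 3) / sqrt(3), tolerance = 1e-9)
  # default is the sample (n-1) sd
  z_smp <- zscore_matrix(x, log_transform = FALSE)
  expect_equal(unname(z_smp["g", ]), c(-0.5, -0.5, -0.5, 1.5),
               tolerance = 1e-12)

  w <- small_world()
  z <- zscore_matrix(w$expression)
  nonconst <- setdiff(rownames(z), attr(z, "constant_genes"))
  expect_true(all(abs(rowMeans(z[nonconst, ])) < 1e-9))
  expect_true(all(abs(apply(z[nonconst, ], 1, sd) - 1) < 1e-9))
})

test_that("constant rows give all-zero z-scores, flagged", {
  x <- matrix(c(2, 2, 2, 1, 5, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("t", 1:3)))
  z <- zscore_matrix(x, log_transform = FALSE)
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_genes"), "flat")
})

test_that("z-scores are invariant to positive affine transforms after log", {
  set.seed(11)
  x <- matrix(rnorm(40, 5, 2), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("t", 1:10)))
  z1 <- zscore_matrix(x, log_transform = FALSE)
  z2 <- zscore_matrix(3.7 * x + 11, log_transform = FALSE)
  expect_equal(z1, z2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("specificity classes follow the five-fold rule", {
  row10 <- setNames(c(10, rep(1, 31)), paste0("t", 1:32))
  out <- classify_specificity_row(row10)
  expect_equal(out$class, "single_tissue_enriched")
  expect_equal(out$fold, 10)
  expect_equal(out$enriched_tissues, "t1")

  flat <- setNames(rep(5, 10), paste0("t", 1:10))
  expect_equal(classify_specificity_row(flat)$class, "not_enriched")

  trace <- setNames(c(0.9, rep(0.01, 9)), paste0("t", 1:10))
  expect_equal(classify_specificity_row(trace)$class, "undetected")

  grp <- setNames(c(50, 40, rep(1, 8)), paste0("t", 1:10))
  out_g <- classify_specificity_row(grp)
  expect_equal(out_g$class, "group_enriched")
  expect_equal(out_g$n_enriched, 2)
})

test_that("fold = 1 marks every above-floor tissue enriched", {
  set.seed(3)
  row <- setNames(rlnorm(12, 1, 1), paste0("t", 1:12))
  out <- classify_specificity_row(row, fold = 1)
  expect_equal(out$n_enriched, sum(row > 1 & row >= sapply(
    seq_along(row), function(i) mean(row[-i]))))
})

test_that("classify_specificity covers every gene of a matrix", {
  w <- small_world()
  sp <- classify_specificity(w$expression)
  expect_equal(sort(sp$gene), sort(rownames(w$expression)))
  expect_true(all(sp$class %in% c("single_tissue_enriched", "group_enriched",
                                  "not_enriched", "undetected")))
  one <- sp[sp$class == "single_tissue_enriched", ]
  expect_true(all(one$n_enriched == 1))
  grp <- sp[sp$class == "group_enriched", ]
  expect_true(all(grp$n_enriched >= 2 & grp$n_enriched <= 7))
})

test_that("replicate collapsing takes per-tissue medians", {
  rep <- structure(list(
    values = matrix(c(1, 2, 9, 4), 1, 4,
                    dimnames = list("g", paste0("s", 1:4))),
    sample_tissue = c(s1 = "liver", s2 = "liver", s3 = "liver",
                      s4 = "brain")), class = "replicate_expression")
  out <- collapse_replicates(rep)
  expect_equal(out["g", "liver"], 2)   # odd count
  expect_equal(out["g", "brain"], 4)   # single sample
  rep$sample_tissue <- c(s1 = "liver", s2 = "liver", s3 = "brain",
                         s4 = "brain")
  out2 <- collapse_replicates(rep)
  expect_equal(out2["g", "liver"], 1.5) # even count: midpoint
})

test_that("proxy lookup: multi-region max, proxy fallback, NA when absent", {
  expr <- matrix(c(0.5, 3, 1, 7), 1, 4,
                 dimnames = list("g", c("brain_r1", "brain_r2", "lobe",
                                        "lymphoblast")))
  mr <- list(brain = c("brain_r1", "brain_r2"))
  px <- c("lymph node" = "lymphoblast", placenta = NA)
  hit <- lookup_with_proxy(expr, "g", "brain", px, mr)
  expect_equal(hit$value, 3)
  expect_equal(hit$tissue_used, "brain_r2")
  hit2 <- lookup_with_proxy(expr, "g", "lymph node", px, mr)
  expect_equal(hit2$value, 7)
  expect_equal(hit2$tissue_used, "lymphoblast")
  hit3 <- lookup_with_proxy(expr, "g", "placenta", px, mr)
  expect_true(is.na(hit3$value))
  # direct hit needs no proxy machinery
  expect_equal(lookup_with_proxy(expr, "g", "lobe")$value, 1)
})

test_that("collapsing then looking up equals lookup on a pre-collapsed matrix", {
  w <- small_world()
  sec <- collapse_replicates(w$replicates)
  g <- rownames(sec)[5]
  for (t in c(names(w$multi_region)[1], names(w$proxy_map))) {
    a <- lookup_with_proxy(sec, g, t, w$proxy_map, w$multi_region)
    b <- lookup_with_proxy(collapse_replicates(w$replicates), g, t,
                           w$proxy_map, w$multi_region)
    expect_equal(a, b)
  }
})
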