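# Bundled example data: a small curated set of well-known drug-target /
# disease pairs with their literature-assigned tissue, MAS score, bulk FPKM
# in that tissue and antibody-based protein detection call. Handy as a
# worked example and as a published-values fixture for the binarization and
# category rules.

#' Curated example gene-disease pairs
#'
#' Fourteen marketed/late-stage drug targets with their indicated disease,
#' disease-ontology class, literature-assigned tissue (with MAS score), the
#' target's bulk RNA-seq FPKM in that tissue and whether antibody staining
#' detected the protein there. Example rows: ACPP in prostate (prostatic
#' neoplasms, 1916.41 FPKM), HCAR2 in brain (brain ischemia, 0.12 FPKM but
#' protein-positive).
#'
#' @return Tibble with columns `gene`, `disease`, `disease_class`, `tissue`,
#'   `mas`, `fpkm`, `protein_detected` (logical).
#' @export
curated_examples <- function() {
  path <- system.file("extdata", "curated_pairs.tsv",
                      package = "targetissue", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           mas = readr::col_double(),
                           fpkm = readr::col_double(),
                           .default = readr::col_character()))
  tbl$protein_detected <- tbl$protein_detected == "Y"
  tbl$gene <- canonicalize_terms(tbl$gene, "gene")
  tbl$disease <- canonicalize_terms(tbl$disease, "disease")
  tbl$tissue <- canonicalize_terms(tbl$tissue, "tissue")
  tbl
}

#' Confirmation records for the curated examples
#'
#' Applies the standard evidence rules to [curated_examples()]: the mRNA
#' flag comes from binarizing the FPKM column at the detection cutoff, the
#' protein flag from the curated staining call, and the category from the
#' usual integration, treating the single curated tissue as the pair's
#' assignment.
#'
#' @param cutoff mRNA detection limit in FPKM (default 1).
#' @return Tibble of confirmation records (same schema as
#'   [confirm_pairs()]).
#' @export
curated_records <- function(cutoff = 1.0) {
  ex <- curated_examples()
  recs <- lapply(seq_len(nrow(ex)), function(i) {
    row <- ex[i, ]
    mprof <- matrix(binarize_mrna(row$fpkm, cutoff), 1, 1,
                    dimnames = list(row$gene, row$tissue))
    pprof <- matrix(ifelse(row$protein_detected, "Expressed", "Undetected"),
                    1, 1, dimnames = list(row$gene, row$tissue))
    expr <- matrix(row$fpkm, 1, 1,
                   dimnames = list(row$gene, row$tissue))
    assignment <- tibble::tibble(disease = row$disease, tissue = row$tissue,
                                 mas = row$mas, rank = 1L)
    confirm_pair(row, assignment, mprof, pprof, mode = "any_assigned",
                 expr = expr)
  })
  dplyr::bind_rows(recs)
}
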