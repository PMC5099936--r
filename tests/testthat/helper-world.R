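# Shared fixture builders. Worlds used in unit tests are small (50 genes x
# 40 diseases x 8 tissues) so the whole suite stays fast; acceptance-level
# checks size up where the property demands it.

small_world <- function(seed = 42, ...) {
  generate_world(world_config(n_genes = 50, n_diseases = 40, n_tissues = 8,
                              seed = seed, ...))
}

# minimal confirmation-record tibble for the statistics functions
make_records <- function(genes, final_tissue,
                         assigned_tissues = final_tissue,
                         category = "both", disease = NULL,
                         disease_class = NA_character_) {
  tibble::tibble(
    gene = genes,
    disease = disease %||% paste0("d", seq_along(genes)),
    disease_class = disease_class,
    assigned_tissues = assigned_tissues,
    final_tissue = final_tissue,
    category = category,
    mrna_detected = category %in% c("both", "mrna_only"),
    protein_detected = category %in% c("both", "protein_only"),
    fpkm_at_final = NA_real_,
    mas_at_final = NA_real_,
    assigned_mas = NA_character_,
    excluded = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-rolled co-occurrence table: one disease row per element of `joint`
toy_cooc <- function(joint, disease_counts, tissue_counts) {
  cooccurrence_table(disease_counts, tissue_counts, joint)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
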