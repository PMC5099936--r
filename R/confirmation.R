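# Joins gene-disease pairs, tissue assignments and binary expression
# profiles into confirmation records, computes the evidence-category
# accounting, and runs the two rescue analyses for unconfirmed targets.

detect_in <- function(profile, gene, tissues) {
  # returns list(flag, states): flag TRUE if Expressed in >= 1 tissue;
  # NotMeasured tissues are skipped; all-NotMeasured -> flag FALSE, no data
  if (is.null(profile) || !gene %in% rownames(profile)) {
    return(list(flag = FALSE, measured = FALSE))
  }
  tissues <- intersect(tissues, colnames(profile))
  if (length(tissues) == 0) return(list(flag = FALSE, measured = FALSE))
  states <- profile[gene, tissues]
  measured <- states != "NotMeasured"
  list(flag = any(states[measured] == "Expressed"),
       measured = any(measured))
}

#' Confirm a single gene-disease pair
#'
#' Decides whether a pair's target is detectably expressed in the tissues
#' assigned to its disease, separately for mRNA and protein evidence, and
#' derives the evidence category (`both` / `mrna_only` / `protein_only` /
#' `unconfirmed`). In mode `any_assigned` (default) detection in any
#' assigned tissue counts; in mode `top1` only the highest-MAS tissue is
#' consulted. Tissues without a measurement are skipped; a pair with no
#' measured tissue for an evidence type has that flag `FALSE` and an
#' annotation.
#'
#' @param pair One-row tibble (or list) with at least `gene` and `disease`.
#' @param assignment Rows of [assign_tissues()] for the pair's disease.
#' @param mrna_profile,prot_profile Gene x tissue state matrices
#'   ([mrna_profile()], [protein_profile()]); either may be `NULL`.
#' @param mode `"any_assigned"` or `"top1"`.
#' @param expr Optional FPKM matrix used for the final-tissue pick and the
#'   reported FPKM.
#' @return One-row tibble (a confirmation record).
#' @export
confirm_pair <- function(pair, assignment, mrna_profile = NULL,
                         prot_profile = NULL,
                         mode = c("any_assigned", "top1"), expr = NULL) {
  mode <- match.arg(mode)
  gene <- pair[["gene"]]
  rec <- tibble::tibble(
    gene = gene, disease = pair[["disease"]],
    disease_class = pair[["disease_class"]] %||% NA_character_,
    target_class = pair[["target_class"]] %||% NA_character_,
    assigned_tissues = NA_character_, assigned_mas = NA_character_,
    n_assigned = 0L, final_tissue = NA_character_,
    mrna_detected = FALSE, protein_detected = FALSE,
    category = "unconfirmed", fpkm_at_final = NA_real_,
    mas_at_final = NA_real_, annotation = NA_character_, excluded = FALSE
  )
  if (is.null(assignment) || nrow(assignment) == 0) {
    rec$excluded <- TRUE
    rec$annotation <- "no assignable tissue"
    return(rec)
  }
  assignment <- assignment[order(assignment$rank), , drop = FALSE]
  rec$assigned_tissues <- paste(assignment$tissue, collapse = ";")
  rec$assigned_mas <- paste(format(assignment$mas, trim = TRUE),
                            collapse = ";")
  rec$n_assigned <- nrow(assignment)
  tissues <- if (mode == "top1") assignment$tissue[1] else assignment$tissue

  m <- detect_in(mrna_profile, gene, tissues)
  p <- detect_in(prot_profile, gene, tissues)
  rec$mrna_detected <- m$flag
  rec$protein_detected <- p$flag
  notes <- character()
  if (!m$measured && !p$measured) {
    notes <- "gene unmeasured"
  } else {
    if (!m$measured) notes <- c(notes, "no mRNA data")
    if (!p$measured) notes <- c(notes, "no protein data")
  }
  if (length(notes)) rec$annotation <- paste(notes, collapse = "; ")
  rec$category <- if (m$flag && p$flag) "both"
  else if (m$flag) "mrna_only"
  else if (p$flag) "protein_only"
  else "unconfirmed"

  rec$final_tissue <- select_final_tissue(assignment, expr, prot_profile, gene)
  if (!is.na(rec$final_tissue)) {
    if (!is.null(expr) && gene %in% rownames(expr) &&
        rec$final_tissue %in% colnames(expr)) {
      rec$fpkm_at_final <- expr[gene, rec$final_tissue]
    }
    i <- match(rec$final_tissue, assignment$tissue)
    if (!is.na(i)) rec$mas_at_final <- assignment$mas[i]
  }
  rec
}

#' Confirm every gene-disease pair of a study
#'
#' Runs the whole evidence-integration step: tissue assignment per disease,
#' binary mRNA/protein profiles, per-pair confirmation and final-tissue
#' selection.
#'
#' @param pairs Tibble from [read_pairs()].
#' @param mas A `mas_matrix` from [compute_mas()].
#' @param expr Gene x tissue FPKM matrix (or `NULL`).
#' @param protein Protein call tibble from [read_protein()] (or `NULL`).
#' @param mode `"any_assigned"` (detection in any assigned tissue counts) or
#'   `"top1"` (only the highest-MAS tissue).
#' @param k,threshold Assignment parameters, see [assign_tissues()].
#' @param cutoff mRNA detection limit in FPKM.
#' @param supportive_labels Protein reliability filter, see
#'   [binarize_protein()].
#' @return Tibble of confirmation records, one per pair. Pairs whose disease
#'   has no assignable tissue are flagged `excluded = TRUE` and are left out
#'   of [summarize_confirmation()] denominators.
#' @export
confirm_pairs <- function(pairs, mas, expr = NULL, protein = NULL,
                          mode = c("any_assigned", "top1"), k = 3,
                          threshold = 8, cutoff = 1.0,
                          supportive_labels = "supportive") {
  mode <- match.arg(mode)
  assignments <- assign_tissues(mas, k = k, threshold = threshold)
  mprof <- if (!is.null(expr)) mrna_profile(expr, cutoff) else NULL
  pprof <- if (!is.null(protein)) protein_profile(protein, supportive_labels)
           else NULL
  by_disease <- split(assignments, assignments$disease)
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    confirm_pair(pairs[i, ], by_disease[[pairs$disease[i]]],
                 mprof, pprof, mode, expr)
  })
  dplyr::bind_rows(recs)
}

#' Confirmation accounting over a set of records
#'
#' Tallies the evidence categories. Records flagged `excluded` (no
#' assignable tissue) are reported separately and are not part of the
#' category denominators. By construction
#' `n_both + n_mrna_only + n_protein_only = n_either` and
#' `n_either + n_unconfirmed = n_pairs`.
#'
#' @param records Tibble from [confirm_pairs()].
#' @return List of class `confirmation_summary`.
#' @export
summarize_confirmation <- function(records) {
  key <- paste(records$gene, records$disease, sep = "\r")
  if (anyDuplicated(key)) {
    stop("targetissue validation error: duplicate gene-disease pair in ",
         "records", call. = FALSE)
  }
  r <- records[!records$excluded, , drop = FALSE]
  n <- function(cat) sum(r$category == cat)
  out <- list(
    n_pairs = nrow(r),
    n_genes = length(unique(r$gene)),
    n_diseases = length(unique(r$disease)),
    n_mrna = sum(r$mrna_detected),
    n_protein = sum(r$protein_detected),
    n_both = n("both"),
    n_mrna_only = n("mrna_only"),
    n_protein_only = n("protein_only"),
    n_unconfirmed = n("unconfirmed"),
    n_either = n("both") + n("mrna_only") + n("protein_only"),
    n_excluded = sum(records$excluded)
  )
  structure(out, class = "confirmation_summary")
}

#' @export
print.confirmation_summary <- function(x, ...) {
  pct <- function(k) sprintf("%d (%.0f%%)", k, 100 * k / max(x$n_pairs, 1))
  cat("Confirmation summary over ", x$n_pairs, " gene-disease pairs (",
      x$n_genes, " genes, ", x$n_diseases, " diseases)\n", sep = "")
  cat("  mRNA detected:        ", pct(x$n_mrna), "\n", sep = "")
  cat("  either evidence:      ", pct(x$n_either), "\n", sep = "")
  cat("    both:               ", pct(x$n_both), "\n", sep = "")
  cat("    mRNA only:          ", pct(x$n_mrna_only), "\n", sep = "")
  cat("    protein only:       ", pct(x$n_protein_only), "\n", sep = "")
  cat("  unconfirmed:          ", pct(x$n_unconfirmed), "\n", sep = "")
  if (x$n_excluded > 0) {
    cat("  excluded (no assignable tissue): ", x$n_excluded, "\n", sep = "")
  }
  invisible(x)
}

#' Alternate-indication rescue of unconfirmed genes
#'
#' For every gene with at least one unconfirmed record, checks whether any
#' other record of the same gene (a different indication) is confirmed at
#' the mRNA or protein level. Rescue is decided per gene; the confirmed
#' records serve as evidence. Genes with a single indication and no rescue
#' are classed `single_indication_weak`, multi-indication genes unconfirmed
#' everywhere are `unrescued`.
#'
#' @param records Tibble from [confirm_pairs()] covering all pairs.
#' @return Tibble with one row per gene having >= 1 unconfirmed record:
#'   `gene`, `status`, `n_indications`, `n_unconfirmed`, `evidence`
#'   (semicolon-joined `disease:tissue:fpkm` of confirmed records).
#' @export
rescue_alternate_indications <- function(records) {
  r <- records[!records$excluded, , drop = FALSE]
  genes <- unique(r$gene[r$category == "unconfirmed"])
  rows <- lapply(genes, function(g) {
    gr <- r[r$gene == g, , drop = FALSE]
    conf <- gr[gr$category != "unconfirmed", , drop = FALSE]
    status <- if (nrow(conf) > 0) {
      "rescued_alternate_indication"
    } else if (nrow(gr) == 1) {
      "single_indication_weak"
    } else {
      "unrescued"
    }
    ev <- if (nrow(conf) > 0) {
      paste(sprintf("%s:%s:%s", conf$disease,
                    ifelse(is.na(conf$final_tissue), "-", conf$final_tissue),
                    ifelse(is.na(conf$fpkm_at_final), "-",
                           format(conf$fpkm_at_final, trim = TRUE))),
            collapse = ";")
    } else {
      ""
    }
    tibble::tibble(gene = g, status = status,
                   n_indications = nrow(gr),
                   n_unconfirmed = sum(gr$category == "unconfirmed"),
                   evidence = ev)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene = character(), status = character(),
                          n_indications = integer(),
                          n_unconfirmed = integer(), evidence = character())
  }
  out
}

#' Secondary-dataset rescue of unconfirmed pairs
#'
#' Re-tests each unconfirmed pair against an independent, replicate-collapsed
#' expression panel: the pair's assigned tissue is looked up with
#' [lookup_with_proxy()] (multi-region tissues expand to the maximum over
#' their regions, missing tissues follow the proxy map) and the pair is
#' rescued when the value strictly exceeds the detection cutoff.
#'
#' @param records Tibble from [confirm_pairs()]; only rows with
#'   `category == "unconfirmed"` are tested.
#' @param secondary Gene x tissue matrix, already replicate-collapsed.
#' @param proxies Named proxy map (see [read_proxy_map()]).
#' @param multi_region Named list tissue -> region columns of `secondary`.
#' @param cutoff Detection limit in FPKM (strict `>`).
#' @return Tibble: `gene`, `disease`, `tissue` (queried), `tissue_used`,
#'   `value`, `status` (`rescued_secondary_dataset` / `unrescued`).
#' @export
rescue_secondary_dataset <- function(records, secondary, proxies = NULL,
                                     multi_region = NULL, cutoff = 1.0) {
  unc <- records[!records$excluded & records$category == "unconfirmed", ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(unc)), function(i) {
    rec <- unc[i, ]
    tissue <- if (!is.na(rec$final_tissue)) {
      rec$final_tissue
    } else {
      strsplit(rec$assigned_tissues, ";", fixed = TRUE)[[1]][1]
    }
    hit <- lookup_with_proxy(secondary, rec$gene, tissue, proxies,
                             multi_region)
    tibble::tibble(
      gene = rec$gene, disease = rec$disease, tissue = tissue,
      tissue_used = hit$tissue_used, value = hit$value,
      status = if (!is.na(hit$value) && hit$value > cutoff) {
        "rescued_secondary_dataset"
      } else {
        "unrescued"
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene = character(), disease = character(),
                          tissue = character(), tissue_used = character(),
                          value = numeric(), status = character())
  }
  out
}

#' Keep records with high-confidence tissue assignments
#'
#' Retains records whose assigned tissues have a mean MAS strictly above
#' `min_mas` percent; used e.g. to pull out the unconfirmed pairs whose
#' literature signal is strong enough to warrant a secondary-panel re-test.
#'
#' @param records Tibble from [confirm_pairs()].
#' @param min_mas Percent threshold (default 70).
#' @return Subset of `records`.
#' @export
high_confidence_filter <- function(records, min_mas = 70) {
  mean_mas <- vapply(records$assigned_mas, function(s) {
    if (is.na(s)) return(NA_real_)
    mean(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
  }, numeric(1), USE.NAMES = FALSE)
  records[!is.na(mean_mas) & mean_mas > min_mas, , drop = FALSE]
}

#' Re-derive the confirmation accounting from an annotated per-pair table
#'
#' Audits a published-style per-pair annotation table (one row per
#' gene-disease pair with a predicted tissue, MAS score, FPKM and protein
#' detection flag) by re-applying the binarization rules to its columns and
#' recomputing the accounting. The reader is schema-tolerant: columns are
#' matched by fuzzy name (`gene`, `disease`, FPKM-like, MAS-like,
#' mRNA/protein detection flags).
#'
#' @param path TSV path.
#' @param cutoff mRNA detection limit in FPKM.
#' @return List with `records` (tibble with re-derived `mrna_detected`,
#'   `protein_detected`, `category`) and `summary`
#'   (a `confirmation_summary`).
#' @export
audit_annotation_table <- function(path, cutoff = 1.0) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(tbl))))
  find <- function(patterns) {
    for (p in patterns) {
      i <- grep(p, nm)
      if (length(i)) return(i[1])
    }
    NA_integer_
  }
  gi <- find(c("^gene$", "gene"))
  di <- find(c("^disease_name$", "^disease$", "disease"))
  fi <- find(c("fpkm", "mrna_intensity", "intensity"))
  pi <- find(c("protein_detected", "^protein"))
  if (anyNA(c(gi, di, fi, pi))) {
    stop("targetissue format error: annotation table must contain gene, ",
         "disease, FPKM and protein-detection columns", call. = FALSE)
  }
  flag <- function(x) {
    toupper(trimws(as.character(x))) %in% c("Y", "YES", "TRUE", "1")
  }
  rec <- tibble::tibble(
    gene = canonicalize_terms(tbl[[gi]], "gene"),
    disease = canonicalize_terms(tbl[[di]], "disease"),
    fpkm = suppressWarnings(as.numeric(tbl[[fi]])),
    mrna_detected = binarize_mrna(
      ifelse(is.na(suppressWarnings(as.numeric(tbl[[fi]]))), NA,
             suppressWarnings(as.numeric(tbl[[fi]]))), cutoff) == "Expressed",
    protein_detected = flag(tbl[[pi]]),
    excluded = FALSE
  )
  rec$category <- ifelse(rec$mrna_detected & rec$protein_detected, "both",
                  ifelse(rec$mrna_detected, "mrna_only",
                  ifelse(rec$protein_detected, "protein_only",
                         "unconfirmed")))
  list(records = rec, summary = summarize_confirmation(rec))
}

#' Write a confirmation summary as JSON
#'
#' @param summary A `confirmation_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
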