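# Binarization, z-normalization and tissue-specificity classification of
# mRNA and protein evidence, plus replicate collapsing and proxy-tissue
# lookup for secondary panels.

#' Binarize FPKM values at a detection cutoff
#'
#' A gene counts as expressed in a tissue when its FPKM is strictly above the
#' cutoff (default 1 FPKM); a value exactly at the cutoff is `Undetected`.
#'
#' @param fpkm Non-negative numeric vector; `NA` is allowed and propagates to
#'   `NotMeasured`.
#' @param cutoff Detection limit in FPKM (default 1).
#' @return Character vector in `Expressed` / `Undetected` / `NotMeasured`.
#' @examples
#' binarize_mrna(c(0.12, 1916.41, 1)) # Undetected, Expressed, Undetected
#' @export
binarize_mrna <- function(fpkm, cutoff = 1.0) {
  if (any(fpkm < 0, na.rm = TRUE)) {
    stop("targetissue domain error: negative FPKM", call. = FALSE)
  }
  out <- ifelse(is.na(fpkm), "NotMeasured",
                ifelse(fpkm > cutoff, "Expressed", "Undetected"))
  as.character(out)
}

#' Binarize ordinal protein calls under a reliability filter
#'
#' Genes whose antibody annotation does not meet the reliability filter are
#' excluded (`NotMeasured`). For the rest, `Medium` and `High` become
#' `Expressed` while `Absent` and `Low` become `Undetected`.
#'
#' @param level Character vector of ordinal calls
#'   (`Absent`/`Low`/`Medium`/`High`).
#' @param reliability Character vector of per-gene reliability labels.
#' @param supportive_labels Labels accepted by the filter (default
#'   `"supportive"`).
#' @return Character vector in `Expressed` / `Undetected` / `NotMeasured`.
#' @export
binarize_protein <- function(level, reliability,
                             supportive_labels = "supportive") {
  bad <- setdiff(unique(level[!is.na(level)]), .PROTEIN_LEVELS)
  if (length(bad)) {
    stop("targetissue validation error: unknown protein level(s) ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(.PROTEIN_LEVELS, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(is.na(level) | !(reliability %in% supportive_labels),
                "NotMeasured",
                ifelse(level %in% c("Medium", "High"), "Expressed",
                       "Undetected"))
  as.character(out)
}

#' Gene x tissue binary mRNA profile
#'
#' @param expr Gene x tissue FPKM matrix.
#' @inheritParams binarize_mrna
#' @return Character matrix of binary states with the same dimnames.
#' @export
mrna_profile <- function(expr, cutoff = 1.0) {
  out <- matrix(binarize_mrna(as.vector(expr), cutoff),
                nrow = nrow(expr), dimnames = dimnames(expr))
  out
}

#' Gene x tissue binary protein profile
#'
#' Expands a long protein call table into a gene x tissue state matrix;
#' (gene, tissue) combinations without a call are `NotMeasured`, and all
#' calls of genes failing the reliability filter are `NotMeasured`.
#'
#' @param protein Tibble from [read_protein()] (columns `gene`, `tissue`,
#'   `level`, `reliability`).
#' @inheritParams binarize_protein
#' @return Character matrix of binary states.
#' @export
protein_profile <- function(protein, supportive_labels = "supportive") {
  genes <- sort(unique(protein$gene))
  tissues <- sort(unique(protein$tissue))
  out <- matrix("NotMeasured", length(genes), length(tissues),
                dimnames = list(genes, tissues))
  out[cbind(protein$gene, protein$tissue)] <-
    binarize_protein(protein$level, protein$reliability, supportive_labels)
  out
}

#' Per-gene z-scores across tissues
#'
#' Expression is optionally log-transformed (`log2(FPKM + pseudocount)`,
#' the default) and then standardized per gene across tissues. Genes with
#' constant (or single-valued) rows would give 0/0; their z-scores are set
#' to 0 and the genes are listed in the `constant_genes` attribute, so they
#' contribute neutrally to tissue-vs-rest comparisons. `NA` values (not
#' measured) are ignored in the mean/sd and stay `NA`.
#'
#' @param expr Gene x tissue FPKM matrix.
#' @param log_transform Apply `log2(x + pseudocount)` first (default `TRUE`).
#' @param pseudocount Added before the log (default 1).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Numeric matrix of z-scores with attribute `constant_genes`.
#' @export
zscore_matrix <- function(expr, log_transform = TRUE, pseudocount = 1,
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- expr
  if (log_transform) x <- log2(x + pseudocount)
  mu <- rowMeans(x, na.rm = TRUE)
  n <- rowSums(!is.na(x))
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  denom <- if (sd_type == "sample") pmax(n - 1, 1) else pmax(n, 1)
  s <- sqrt(ss / denom)
  z <- (x - mu) / s
  const <- s == 0 | n < 2
  z[const, ] <- 0
  z[is.na(x)] <- NA
  attr(z, "constant_genes") <- rownames(expr)[const]
  z
}

#' Tissue-specificity classification of one expression row
#'
#' A tissue is *enriched* for a gene when its FPKM is at least `fold` times
#' the mean of all other tissues and above the detection floor. Genes are
#' classed `single_tissue_enriched` (exactly one enriched tissue),
#' `group_enriched` (2 to `max_group`), `undetected` (no tissue above the
#' floor) or `not_enriched`. Not-measured (`NA`) tissues are excluded from
#' both sides of the comparison.
#'
#' @param row Named numeric vector of per-tissue FPKM (>= 2 measured
#'   tissues).
#' @param fold Enrichment fold versus the mean of the other tissues
#'   (default 5).
#' @param max_group Largest enriched-tissue count still called
#'   `group_enriched` (default 7).
#' @param floor Detection floor in FPKM (default 1; enrichment additionally
#'   requires FPKM > floor, so ratios among trace values never count).
#' @return One-row tibble: `class`, `enriched_tissues` (semicolon-joined),
#'   `n_enriched`, `fold` (achieved fold of the top tissue).
#' @export
classify_specificity_row <- function(row, fold = 5, max_group = 7,
                                     floor = 1.0) {
  vals <- row[!is.na(row)]
  if (length(vals) < 2) {
    stop("targetissue domain error: specificity needs >= 2 measured tissues",
         call. = FALSE)
  }
  other_mean <- vapply(seq_along(vals),
                       function(i) mean(vals[-i]), numeric(1))
  achieved <- ifelse(other_mean > 0, vals / other_mean, Inf)
  enriched <- vals > floor & vals >= fold * other_mean
  top <- which.max(vals)
  n_enr <- sum(enriched)
  class <- if (all(vals <= floor)) {
    "undetected"
  } else if (n_enr == 1) {
    "single_tissue_enriched"
  } else if (n_enr >= 2 && n_enr <= max_group) {
    "group_enriched"
  } else {
    "not_enriched"
  }
  tibble::tibble(
    class = class,
    enriched_tissues = paste(sort(names(vals)[enriched]), collapse = ";"),
    n_enriched = n_enr,
    fold = unname(achieved[top])
  )
}

#' Tissue-specificity classes for all genes of a matrix
#'
#' @param expr Gene x tissue FPKM matrix.
#' @inheritParams classify_specificity_row
#' @return Tibble with one row per gene: `gene`, `class`,
#'   `enriched_tissues`, `n_enriched`, `fold`.
#' @export
classify_specificity <- function(expr, fold = 5, max_group = 7, floor = 1.0) {
  rows <- lapply(rownames(expr), function(g) {
    out <- classify_specificity_row(expr[g, ], fold, max_group, floor)
    out$gene <- g
    out
  })
  dplyr::relocate(dplyr::bind_rows(rows), "gene")
}

#' Collapse replicate samples to per-tissue medians
#'
#' @param rep A `replicate_expression` object (see
#'   [read_replicate_expression()]) or a list with `values` (gene x sample
#'   matrix) and `sample_tissue` (named character).
#' @return Gene x tissue matrix of median FPKM (even replicate counts use
#'   the midpoint of the two central values).
#' @export
collapse_replicates <- function(rep) {
  vals <- rep$values
  st <- rep$sample_tissue[colnames(vals)]
  if (anyNA(st)) {
    stop("targetissue validation error: sample(s) without a tissue mapping",
         call. = FALSE)
  }
  tissues <- unique(unname(st))
  out <- vapply(tissues, function(t) {
    apply(vals[, st == t, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(rownames(vals), tissues))
  out
}

#' Look up expression in a secondary panel with proxy and multi-region rules
#'
#' Mirrors how a replicate-collapsed secondary panel is queried for a tissue
#' from the primary vocabulary: if the tissue maps to several sampled
#' regions (e.g. brain to its region panel), the maximum median FPKM over
#' the regions is returned together with the winning region; if the tissue
#' is absent from the panel, the proxy map is followed; a proxy of `NA` (or
#' no proxy) yields `NA`.
#'
#' @param expr Gene x tissue matrix, already replicate-collapsed.
#' @param gene,tissue Query names.
#' @param proxies Named character vector tissue -> proxy (`NA` = no proxy).
#' @param multi_region Named list tissue -> character vector of region
#'   columns in `expr`.
#' @return List with `value` (FPKM or `NA`) and `tissue_used` (or `NA`).
#' @export
lookup_with_proxy <- function(expr, gene, tissue, proxies = NULL,
                              multi_region = NULL) {
  miss <- list(value = NA_real_, tissue_used = NA_character_)
  if (!gene %in% rownames(expr)) return(miss)
  if (!is.null(multi_region) && tissue %in% names(multi_region)) {
    regions <- intersect(multi_region[[tissue]], colnames(expr))
    if (length(regions) > 0) {
      vals <- expr[gene, regions]
      if (all(is.na(vals))) return(miss)
      i <- which.max(vals)
      return(list(value = unname(vals[i]), tissue_used = regions[i]))
    }
  }
  if (tissue %in% colnames(expr)) {
    return(list(value = unname(expr[gene, tissue]), tissue_used = tissue))
  }
  if (!is.null(proxies) && tissue %in% names(proxies) &&
      !is.na(proxies[[tissue]]) && proxies[[tissue]] %in% colnames(expr)) {
    p <- proxies[[tissue]]
    return(list(value = unname(expr[gene, p]), tissue_used = p))
  }
  miss
}
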