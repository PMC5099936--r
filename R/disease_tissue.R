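# Disease-tissue association scoring from literature co-occurrence counts.
#
# The association of a disease d and tissue t is the Ochiai coefficient of
# their abstract sets, OC = N_dt / sqrt(N_d * N_t), i.e. the cosine
# similarity of the two binary occurrence vectors. Per disease the OCs are
# normalized to sum to 100, giving the maximal association score (MAS);
# 100 means all of the disease's tissue literature points at one tissue.

#' Ochiai coefficient of two occurrence sets
#'
#' @param joint Number of abstracts mentioning both terms.
#' @param n_d,n_t Marginal abstract counts for disease and tissue. Must be
#'   strictly positive; use [compute_ochiai()] for matrix computation, where
#'   zero marginals are defined as non-association.
#' @return `joint / sqrt(n_d * n_t)`, in `[0, 1]`. Vectorized.
#' @examples
#' ochiai(20, 100, 400) # 0.1
#' @export
ochiai <- function(joint, n_d, n_t) {
  if (any(n_d <= 0) || any(n_t <= 0)) {
    stop("targetissue domain error: ochiai() requires positive marginal ",
         "counts", call. = FALSE)
  }
  if (any(joint < 0) || any(joint > pmin(n_d, n_t))) {
    stop("targetissue domain error: joint count outside [0, min(n_d, n_t)]",
         call. = FALSE)
  }
  joint / sqrt(n_d * n_t)
}

#' Ochiai coefficient matrix of a co-occurrence table
#'
#' Terms whose marginal count is zero never appear in the literature, which
#' is treated as non-association: their coefficients are set to 0 with a
#' warning rather than raising an error, so that row normalization stays
#' total.
#'
#' @param cooc A [cooccurrence_table()].
#' @return Disease x tissue numeric matrix in `[0, 1]`.
#' @export
compute_ochiai <- function(cooc) {
  stopifnot(inherits(cooc, "cooccurrence_table"))
  nd <- cooc$disease_counts
  nt <- cooc$tissue_counts
  denom <- sqrt(outer(nd, nt))
  oc <- cooc$joint / denom
  zero <- denom == 0
  if (any(zero)) {
    warning("zero marginal count for ",
            sum(nd == 0), " disease(s) and ", sum(nt == 0),
            " tissue(s); their Ochiai coefficients are set to 0",
            call. = FALSE)
    oc[zero] <- 0
  }
  oc
}

#' Maximal association scores from co-occurrence counts
#'
#' Normalizes each disease's Ochiai coefficients by their sum and scales to
#' 0-100. Diseases whose coefficients are all zero cannot be associated with
#' any tissue; their rows stay all-zero and are listed in `unassociable`.
#'
#' @param cooc A [cooccurrence_table()].
#' @return An object of class `mas_matrix`: a list with elements `mas` and
#'   `oc` (disease x tissue matrices), and `unassociable` (character vector
#'   of diseases with an all-zero row).
#' @export
compute_mas <- function(cooc) {
  oc <- compute_ochiai(cooc)
  rs <- rowSums(oc)
  mas <- oc
  ok <- rs > 0
  mas[ok, ] <- 100 * oc[ok, , drop = FALSE] / rs[ok]
  mas[!ok, ] <- 0
  structure(list(mas = mas, oc = oc,
                 unassociable = rownames(oc)[!ok]),
            class = "mas_matrix")
}

#' @export
print.mas_matrix <- function(x, ...) {
  cat("<mas_matrix> ", nrow(x$mas), " diseases x ", ncol(x$mas), " tissues",
      sep = "")
  if (length(x$unassociable)) {
    cat("; ", length(x$unassociable), " unassociable disease(s)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Assign tissues to diseases from MAS scores
#'
#' Per disease, keeps the up-to-`k` highest-scoring tissues whose MAS meets
#' the threshold (inclusive, i.e. `mas >= threshold`). Ties at the k-th rank
#' are broken by tissue name, alphabetically. Diseases with no tissue passing
#' (including unassociable all-zero rows) get no rows; they can be listed
#' with [unassigned_diseases()].
#'
#' @param mas A `mas_matrix` from [compute_mas()], or a named numeric vector
#'   of per-tissue scores for a single disease (on the 0-100 scale).
#' @param k Maximum number of tissues per disease (default 3).
#' @param threshold Minimum MAS, in percent (default 8; inclusive).
#' @return Tibble with columns `disease`, `tissue`, `mas`, `rank`, sorted by
#'   disease then rank (descending MAS).
#' @export
assign_tissues <- function(mas, k = 3, threshold = 8) {
  stopifnot(k >= 1, threshold >= 0)
  if (is.numeric(mas) && !is.matrix(mas)) {
    m <- matrix(mas, nrow = 1, dimnames = list(".", names(mas)))
  } else if (inherits(mas, "mas_matrix")) {
    m <- mas$mas
  } else if (is.matrix(mas)) {
    m <- mas
  } else {
    stop("targetissue: assign_tissues() expects a mas_matrix, matrix or ",
         "named numeric vector", call. = FALSE)
  }
  rows <- lapply(rownames(m), function(d) {
    s <- m[d, ]
    pass <- which(s >= threshold & s > 0)
    if (length(pass) == 0) return(NULL)
    ord <- pass[order(-s[pass], names(s)[pass])]
    keep <- head(ord, k)
    tibble::tibble(disease = d, tissue = names(s)[keep],
                   mas = unname(s[keep]), rank = seq_along(keep))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(disease = character(), tissue = character(),
                          mas = numeric(), rank = integer())
  }
  attr(out, "k") <- k
  attr(out, "threshold") <- threshold
  out
}

#' Diseases left without a tissue assignment
#'
#' @param assignments Output of [assign_tissues()].
#' @param mas The `mas_matrix` the assignments were made from.
#' @return Character vector of diseases with no passing tissue.
#' @export
unassigned_diseases <- function(assignments, mas) {
  setdiff(rownames(mas$mas), unique(assignments$disease))
}

#' Final single-tissue selection for a gene-disease pair
#'
#' Among a disease's assigned tissues, picks the one where the gene shows the
#' highest measured FPKM. If the gene has no measured FPKM in any assigned
#' tissue, falls back to the highest-MAS assigned tissue with an `Expressed`
#' protein call; if neither evidence type is available, returns `NA`.
#'
#' @param assignment Rows of [assign_tissues()] for one disease (columns
#'   `tissue`, `mas`, `rank`).
#' @param expr Gene x tissue FPKM matrix (may be `NULL`).
#' @param protein_profile Gene x tissue binary-state matrix from
#'   [protein_profile()] (may be `NULL`).
#' @param gene Gene symbol.
#' @return Single tissue name, or `NA_character_`.
#' @export
select_final_tissue <- function(assignment, expr = NULL,
                                protein_profile = NULL, gene) {
  if (is.null(assignment) || nrow(assignment) == 0) return(NA_character_)
  tissues <- assignment$tissue[order(assignment$rank)]
  if (!is.null(expr) && gene %in% rownames(expr)) {
    tt <- intersect(tissues, colnames(expr))
    vals <- setNames(as.numeric(expr[gene, tt]), tt)
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) return(names(vals)[which.max(vals)])
  }
  if (!is.null(protein_profile) && gene %in% rownames(protein_profile)) {
    for (t in tissues) { # already in MAS rank order
      if (t %in% colnames(protein_profile) &&
          identical(protein_profile[gene, t], "Expressed")) {
        return(t)
      }
    }
  }
  NA_character_
}

#' Write a MAS matrix as a long TSV
#'
#' One row per (disease, tissue) with a positive Ochiai coefficient, columns
#' `disease`, `tissue`, `oc`, `mas`, `rank`, `passed_threshold`. `rank` is
#' the within-disease MAS rank; `passed_threshold` marks the tissues kept by
#' [assign_tissues()] with the same `k` and `threshold`.
#'
#' @param mas A `mas_matrix`.
#' @param path Output path.
#' @inheritParams assign_tissues
#' @return `path`, invisibly.
#' @export
write_mas <- function(mas, path, k = 3, threshold = 8) {
  stopifnot(inherits(mas, "mas_matrix"))
  long <- tibble::as_tibble(as.table(mas$mas), .name_repair = "minimal")
  names(long) <- c("disease", "tissue", "mas")
  long$oc <- mas$oc[cbind(long$disease, long$tissue)]
  long <- long[long$oc > 0, c("disease", "tissue", "oc", "mas")]
  long <- dplyr::arrange(long, .data$disease, dplyr::desc(.data$mas),
                         .data$tissue)
  long <- dplyr::mutate(dplyr::group_by(long, .data$disease),
                        rank = dplyr::row_number())
  long <- dplyr::ungroup(long)
  assigned <- assign_tissues(mas, k = k, threshold = threshold)
  long$passed_threshold <- paste(long$disease, long$tissue) %in%
    paste(assigned$disease, assigned$tissue)
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
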