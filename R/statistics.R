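# Inferential statistics and summary tables over confirmation records:
# paired comparison of disease-tissue vs remaining-tissue z-scores,
# enrichment of multi-indication targets among unconfirmed pairs, and the
# disease-class x tissue cross-tabulations.

assigned_list <- function(records) {
  strsplit(ifelse(is.na(records$assigned_tissues), "",
                  records$assigned_tissues), ";", fixed = TRUE)
}

#' Paired comparison of disease-tissue vs remaining-tissue expression
#'
#' For every record with a final tissue, pairs the gene's z-score in that
#' tissue with its mean z-score over the remaining measured tissues, and
#' runs a two-sided paired t-test on the differences. "Remaining" excludes
#' all assigned tissues by default (`out_group = "exclude_assigned"`) or
#' only the final tissue (`"exclude_final"`). Raw-FPKM means of both sides
#' are reported alongside when `expr` is given.
#'
#' If every difference is identical the t statistic is undefined (zero
#' variance); the convention used here is `t = 0, p = 1`, flagged by
#' `degenerate = TRUE`.
#'
#' @param z Gene x tissue z-score matrix ([zscore_matrix()]).
#' @param records Tibble from [confirm_pairs()].
#' @param expr Optional raw FPKM matrix for the descriptive means.
#' @param out_group `"exclude_assigned"` (default) or `"exclude_final"`.
#' @return List of class `paired_comparison`: `n_pairs`, `mean_in`,
#'   `mean_out`, `mean_fpkm_in`, `mean_fpkm_out`, `t_stat`, `p_value`,
#'   `degenerate`.
#' @export
paired_zscore_test <- function(z, records, expr = NULL,
                               out_group = c("exclude_assigned",
                                             "exclude_final")) {
  out_group <- match.arg(out_group)
  assigned <- assigned_list(records)
  ins <- outs <- fin <- fout <- numeric(0)
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]
    t0 <- records$final_tissue[i]
    if (is.na(t0) || !g %in% rownames(z) || !t0 %in% colnames(z)) next
    drop <- if (out_group == "exclude_assigned") assigned[[i]] else t0
    rest <- setdiff(colnames(z), drop)
    zin <- z[g, t0]
    zout <- z[g, rest]
    zout <- zout[!is.na(zout)]
    if (is.na(zin) || length(zout) == 0) next
    ins <- c(ins, zin)
    outs <- c(outs, mean(zout))
    if (!is.null(expr) && g %in% rownames(expr)) {
      fin <- c(fin, expr[g, t0])
      erest <- expr[g, intersect(rest, colnames(expr))]
      fout <- c(fout, mean(erest, na.rm = TRUE))
    }
  }
  n <- length(ins)
  if (n < 2) {
    stop("targetissue: paired test undefined for fewer than 2 usable pairs",
         call. = FALSE)
  }
  d <- ins - outs
  degenerate <- sd(d) == 0
  if (degenerate) {
    t_stat <- 0
    p <- 1
  } else {
    ht <- t.test(ins, outs, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(
    n_pairs = n, mean_in = mean(ins), mean_out = mean(outs),
    mean_fpkm_in = if (length(fin)) mean(fin, na.rm = TRUE) else NA_real_,
    mean_fpkm_out = if (length(fout)) mean(fout, na.rm = TRUE) else NA_real_,
    t_stat = t_stat, p_value = p, degenerate = degenerate
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired disease-tissue vs remaining-tissue comparison (n = ",
      x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  mean z in/out:    %.2f vs %.2f\n", x$mean_in, x$mean_out))
  if (!is.na(x$mean_fpkm_in)) {
    cat(sprintf("  mean FPKM in/out: %.1f vs %.1f\n",
                x$mean_fpkm_in, x$mean_fpkm_out))
  }
  cat(sprintf("  paired t = %.3f, p = %.3g\n", x$t_stat, x$p_value))
  invisible(x)
}

#' Enrichment of multi-indication targets among unconfirmed pairs
#'
#' Classifies every (non-excluded) record by whether its gene has two or
#' more indications in the record set and whether the pair is unconfirmed,
#' and tests independence of the two classifications with a 2x2 chi-square
#' frequency test (no continuity correction by default).
#'
#' @param records Tibble from [confirm_pairs()].
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List of class `enrichment_table`: `table` (2x2 counts,
#'   multi/single x unconfirmed/confirmed), `chi2`, `p_value`.
#' @export
multi_indication_enrichment <- function(records, correct = FALSE) {
  r <- records[!records$excluded, , drop = FALSE]
  n_ind <- table(r$gene)
  multi <- factor(ifelse(n_ind[r$gene] >= 2, "multi", "single"),
                  levels = c("multi", "single"))
  unconf <- factor(ifelse(r$category == "unconfirmed", "unconfirmed",
                          "confirmed"),
                   levels = c("unconfirmed", "confirmed"))
  tab <- table(multi, unconf)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("targetissue: degenerate table - a margin of the 2x2 ",
         "indication-by-confirmation table is zero", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(table = tab, chi2 = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.3f, p = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

record_classes <- function(records, class_map = NULL) {
  cls <- records$disease_class
  if (!is.null(class_map)) {
    mapped <- unname(class_map[records$disease])
    cls <- ifelse(!is.na(mapped), mapped, cls)
  }
  ifelse(is.na(cls) | cls == "", "unclassified", cls)
}

#' Disease-class by tissue target counts
#'
#' Counts, for every (disease class, tissue) cell, the number of distinct
#' target genes whose records in that class carry that tissue among their
#' assigned (up to top-3) tissues. A target appearing under two diseases of
#' one class in the same tissue is counted once.
#'
#' @param records Tibble from [confirm_pairs()].
#' @param class_map Optional named character vector disease -> class,
#'   overriding the records' `disease_class` column; diseases without a
#'   class fall into `"unclassified"`.
#' @return Integer matrix, classes in rows, tissues in columns.
#' @export
class_tissue_crosstab <- function(records, class_map = NULL) {
  r <- records[!records$excluded, , drop = FALSE]
  cls <- record_classes(r, class_map)
  tiss <- assigned_list(r)
  long <- tibble::tibble(
    gene = rep(r$gene, lengths(tiss)),
    class = rep(cls, lengths(tiss)),
    tissue = unlist(tiss)
  )
  long <- dplyr::distinct(long)
  tab <- table(long$class, long$tissue)
  mat <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  mat
}

#' Targets shared between disease classes
#'
#' Symmetric class-by-class matrix of distinct targets: the diagonal is the
#' number of distinct targets per class, off-diagonal cells the size of the
#' intersection of the two classes' target sets. The gene lists behind the
#' off-diagonal cells are returned alongside.
#'
#' @inheritParams class_tissue_crosstab
#' @return List with `counts` (symmetric integer matrix) and `genes`
#'   (named list `"classA|classB"` -> character vector).
#' @export
shared_targets <- function(records, class_map = NULL) {
  r <- records[!records$excluded, , drop = FALSE]
  cls <- record_classes(r, class_map)
  sets <- lapply(split(r$gene, cls), unique)
  classes <- names(sets)
  k <- length(classes)
  counts <- matrix(0L, k, k, dimnames = list(classes, classes))
  genes <- list()
  for (i in seq_len(k)) {
    counts[i, i] <- length(sets[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      shared <- sort(intersect(sets[[i]], sets[[j]]))
      counts[i, j] <- counts[j, i] <- length(shared)
      if (length(shared)) {
        genes[[paste(classes[i], classes[j], sep = "|")]] <- shared
      }
    }
  }
  list(counts = counts, genes = genes)
}

#' Ward-linkage display order for a crosstab
#'
#' Orders the rows and columns of a class-by-tissue count matrix by Ward
#' agglomerative clustering (Euclidean distance, `ward.D2`). Display
#' convenience only - counts are untouched.
#'
#' @param mat Matrix from [class_tissue_crosstab()].
#' @return The matrix with rows/columns permuted to the dendrogram order.
#' @export
order_crosstab <- function(mat) {
  ro <- if (nrow(mat) > 2) hclust(dist(mat), method = "ward.D2")$order
        else seq_len(nrow(mat))
  co <- if (ncol(mat) > 2) hclust(dist(t(mat)), method = "ward.D2")$order
        else seq_len(ncol(mat))
  mat[ro, co, drop = FALSE]
}
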