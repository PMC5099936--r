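# Readers/writers for the tabular inputs and outputs of the pipeline.
# All files are TSV, UTF-8, header row, decimal point. Gene, disease and
# tissue names are canonicalized before any join: whitespace-trimmed,
# genes upper-cased, disease/tissue terms lower-cased, then an optional
# user-supplied synonym table is applied.

#' Canonicalize gene, disease or tissue terms
#'
#' Joins across literature counts, expression panels and protein-call tables
#' use vocabularies that differ in case and spacing. All readers funnel names
#' through this helper: whitespace is trimmed and squeezed, case is folded
#' (upper for gene symbols, lower otherwise), and an optional named character
#' vector of synonyms (`c(raw = "canonical")`, matched after case folding) is
#' applied.
#'
#' @param x Character vector of terms.
#' @param type `"gene"`, `"disease"` or `"tissue"`.
#' @param synonyms Optional named character vector mapping terms to their
#'   canonical spelling.
#' @return Character vector of canonical terms.
#' @export
canonicalize_terms <- function(x, type = c("tissue", "disease", "gene"),
                               synonyms = NULL) {
  type <- match.arg(type)
  out <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  out <- if (type == "gene") toupper(out) else tolower(out)
  if (!is.null(synonyms)) {
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) {
    stop("targetissue format error: file not found: ", path, call. = FALSE)
  }
  tbl <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop("targetissue format error reading ", what, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tbl) == 0) {
    stop("targetissue format error: ", what, " file has a header but no rows: ",
         path, call. = FALSE)
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("targetissue format error: ", what, " is missing mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}

num_col <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) && !all(is.na(out) == (is.na(x) | x %in% c("NA", "")))) {
    stop("targetissue format error: non-numeric value in ", what, call. = FALSE)
  }
  out
}

#' Read a gene-disease pair table
#'
#' Expects a TSV with mandatory columns `gene` and `disease`; optional columns
#' `disease_class` (ontology class) and `target_class` (protein family) are
#' carried through, any other columns are kept untouched. Duplicate
#' (gene, disease) rows are collapsed to the first occurrence with a warning.
#'
#' @param path Path to `pairs.tsv`.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return A tibble with one row per unique (gene, disease) pair.
#' @export
read_pairs <- function(path, synonyms = NULL) {
  tbl <- read_tsv_strict(path, c("gene", "disease"), "pairs table")
  tbl$gene <- canonicalize_terms(tbl$gene, "gene", synonyms)
  tbl$disease <- canonicalize_terms(tbl$disease, "disease", synonyms)
  if (any(tbl$gene == "" | tbl$disease == "")) {
    stop("targetissue validation error: empty gene or disease name in pairs table",
         call. = FALSE)
  }
  key <- paste(tbl$gene, tbl$disease, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (gene, disease) row(s) collapsed",
            call. = FALSE)
    tbl <- tbl[!duplicated(key), , drop = FALSE]
  }
  if (!"disease_class" %in% names(tbl)) tbl$disease_class <- NA_character_
  if (!"target_class" %in% names(tbl)) tbl$target_class <- NA_character_
  tibble::as_tibble(tbl)
}

#' Construct a validated literature co-occurrence table
#'
#' Holds per-disease and per-tissue marginal abstract counts together with
#' the joint disease-by-tissue co-occurrence counts that feed the Ochiai /
#' MAS computation. Joint cells never present are 0.
#'
#' @param disease_counts Named non-negative integer vector (abstracts
#'   mentioning the disease).
#' @param tissue_counts Named non-negative integer vector (abstracts
#'   mentioning the tissue).
#' @param joint Numeric matrix of joint counts, diseases in rows, tissues in
#'   columns; dimnames must be subsets of the marginal names.
#' @return An object of class `cooccurrence_table`.
#' @export
cooccurrence_table <- function(disease_counts, tissue_counts, joint) {
  stopifnot(is.numeric(disease_counts), is.numeric(tissue_counts),
            is.matrix(joint))
  if (is.null(names(disease_counts)) || is.null(names(tissue_counts)) ||
      is.null(rownames(joint)) || is.null(colnames(joint))) {
    stop("targetissue validation error: co-occurrence counts must be named",
         call. = FALSE)
  }
  if (any(disease_counts < 0) || any(tissue_counts < 0) || any(joint < 0)) {
    stop("targetissue validation error: negative count in co-occurrence table",
         call. = FALSE)
  }
  missing_d <- setdiff(rownames(joint), names(disease_counts))
  missing_t <- setdiff(colnames(joint), names(tissue_counts))
  if (length(missing_d) || length(missing_t)) {
    stop("targetissue validation error: joint counts for terms without a ",
         "marginal: ", paste(c(missing_d, missing_t), collapse = ", "),
         call. = FALSE)
  }
  # expand joint to the full disease x tissue universe, absent cells = 0
  full <- matrix(0, length(disease_counts), length(tissue_counts),
                 dimnames = list(names(disease_counts), names(tissue_counts)))
  full[rownames(joint), colnames(joint)] <- joint
  cap <- outer(disease_counts, tissue_counts, pmin)
  bad <- which(full > cap, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("targetissue validation error: joint count exceeds a marginal at (",
         rownames(full)[bad[1, 1]], ", ", colnames(full)[bad[1, 2]], "): ",
         full[bad[1, , drop = FALSE]], " > ", cap[bad[1, , drop = FALSE]],
         call. = FALSE)
  }
  structure(list(disease_counts = disease_counts,
                 tissue_counts = tissue_counts,
                 joint = full),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("<cooccurrence_table> ", length(x$disease_counts), " diseases x ",
      length(x$tissue_counts), " tissues; ",
      sum(x$joint > 0), " non-zero joint cells\n", sep = "")
  invisible(x)
}

#' Read literature co-occurrence counts
#'
#' `path_joint` is a TSV with columns `disease`, `tissue`, `count`;
#' `path_marginals` has columns `term`, `kind` (`disease` or `tissue`) and
#' `count`. Joint cells absent from the file default to 0.
#'
#' @param path_joint,path_marginals File paths.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return A [cooccurrence_table()].
#' @export
read_cooccurrence <- function(path_joint, path_marginals, synonyms = NULL) {
  marg <- read_tsv_strict(path_marginals, c("term", "kind", "count"),
                          "marginal counts")
  if (!all(marg$kind %in% c("disease", "tissue"))) {
    stop("targetissue validation error: marginal kind must be 'disease' or ",
         "'tissue'", call. = FALSE)
  }
  marg$count <- num_col(marg$count, "marginal counts")
  d <- marg[marg$kind == "disease", ]
  t <- marg[marg$kind == "tissue", ]
  disease_counts <- setNames(d$count, canonicalize_terms(d$term, "disease", synonyms))
  tissue_counts <- setNames(t$count, canonicalize_terms(t$term, "tissue", synonyms))

  joint_tbl <- read_tsv_strict(path_joint, c("disease", "tissue", "count"),
                               "joint counts")
  joint_tbl$disease <- canonicalize_terms(joint_tbl$disease, "disease", synonyms)
  joint_tbl$tissue <- canonicalize_terms(joint_tbl$tissue, "tissue", synonyms)
  joint_tbl$count <- num_col(joint_tbl$count, "joint counts")
  joint <- matrix(0, length(disease_counts), length(tissue_counts),
                  dimnames = list(names(disease_counts), names(tissue_counts)))
  extra_d <- setdiff(unique(joint_tbl$disease), names(disease_counts))
  extra_t <- setdiff(unique(joint_tbl$tissue), names(tissue_counts))
  if (length(extra_d) || length(extra_t)) {
    stop("targetissue validation error: joint counts for terms without a ",
         "marginal: ", paste(c(extra_d, extra_t), collapse = ", "),
         call. = FALSE)
  }
  joint[cbind(joint_tbl$disease, joint_tbl$tissue)] <- joint_tbl$count
  cooccurrence_table(disease_counts, tissue_counts, joint)
}

#' Read a gene-by-tissue FPKM expression matrix
#'
#' Expects a TSV whose first column is `gene` and whose remaining columns are
#' tissues; values are non-negative FPKM. Empty cells and literal `NA` are
#' read as "not measured" and excluded from downstream denominators (they are
#' never treated as 0).
#'
#' @param path File path.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return A numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression <- function(path, synonyms = NULL) {
  tbl <- read_tsv_strict(path, "gene", "expression matrix")
  genes <- canonicalize_terms(tbl$gene, "gene", synonyms)
  tissues <- canonicalize_terms(setdiff(names(tbl), "gene"), "tissue", synonyms)
  if (anyDuplicated(genes) || anyDuplicated(tissues)) {
    stop("targetissue validation error: duplicate gene or tissue name in ",
         "expression matrix", call. = FALSE)
  }
  vals <- vapply(setdiff(names(tbl), "gene"),
                 function(cn) num_col(tbl[[cn]], paste0("expression column ", cn)),
                 numeric(nrow(tbl)))
  vals <- matrix(vals, nrow = nrow(tbl), dimnames = list(genes, tissues))
  if (any(vals < 0, na.rm = TRUE)) {
    stop("targetissue validation error: negative FPKM in expression matrix",
         call. = FALSE)
  }
  vals
}

#' Read a replicate-bearing expression matrix and its sample-to-tissue map
#'
#' Secondary panels (GTEx-style) carry several samples per tissue. The value
#' file has columns `gene` then one per sample id; the sample file has columns
#' `sample` and `tissue`.
#'
#' @param path_values,path_samples File paths.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return A list of class `replicate_expression` with elements `values`
#'   (gene x sample matrix) and `sample_tissue` (named character vector).
#' @export
read_replicate_expression <- function(path_values, path_samples,
                                      synonyms = NULL) {
  tbl <- read_tsv_strict(path_values, "gene", "replicate expression matrix")
  smp <- read_tsv_strict(path_samples, c("sample", "tissue"), "sample map")
  genes <- canonicalize_terms(tbl$gene, "gene", synonyms)
  samples <- setdiff(names(tbl), "gene")
  sample_tissue <- setNames(canonicalize_terms(smp$tissue, "tissue", synonyms),
                            trimws(smp$sample))
  missing <- setdiff(samples, names(sample_tissue))
  if (length(missing)) {
    stop("targetissue validation error: sample(s) without a tissue mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(samples,
                 function(cn) num_col(tbl[[cn]], paste0("sample column ", cn)),
                 numeric(nrow(tbl)))
  vals <- matrix(vals, nrow = nrow(tbl), dimnames = list(genes, samples))
  if (any(vals < 0, na.rm = TRUE)) {
    stop("targetissue validation error: negative FPKM in replicate matrix",
         call. = FALSE)
  }
  structure(list(values = vals, sample_tissue = sample_tissue[samples]),
            class = "replicate_expression")
}

#' Read a protein call table
#'
#' Expects a TSV with columns `gene`, `tissue`, `level`
#' (Absent/Low/Medium/High) and `reliability` (e.g. supportive / uncertain /
#' unreliable; the accepted vocabulary is open, the filter is applied later
#' by [binarize_protein()]).
#'
#' @param path File path.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return A tibble with canonical gene/tissue names, ordinal `level` and
#'   per-gene `reliability`.
#' @export
read_protein <- function(path, synonyms = NULL) {
  tbl <- read_tsv_strict(path, c("gene", "tissue", "level", "reliability"),
                         "protein call table")
  tbl$gene <- canonicalize_terms(tbl$gene, "gene", synonyms)
  tbl$tissue <- canonicalize_terms(tbl$tissue, "tissue", synonyms)
  bad <- setdiff(unique(tbl$level), .PROTEIN_LEVELS)
  if (length(bad)) {
    stop("targetissue validation error: unknown protein level(s) ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(.PROTEIN_LEVELS, collapse = ", "), call. = FALSE)
  }
  rel_per_gene <- tapply(tbl$reliability, tbl$gene,
                         function(r) length(unique(r)))
  if (any(rel_per_gene > 1)) {
    stop("targetissue validation error: conflicting reliability labels for ",
         "gene(s) ", paste(names(rel_per_gene)[rel_per_gene > 1],
                           collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl[c("gene", "tissue", "level", "reliability")])
}

#' Read a proxy-tissue map
#'
#' Maps tissues required by the analysis to substitutes available in a
#' secondary panel; the value `NA` marks tissues with no usable proxy.
#'
#' @param path TSV with columns `tissue` and `proxy`.
#' @param synonyms Optional synonym table passed to [canonicalize_terms()].
#' @return Named character vector; `NA` entries mean "no proxy".
#' @export
read_proxy_map <- function(path, synonyms = NULL) {
  tbl <- read_tsv_strict(path, c("tissue", "proxy"), "proxy map")
  proxy <- canonicalize_terms(tbl$proxy, "tissue", synonyms)
  proxy[tbl$proxy %in% c("NA", "")] <- NA_character_
  setNames(proxy, canonicalize_terms(tbl$tissue, "tissue", synonyms))
}

#' Write / read confirmation records
#'
#' `write_records()` serializes a confirmation-record tibble (see
#' [confirm_pairs()]) as TSV; `read_records()` reads it back with the same
#' column types, so a write/read round trip reproduces the table.
#'
#' @param records Tibble of confirmation records.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()` the
#'   tibble.
#' @export
write_records <- function(records, path) {
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           mrna_detected = readr::col_logical(),
                           protein_detected = readr::col_logical(),
                           excluded = readr::col_logical(),
                           n_assigned = readr::col_integer(),
                           fpkm_at_final = readr::col_double(),
                           mas_at_final = readr::col_double(),
                           .default = readr::col_character()
                         ))
  tibble::as_tibble(tbl)
}

#' Write an expression matrix as TSV
#'
#' @param expr Gene x tissue numeric matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tbl <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}
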