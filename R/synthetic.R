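# Synthetic-world generator. Emulates the five pipeline inputs with planted
# ground truth: each disease gets one planted tissue whose literature
# co-occurrence mass is `concentration`-fold the background; targets of
# confirmable pairs get an expression boost in the planted tissue; protein
# calls are derived from per-gene expression quartiles and then degraded by
# a dropout probability. Every table is drawn from its own pseudo-random
# stream derived from the master seed, so adding one table never perturbs
# the others.

# Tissue vocabulary used for default worlds; tissues with special roles in
# secondary panels (region expansion, proxy, absent) come first so that
# small worlds still exercise those paths.
.TISSUE_PANEL <- c(
  "brain", "lymph node", "placenta", "kidney", "liver", "skin", "heart",
  "lung", "adipose tissue", "adrenal gland", "appendix", "bone marrow",
  "colon", "duodenum", "endometrium", "esophagus", "gallbladder", "ovary",
  "pancreas", "prostate", "salivary gland", "skeletal muscle",
  "small intestine", "smooth muscle", "spleen", "stomach", "testis",
  "thyroid", "tonsil", "urinary bladder", "cervix", "fallopian tube"
)

.DISEASE_CLASSES <- c(
  "cardiovascular system disease", "nervous system disease",
  "disease of metabolism", "disease of cellular proliferation",
  "immune system disease", "urinary system disease",
  "gastrointestinal system disease", "respiratory system disease",
  "musculoskeletal system disease", "endocrine system disease",
  "integumentary system disease", "reproductive system disease"
)

.TARGET_CLASSES <- c("gpcr", "enzyme", "transporter", "cytokine",
                     "nuclear receptor", "kinase", "ion channel",
                     "unclassified")

stream_seed <- function(seed, label) {
  offsets <- c(truth = 1L, pairs = 2L, cooccurrence = 3L, expression = 4L,
               protein = 5L, replicates = 6L)
  (abs(as.integer(seed)) %% 100000000L) * 20L + offsets[[label]]
}

with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, label))
  force(code)
}

#' Configuration of a synthetic study world
#'
#' The defaults echo the scale of the study the pipeline is designed for:
#' 345 target genes, 406 diseases over a 32-tissue panel, a mean of ~3.8
#' indications per gene (about 1,300 pairs), a 10:1 literature concentration
#' on the planted tissue, a log-normal FPKM background, a 20x expression
#' boost in confirmable pairs' planted tissues and 30% protein dropout.
#'
#' @param n_genes,n_diseases,n_tissues World dimensions (`n_tissues >= 3`).
#' @param mean_indications Mean of the zero-truncated geometric number of
#'   indications per gene (must be >= 1).
#' @param concentration Ratio of planted-tissue to per-background-tissue
#'   literature mass (>= 1; `Inf` puts all mass on the planted tissue).
#' @param background_meanlog,background_sdlog Log-normal parameters of
#'   background FPKM.
#' @param boost Multiplicative expression boost in the planted tissue of
#'   confirmable pairs (>= 1).
#' @param confirmable_fraction Probability that a pair receives the boost.
#' @param protein_dropout Probability that an mRNA-expressed (gene, tissue)
#'   with a Medium/High call is degraded to Low.
#' @param supportive_fraction Fraction of genes whose antibody reliability
#'   is `supportive` (the rest are `uncertain`).
#' @param n_replicates Samples per tissue in the secondary panel.
#' @param cutoff Detection limit (FPKM) used when recording ground truth.
#' @param seed Master seed; all table streams derive from it.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_genes = 345, n_diseases = 406, n_tissues = 32,
                         mean_indications = 1305 / 345, concentration = 10,
                         background_meanlog = -1, background_sdlog = 2.5,
                         boost = 20, confirmable_fraction = 0.8,
                         protein_dropout = 0.3, supportive_fraction = 1,
                         n_replicates = 3, cutoff = 1, seed = 1) {
  cfg <- list(n_genes = n_genes, n_diseases = n_diseases,
              n_tissues = n_tissues, mean_indications = mean_indications,
              concentration = concentration,
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog, boost = boost,
              confirmable_fraction = confirmable_fraction,
              protein_dropout = protein_dropout,
              supportive_fraction = supportive_fraction,
              n_replicates = n_replicates, cutoff = cutoff, seed = seed)
  if (n_tissues < 3) {
    stop("targetissue config error: a world needs at least 3 tissues",
         call. = FALSE)
  }
  if (n_genes < 1 || n_diseases < 1 || n_replicates < 1) {
    stop("targetissue config error: non-positive world dimension",
         call. = FALSE)
  }
  probs <- c(confirmable_fraction, protein_dropout, supportive_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("targetissue config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (concentration < 1 || boost < 1 || mean_indications < 1) {
    stop("targetissue config error: concentration, boost and ",
         "mean_indications must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

world_tissues <- function(n) {
  if (n <= length(.TISSUE_PANEL)) {
    .TISSUE_PANEL[seq_len(n)]
  } else {
    c(.TISSUE_PANEL, sprintf("tissue%03d", seq_len(n - length(.TISSUE_PANEL))))
  }
}

#' Generate a synthetic study world with planted ground truth
#'
#' Draws all five pipeline inputs from the model described in
#' [world_config()]:
#' joint literature counts are multinomial per disease with
#' `concentration`-fold mass on the planted tissue; FPKM is log-normal
#' background times a `boost` at the planted tissues of confirmable pairs;
#' ordinal protein calls come from per-gene expression quartiles
#' (Absent/Low/Medium/High by quartile bin) and are then degraded by
#' `protein_dropout`; the secondary panel replicates the primary values with
#' sampling noise, expands the first panel tissue into three regions, and
#' withholds two tissues (one with a proxy, one without).
#'
#' The ground truth records, per pair, whether the *realized* FPKM at the
#' planted tissue exceeds the detection cutoff (`truly_confirmable`) and
#' the evidence category the pair would earn if its disease were assigned
#' exactly its planted tissue (`expected_category`).
#'
#' @param config A [world_config()].
#' @return List of class `world`: `pairs`, `cooccurrence`, `expression`,
#'   `protein`, `replicates` (a `replicate_expression`), `proxy_map`,
#'   `multi_region`, `truth`, `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  seed <- config$seed
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  diseases <- sprintf("disease%04d", seq_len(config$n_diseases))
  tissues <- world_tissues(config$n_tissues)

  truth_draws <- with_stream(seed, "truth", {
    list(
      planted = setNames(sample(tissues, config$n_diseases, replace = TRUE),
                         diseases),
      disease_class = setNames(
        sample(.DISEASE_CLASSES, config$n_diseases, replace = TRUE),
        diseases)
    )
  })
  planted <- truth_draws$planted
  disease_class <- truth_draws$disease_class

  pairs <- with_stream(seed, "pairs", {
    target_class <- setNames(
      sample(.TARGET_CLASSES, config$n_genes, replace = TRUE), genes)
    n_ind <- pmin(rgeom(config$n_genes, 1 / config$mean_indications) + 1L,
                  config$n_diseases)
    rows <- lapply(seq_along(genes), function(i) {
      ds <- sample(diseases, n_ind[i])
      tibble::tibble(gene = genes[i], disease = ds,
                     disease_class = unname(disease_class[ds]),
                     target_class = unname(target_class[genes[i]]))
    })
    tbl <- dplyr::bind_rows(rows)
    tbl$boosted <- runif(nrow(tbl)) < config$confirmable_fraction
    tbl
  })

  cooc <- with_stream(seed, "cooccurrence", {
    r <- config$concentration
    joint <- matrix(0, config$n_diseases, config$n_tissues,
                    dimnames = list(diseases, tissues))
    totals <- 50 + rpois(config$n_diseases, 150)
    for (i in seq_len(config$n_diseases)) {
      w <- rep(1, config$n_tissues)
      w[match(planted[i], tissues)] <- r
      if (is.infinite(r)) {
        w <- as.numeric(tissues == planted[i])
      }
      joint[i, ] <- rmultinom(1, totals[i], w / sum(w))
    }
    disease_counts <- rowSums(joint) + rpois(config$n_diseases, 100)
    tissue_counts <- colSums(joint) + rpois(config$n_tissues, 500)
    cooccurrence_table(disease_counts, tissue_counts, joint)
  })

  boost_cell <- matrix(FALSE, config$n_genes, config$n_tissues,
                       dimnames = list(genes, tissues))
  bp <- pairs[pairs$boosted, , drop = FALSE]
  boost_cell[cbind(bp$gene, unname(planted[bp$disease]))] <- TRUE
  expr <- with_stream(seed, "expression", {
    m <- matrix(rlnorm(config$n_genes * config$n_tissues,
                       config$background_meanlog, config$background_sdlog),
                config$n_genes, config$n_tissues,
                dimnames = list(genes, tissues))
    m[boost_cell] <- m[boost_cell] * config$boost
    m
  })

  protein_parts <- with_stream(seed, "protein", {
    reliability <- setNames(
      ifelse(runif(config$n_genes) < config$supportive_fraction,
             "supportive", "uncertain"), genes)
    level <- matrix("Absent", config$n_genes, config$n_tissues,
                    dimnames = list(genes, tissues))
    for (g in genes) {
      q <- quantile(expr[g, ], probs = c(0.25, 0.5, 0.75), names = FALSE)
      bin <- findInterval(expr[g, ], q, left.open = TRUE) + 1L
      level[g, ] <- .PROTEIN_LEVELS[bin]
    }
    u <- matrix(runif(config$n_genes * config$n_tissues),
                config$n_genes, config$n_tissues)
    eligible <- expr > config$cutoff & level %in% c("Medium", "High")
    dim(eligible) <- dim(level)
    dropped <- eligible & u < config$protein_dropout
    level[dropped] <- "Low"
    list(level = level, reliability = reliability)
  })
  protein <- tibble::tibble(
    gene = rep(genes, times = config$n_tissues),
    tissue = rep(tissues, each = config$n_genes),
    level = as.vector(protein_parts$level),
    reliability = unname(protein_parts$reliability[
      rep(genes, times = config$n_tissues)])
  )

  # secondary, replicate-bearing panel: first tissue expands to regions,
  # second is withheld but proxied, third is withheld with no proxy
  multi_t <- tissues[1]
  proxy_t <- tissues[2]
  na_t <- tissues[3]
  regions <- paste0(gsub(" ", "_", multi_t), "_region", 1:3)
  proxy_src <- if (proxy_t == "lymph node") "ebv lymphoblasts"
               else paste0(gsub(" ", "_", proxy_t), "_proxy")
  sec_tissues <- c(setdiff(tissues, c(multi_t, proxy_t, na_t)),
                   regions, proxy_src)
  sec_base <- c(setdiff(tissues, c(multi_t, proxy_t, na_t)),
                rep(multi_t, 3), proxy_t)
  replicates <- with_stream(seed, "replicates", {
    n_rep <- config$n_replicates
    sample_ids <- paste0("s", rep(seq_along(sec_tissues), each = n_rep),
                         "_", rep(seq_len(n_rep), length(sec_tissues)))
    sample_tissue <- setNames(rep(sec_tissues, each = n_rep), sample_ids)
    base <- expr[, sec_base, drop = FALSE]
    # per-secondary-tissue systematic shift plus per-sample noise
    shift <- matrix(exp(rnorm(config$n_genes * length(sec_tissues), 0, 0.3)),
                    config$n_genes)
    vals <- matrix(NA_real_, config$n_genes, length(sample_ids),
                   dimnames = list(genes, sample_ids))
    for (j in seq_along(sec_tissues)) {
      lvl <- base[, j] * shift[, j]
      for (k in seq_len(n_rep)) {
        vals[, (j - 1) * n_rep + k] <-
          lvl * exp(rnorm(config$n_genes, 0, 0.2))
      }
    }
    structure(list(values = vals, sample_tissue = sample_tissue),
              class = "replicate_expression")
  })
  proxy_map <- setNames(c(proxy_src, NA_character_), c(proxy_t, na_t))
  multi_region <- setNames(list(regions), multi_t)

  # realized ground truth at the planted tissue
  pt <- unname(planted[pairs$disease])
  fpkm_at_planted <- expr[cbind(pairs$gene, pt)]
  mrna_ok <- fpkm_at_planted > config$cutoff
  prot_state <- binarize_protein(
    protein_parts$level[cbind(pairs$gene, pt)],
    protein_parts$reliability[pairs$gene])
  prot_ok <- prot_state == "Expressed"
  truth_pairs <- tibble::tibble(
    gene = pairs$gene, disease = pairs$disease, planted_tissue = pt,
    boosted = pairs$boosted, fpkm_at_planted = fpkm_at_planted,
    truly_confirmable = mrna_ok,
    expected_category = ifelse(mrna_ok & prot_ok, "both",
                        ifelse(mrna_ok, "mrna_only",
                        ifelse(prot_ok, "protein_only", "unconfirmed")))
  )
  # per-gene specificity class implied by the realized matrix (recorded by
  # the generator with the same five-fold / floor rule the classifier uses)
  other_mean <- (rowSums(expr) - expr) / (config$n_tissues - 1)
  enriched <- expr > config$cutoff & expr >= 5 * other_mean
  n_enr <- rowSums(enriched)
  gene_class <- ifelse(rowSums(expr > config$cutoff) == 0, "undetected",
                ifelse(n_enr == 1, "single_tissue_enriched",
                ifelse(n_enr >= 2 & n_enr <= 7, "group_enriched",
                       "not_enriched")))
  truth <- list(disease_tissue = planted,
                pairs = truth_pairs,
                gene_class = setNames(unname(gene_class), genes))

  structure(list(pairs = pairs[, c("gene", "disease", "disease_class",
                                   "target_class")],
                 cooccurrence = cooc, expression = expr, protein = protein,
                 replicates = replicates, proxy_map = proxy_map,
                 multi_region = multi_region, truth = truth,
                 config = config),
            class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat("<world> ", x$config$n_genes, " genes, ", x$config$n_diseases,
      " diseases, ", x$config$n_tissues, " tissues; ",
      nrow(x$pairs), " gene-disease pairs (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write all world inputs as TSV files
#'
#' Serializes the generated inputs in the dialects the readers expect
#' (`pairs.tsv`, `cooccurrence_joint.tsv`, `marginals.tsv`,
#' `expression.tsv`, `protein.tsv`, `replicates.tsv` + `samples.tsv`,
#' `proxy_map.tsv`) plus the planted truth (`truth.tsv`).
#'
#' @param world A `world` from [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(world$pairs, p("pairs.tsv"), progress = FALSE)
  joint <- tibble::as_tibble(as.table(world$cooccurrence$joint),
                             .name_repair = "minimal")
  names(joint) <- c("disease", "tissue", "count")
  readr::write_tsv(joint[joint$count > 0, ], p("cooccurrence_joint.tsv"),
                   progress = FALSE)
  marg <- dplyr::bind_rows(
    tibble::tibble(term = names(world$cooccurrence$disease_counts),
                   kind = "disease",
                   count = unname(world$cooccurrence$disease_counts)),
    tibble::tibble(term = names(world$cooccurrence$tissue_counts),
                   kind = "tissue",
                   count = unname(world$cooccurrence$tissue_counts)))
  readr::write_tsv(marg, p("marginals.tsv"), progress = FALSE)
  write_expression(world$expression, p("expression.tsv"))
  readr::write_tsv(world$protein, p("protein.tsv"), progress = FALSE)
  write_expression(world$replicates$values, p("replicates.tsv"))
  readr::write_tsv(
    tibble::tibble(sample = names(world$replicates$sample_tissue),
                   tissue = unname(world$replicates$sample_tissue)),
    p("samples.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(tissue = names(world$proxy_map),
                   proxy = unname(world$proxy_map)),
    p("proxy_map.tsv"), progress = FALSE)
  readr::write_tsv(world$truth$pairs, p("truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Recovery metrics of a pipeline run against the planted truth
#'
#' @param world A `world` from [generate_world()].
#' @param mas A `mas_matrix` computed from the world's co-occurrence table.
#' @param records Confirmation records from [confirm_pairs()] on the world's
#'   inputs (optional).
#' @param specificity Output of [classify_specificity()] on the world's
#'   expression matrix (optional).
#' @return List with `planted_recovery` (fraction of diseases whose
#'   argmax-MAS tissue is the planted one), `confirmable_accuracy`
#'   (agreement of `mrna_detected` with the realized truth),
#'   `category_accuracy`, and `specificity_confusion` (class table), the
#'   latter three `NULL` when their inputs are not supplied.
#' @export
world_report <- function(world, mas, records = NULL, specificity = NULL) {
  truth <- world$truth
  top <- colnames(mas$mas)[max.col(mas$mas, ties.method = "first")]
  names(top) <- rownames(mas$mas)
  assessable <- setdiff(names(truth$disease_tissue), mas$unassociable)
  planted_recovery <- mean(top[assessable] ==
                             truth$disease_tissue[assessable])
  out <- list(planted_recovery = planted_recovery,
              confirmable_accuracy = NULL, category_accuracy = NULL,
              specificity_confusion = NULL)
  if (!is.null(records)) {
    key <- function(d) paste(d$gene, d$disease, sep = "\r")
    i <- match(key(records), key(truth$pairs))
    ok <- !is.na(i) & !records$excluded
    out$confirmable_accuracy <-
      mean(records$mrna_detected[ok] == truth$pairs$truly_confirmable[i[ok]])
    out$category_accuracy <-
      mean(records$category[ok] == truth$pairs$expected_category[i[ok]])
  }
  if (!is.null(specificity)) {
    out$specificity_confusion <-
      table(truth = truth$gene_class[specificity$gene],
            called = specificity$class)
  }
  out
}
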