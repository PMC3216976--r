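#' Pairwise squared correlations of group-mean methylation
#'
#' Squared Pearson correlation of per-probe group-mean beta vectors for
#' every pair of gestational groups (pairwise-complete). Optionally also
#' correlates each group against an external methylation profile (for
#' example a purified cell population).
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param external Optional named numeric vector of per-probe beta from
#'   an external profile (names = probe ids).
#' @return Data frame with columns `profile1`, `profile2`, `r2`, `n`.
#' @export
group_correlations <- function(beta, metadata, external = NULL) {
  gm <- group_mean_beta(beta, metadata)
  if (ncol(gm) < 2L) stop("need at least two groups")
  profiles <- as.data.frame(gm)
  if (!is.null(external)) {
    profiles$external <- as.numeric(external[rownames(beta)])
  }
  nm <- names(profiles)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    x <- profiles[[i]]; y <- profiles[[j]]
    ok <- !is.na(x) & !is.na(y)
    r2 <- if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      NA_real_
    } else stats::cor(x[ok], y[ok])^2
    rows[[length(rows) + 1L]] <- data.frame(
      profile1 = nm[i], profile2 = nm[j], r2 = r2, n = sum(ok),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Hierarchical clustering of samples by methylation profile
#'
#' Agglomerative clustering of samples on their beta-value columns.
#' Missing cells are imputed by the probe mean for the distance
#' computation only.
#'
#' @param beta Beta-value matrix.
#' @param distance Distance metric for [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()]. Ward
#'   linkage (`"ward.D2"`, the default) recovers compact sample groups
#'   from centroid separation and is robust to within-group variance
#'   inflation; `"complete"` and the other [stats::hclust()] methods
#'   are available.
#' @return The `hclust` tree with an added `leaf_order` attribute
#'   (sample ids in dendrogram order).
#' @export
hierarchical_cluster <- function(beta, distance = "euclidean",
                                 linkage = "ward.D2") {
  if (ncol(beta) < 2L) stop("clustering needs at least two samples")
  if (anyNA(beta)) {
    pm <- rowMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- pm[idx[, 1]]
  }
  d <- stats::dist(t(beta), method = distance)
  tree <- stats::hclust(d, method = linkage)
  attr(tree, "leaf_order") <- tree$labels[tree$order]
  tree
}

#' Agreement between a tree cut and gestational-age labels
#'
#' Cuts the dendrogram into `k` flat clusters and scores agreement with
#' the gestational-group labels by the adjusted Rand index (1 = perfect
#' recovery of the groups, ~0 for random labels).
#'
#' @param tree An `hclust` tree over samples.
#' @param metadata Sample metadata.
#' @param k Number of flat clusters (default 3).
#' @return List with `ari`, `clusters` (named membership vector) and
#'   the `k` used.
#' @export
cluster_purity <- function(tree, metadata, k = 3L) {
  if (k > length(tree$labels)) stop("k exceeds the sample count")
  cl <- stats::cutree(tree, k = k)
  grp <- metadata$group[match(names(cl), metadata$sample_id)]
  list(ari = mclust::adjustedRandIndex(cl, grp), clusters = cl, k = k)
}

#' Export an hclust tree as Newick text
#'
#' @param tree An `hclust` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(delta_thresholds = c(0.1, 0.2), p_threshold = 0.05,
       detection_alpha = 0.05, detection_policy = "drop_any",
       high_cut = 0.02, low_cut = 0.009, bands = c(0.2, 0.6),
       batch_policy = "logit_group", lfc_cut = 1.0,
       transition_weeks = c(8, 12), cluster_k = 3L, seed = 1L)
}

#' Run the full gestational methylation analysis pipeline
#'
#' Orchestrates preprocessing, global methylation summaries, the three
#' pairwise differential comparisons (plus the week-8-vs-12 transition
#' and the fluctuating-pattern screen), variability analysis with
#' quadrant and Venn partitions, CGI-context enrichment, optional
#' expression integration and validation-table cleaning, and
#' clustering/correlation reporting. Writes per-stage TSV/JSON to
#' `outdir` plus a single run-summary JSON.
#'
#' @param config A list (or YAML file path) with either `dataset` (a
#'   `synthetic_dataset`) or input paths `beta_path`, `annotation_path`,
#'   `metadata_path` (optional `detection_p_path`,
#'   `expression_paths` named first/second/third, `validation_path`),
#'   plus any of the threshold/policy fields of the default config
#'   (delta_thresholds, p_threshold, detection_alpha, detection_policy,
#'   high_cut, low_cut, bands, batch_policy, lfc_cut, transition_weeks,
#'   cluster_k, seed) and `outdir`.
#' @return The run summary (list), invisibly; side effect: files under
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  outdir <- cfg$outdir
  if (is.null(outdir)) stop("config must name an output directory (outdir)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line); cat(line, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(cfg$seed)

  # ---- inputs -------------------------------------------------------
  expression <- NULL; validation <- NULL
  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
    beta <- compute_beta(ds$signals)
    detp <- ds$signals$detection_p
    annotation <- ds$annotation
    metadata <- ds$metadata
    expression <- ds$expression
  } else {
    for (p in c(cfg$beta_path, cfg$annotation_path, cfg$metadata_path,
                cfg$detection_p_path, cfg$validation_path,
                unlist(cfg$expression_paths))) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
    beta <- stage("read", read_beta_matrix(cfg$beta_path))
    detp <- if (!is.null(cfg$detection_p_path)) {
      read_beta_matrix(cfg$detection_p_path)
    }
    annotation <- stage("read", read_annotation(cfg$annotation_path))
    metadata <- stage("read", read_metadata(cfg$metadata_path))
    if (!is.null(cfg$expression_paths)) {
      expression <- lapply(cfg$expression_paths, function(p) {
        read_beta_matrix(p)
      })
    }
    if (!is.null(cfg$validation_path)) {
      validation <- read_beta_matrix(cfg$validation_path)
    }
  }
  if (!is.null(cfg$validation_table)) validation <- cfg$validation_table
  log_msg("input: ", nrow(beta), " probes x ", ncol(beta), " samples")

  # ---- preprocessing ------------------------------------------------
  if (!is.null(detp)) {
    beta <- stage("detection", filter_detection(beta, detp,
      alpha = cfg$detection_alpha, policy = cfg$detection_policy))
    log_msg("detection filter (", cfg$detection_policy, "): ",
            nrow(beta), " probes retained")
  }
  beta <- stage("sex_chromosomes", drop_sex_chromosomes(beta, annotation))
  log_msg("autosomal probes: ", nrow(beta))
  if (cfg$batch_policy == "logit_group" &&
      length(unique(metadata$batch)) > 1L) {
    beta <- stage("batch", correct_batch(beta, metadata))
    log_msg("batch correction applied (logit-scale, group-protected)")
  }
  write_id_matrix(beta, file.path(outdir, "beta_analysable.tsv"))

  # ---- global methylation -------------------------------------------
  mi <- stage("global", methylation_index(beta))
  mi_tests <- compare_mi(mi, metadata)
  bands <- band_proportions(beta, metadata, cfg$bands)
  utils::write.table(
    data.frame(sample_id = names(mi), mi = mi, row.names = NULL),
    file.path(outdir, "methylation_index.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- differential -------------------------------------------------
  comparisons <- list(first_v_second = c("first", "second"),
                      first_v_third = c("first", "third"),
                      second_v_third = c("second", "third"))
  diff_results <- list(); diff_counts <- list()
  for (nm in names(comparisons)) {
    pr <- comparisons[[nm]]
    res <- stage("differential",
                 differential_comparison(beta, metadata, pr[1], pr[2]))
    diff_results[[nm]] <- res
    diff_counts[[nm]] <- lapply(stats::setNames(
      cfg$delta_thresholds, paste0("delta_", cfg$delta_thresholds)),
      function(d) {
        cl <- classify_differential(res, d, cfg$p_threshold)
        list(hyper = cl$n_hyper, hypo = cl$n_hypo)
      })
    utils::write.table(res, file.path(outdir, paste0("differential_", nm,
                                                     ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gm <- group_mean_beta(beta, metadata)
  fluct <- detect_fluctuating(gm[, "first"], gm[, "second"], gm[, "third"],
                              threshold = 0.1)
  transition <- tryCatch(
    transition_comparison(beta, metadata, cfg$transition_weeks),
    error = function(e) { log_msg("transition skipped: ",
                                  conditionMessage(e)); NULL })

  # ---- variability --------------------------------------------------
  s2 <- stage("variability", probe_variance(beta, metadata))
  vcl <- classify_variability(s2, cfg$high_cut, cfg$low_cut)
  high_sets <- lapply(colnames(s2), function(g) {
    rownames(beta)[vcl$class[, g] == "high"]
  })
  names(high_sets) <- colnames(s2)
  quad <- quadrant_partition(s2[, "first"], s2[, "third"], cfg$high_cut)
  venn <- venn_partition(high_sets$first, high_sets$second,
                         high_sets$third)
  chisq_3v1 <- compare_variable_counts(length(high_sets$third),
                                       length(high_sets$first), nrow(beta))
  vlevel <- variance_by_level(beta, metadata, s2, cfg$bands,
                              cfg$high_cut, cfg$low_cut)
  write_id_matrix(s2, file.path(outdir, "probe_variance.tsv"))

  # ---- context ------------------------------------------------------
  bg <- stage("context", background_proportions(annotation, rownames(beta)))
  cl13 <- classify_differential(diff_results$first_v_third,
                                cfg$delta_thresholds[length(cfg$delta_thresholds)],
                                cfg$p_threshold)
  enrich <- list()
  for (nm in c("hyper", "hypo")) {
    if (length(cl13[[nm]]) > 0) {
      enrich[[paste0("differential_", nm)]] <-
        cgi_enrichment(cl13[[nm]], annotation, bg)
    }
  }
  for (nm in c("A", "B", "C")) {
    if (length(quad$sets[[nm]]) > 0) {
      enrich[[paste0("quadrant_", nm)]] <-
        cgi_enrichment(quad$sets[[nm]], annotation, bg)
    }
  }

  # ---- expression integration ---------------------------------------
  expr_summary <- NULL
  if (!is.null(expression)) {
    expr_summary <- list()
    for (g in intersect(colnames(gm), names(expression))) {
      ev <- rowMeans(expression[[g]])
      linked <- merge_by_gene(
        data.frame(probe_id = rownames(beta), beta = gm[, g],
                   stringsAsFactors = FALSE),
        annotation, ev)
      qq <- quartile_by_methylation(stats::setNames(gm[, g], rownames(beta)))
      expr_summary[[g]] <- expression_by_quartile(linked, qq)
    }
    if (all(c("first", "third") %in% names(expression))) {
      lfc <- expression_logfc(expression$first, expression$third)
      conc <- delta_vs_logfc(diff_results$first_v_third, annotation, lfc,
                             delta_cut = cfg$delta_thresholds[
                               length(cfg$delta_thresholds)],
                             lfc_cut = cfg$lfc_cut)
      utils::write.table(conc$scatter,
                         file.path(outdir, "delta_vs_logfc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      expr_summary$concordant_genes <- conc$concordant
    }
  }

  # ---- validation cleaning ------------------------------------------
  validation_report <- NULL
  if (!is.null(validation)) {
    cleaned <- stage("epityper", clean_validation(validation))
    validation_report <- cleaned$report
    if (nrow(cleaned$cleaned)) {
      write_id_matrix(cleaned$cleaned,
                      file.path(outdir, "validation_cleaned.tsv"),
                      id_name = "site_id")
    }
  }

  # ---- clustering & correlations ------------------------------------
  tree <- stage("clustering", hierarchical_cluster(beta))
  purity <- cluster_purity(tree, metadata, cfg$cluster_k)
  correlations <- group_correlations(beta, metadata)
  write_newick(tree, file.path(outdir, "dendrogram.newick"))
  write_id_matrix(beta[, attr(tree, "leaf_order"), drop = FALSE],
                  file.path(outdir, "heatmap_matrix.tsv"))

  summary <- list(
    config = cfg[setdiff(names(cfg), "dataset")],
    n_probes_analysable = nrow(beta),
    n_samples = ncol(beta),
    methylation_index = list(
      per_group_mean = tapply(mi, metadata$group[
        match(names(mi), metadata$sample_id)], mean),
      tests = mi_tests),
    band_proportions = bands,
    differential_counts = diff_counts,
    fluctuating_delta_0.1 = length(fluct),
    transition_8v12 = if (!is.null(transition)) {
      cl <- classify_differential(transition, 0.2, cfg$p_threshold)
      list(hyper_at_12w = cl$n_hyper, hypo_at_12w = cl$n_hypo)
    },
    variability = list(counts = vcl$counts, quadrant = quad$counts,
                       venn = venn, chisq_third_v_first = chisq_3v1,
                       by_level = lapply(vlevel, function(tb) {
                         as.data.frame.matrix(tb) })),
    context = list(background = bg, enrichment = enrich),
    expression = expr_summary,
    validation = validation_report,
    clustering = list(ari = purity$ari, k = purity$k,
                      leaf_order = attr(tree, "leaf_order")),
    correlations = correlations)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_msg("run complete; summary written to ",
          file.path(outdir, "run_summary.json"))
  invisible(summary)
}
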