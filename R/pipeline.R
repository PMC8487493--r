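# Pipeline orchestration: ordination and clustering reports plus the
# end-to-end run over a synthetic or user-supplied dataset.

#' Classical MDS of samples from pairwise log2 differences
#'
#' Sample distances are root-mean-square log2 expression differences over a
#' gene selection: either all provided genes (`"all"`), or, per sample
#' pair, the `top_n` genes with the largest absolute difference
#' (`"pairwise"`). Coordinates are the top-2 eigenvectors of the
#' double-centred squared-distance matrix scaled by the square root of
#' their eigenvalues (Torgerson MDS).
#'
#' @param log2_cpm genes x samples matrix (pre-subset to DE genes for the
#'   "all DE genes" display).
#' @param gene_selection `"all"` or `"pairwise"`.
#' @param top_n number of genes per pair in `"pairwise"` mode.
#' @return samples x 2 coordinate matrix with attribute `eig`.
#' @export
mds_coordinates <- function(log2_cpm, gene_selection = c("all", "pairwise"),
                            top_n = 500L) {
  gene_selection <- match.arg(gene_selection)
  S <- ncol(log2_cpm)
  if (S < 3L) stop("need at least 3 samples")
  d <- matrix(0, S, S, dimnames = list(colnames(log2_cpm),
                                       colnames(log2_cpm)))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    diff <- log2_cpm[, i] - log2_cpm[, j]
    if (gene_selection == "pairwise") {
      keep <- order(-abs(diff))[seq_len(min(top_n, length(diff)))]
      diff <- diff[keep]
    }
    d[i, j] <- d[j, i] <- sqrt(mean(diff^2))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  if (any(fit$eig[1:2] < 0))
    warning("negative leading eigenvalues clipped")
  coords <- fit$points
  colnames(coords) <- c("dim1", "dim2")
  attr(coords, "eig") <- fit$eig
  coords
}

# leaf sets of all internal nodes of an hclust tree, as sorted label vectors
.cluster_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    sets[[i]] <- sort(c(if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]],
                        if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]))
  }
  sets
}

#' Hierarchical clustering of samples with bootstrap support
#'
#' Average-linkage clustering of samples on the correlation dissimilarity
#' (1 - Pearson r over genes), with plain bootstrap support: genes are
#' resampled with replacement `n_boot` times and each original cluster's
#' support is the percentage of bootstrap dendrograms containing exactly
#' that sample set.
#'
#' @param log2_cpm genes x samples matrix (typically subset to the DE genes
#'   of one comparison).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return list with `hclust`, `support` (data.frame: cluster members,
#'   support percentage), `n_boot`.
#' @export
cluster_with_support <- function(log2_cpm, n_boot = 100L, seed = 1L) {
  if (n_boot < 1L) stop("`n_boot` must be >= 1")
  if (ncol(log2_cpm) < 3L) stop("need at least 3 samples")
  dfun <- function(m) stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(dfun(log2_cpm), method = "average")
  ref_sets <- .cluster_leaf_sets(hc)
  keys <- vapply(ref_sets, paste, character(1), collapse = "\r")
  hits <- numeric(length(keys))
  G <- nrow(log2_cpm)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    bs <- log2_cpm[sample.int(G, G, replace = TRUE), , drop = FALSE]
    if (any(apply(bs, 2L, stats::sd) == 0)) next
    bhc <- stats::hclust(dfun(bs), method = "average")
    bkeys <- vapply(.cluster_leaf_sets(bhc), paste, character(1),
                    collapse = "\r")
    hits <- hits + (keys %in% bkeys)
  }
  support <- data.frame(
    cluster = vapply(ref_sets, paste, character(1), collapse = ","),
    n_members = lengths(ref_sets),
    support = 100 * hits / n_boot, stringsAsFactors = FALSE)
  list(hclust = hc, support = support, n_boot = n_boot)
}

#' Run the full analysis pipeline
#'
#' Executes the complete stage order on a dataset: CPM filter, TMM
#' normalization, dispersion estimation, the six DE comparisons, candidate
#' identification and candidate-set DE with random-set calibration,
#' divergence randomization tests, the three DE-count ratio tests, the
#' co-expression network with module-trait correlation and connectivity,
#' and the four synaptic-pathway concentration tests. When no dataset is
#' supplied one is simulated from `sim_config`; the pathway table is then
#' planted so that detected modules dominated by the geography-associated
#' planted module receive a high synaptic fraction.
#'
#' @param dataset optional list with `counts`, `samples`, and optionally
#'   `truth`; defaults to [generate_dataset()] of `sim_config`.
#' @param sim_config simulation configuration used when `dataset` is NULL.
#' @param annotations optional annotation table; simulated when truth is
#'   available and this is NULL.
#' @param pathway_table optional pathway table; planted from the simulation
#'   plan when NULL and truth is available.
#' @param alpha significance threshold (default 0.05).
#' @param n_reps randomization replicates (default 10000).
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param net_config [network_config()] for the co-expression stage.
#' @param out_dir optional directory: writes the summary JSON and stage
#'   TSVs there.
#' @return list of class `pipeline_result` with all stage outputs and a
#'   `summary` list (DE counts, ratio tests, module-trait table, pathway
#'   tests).
#' @export
run_all <- function(dataset = NULL, sim_config = simulation_config(),
                    annotations = NULL, pathway_table = NULL, alpha = 0.05,
                    n_reps = 10000L, seed = 1L,
                    net_config = network_config(), out_dir = NULL) {
  if (is.null(dataset)) {
    sim_config$seed <- .sub_seed(seed, 10L)
    dataset <- generate_dataset(sim_config)
  }
  counts <- dataset$counts
  samples <- .check_samples(counts, dataset$samples)

  norm <- normalize_counts(counts)
  de <- run_comparisons(counts, samples, which = 1:6, alpha = alpha,
                        norm = norm)
  dispersions <- attr(de, "dispersions")

  if (is.null(annotations) && !is.null(dataset$truth))
    annotations <- generate_annotations(dataset$truth,
                                        frac_decoy = sim_config$frac_decoy,
                                        seed = .sub_seed(seed, 11L))
  rules <- default_keyword_rules()
  cand <- if (!is.null(annotations))
    match_candidates(annotations, rules, rownames(norm$counts)) else NULL

  cand_de <- cal <- div <- NULL
  if (!is.null(cand) && length(cand$gene_ids) >= 2L) {
    cand_de <- candidate_de(counts, samples, cand$gene_ids, alpha = alpha,
                            norm = norm, dispersions = dispersions)
    n_obs <- sum(cand_de$geo_all$significant)
    cal <- random_set_calibration(de$geo_all, length(cand$gene_ids), n_obs,
                                  n_reps = n_reps,
                                  seed = .sub_seed(seed, 12L))
    div <- divergence_tests(norm$log2_cpm, cand$gene_ids, samples,
                            n_reps = n_reps, seed = .sub_seed(seed, 13L))
  }

  tables <- build_comparison_tables(de)
  ratio <- lapply(seq_along(tables), function(i)
    ratio_randomization_test(tables[[i]], n_reps = n_reps,
                             seed = .sub_seed(seed, 14L + i)))
  names(ratio) <- names(tables)

  # co-expression network
  top <- select_top_variance(norm$cpm, net_config$top_variance_fraction)
  expr <- norm$log2_cpm[top, , drop = FALSE]
  beta_pick <- if (identical(net_config$beta, "auto"))
    pick_soft_threshold(expr, net_config) else
      list(beta = net_config$beta, fit_table = NULL)
  adj <- adjacency_from_expr(expr, beta_pick$beta, net_config$network_sign)
  tom <- tom_similarity(adj$adjacency)
  partition <- detect_modules(tom, net_config)
  n_modules_before <- length(partition$sizes)
  mt <- eg <- conn <- NULL
  if (length(partition$sizes) > 0) {
    partition <- merge_modules(expr, partition,
                               net_config$merge_dissimilarity)
    eg <- module_eigengenes(expr, partition)
    mt <- module_trait_correlation(eg, samples, alpha = alpha)
    conn <- connectivity_stats(adj$cor, partition, net_config, annotations)
  }

  # pathway table and concentration tests. In synthetic mode the plan
  # plants the study's structure: modules whose eigengene is significantly
  # associated with geography carry a high synaptic-pathway fraction, the
  # rest a low one.
  pw <- NULL
  if (is.null(pathway_table) && !is.null(dataset$truth) && !is.null(mt)) {
    geo_assoc <- unique(mt$module[mt$significant & mt$trait == "geography"])
    plan <- do.call(rbind, lapply(names(partition$sizes), function(m) {
      frac <- if (m %in% geo_assoc) sim_config$pathway_synaptic_frac_assoc
        else sim_config$pathway_synaptic_frac_other
      data.frame(module = m,
                 n_pathways = sim_config$pathway_n_per_module,
                 n_synaptic = round(frac * sim_config$pathway_n_per_module),
                 stringsAsFactors = FALSE)
    }))
    pathway_table <- generate_pathway_table(names(partition$sizes), plan,
                                            seed = .sub_seed(seed, 20L))
  }
  pw_tests <- NULL
  if (!is.null(pathway_table) && !is.null(mt)) {
    pathway_table <- flag_synaptic(pathway_table)
    per_mod <- per_module_concentration_test(pathway_table, n_reps = n_reps,
                                             seed = .sub_seed(seed, 21L))
    sig_mods <- unique(mt$module[mt$significant])
    geo_mods <- unique(mt$module[mt$significant & mt$trait == "geography"])
    overall <- if (length(sig_mods))
      overall_concentration_test(pathway_table, sig_mods, n_reps,
                                 .sub_seed(seed, 22L)) else NULL
    mean_sig <- if (length(sig_mods) &&
                    length(sig_mods) < length(unique(pathway_table$module)))
      mean_per_significant_test(pathway_table, sig_mods, n_reps,
                                .sub_seed(seed, 23L)) else NULL
    geo_ratio <- if (length(geo_mods) &&
                     length(geo_mods) < length(unique(pathway_table$module)))
      geo_ratio_test(pathway_table, geo_mods, n_reps,
                     .sub_seed(seed, 24L)) else NULL
    pw_tests <- list(per_module = per_mod, overall = overall,
                     mean_per_significant = mean_sig, geo_ratio = geo_ratio)
    pw <- pathway_table
  }

  de_counts <- vapply(de, function(d) sum(d$significant), numeric(1))
  summary <- list(
    n_genes_tested = nrow(norm$counts),
    de_counts = as.list(de_counts),
    ratio_tests = lapply(ratio, function(r)
      list(observed = r$observed, p = r$p, n_reps = r$n_reps)),
    n_modules = length(partition$sizes),
    n_modules_before_merge = n_modules_before,
    beta = beta_pick$beta,
    module_trait = if (!is.null(mt)) as.data.frame(mt) else NULL,
    pathway_geo_ratio = if (!is.null(pw_tests$geo_ratio))
      list(observed = pw_tests$geo_ratio$observed,
           p = pw_tests$geo_ratio$p) else NULL,
    seed = seed, alpha = alpha, n_reps = n_reps)
  # internal consistency: summary counts equal column sums of the flags
  stopifnot(identical(unname(de_counts),
                      unname(vapply(de, function(d) sum(d$significant),
                                    numeric(1)))))

  res <- structure(list(dataset = dataset, norm = norm, dispersions =
                          dispersions, de = de, candidates = cand,
                        candidate_de = cand_de, calibration = cal,
                        divergence = div, ratio_tables = tables,
                        ratio_tests = ratio, network = list(
                          top_genes = top, beta = beta_pick,
                          adjacency = NULL, partition = partition,
                          eigengenes = eg, module_trait = mt,
                          connectivity = conn),
                        pathway_table = pw, pathway_tests = pw_tests,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    for (nm in names(de))
      utils::write.table(de[[nm]], file.path(out_dir,
                                             paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run (seed ", s$seed, "): ", s$n_genes_tested,
      " genes tested\n", sep = "")
  cat("DE counts:", paste(names(s$de_counts), unlist(s$de_counts),
                          sep = "=", collapse = ", "), "\n")
  for (nm in names(s$ratio_tests))
    cat(sprintf("ratio %s: %.4f (p = %.4g)\n", nm,
                s$ratio_tests[[nm]]$observed, s$ratio_tests[[nm]]$p))
  cat("modules:", s$n_modules, "(", s$n_modules_before_merge,
      "before merging), beta =", s$beta, "\n")
  invisible(x)
}
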