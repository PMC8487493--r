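# Weighted gene co-expression network analysis: variance filtering, soft
# threshold selection by scale-free topology fit, topological overlap,
# module detection by average-linkage clustering with a recursive tree cut,
# eigengene computation and merging, module-trait correlation, and
# connectivity statistics on the thresholded correlation graph.

#' Select the most variable genes
#'
#' Ranks genes by CPM variance across samples and keeps the top fraction
#' (ceiling), breaking ties by gene ID for determinism.
#'
#' @param cpm genes x samples CPM matrix (see [log_cpm()]).
#' @param fraction fraction of genes to keep, in (0, 1] (default 0.10).
#' @return character vector of kept gene IDs, in original matrix order.
#' @export
select_top_variance <- function(cpm, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  v <- apply(cpm, 1L, stats::var)
  n_keep <- ceiling(fraction * nrow(cpm))
  ord <- order(-v, rownames(cpm))
  keep <- rownames(cpm)[sort(ord[seq_len(n_keep)])]
  keep
}

#' Network configuration defaults
#'
#' @param top_variance_fraction fraction of most-variable genes retained.
#' @param beta soft-threshold power (default 6), or `"auto"` to pick the
#'   smallest power whose scale-free fit exceeds the threshold (reliable
#'   from a few hundred network genes upward).
#' @param beta_grid candidate powers for auto selection.
#' @param scale_free_r2_threshold minimum scale-free fit R^2.
#' @param network_sign `"unsigned"` (|r|^beta) or `"signed"`
#'   (((1 + r)/2)^beta).
#' @param min_module_size minimum genes per module (default 40).
#' @param cut_height static dendrogram cut height (default 0.99).
#' @param deep_split number of nested branch re-splitting levels, 0
#'   (static cut only) to 4 (aggressive), default 3.
#' @param merge_dissimilarity eigengene dissimilarity below which modules
#'   merge (default 0.3).
#' @param edge_filter_r minimum |r| for graph edges (default 0.05).
#' @param report_thresholds extra |r| thresholds for connection counts.
#' @return list of class `network_config`.
#' @export
network_config <- function(top_variance_fraction = 0.10, beta = 6,
                           beta_grid = 1:20, scale_free_r2_threshold = 0.9,
                           network_sign = c("unsigned", "signed"),
                           min_module_size = 40, cut_height = 0.99,
                           deep_split = 3, merge_dissimilarity = 0.3,
                           edge_filter_r = 0.05,
                           report_thresholds = c(0.1, 0.3)) {
  stopifnot(cut_height > 0, cut_height <= 1, merge_dissimilarity > 0,
            min_module_size >= 1, deep_split %in% 0:4)
  structure(list(top_variance_fraction = top_variance_fraction, beta = beta,
                 beta_grid = beta_grid,
                 scale_free_r2_threshold = scale_free_r2_threshold,
                 network_sign = match.arg(network_sign),
                 min_module_size = min_module_size, cut_height = cut_height,
                 deep_split = deep_split,
                 merge_dissimilarity = merge_dissimilarity,
                 edge_filter_r = edge_filter_r,
                 report_thresholds = report_thresholds),
            class = "network_config")
}

#' Soft-threshold adjacency from expression
#'
#' @param expr genes x samples expression matrix (log2 CPM by default
#'   upstream).
#' @param beta soft-threshold power.
#' @param network_sign `"unsigned"` or `"signed"`.
#' @return list with `adjacency` (genes x genes, zero diagonal) and `cor`
#'   (the Pearson correlation matrix).
#' @export
adjacency_from_expr <- function(expr, beta,
                                network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  r <- stats::cor(t(expr))
  a <- if (network_sign == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 0
  list(adjacency = a, cor = r)
}

# Scale-free topology fit: bin connectivities, regress log10 frequency on
# log10 mean connectivity; the fit index is R^2 when the slope is negative
# and -R^2 otherwise.
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 3L) return(c(fit = NA, slope = NA))
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mids <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(c(fit = NA, slope = NA))
  x <- log10(mids[ok]); y <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  c(fit = if (slope < 0) r2 else -r2, slope = unname(slope))
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes the adjacency, the per-gene
#' connectivity distribution, and the scale-free fit index (signed R^2 of
#' the log-log degree-frequency regression). Returns the smallest power
#' whose fit exceeds the threshold; if none qualifies, the power with the
#' best fit is returned with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param config a [network_config()].
#' @return list with `beta` and `fit_table` (data.frame: beta, fit, slope,
#'   mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(expr, config = network_config()) {
  if (length(config$beta_grid) == 0L) stop("empty beta grid")
  if (nrow(expr) < 3L) stop("need at least 3 genes")
  r <- stats::cor(t(expr))
  diag(r) <- 0
  base <- if (config$network_sign == "unsigned") abs(r) else (1 + r) / 2
  rows <- lapply(config$beta_grid, function(b) {
    k <- rowSums(base^b)
    sf <- .scale_free_fit(k)
    data.frame(beta = b, fit = sf[["fit"]], slope = sf[["slope"]],
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$fit) & tab$fit >= config$scale_free_r2_threshold)
  if (length(ok)) {
    beta <- tab$beta[ok[1]]
  } else {
    beta <- tab$beta[which.max(tab$fit)]
    warning("no power reached the scale-free fit threshold; using beta = ",
            beta, " (best fit ", signif(max(tab$fit, na.rm = TRUE), 3), ")")
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Converts a soft adjacency into topological overlap:
#' \deqn{\omega_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' for i != j, with unit diagonal. Overlap is high when two genes are
#' strongly connected and share neighbors.
#'
#' @param adjacency symmetric genes x genes matrix, zero diagonal, entries
#'   in [0, 1].
#' @return the TOM, same dimensions, entries in [0, 1], diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Recursive tree cut on an hclust object. Returns integer cluster labels
# (0 = unassigned). A static cut at cut_height defines coarse branches.
# Inside each branch the cut height that maximizes the number of valid
# subclusters (size >= min_size) is searched over the branch's own merge
# heights, preferring the highest such cut; valid subclusters are split
# again up to deep_split nested levels. Average-linkage TOM dissimilarities
# concentrate near 1, so fixed height-gap rules cannot separate real
# branch boundaries from chaining noise; maximizing the count of
# minimum-size subclusters is scale-free in the heights. Over-eager splits
# of homogeneous branches are undone later by the eigengene merge step.
.cutree_tree <- function(hc, cut_height, min_size, deep_split) {
  n <- length(hc$order)
  nm <- nrow(hc$merge)
  cut_cluster <- function(members, depth) {
    if (depth < 1L || length(members) < 2L * min_size)
      return(list(members))
    inmem <- rep(FALSE, n)
    inmem[members] <- TRUE
    # merges lying entirely inside this cluster (dynamic programme)
    node_in <- logical(nm)
    for (i in seq_len(nm)) {
      m <- hc$merge[i, ]
      node_in[i] <- (if (m[1] < 0) inmem[-m[1]] else node_in[m[1]]) &&
        (if (m[2] < 0) inmem[-m[2]] else node_in[m[2]])
    }
    hs <- sort(unique(hc$height[node_in]), decreasing = TRUE)
    if (length(hs) < 2L) return(list(members))
    best_count <- 1L
    best_labels <- NULL
    for (h in hs[-1]) {  # cutting at the top height keeps one cluster
      lab <- stats::cutree(hc, h = h)[members]
      count <- sum(table(lab) >= min_size)
      if (count > best_count) {  # ties resolved to the highest cut
        best_count <- count
        best_labels <- lab
      }
    }
    if (is.null(best_labels)) return(list(members))
    out <- list()
    for (g in unique(best_labels)) {
      sub <- members[best_labels == g]
      if (length(sub) >= min_size)
        out <- c(out, cut_cluster(sub, depth - 1L))
      else out <- c(out, list(sub))
    }
    out
  }
  static <- stats::cutree(hc, h = cut_height)
  labels <- integer(n)
  nxt <- 1L
  for (cl in unique(static)) {
    members <- which(static == cl)
    if (length(members) < min_size) next
    for (g in cut_cluster(members, max(deep_split, 0L))) {
      if (length(g) >= min_size) {
        labels[g] <- nxt
        nxt <- nxt + 1L
      }
    }
  }
  labels
}

# WGCNA-style color names used to label modules in decreasing size order.
.module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2")
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - overlap) followed by a recursive tree cut: a static cut at
#' `cut_height` defines branches; within each branch the cut height that
#' yields the most subclusters of at least `min_module_size` genes is
#' searched (preferring the highest such cut), and valid subclusters are
#' re-split up to `deep_split` nested levels. Genes in branches smaller
#' than the minimum size are left unassigned ("grey"). Modules are named
#' by conventional colors in decreasing size order.
#'
#' @param tom topological overlap matrix (see [tom_similarity()]).
#' @param config a [network_config()].
#' @return object of class `module_partition`: list with `labels` (named
#'   character vector gene -> module color, "grey" = unassigned), `sizes`,
#'   `dendrogram` (the `hclust`), `merge_history` (filled by
#'   [merge_modules()]).
#' @export
detect_modules <- function(tom, config = network_config()) {
  genes <- rownames(tom)
  if (nrow(tom) < config$min_module_size) {
    warning("fewer genes than `min_module_size`: all genes left grey")
    labels <- stats::setNames(rep("grey", nrow(tom)), genes)
    return(structure(list(labels = labels,
                          sizes = table(labels), dendrogram = NULL,
                          merge_history = NULL),
                     class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- .cutree_tree(hc, config$cut_height, config$min_module_size,
                      config$deep_split)
  labels <- rep("grey", length(raw))
  if (any(raw > 0)) {
    sz <- sort(table(raw[raw > 0]), decreasing = TRUE)
    cols <- .module_colors()
    map <- stats::setNames(cols[seq_along(sz)], names(sz))
    labels[raw > 0] <- map[as.character(raw[raw > 0])]
  }
  labels <- stats::setNames(labels, genes)
  structure(list(labels = labels,
                 sizes = sort(table(labels[labels != "grey"]),
                              decreasing = TRUE),
                 dendrogram = hc, merge_history = NULL),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", length(x$sizes), "modules,",
      sum(x$labels == "grey"), "grey genes of", length(x$labels), "\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' (row-standardized) member expression across samples, a unit-norm sample
#' profile oriented so that its correlation with the module-average
#' expression is non-negative. A single-gene module's eigengene is that
#' gene's standardized profile (unit norm).
#'
#' @param expr genes x samples expression matrix covering all module genes.
#' @param partition a `module_partition`.
#' @return samples x modules matrix of class `eigengenes`, with attribute
#'   `var_explained`.
#' @export
module_eigengenes <- function(expr, partition) {
  mods <- names(partition$sizes)
  if (length(mods) == 0L) stop("no non-grey modules")
  S <- ncol(expr)
  E <- matrix(0, S, length(mods), dimnames = list(colnames(expr), mods))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    g <- names(partition$labels)[partition$labels == mods[i]]
    z <- expr[g, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1L, stats::sd)
    z <- z[is.finite(rowSums(z)), , drop = FALSE]
    if (nrow(z) == 1L) {
      v <- as.numeric(z) / sqrt(sum(z^2))
      ve[i] <- 1
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      v <- sv$v[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    E[, i] <- v
  }
  structure(E, var_explained = stats::setNames(ve, mods),
            class = c("eigengenes", "matrix"))
}

#' Merge similar modules by eigengene dissimilarity
#'
#' Iteratively merges groups of modules whose eigengene dissimilarity
#' (1 - Pearson correlation, average linkage) falls below the threshold,
#' recomputing eigengenes after each pass until no pair qualifies. A merged
#' module keeps the name of its largest constituent.
#'
#' @param expr genes x samples expression matrix.
#' @param partition a `module_partition`.
#' @param threshold merge dissimilarity (default 0.3).
#' @return the merged `module_partition` with `merge_history` recorded.
#' @export
merge_modules <- function(expr, partition, threshold = 0.3) {
  history <- list()
  step <- 0L
  repeat {
    mods <- names(partition$sizes)
    if (length(mods) < 2L) break
    E <- module_eigengenes(expr, partition)
    diss <- 1 - stats::cor(unclass(E))
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(hc, h = threshold)
    if (max(table(grp)) == 1L) break
    step <- step + 1L
    labels <- partition$labels
    for (g in unique(grp)) {
      members <- colnames(E)[grp == g]
      if (length(members) < 2L) next
      keep <- members[which.max(partition$sizes[members])]
      history[[length(history) + 1L]] <-
        data.frame(step = step, from = setdiff(members, keep), into = keep,
                   stringsAsFactors = FALSE)
      labels[labels %in% members] <- keep
    }
    partition$labels <- labels
    partition$sizes <- sort(table(labels[labels != "grey"]),
                            decreasing = TRUE)
  }
  partition$merge_history <- if (length(history))
    do.call(rbind, history) else NULL
  partition
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with the binary-coded traits
#' (allopatric = 0 / sympatric = 1; male = 0 / female = 1), p-values from
#' the t distribution with n - 2 degrees of freedom, and Storey q-values
#' over all module x trait tests.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param samples sample table aligned to the eigengene rows.
#' @param alpha significance threshold on q (default 0.05).
#' @param use_bh use BH instead of Storey q-values.
#' @return data.frame of class `module_trait_result`: `module`, `trait`,
#'   `r`, `p`, `q`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, samples, alpha = 0.05,
                                     use_bh = FALSE) {
  samples <- samples[match(rownames(eigengenes), samples$sample_id), ,
                     drop = FALSE]
  traits <- cbind(geography = as.numeric(samples$geography == "sympatric"),
                  sex = as.numeric(samples$sex == "female"))
  n <- nrow(eigengenes)
  out <- do.call(rbind, lapply(colnames(eigengenes), function(m) {
    vapply(colnames(traits), function(tr) {
      e <- eigengenes[, m]
      if (stats::sd(e) < .Machine$double.eps^0.5) return(NA_real_)
      stats::cor(e, traits[, tr])
    }, numeric(1)) -> r
    data.frame(module = m, trait = colnames(traits), r = unname(r),
               stringsAsFactors = FALSE)
  }))
  tstat <- out$r * sqrt((n - 2) / (1 - out$r^2))
  out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out$q <- if (use_bh || sum(!is.na(out$p)) < 2L) bh_fdr(out$p) else
    storey_qvalue(out$p)$qvalue
  out$significant <- !is.na(out$q) & out$q < alpha
  class(out) <- c("module_trait_result", "data.frame")
  out
}

#' Connectivity statistics on the thresholded correlation graph
#'
#' Builds the binary graph whose edges are gene pairs with |r| at or above
#' `edge_filter_r`, then computes per gene: degree, clustering coefficient
#' (realized fraction of possible edges among neighbors) and neighborhood
#' connectivity (mean degree of neighbors); per module averages; counts of
#' genes with at least one edge at each reporting threshold; and hub genes
#' (maximum within-module adjacency sum, plus the highest-degree annotated
#' alternative).
#'
#' @param correlations genes x genes Pearson correlation matrix.
#' @param partition a `module_partition`.
#' @param config a [network_config()].
#' @param annotations optional data.frame (`gene_id`, `terms`) used to pick
#'   the secondary annotated hub.
#' @return list with `per_gene` (gene, module, degree, clustering,
#'   neighborhood_connectivity), `per_module` (averages + hubs),
#'   `threshold_counts`.
#' @export
connectivity_stats <- function(correlations, partition,
                               config = network_config(),
                               annotations = NULL) {
  if (!isSymmetric(unname(correlations), tol = 1e-10))
    stop("correlation matrix must be symmetric")
  A <- (abs(correlations) >= config$edge_filter_r) * 1
  diag(A) <- 0
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  nc <- ifelse(k > 0, as.numeric(A %*% k) / k, 0)
  genes <- rownames(correlations)
  per_gene <- data.frame(gene_id = genes,
                         module = unname(partition$labels[genes]),
                         degree = k, clustering = cc,
                         neighborhood_connectivity = nc,
                         stringsAsFactors = FALSE)
  mods <- names(partition$sizes)
  per_module <- do.call(rbind, lapply(mods, function(m) {
    g <- genes[partition$labels[genes] == m]
    intra <- abs(correlations[g, g, drop = FALSE])
    diag(intra) <- 0
    strength <- rowSums(intra)
    hub <- g[which.max(strength)]
    hub2 <- NA_character_
    if (!is.null(annotations)) {
      ann <- annotations$gene_id[nzchar(annotations$terms)]
      alt <- setdiff(g[order(-per_gene$degree[match(g, genes)])], hub)
      alt <- alt[alt %in% ann]
      if (length(alt)) hub2 <- alt[1]
    }
    data.frame(module = m, n_genes = length(g),
               mean_degree = mean(per_gene$degree[match(g, genes)]),
               mean_clustering = mean(per_gene$clustering[match(g, genes)]),
               mean_neighborhood_connectivity =
                 mean(per_gene$neighborhood_connectivity[match(g, genes)]),
               hub_gene = hub, secondary_hub = hub2,
               stringsAsFactors = FALSE)
  }))
  threshold_counts <- vapply(config$report_thresholds, function(thr) {
    At <- abs(correlations) >= thr
    diag(At) <- FALSE
    sum(rowSums(At) > 0)
  }, numeric(1))
  names(threshold_counts) <- paste0("r_ge_", config$report_thresholds)
  list(per_gene = per_gene, per_module = per_module,
       threshold_counts = threshold_counts)
}

#' Export the thresholded network
#'
#' Writes a node table (gene, module, optional DE flag), an edge table
#' (gene1, gene2, r) for pairs with |r| at or above the filter, and a
#' GraphML file loadable by standard graph tools.
#'
#' @param correlations genes x genes correlation matrix.
#' @param partition a `module_partition`.
#' @param dir output directory.
#' @param edge_filter_r minimum |r| for an edge (default 0.05).
#' @param de_flags optional named logical vector of DE status per gene.
#' @return invisibly, a list with the node and edge data.frames and the
#'   file paths written.
#' @export
export_network <- function(correlations, partition, dir,
                           edge_filter_r = 0.05, de_flags = NULL) {
  genes <- rownames(correlations)
  nodes <- data.frame(gene_id = genes,
                      module = unname(partition$labels[genes]),
                      stringsAsFactors = FALSE)
  if (!is.null(de_flags))
    nodes$de <- as.logical(de_flags[genes])
  idx <- which(abs(correlations) >= edge_filter_r & upper.tri(correlations),
               arr.ind = TRUE)
  edges <- data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                      r = correlations[idx], stringsAsFactors = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  node_path <- file.path(dir, "network_nodes.tsv")
  edge_path <- file.path(dir, "network_edges.tsv")
  gml_path <- file.path(dir, "network.graphml")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(list(nodes = nodes, edges = edges,
                 files = c(node_path, edge_path, gml_path)))
}
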