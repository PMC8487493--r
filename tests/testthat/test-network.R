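# Co-expression network: variance filter, soft threshold, TOM, module
# detection, eigengenes, merging, trait correlation, connectivity, export.

block_expr <- function(blocks, n_samples = 40, load = 0.9, seed = 1,
                       noise_genes = 0) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(blocks)) {
    z <- rnorm(n_samples)
    rows[[b]] <- t(sapply(seq_len(blocks[b]), function(i)
      load * z + sqrt(1 - load^2) * rnorm(n_samples)))
  }
  if (noise_genes > 0)
    rows[[length(rows) + 1]] <- matrix(rnorm(noise_genes * n_samples),
                                       noise_genes, n_samples)
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))),
                      sprintf("s%02d", seq_len(n_samples)))
  attr(x, "truth") <- rep(c(seq_along(blocks),
                            if (noise_genes > 0) 0),
                          c(blocks, if (noise_genes > 0) noise_genes))
  x
}

test_that("top-variance selection is a ceiling rank filter with deterministic ties", {
  m <- quick_counts(200, 5, seed = 31)
  cpm <- t(t(m) / colSums(m)) * 1e6
  expect_setequal(select_top_variance(cpm, 1), rownames(cpm))
  keep <- select_top_variance(cpm, 0.1)
  expect_length(keep, 20)
  v <- apply(cpm, 1, var)
  expect_true(min(v[keep]) >= sort(v, decreasing = TRUE)[21])
  # constant gene never selected below fraction 1
  cpm2 <- rbind(cpm, const = rep(5, 5))
  expect_false("const" %in% select_top_variance(cpm2, 0.5))
  # study scale: ceiling(0.1 * 48254) = 4826 genes kept
  big <- matrix(rnorm(48254 * 2), 48254, 2,
                dimnames = list(paste0("g", 1:48254), c("a", "b")))
  expect_length(select_top_variance(big, 0.10), 4826)
})

test_that("scale-free fit is exact on constructed power-law connectivity and oracle-checked", {
  # connectivity values whose binned log-log frequency line is exact
  k <- rep(c(1, 2, 4, 8), c(64, 32, 16, 8))
  sf <- neurodiverge:::.scale_free_fit(k)
  expect_gt(sf[["fit"]], 1 - 1e-6)
  expect_lt(sf[["slope"]], 0)

  # fit table equals an independent least-squares recomputation
  x <- block_expr(c(30, 20), n_samples = 16, seed = 5, noise_genes = 30)
  cfg <- network_config(beta_grid = c(2, 6, 10))
  pk <- suppressWarnings(pick_soft_threshold(x, cfg))
  r <- cor(t(x)); diag(r) <- 0
  for (i in seq_len(nrow(pk$fit_table))) {
    kk <- rowSums(abs(r)^pk$fit_table$beta[i])
    cuts <- cut(kk, 10)
    freq <- tapply(kk, cuts, length); mids <- tapply(kk, cuts, mean)
    ok <- !is.na(freq)
    fit <- lm(log10(freq[ok] / sum(freq[ok])) ~ log10(mids[ok]))
    r2 <- summary(fit)$r.squared * ifelse(coef(fit)[2] < 0, 1, -1)
    expect_equal(pk$fit_table$fit[i], unname(r2), tolerance = 1e-10)
  }
  expect_error(pick_soft_threshold(x, network_config(beta_grid = integer(0))),
               "empty beta grid")
})

test_that("the smallest power reaching the fit threshold is selected", {
  x <- block_expr(c(30, 20), n_samples = 16, seed = 5, noise_genes = 30)
  cfg <- network_config(beta_grid = 1:12)
  pk <- suppressWarnings(pick_soft_threshold(x, cfg))
  above <- pk$fit_table$beta[!is.na(pk$fit_table$fit) &
                               pk$fit_table$fit >= 0.9]
  if (length(above)) expect_equal(pk$beta, min(above)) else
    expect_equal(pk$beta,
                 pk$fit_table$beta[which.max(pk$fit_table$fit)])
})

test_that("TOM matches closed forms and a brute-force triple loop", {
  # isolated pair with a12 = 1: overlap 1; with a12 = 0: overlap 0
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom_similarity(a)[1, 2], 1)
  expect_equal(tom_similarity(a)[1, 3], 0)

  set.seed(44)
  a8 <- matrix(runif(64, 0, 0.9), 8, 8)
  a8 <- (a8 + t(a8)) / 2; diag(a8) <- 0
  rownames(a8) <- colnames(a8) <- paste0("n", 1:8)
  tom <- tom_similarity(a8)
  k <- rowSums(a8)
  for (i in 1:8) for (j in 1:8) {
    expected <- if (i == j) 1 else {
      s <- 0
      for (u in 1:8) s <- s + a8[i, u] * a8[u, j]
      (s + a8[i, j]) / (min(k[i], k[j]) + 1 - a8[i, j])
    }
    expect_equal(tom[i, j], expected, tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1))

  # monotonicity: increasing one adjacency entry cannot decrease its overlap
  a9 <- a8; a9[2, 5] <- a9[5, 2] <- min(a8[2, 5] + 0.05, 1)
  expect_gte(tom_similarity(a9)[2, 5], tom[2, 5])

  expect_error(tom_similarity(a8 + diag(8)), "diagonal")
  expect_error(tom_similarity(a8 * 3), "\\[0, 1\\]")
})

test_that("planted blocks are recovered exactly and noise stays grey", {
  x <- block_expr(c(50, 50), n_samples = 40, load = 0.9, seed = 3,
                  noise_genes = 20)
  adj <- adjacency_from_expr(x, 6)
  tom <- tom_similarity(adj$adjacency)
  part <- detect_modules(tom, network_config(min_module_size = 40))
  truth <- attr(x, "truth")
  planted <- truth > 0
  expect_length(part$sizes, 2)
  expect_equal(adjusted_rand(truth[planted], part$labels[planted]), 1)

  # min_module_size above the block size leaves everything grey
  part_big <- detect_modules(tom, network_config(min_module_size = 60))
  expect_true(all(part_big$labels[1:100] %in%
                    c("grey", names(part_big$sizes))))
  expect_lte(length(part_big$sizes), 1)

  # pure noise: almost everything grey across seeds
  grey_frac <- sapply(1:8, function(s) {
    xn <- block_expr(integer(0), n_samples = 16, seed = s,
                     noise_genes = 150)
    adjn <- adjacency_from_expr(xn, 6)
    pn <- detect_modules(tom_similarity(adjn$adjacency),
                         network_config(min_module_size = 40))
    mean(pn$labels == "grey")
  })
  expect_gte(mean(grey_frac >= 0.95), 0.9)
})

test_that("eigengenes are unit-norm oriented first principal components", {
  x <- block_expr(c(30), n_samples = 20, load = 0.95, seed = 9)
  part <- structure(list(labels = setNames(rep("blue", 30), rownames(x)),
                         sizes = table(rep("blue", 30))),
                    class = "module_partition")
  eg <- module_eigengenes(x, part)
  expect_equal(sum(eg[, 1]^2), 1, tolerance = 1e-10)
  # oracle: first right singular vector of the standardized matrix
  z <- t(scale(t(x)))
  sv <- svd(z)
  v1 <- sv$v[, 1]
  if (cor(v1, colMeans(z)) < 0) v1 <- -v1
  expect_equal(unname(eg[, 1]), v1, tolerance = 1e-8)
  expect_gte(attr(eg, "var_explained")[["blue"]],
             sv$d[2]^2 / sum(sv$d^2))
  expect_gte(cor(eg[, 1], colMeans(z)), 0)

  # module of identical genes: eigengene proportional to the profile
  xid <- x[rep(1, 5), ]; rownames(xid) <- paste0("dup", 1:5)
  pid <- structure(list(labels = setNames(rep("m", 5), rownames(xid)),
                        sizes = table(rep("m", 5))),
                   class = "module_partition")
  egid <- module_eigengenes(xid, pid)
  prof <- scale(x[1, ])[, 1]
  expect_gt(abs(cor(egid[, 1], prof)), 1 - 1e-10)
})

test_that("redundant modules merge and orthogonal ones do not", {
  x <- block_expr(c(40, 40), n_samples = 30, load = 0.95, seed = 12)
  truth <- attr(x, "truth")
  # artificially split block 1 into two labels: dissimilarity ~ 0
  lab <- c(rep("red", 20), rep("salmon", 20), rep("blue", 40))
  part <- structure(list(labels = setNames(lab, rownames(x)),
                         sizes = sort(table(lab), decreasing = TRUE)),
                    class = "module_partition")
  merged <- merge_modules(x, part, threshold = 0.3)
  expect_length(merged$sizes, 2)           # 3 modules -> 2 after merging
  expect_false(is.null(merged$merge_history))
  expect_equal(length(unique(merged$labels[1:40])), 1)
  expect_equal(length(unique(merged$labels[41:80])), 1)
})

test_that("module-trait correlation flags a separating eigengene and reports NA for constants", {
  samples <- four_group_samples()
  E <- cbind(sep = as.numeric(samples$geography == "sympatric"),
             flat = rep(0.25, 16),
             noise = rnorm(16))
  rownames(E) <- samples$sample_id
  mt <- module_trait_correlation(E, samples, use_bh = TRUE)
  sep_geo <- mt[mt$module == "sep" & mt$trait == "geography", ]
  expect_equal(sep_geo$r, 1, tolerance = 1e-12)
  expect_equal(sep_geo$p, 0)
  expect_true(sep_geo$significant)
  expect_true(all(is.na(mt$r[mt$module == "flat"])))
  expect_equal(nrow(mt), 6)  # modules x two traits
})

test_that("connectivity statistics match igraph on a random graph plus closed forms", {
  # complete graph: C = 1 everywhere, degree n - 1
  n <- 6
  rc <- matrix(0.9, n, n); diag(rc) <- 1
  dimnames(rc) <- list(paste0("g", 1:n), paste0("g", 1:n))
  part <- structure(list(labels = setNames(rep("m1", n), rownames(rc)),
                         sizes = table(rep("m1", n))),
                    class = "module_partition")
  cs <- connectivity_stats(rc, part, network_config(edge_filter_r = 0.5))
  expect_equal(cs$per_gene$degree, rep(n - 1, n))
  expect_equal(cs$per_gene$clustering, rep(1, n))

  # random graph vs igraph
  set.seed(19)
  r12 <- matrix(runif(144, -1, 1), 12, 12)
  r12 <- (r12 + t(r12)) / 2; diag(r12) <- 1
  dimnames(r12) <- list(paste0("g", 1:12), paste0("g", 1:12))
  part12 <- structure(list(labels = setNames(rep("m1", 12), rownames(r12)),
                           sizes = table(rep("m1", 12))),
                      class = "module_partition")
  cfg <- network_config(edge_filter_r = 0.3)
  cs12 <- connectivity_stats(r12, part12, cfg)
  A <- (abs(r12) >= 0.3) * 1; diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(cs12$per_gene$degree, unname(igraph::degree(g)))
  expect_equal(cs12$per_gene$clustering,
               unname(igraph::transitivity(g, type = "local",
                                           isolates = "zero")),
               tolerance = 1e-12)
  knn <- igraph::knn(g)$knn
  knn[is.nan(knn)] <- 0
  expect_equal(cs12$per_gene$neighborhood_connectivity, unname(knn),
               tolerance = 1e-12)
  # hub: maximum intramodular |r| strength
  strength <- rowSums(abs(r12) - diag(12))
  expect_equal(cs12$per_module$hub_gene,
               names(which.max(strength)))
})

test_that("network export round-trips and honours the edge filter", {
  set.seed(23)
  r <- matrix(runif(100, -0.5, 0.5), 10, 10)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("g", 1:10), paste0("g", 1:10))
  part <- structure(list(labels = setNames(rep("m", 10), rownames(r)),
                         sizes = table(rep("m", 10))),
                    class = "module_partition")
  dir <- withr::local_tempdir()
  out <- export_network(r, part, dir, edge_filter_r = 0.2)
  # counting oracle
  expect_equal(nrow(out$edges),
               sum(abs(r[upper.tri(r)]) >= 0.2))
  g <- igraph::read_graph(file.path(dir, "network.graphml"),
                          format = "graphml")
  expect_equal(igraph::ecount(g), nrow(out$edges))
  el <- igraph::as_edgelist(g)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(el[, 1], el[, 2]),
                  key(out$edges$gene1, out$edges$gene2))
  # filter 1.0: empty edge set
  out2 <- export_network(r, part, dir, edge_filter_r = 1.0)
  expect_equal(nrow(out2$edges), 0)
})
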