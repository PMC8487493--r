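# Expression-divergence trees among the four geography x sex groups.
#
# Per gene: expression is standardized across samples (mean 0, sd 1), group
# means computed (one scalar per group), the 4 x 4 Euclidean distance matrix
# formed, and a neighbor-joining tree estimated. Tip branch lengths measure
# each group's contribution to expression divergence; candidate vs
# non-candidate contrasts of mean tip-length differences are tested by
# shuffling the candidate labels across genes.

#' Standardize genes (rows) to mean 0 and sd 1
#'
#' @param x genes x samples numeric matrix.
#' @return matrix of row z-scores. Zero-variance rows are dropped with a
#'   warning; dropped IDs are attached as attribute `dropped`.
#' @export
standardize_genes <- function(x) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  drop <- sd < .Machine$double.eps^0.5
  if (any(drop))
    warning(sum(drop), " constant gene(s) dropped before standardization")
  z <- (x[!drop, , drop = FALSE] - mu[!drop]) / sd[!drop]
  attr(z, "dropped") <- rownames(x)[drop]
  z
}

# Vectorized neighbor joining for many 4-taxon distance matrices at once.
# D: n x 6 matrix of pairwise distances in column order
# (12, 13, 14, 23, 24, 34). Returns n x 5: tip lengths 1..4 and the internal
# branch, negatives clipped to zero (count attached as attribute).
.nj_four <- function(D) {
  n <- nrow(D)
  r1 <- D[, 1] + D[, 2] + D[, 3]
  r2 <- D[, 1] + D[, 4] + D[, 5]
  r3 <- D[, 2] + D[, 4] + D[, 6]
  r4 <- D[, 3] + D[, 5] + D[, 6]
  R <- cbind(r1, r2, r3, r4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  Q <- sapply(seq_len(6), function(p)
    2 * D[, p] - R[, pairs[p, 1]] - R[, pairs[p, 2]])
  if (n == 1L) Q <- matrix(Q, nrow = 1)
  # first join: pair minimizing Q (ties -> first pair in fixed order)
  j <- max.col(-Q, ties.method = "first")
  i1 <- pairs[j, 1]; i2 <- pairs[j, 2]
  dij <- D[cbind(seq_len(n), j)]
  Li <- dij / 2 + (R[cbind(seq_len(n), i1)] - R[cbind(seq_len(n), i2)]) / 4
  Lj <- dij - Li
  # remaining two taxa and their distances to the new node u
  oth <- t(vapply(seq_len(n), function(g) setdiff(1:4, c(i1[g], i2[g])),
                  integer(2)))
  pidx <- function(a, b) {  # column index for unordered pair (a, b)
    lo <- pmin(a, b); hi <- pmax(a, b)
    c(0L, 3L, 5L)[lo] + (hi - lo)
  }
  dk_i <- D[cbind(seq_len(n), pidx(i1, oth[, 1]))]
  dk_j <- D[cbind(seq_len(n), pidx(i2, oth[, 1]))]
  dl_i <- D[cbind(seq_len(n), pidx(i1, oth[, 2]))]
  dl_j <- D[cbind(seq_len(n), pidx(i2, oth[, 2]))]
  dkl  <- D[cbind(seq_len(n), pidx(oth[, 1], oth[, 2]))]
  duk <- (dk_i + dk_j - dij) / 2
  dul <- (dl_i + dl_j - dij) / 2
  Lk <- (duk + dkl - dul) / 2
  Ll <- (dul + dkl - duk) / 2
  Lu <- (duk + dul - dkl) / 2
  out <- matrix(0, n, 5)
  out[cbind(seq_len(n), i1)] <- Li
  out[cbind(seq_len(n), i2)] <- Lj
  out[cbind(seq_len(n), oth[, 1])] <- Lk
  out[cbind(seq_len(n), oth[, 2])] <- Ll
  out[, 5] <- Lu
  clipped <- sum(out < 0)
  out[out < 0] <- 0
  attr(out, "n_clipped") <- clipped
  out
}

#' Expression-divergence tree for one gene or gene set
#'
#' Computes per-group mean standardized expression, the pairwise Euclidean
#' distance matrix between the four groups, and a neighbor-joining tree.
#' For a single gene each group mean is a scalar so distances reduce to
#' absolute differences; for a set of genes the per-gene vectors are used.
#'
#' @param z standardized expression, genes x samples (one row allowed).
#' @param samples sample table; all four groups must be present.
#' @return object of class `divergence_tree`: list with `tip_lengths` (named
#'   AF, AM, SF, SM), `internal_length`, `distances` (the 4 x 4 matrix),
#'   `tree` (an `ape::phylo`), `n_clipped`.
#' @export
gene_divergence_tree <- function(z, samples) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  samples <- samples[match(colnames(z), samples$sample_id), , drop = FALSE]
  groups <- c("AF", "AM", "SF", "SM")
  if (!all(groups %in% samples$group)) stop("all four groups must be present")
  gm <- vapply(groups, function(g)
    rowMeans(z[, samples$group == g, drop = FALSE]), numeric(nrow(z)))
  if (nrow(z) == 1L) gm <- matrix(gm, nrow = 1, dimnames = list(NULL, groups))
  d <- as.matrix(stats::dist(t(gm)))
  D <- matrix(c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4]),
              nrow = 1)
  tl <- .nj_four(D)
  tree <- ape::nj(d)
  tips <- tl[1, 1:4]
  names(tips) <- groups
  structure(list(tip_lengths = tips, internal_length = tl[1, 5],
                 distances = d, tree = tree,
                 n_clipped = attr(tl, "n_clipped")),
            class = "divergence_tree")
}

#' Per-gene NJ tip branch lengths
#'
#' Builds one four-taxon NJ tree per gene from the standardized expression
#' matrix and returns the tip branch lengths (negative lengths clipped to 0).
#'
#' @param z standardized genes x samples matrix.
#' @param samples sample table with all four groups.
#' @return genes x 4 matrix with columns AF, AM, SF, SM; attribute
#'   `n_clipped` counts clipped negative branch lengths.
#' @export
tip_branch_lengths <- function(z, samples) {
  samples <- samples[match(colnames(z), samples$sample_id), , drop = FALSE]
  groups <- c("AF", "AM", "SF", "SM")
  if (!all(groups %in% samples$group)) stop("all four groups must be present")
  gm <- vapply(groups, function(g)
    rowMeans(z[, samples$group == g, drop = FALSE]), numeric(nrow(z)))
  # scalar group means per gene: distance = |difference|
  D <- cbind(abs(gm[, 1] - gm[, 2]), abs(gm[, 1] - gm[, 3]),
             abs(gm[, 1] - gm[, 4]), abs(gm[, 2] - gm[, 3]),
             abs(gm[, 2] - gm[, 4]), abs(gm[, 3] - gm[, 4]))
  tl <- .nj_four(D)
  out <- tl[, 1:4, drop = FALSE]
  dimnames(out) <- list(rownames(z), groups)
  attr(out, "n_clipped") <- attr(tl, "n_clipped")
  out
}

#' Log2 ratio of two tip branch lengths (reporting aid)
#'
#' @param a,b branch lengths. Returns NA where either is zero.
#' @export
log2_tip_ratio <- function(a, b) {
  out <- ifelse(a > 0 & b > 0, log2(a / b), NA_real_)
  if (anyNA(out)) warning("zero branch length(s): log2 ratio set to NA")
  out
}

#' Randomization tests of unequal expression divergence
#'
#' For each of four group pairs and each gene set (candidate,
#' non-candidate), the test statistic is the mean across genes of the tip
#' branch-length difference between the two groups (8 tests); four further
#' tests contrast the candidate and non-candidate differences. The null
#' distribution shuffles the candidate/non-candidate labels across genes
#' (set sizes preserved); p is the proportion of null replicates greater
#' than or equal to the observed statistic (one-sided), optionally with the
#' (r + 1) / (N + 1) estimator. FDR is computed over the 12 tests.
#'
#' @param log2_cpm expression matrix (log2 CPM), genes x samples.
#' @param candidate_ids gene IDs of the candidate set.
#' @param samples sample table with all four groups.
#' @param group_pairs list of length-2 character vectors of group codes; the
#'   statistic is mean(first) - mean(second). Default: SF-AF, SM-AM, SF-SM,
#'   AF-AM.
#' @param n_reps null replicates (default 10000).
#' @param seed RNG seed.
#' @param add_one use the (r + 1)/(N + 1) p-value estimator.
#' @return list with `tests` (data.frame: test, pair, set, statistic, p,
#'   fdr), `tip_lengths` (per-gene matrix), `n_reps`, `seed`.
#' @export
divergence_tests <- function(log2_cpm, candidate_ids, samples,
                             group_pairs = list(c("SF", "AF"), c("SM", "AM"),
                                                c("SF", "SM"), c("AF", "AM")),
                             n_reps = 10000L, seed = 1L, add_one = FALSE) {
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  z <- standardize_genes(log2_cpm)
  tl <- tip_branch_lengths(z, samples)
  is_cand <- rownames(tl) %in% candidate_ids
  n_cand <- sum(is_cand)
  if (n_cand < 2L || nrow(tl) - n_cand < 2L)
    stop("need at least 2 genes in each of the candidate and non-candidate sets")
  # per-gene differences for each pair: genes x pairs
  diffs <- vapply(group_pairs, function(p) tl[, p[1]] - tl[, p[2]],
                  numeric(nrow(tl)))
  obs_c <- colMeans(diffs[is_cand, , drop = FALSE])
  obs_n <- colMeans(diffs[!is_cand, , drop = FALSE])
  obs_d <- obs_c - obs_n
  tot <- colSums(diffs)
  G <- nrow(diffs)
  set.seed(seed)
  null_c <- matrix(0, n_reps, length(group_pairs))
  for (r in seq_len(n_reps)) {
    idx <- sample.int(G, n_cand)
    null_c[r, ] <- colSums(diffs[idx, , drop = FALSE]) / n_cand
  }
  null_n <- sweep(-null_c * n_cand, 2L, tot, "+") / (G - n_cand)
  null_d <- null_c - null_n
  pval <- function(null, obs) {
    # >= with a small tolerance so exact ties are counted despite rounding
    r <- colSums(sweep(null, 2L, obs - 1e-12, ">="))
    if (add_one) (r + 1) / (n_reps + 1) else r / n_reps
  }
  p <- c(pval(null_c, obs_c), pval(null_n, obs_n), pval(null_d, obs_d))
  pair_lab <- vapply(group_pairs, paste, character(1), collapse = "-")
  tests <- data.frame(
    test = c(paste0("candidate_", pair_lab),
             paste0("noncandidate_", pair_lab),
             paste0("cand_minus_noncand_", pair_lab)),
    pair = rep(pair_lab, 3),
    set = rep(c("candidate", "non-candidate", "difference"),
              each = length(group_pairs)),
    statistic = c(obs_c, obs_n, obs_d),
    p = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
  list(tests = tests, tip_lengths = tl, n_reps = n_reps, seed = seed)
}
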