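# Count filtering, TMM normalization and prior-count log-CPM.
#
# The normalization contract mirrors standard bulk RNA-seq practice: genes
# with mean unnormalized CPM below a threshold are dropped, between-sample
# scaling factors come from a doubly trimmed, precision-weighted mean of
# per-gene log fold changes (TMM), and log2 CPM uses a library-size-scaled
# prior count so zeros stay finite.

#' Filter genes by average CPM
#'
#' Removes genes whose mean counts-per-million across all samples (computed
#' from raw library sizes, before any between-sample normalization) falls
#' below `min_mean_cpm`. The boundary is kept: mean CPM exactly equal to the
#' threshold survives.
#'
#' @param counts genes x samples count matrix.
#' @param min_mean_cpm minimum average CPM (default 1).
#' @return the filtered count matrix, row order preserved.
#' @export
filter_low_expression <- function(counts, min_mean_cpm = 1) {
  .check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  cpm <- t(t(counts) / lib) * 1e6
  keep <- rowMeans(cpm) >= min_mean_cpm
  if (!any(keep))
    stop("all genes removed by the CPM filter; lower `min_mean_cpm`")
  counts[keep, , drop = FALSE]
}

# Trimmed mean of M-values between one sample and the reference.
# logratio_trim and abs_trim are the two-sided trim fractions on the M and A
# scales; weights are inverse asymptotic (delta-method) variances of M.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep] / lib_obs
  r <- ref[keep] / lib_ref
  M <- log2(o / r)
  A <- 0.5 * log2(o * r)
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
       (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  if (length(M) == 0L || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * abs_trim) + 1L;      hiA <- n + 1L - loA
  rM <- rank(M); rA <- rank(A)
  use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(use)) return(1)
  f <- 2^(sum(M[use] / w[use]) / sum(1 / w[use]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors. The reference sample is
#' the one whose 75th-percentile count fraction is closest to the mean across
#' samples; per pair, genes with a zero count in either sample are excluded,
#' M-values are trimmed 30% on each side and A-values 5% on each side, and
#' the surviving M-values are averaged with inverse-variance weights. Factors
#' are rescaled to have geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  .check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalized expression: CPM and log2 CPM with a prior count
#'
#' Effective library sizes are raw library sizes times the TMM factor. The
#' prior count is scaled per sample by effective library size (relative to
#' the mean), so a gene with equal relative abundance in two samples has a
#' log ratio of exactly zero:
#' \deqn{log2CPM = \log_2\left(\frac{y + p_s}{L_s + 2 p_s} \cdot 10^6\right)}
#' with \eqn{p_s = prior \cdot L_s / \bar L}.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample TMM factors aligned to columns.
#' @param prior_count prior count (default 2); must be >= 0.
#' @return object of class `norm_expr`: list with `tmm_factor`,
#'   `eff_lib_size`, `cpm`, `log2_cpm`, `kept_gene_ids`, `prior_count`.
#' @export
log_cpm <- function(counts, factors, prior_count = 2) {
  .check_count_matrix(counts)
  if (length(factors) != ncol(counts))
    stop("`factors` must have one value per sample")
  if (!is.null(names(factors)) &&
      !identical(names(factors), colnames(counts)))
    factors <- factors[colnames(counts)]
  if (prior_count < 0) stop("`prior_count` must be non-negative")
  eff <- colSums(counts) * factors
  adj_prior <- prior_count * eff / mean(eff)
  cpm <- t(t(counts) / eff) * 1e6
  l2 <- log2(t((t(counts) + adj_prior) / (eff + 2 * adj_prior)) * 1e6)
  if (prior_count == 0 && any(counts == 0))
    warning("prior_count = 0 with zero counts: -Inf log2 CPM produced")
  structure(list(tmm_factor = factors, eff_lib_size = eff, cpm = cpm,
                 log2_cpm = l2, kept_gene_ids = rownames(counts),
                 prior_count = prior_count),
            class = "norm_expr")
}

#' Filter and normalize in one step
#'
#' Convenience wrapper: CPM filter, TMM factors, then prior-count log2 CPM.
#'
#' @inheritParams filter_low_expression
#' @inheritParams log_cpm
#' @return a `norm_expr` object (see [log_cpm()]); the filtered counts are
#'   attached as element `counts`.
#' @export
normalize_counts <- function(counts, min_mean_cpm = 1, prior_count = 2) {
  kept <- filter_low_expression(counts, min_mean_cpm)
  f <- tmm_factors(kept)
  ne <- log_cpm(kept, f, prior_count)
  ne$counts <- kept
  ne
}

#' @export
print.norm_expr <- function(x, ...) {
  cat("Normalized expression:", length(x$kept_gene_ids), "genes x",
      ncol(x$log2_cpm), "samples\n")
  cat("TMM factors:", paste(sprintf("%.3f", x$tmm_factor), collapse = " "),
      "\n")
  invisible(x)
}
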