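# Negative-binomial GLM with group-mean parametrization.
#
# The design is a one-way layout: each sample belongs to exactly one group
# and the model has one coefficient per group (the average log-count of that
# group), plus per-sample offsets (log effective library sizes). Because the
# design matrix is block diagonal, each coefficient can be fit by a
# one-dimensional Newton iteration, vectorized across genes.

# Core fitter. y: genes x samples; groups: factor per sample; offsets:
# per-sample; phi: per-gene dispersion (scalar recycled). Returns natural-log
# coefficients per group, fitted means, per-gene log-likelihood, Cox-Reid
# weight sums per group (for the adjusted profile likelihood), and
# convergence diagnostics. Convergence: relative log-likelihood change below
# `tol` (or `max_iter` reached, flagged).
.fit_group_means <- function(y, groups, offsets, phi,
                             tol = 1e-8, max_iter = 100L) {
  groups <- droplevels(as.factor(groups))
  G <- nrow(y)
  phi <- rep_len(pmax(phi, 1e-10), G)
  K <- nlevels(groups)
  beta <- matrix(0, G, K, dimnames = list(rownames(y), levels(groups)))
  mu <- matrix(0, G, ncol(y), dimnames = dimnames(y))
  wsum <- matrix(0, G, K)
  iters <- integer(K)
  conv <- rep(TRUE, G)
  for (k in seq_len(K)) {
    idx <- which(groups == levels(groups)[k])
    yk <- y[, idx, drop = FALSE]
    eo <- exp(offsets[idx])
    ys <- rowSums(yk)
    zero <- ys == 0
    b <- ifelse(zero, -30, log(pmax(ys, 1e-8) / sum(eo)))
    ll_old <- rep(-Inf, G)
    for (it in seq_len(max_iter)) {
      muk <- exp(b) %o% eo
      pm <- muk * phi
      score <- ys - rowSums((yk + 1 / phi) * pm / (1 + pm))
      info <- rowSums(muk / (1 + pm))
      step <- ifelse(zero | info < 1e-12, 0, score / pmax(info, 1e-12))
      step <- pmin(pmax(step, -5), 5)
      b <- b + step
      ll <- rowSums(stats::dnbinom(yk, size = 1 / phi,
                                   mu = exp(b) %o% eo, log = TRUE))
      done <- abs(ll - ll_old) < tol * (abs(ll) + 1)
      iters[k] <- it
      if (all(done | zero)) break
      ll_old <- ll
    }
    if (it == max_iter) conv <- conv & (abs(step) < 1e-6)
    muk <- exp(b) %o% eo
    beta[, k] <- b
    mu[, idx] <- muk
    wsum[, k] <- rowSums(muk / (1 + muk * phi))
  }
  ll <- rowSums(stats::dnbinom(y, size = 1 / phi, mu = pmax(mu, 1e-300),
                               log = TRUE))
  # all-zero rows: dnbinom(0, mu = 0) = 1, loglik 0; ensure no NaN leaked
  ll[rowSums(y) == 0] <- 0
  list(coefficients = beta, fitted = mu, loglik = ll,
       cr_wsum = wsum, converged = conv, iterations = max(iters))
}

#' Fit a negative-binomial GLM with one mean per group
#'
#' Log-link NB regression with a group-mean design (one coefficient per
#' group, the average log-count) and per-sample offsets, fit by Newton
#' iteration per group. Genes that fail to converge within `max_iter`
#' iterations are flagged and the last iterate returned with a warning.
#'
#' @param counts genes x samples count matrix (a single gene may be passed as
#'   a one-row matrix).
#' @param groups factor of group membership per sample.
#' @param offsets per-sample offsets, typically log effective library sizes.
#' @param dispersion per-gene NB dispersion (phi >= 0); scalar recycled.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `nb_glm_fit`: list with `coefficients` (natural
#'   log average counts, genes x groups), `fitted` means, `loglik` per gene,
#'   `converged` flags, `dispersion`, `groups`.
#' @export
fit_nb_glm <- function(counts, groups, offsets, dispersion,
                       tol = 1e-8, max_iter = 100L) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  if (length(offsets) != ncol(counts))
    stop("`offsets` must have one value per sample")
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  fit <- .fit_group_means(counts, groups, offsets, dispersion,
                          tol = tol, max_iter = max_iter)
  if (!all(fit$converged))
    warning(sum(!fit$converged), " gene(s) did not converge; ",
            "last iterate returned")
  structure(c(fit, list(dispersion = rep_len(dispersion, nrow(counts)),
                        groups = droplevels(as.factor(groups)))),
            class = "nb_glm_fit")
}

#' Likelihood-ratio contrast between nested NB GLM fits
#'
#' Twice the log-likelihood difference between a full and a nested null fit
#' (same genes, same dispersions), clipped at zero, with a chi-square
#' reference distribution whose degrees of freedom equal the difference in
#' coefficient count.
#'
#' @param fit_full,fit_null `nb_glm_fit` objects on the same genes; the null
#'   model must have fewer groups.
#' @return data.frame with `lrt_stat` and `p_value` per gene.
#' @export
lrt_contrast <- function(fit_full, fit_null) {
  k_full <- ncol(fit_full$coefficients)
  k_null <- ncol(fit_null$coefficients)
  if (k_null >= k_full && !isTRUE(all.equal(fit_full$loglik,
                                            fit_null$loglik)))
    stop("null model must be nested in (have fewer coefficients than) full")
  if (length(fit_full$loglik) != length(fit_null$loglik))
    stop("fits cover different gene sets")
  df <- max(k_full - k_null, 1L)
  stat <- pmax(2 * (fit_full$loglik - fit_null$loglik), 0)
  data.frame(lrt_stat = stat,
             p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
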