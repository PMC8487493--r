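# Multiple-testing corrections: Benjamini-Hochberg FDR and Storey q-values.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, capped at 1 and monotone in p-value rank. NA
#' p-values propagate as NA and are excluded from the ranking.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' q-values with the null proportion pi0 estimated by Storey's smoother: the
#' tail proportions pi0(lambda) = mean(p > lambda) / (1 - lambda) over a
#' lambda grid are smoothed with a cubic spline and the fit at the largest
#' lambda taken as pi0. If the estimate leaves (0, 1] the function falls
#' back to pi0 = 1 (the BH adjustment) with a warning. q-values are
#' pi0 * m * p / rank, made monotone by a cumulative minimum from the
#' largest p downward.
#'
#' @param p numeric vector of p-values (>= 2 values for pi0 estimation).
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional: force a null proportion (pi0 = 1 reproduces
#'   [bh_fdr()] exactly).
#' @return list with `qvalue` (aligned to `p`) and `pi0`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (sum(ok) < 2L) stop("need at least 2 p-values to estimate pi0")
  pv <- p[ok]
  m <- length(pv)
  if (is.null(pi0)) {
    lambda <- lambda[lambda < max(pv)]
    if (length(lambda) < 4L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
      fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
      pi0 <- if (inherits(fit, "try-error")) min(pi0_l) else
        stats::predict(fit, x = max(lambda))$y
    }
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
      warning("pi0 estimate outside (0, 1]; falling back to pi0 = 1")
      pi0 <- 1
    }
  }
  o <- order(pv, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  list(qvalue = out, pi0 = pi0)
}
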