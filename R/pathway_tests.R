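# Synaptic-pathway flagging and module-concentration randomization tests.
#
# A pathway counts as synaptic when its name or ancestor/child term text
# contains "synap" (synaptic transmission) or "neuro"/"neura"
# (neurotransmission), case-insensitively. Four randomization tests ask
# whether synaptic pathways concentrate in particular co-expression modules:
# per module, overall in trait-associated modules, as a mean per significant
# module, and as a geography/non-geography mean ratio.

#' Flag synaptic pathways by keyword
#'
#' @param table data.frame with columns `pathway_id`, `module`, `name_text`,
#'   `ancestor_child_text`.
#' @return the table with a logical `is_synaptic` column added.
#' @export
flag_synaptic <- function(table) {
  txt <- paste(table$name_text, table$ancestor_child_text)
  table$is_synaptic <- grepl("synap|neuro|neura", txt, ignore.case = TRUE)
  table
}

# shared permutation core: permute the pathway -> module assignment (module
# sizes fixed) and return a modules x n_reps matrix of synaptic counts
.null_module_counts <- function(module, synaptic, n_reps) {
  lv <- sort(unique(module))
  P <- length(module)
  fl <- as.integer(synaptic)
  out <- matrix(0L, length(lv), n_reps, dimnames = list(lv, NULL))
  fm <- factor(module, levels = lv)
  for (r in seq_len(n_reps))
    out[, r] <- as.integer(rowsum(fl[sample.int(P)], fm))
  out
}

#' Per-module synaptic-pathway concentration tests
#'
#' For each module the statistic is its number of synaptic pathways. The
#' null shuffles the pathway-to-module assignment, holding the number of
#' pathways per module constant; p is the proportion of null replicates
#' greater than or equal to the observed count, and q-values (Storey) are
#' computed across modules.
#'
#' @param table pathway table with `module` and `is_synaptic` (run
#'   [flag_synaptic()] first if needed).
#' @param n_reps null replicates (default 10000).
#' @param seed RNG seed.
#' @param alpha significance threshold on q (default 0.05).
#' @param use_bh use BH instead of Storey q-values.
#' @return data.frame: `module`, `n_pathways`, `n_synaptic`, `p`, `q`,
#'   `significant`; the null count matrix is attached as attribute `null`.
#' @export
per_module_concentration_test <- function(table, n_reps = 10000L, seed = 1L,
                                          alpha = 0.05, use_bh = FALSE) {
  if (nrow(table) < 1L) stop("pathway table is empty")
  if (is.null(table$is_synaptic)) table <- flag_synaptic(table)
  set.seed(seed)
  null <- .null_module_counts(table$module, table$is_synaptic, n_reps)
  obs <- tapply(table$is_synaptic, factor(table$module,
                                          levels = rownames(null)), sum)
  p <- rowMeans(null >= rep(obs, ncol(null)))
  q <- if (use_bh || length(p) < 2L) bh_fdr(p) else storey_qvalue(p)$qvalue
  out <- data.frame(module = rownames(null),
                    n_pathways = as.integer(table(factor(table$module,
                                                         levels = rownames(null)))),
                    n_synaptic = as.integer(obs), p = as.numeric(p), q = q,
                    significant = q < alpha, stringsAsFactors = FALSE)
  attr(out, "null") <- null
  out
}

#' Overall synaptic concentration in significant modules
#'
#' Statistic: total number of synaptic pathways in the trait-associated
#' (significant) modules; null shuffles the pathway-to-module assignment.
#'
#' @inheritParams per_module_concentration_test
#' @param significant_modules character vector of significant module names.
#' @return a `rand_test` object.
#' @export
overall_concentration_test <- function(table, significant_modules,
                                       n_reps = 10000L, seed = 1L) {
  if (nrow(table) < 1L) stop("pathway table is empty")
  if (length(significant_modules) == 0L)
    stop("significant module set is empty")
  if (is.null(table$is_synaptic)) table <- flag_synaptic(table)
  set.seed(seed)
  null_m <- .null_module_counts(table$module, table$is_synaptic, n_reps)
  sel <- rownames(null_m) %in% significant_modules
  obs <- sum(table$is_synaptic[table$module %in% significant_modules])
  null <- colSums(null_m[sel, , drop = FALSE])
  structure(list(observed = obs, null_samples = null,
                 p = mean(null >= obs), n_reps = n_reps, seed = seed),
            class = "rand_test")
}

#' Mean synaptic pathways per significant module
#'
#' Statistic: the mean synaptic-pathway count over significant modules; the
#' null shuffles the significant/non-significant designation across modules
#' (synaptic counts held fixed).
#'
#' @inheritParams overall_concentration_test
#' @return a `rand_test` object.
#' @export
mean_per_significant_test <- function(table, significant_modules,
                                      n_reps = 10000L, seed = 1L) {
  if (is.null(table$is_synaptic)) table <- flag_synaptic(table)
  counts <- tapply(table$is_synaptic, table$module, sum)
  M <- length(counts)
  sel <- names(counts) %in% significant_modules
  if (!any(sel)) stop("significant module set is empty")
  if (all(sel)) stop("all modules significant: no null variability")
  obs <- mean(counts[sel])
  k <- sum(sel)
  set.seed(seed)
  null <- vapply(seq_len(n_reps),
                 function(r) mean(counts[sample.int(M, k)]), numeric(1))
  structure(list(observed = obs, null_samples = null,
                 p = mean(null >= obs - 1e-12), n_reps = n_reps,
                 seed = seed), class = "rand_test")
}

#' Geography-module synaptic concentration ratio test
#'
#' Statistic: mean synaptic-pathway count in geography-associated modules
#' divided by the mean in the remaining modules; the null shuffles the
#' geography designation across modules.
#'
#' @inheritParams overall_concentration_test
#' @param geo_modules names of the geography-associated modules.
#' @return a `rand_test` object.
#' @export
geo_ratio_test <- function(table, geo_modules, n_reps = 10000L, seed = 1L) {
  if (is.null(table$is_synaptic)) table <- flag_synaptic(table)
  counts <- tapply(table$is_synaptic, table$module, sum)
  M <- length(counts)
  sel <- names(counts) %in% geo_modules
  if (!any(sel) || all(sel))
    stop("need both geography-associated and other modules")
  if (mean(counts[!sel]) == 0)
    stop("non-geography modules contain no synaptic pathways: ",
         "ratio undefined")
  obs <- mean(counts[sel]) / mean(counts[!sel])
  k <- sum(sel)
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(r) {
    i <- sample.int(M, k)
    den <- mean(counts[-i])
    if (den == 0) Inf else mean(counts[i]) / den
  }, numeric(1))
  structure(list(observed = obs, null_samples = null,
                 p = mean(null >= obs - 1e-12), n_reps = n_reps,
                 seed = seed), class = "rand_test")
}
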