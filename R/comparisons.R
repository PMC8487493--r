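# The six differential-expression comparisons of the two-by-two
# geography x sex design, each a two-group NB likelihood-ratio test:
#   1 geo_all        all sympatric vs all allopatric frogs
#   2 sex_all        all female vs all male frogs
#   3 geo_female     sympatric vs allopatric, females only
#   4 geo_male       sympatric vs allopatric, males only
#   5 sex_allopatric female vs male, allopatric frogs only
#   6 sex_sympatric  female vs male, sympatric frogs only
# Sign convention: positive log2 fold change = overexpressed in sympatry
# (geography contrasts) or in females (sex contrasts).

.comparison_defs <- function() {
  list(
    geo_all = list(subset = function(s) rep(TRUE, nrow(s)),
                   factor_of = function(s) s$geography, up = "sympatric"),
    sex_all = list(subset = function(s) rep(TRUE, nrow(s)),
                   factor_of = function(s) s$sex, up = "female"),
    geo_female = list(subset = function(s) s$sex == "female",
                      factor_of = function(s) s$geography, up = "sympatric"),
    geo_male = list(subset = function(s) s$sex == "male",
                    factor_of = function(s) s$geography, up = "sympatric"),
    sex_allopatric = list(subset = function(s) s$geography == "allopatric",
                          factor_of = function(s) s$sex, up = "female"),
    sex_sympatric = list(subset = function(s) s$geography == "sympatric",
                         factor_of = function(s) s$sex, up = "female"))
}

#' Run differential-expression comparisons
#'
#' Filters and TMM-normalizes the counts (unless a `norm_expr` is supplied),
#' estimates tagwise dispersions once on the full four-group design, then for
#' each requested comparison fits a two-group NB GLM and its one-group null
#' on the relevant sample subset, computes the likelihood-ratio test, and
#' applies Benjamini-Hochberg FDR within that comparison.
#'
#' @param counts raw genes x samples count matrix.
#' @param samples sample table (see [sample_table()]).
#' @param which comparisons to run: integers 1-6 or names (`"geo_all"`,
#'   `"sex_all"`, `"geo_female"`, `"geo_male"`, `"sex_allopatric"`,
#'   `"sex_sympatric"`).
#' @param alpha FDR significance threshold (default 0.05).
#' @param gene_subset optional gene IDs: tests and the FDR family are
#'   restricted to this subset (candidate-set mode).
#' @param norm optional precomputed `norm_expr` (with `$counts`).
#' @param dispersions optional precomputed `dispersion_estimates`.
#' @param min_mean_cpm,prior_count,prior_df passed to the preprocessing and
#'   dispersion stages when those are not supplied.
#' @return named list of per-comparison data.frames (class `de_result`) with
#'   columns `gene_id`, `logFC`, `avg_log2_cpm`, `lrt_stat`, `p`, `fdr`,
#'   `significant`. The normalization and dispersion objects are attached as
#'   attributes `norm` and `dispersions`.
#' @export
run_comparisons <- function(counts, samples, which = 1:6, alpha = 0.05,
                            gene_subset = NULL, norm = NULL,
                            dispersions = NULL, min_mean_cpm = 1,
                            prior_count = 2, prior_df = 10) {
  defs <- .comparison_defs()
  if (is.numeric(which)) {
    if (any(which < 1 | which > 6)) stop("comparisons are numbered 1..6")
    which <- names(defs)[which]
  }
  if (!all(which %in% names(defs)))
    stop("unknown comparison(s): ",
         paste(setdiff(which, names(defs)), collapse = ", "))
  samples <- .check_samples(counts, samples)
  if (is.null(norm))
    norm <- normalize_counts(counts, min_mean_cpm = min_mean_cpm,
                             prior_count = prior_count)
  kept <- norm$counts
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(kept, norm, samples$group,
                                        prior_df = prior_df)
  genes <- rownames(kept)
  if (!is.null(gene_subset)) {
    genes <- intersect(genes, gene_subset)
    if (length(genes) == 0L) stop("gene_subset has no expressed genes")
  }
  y_all <- kept[genes, , drop = FALSE]
  phi <- dispersions$tagwise[genes]
  avg <- dispersions$avg_log2_cpm[match(genes, rownames(kept))]
  offsets_all <- log(norm$eff_lib_size)

  out <- lapply(which, function(nm) {
    d <- defs[[nm]]
    sel <- d$subset(samples)
    fac <- droplevels(factor(d$factor_of(samples)[sel]))
    if (nlevels(fac) < 2L)
      stop("comparison ", nm, " references an empty group")
    y <- y_all[, sel, drop = FALSE]
    off <- offsets_all[sel]
    full <- fit_nb_glm(y, fac, off, phi)
    null <- fit_nb_glm(y, factor(rep("all", sum(sel))), off, phi)
    lrt <- lrt_contrast(full, null)
    up <- d$up
    dn <- setdiff(levels(fac), up)
    lfc <- (full$coefficients[, up] - full$coefficients[, dn]) / log(2)
    fdr <- bh_fdr(lrt$p_value)
    data.frame(gene_id = genes, logFC = unname(lfc), avg_log2_cpm = avg,
               lrt_stat = lrt$lrt_stat, p = lrt$p_value, fdr = fdr,
               significant = !is.na(fdr) & fdr < alpha,
               stringsAsFactors = FALSE)
  })
  names(out) <- which
  for (nm in which) class(out[[nm]]) <- c("de_result", "data.frame")
  attr(out, "norm") <- norm
  attr(out, "dispersions") <- dispersions
  out
}

#' Candidate-set differential expression
#'
#' Runs the three comparisons used for candidate synaptic-transmission genes
#' (both sexes combined, females only, males only) with the FDR family
#' restricted to the candidate set.
#'
#' @inheritParams run_comparisons
#' @param candidate_ids gene IDs of the candidate set.
#' @return list of three `de_result` data.frames.
#' @export
candidate_de <- function(counts, samples, candidate_ids, alpha = 0.05,
                         norm = NULL, dispersions = NULL) {
  run_comparisons(counts, samples,
                  which = c("geo_all", "geo_female", "geo_male"),
                  alpha = alpha, gene_subset = candidate_ids,
                  norm = norm, dispersions = dispersions)
}
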