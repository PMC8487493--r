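# Candidate synaptic-transmission gene identification by keyword search over
# free-text annotations, with include/exclude refinements, and calibration of
# observed candidate DE counts against random gene sets.
#
# Categories (protein classes):
#   1 ionotropic receptors
#   2 synaptic vesicle proteins
#   3 proteins that associate with synaptic vesicles
#   4 synaptic plasma membrane proteins
#   5 proteins that reversibly associate with plasma membrane proteins

#' Default keyword rule table
#'
#' A replaceable starter rule set covering the classic synaptic-transmission
#' protein families across the five categories. Matching is case-insensitive
#' substring on `keyword`; `include` (regex, must also match) and `exclude`
#' (regex, must not match) refine broad keywords. Users studying a specific
#' system should supply their own curated table.
#'
#' @return data.frame with columns `keyword`, `category`, `family`,
#'   `include`, `exclude`.
#' @export
default_keyword_rules <- function() {
  r <- function(keyword, category, family, include = "", exclude = "")
    data.frame(keyword = keyword, category = category, family = family,
               include = include, exclude = exclude,
               stringsAsFactors = FALSE)
  rbind(
    # 1: ionotropic receptors
    r("glutamate receptor ionotropic", 1, "ionotropic glutamate receptor"),
    r("nmda receptor", 1, "NMDA receptor"),
    r("ampa", 1, "AMPA receptor", include = "receptor"),
    r("kainate", 1, "kainate receptor"),
    r("gamma-aminobutyric acid receptor", 1, "GABA-A receptor"),
    r("glycine receptor", 1, "glycine receptor"),
    r("acetylcholine receptor", 1, "nicotinic acetylcholine receptor"),
    r("p2x", 1, "P2X purinoceptor"),
    r("5-hydroxytryptamine receptor 3", 1, "5-HT3 receptor"),
    # 2: synaptic vesicle proteins
    r("synaptotagmin", 2, "synaptotagmin"),
    r("synaptophysin", 2, "synaptophysin"),
    r("synaptogyrin", 2, "synaptogyrin"),
    r("synaptobrevin", 2, "synaptobrevin (VAMP)"),
    r("vesicle-associated membrane protein", 2, "synaptobrevin (VAMP)"),
    r("synapsin", 2, "synapsin"),
    r("sv2", 2, "synaptic vesicle glycoprotein 2"),
    r("rab3", 2, "Rab3"),
    r("rab27", 2, "Rab27"),
    r("secretory carrier-associated membrane protein", 2, "SCAMP"),
    r("vesicular glutamate transporter", 2, "vesicular glutamate transporter"),
    r("vesicular gaba transporter", 2, "vesicular GABA transporter"),
    r("vesicular acetylcholine transporter", 2,
      "vesicular acetylcholine transporter"),
    r("gaba transporter", 2, "GABA transporter"),
    r("betaine/gaba transporter", 2, "betaine/GABA transporter"),
    r("zinc transporter", 2, "zinc transporter ZIP/ZnT"),
    # 3: proteins that associate with synaptic vesicles
    r("synapt", 3, "synaptojanin", include = "synaptojanin",
      exclude = "pseudogene"),
    r("rabphilin", 3, "rabphilin"),
    r("amphiphysin", 3, "amphiphysin"),
    r("dynamin", 3, "dynamin"),
    r("clathrin", 3, "clathrin"),
    r("ap-2 complex", 3, "AP-2 adaptor complex"),
    r("endophilin", 3, "endophilin"),
    r("kinesin", 3, "kinesin-associated protein", include = "associated"),
    r("munc-13", 3, "Munc13"),
    r("munc-18", 3, "Munc18"),
    r("n-ethylmaleimide sensitive factor", 3, "NSF"),
    # 4: synaptic plasma membrane proteins
    r("syntaxin", 4, "syntaxin", exclude = "syntaxin-binding"),
    r("snap-25", 4, "SNAP-25"),
    r("neurexin", 4, "neurexin"),
    r("neuroligin", 4, "neuroligin"),
    r("cadherin", 4, "synaptic cadherin"),
    r("voltage-dependent calcium channel", 4,
      "voltage-gated calcium channel"),
    # 5: proteins that reversibly associate with plasma membrane proteins
    r("syntaxin-binding protein", 5, "syntaxin-binding protein (Munc18)"),
    r("complexin", 5, "complexin"),
    r("calcium/calmodulin-dependent protein kinase", 5, "CaMKII"),
    r("disks large homolog", 5, "PSD-95 family (DLG)"))
}

#' Match candidate genes by keyword over annotations
#'
#' A gene matches a rule when any of its annotation strings contains the
#' rule's keyword (case-insensitive substring), also matches the rule's
#' `include` pattern (if non-empty), and matches no `exclude` pattern. The
#' result is intersected with the expressed gene set. A gene may match
#' several rules: all matches are retained and the primary category is the
#' first matching rule in table order.
#'
#' @param annotations data.frame with columns `gene_id` and `terms`
#'   (pipe-separated annotation strings).
#' @param rules keyword rule table (see [default_keyword_rules()]).
#' @param expressed_gene_ids character vector: genes present in the
#'   expression data after filtering.
#' @return object of class `candidate_set`: list with `matches` (gene_id,
#'   family, category, keyword), `gene_ids` (unique matched expressed
#'   genes), `primary` (gene_id, category of first match), and
#'   `category_counts`.
#' @export
match_candidates <- function(annotations, rules, expressed_gene_ids) {
  if (nrow(rules) == 0L) stop("`rules` must be nonempty")
  terms <- strsplit(as.character(annotations$terms), "|", fixed = TRUE)
  gene_of <- rep(annotations$gene_id, lengths(terms))
  str <- unlist(terms, use.names = FALSE)
  hits <- lapply(seq_len(nrow(rules)), function(i) {
    rl <- rules[i, ]
    m <- tryCatch({
      ok <- grepl(rl$keyword, str, ignore.case = TRUE, fixed = FALSE)
      if (nzchar(rl$include))
        ok <- ok & grepl(rl$include, str, ignore.case = TRUE)
      if (nzchar(rl$exclude))
        ok <- ok & !grepl(rl$exclude, str, ignore.case = TRUE)
      ok
    }, error = function(e)
      stop("malformed pattern in rule for family '", rl$family, "': ",
           conditionMessage(e), call. = FALSE))
    if (!any(m)) return(NULL)
    data.frame(gene_id = unique(gene_of[m]), family = rl$family,
               category = rl$category, keyword = rl$keyword,
               rule_order = i, stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, hits)
  if (is.null(matches))
    matches <- data.frame(gene_id = character(), family = character(),
                          category = integer(), keyword = character(),
                          rule_order = integer(), stringsAsFactors = FALSE)
  matches <- matches[matches$gene_id %in% expressed_gene_ids, , drop = FALSE]
  matches <- matches[order(matches$gene_id, matches$rule_order), ,
                     drop = FALSE]
  first <- matches[!duplicated(matches$gene_id), c("gene_id", "category")]
  by_cat <- unique(matches[, c("gene_id", "category")])
  structure(list(matches = matches[, 1:4],
                 gene_ids = unique(matches$gene_id),
                 primary = first,
                 category_counts = table(factor(by_cat$category,
                                                levels = 1:5))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$gene_ids), "expressed genes\n")
  print(x$category_counts)
  invisible(x)
}

#' Calibrate an observed DE count against random gene sets
#'
#' Draws random gene subsets of the candidate-set size from all tested genes
#' and counts how many are significant in each draw, giving the expected
#' number of significant genes for an arbitrary set of that size and an
#' empirical p-value for the observed count (strictly greater, one-sided).
#'
#' @param de_result a `de_result` data.frame (uses its `significant` column),
#'   or a logical vector of significance flags.
#' @param set_size size of the random sets (e.g. the candidate-set size).
#' @param n_observed_sig observed number of significant candidate genes.
#' @param n_reps number of random draws (default 10000).
#' @param seed RNG seed.
#' @return object of class `rand_test`: `observed` (= `n_observed_sig`),
#'   `mean_sig`, `null_samples`, `p`, `n_reps`, `seed`.
#' @export
random_set_calibration <- function(de_result, set_size, n_observed_sig,
                                   n_reps = 10000L, seed = 1L) {
  sig <- if (is.data.frame(de_result)) de_result$significant else de_result
  sig <- as.logical(sig)
  G <- length(sig)
  if (set_size <= 0) stop("`set_size` must be positive")
  if (set_size > G) stop("`set_size` exceeds the number of tested genes")
  set.seed(seed)
  null <- if (set_size == G) rep(sum(sig), n_reps) else
    vapply(seq_len(n_reps),
           function(i) sum(sig[sample.int(G, set_size)]), numeric(1))
  structure(list(observed = n_observed_sig, mean_sig = mean(null),
                 null_samples = null, p = mean(null > n_observed_sig),
                 n_reps = n_reps, seed = seed),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("Randomization test: observed = %.4g, null mean = %.4g, p = %.4g (%d replicates)\n",
              x$observed, if (!is.null(x$mean_sig)) x$mean_sig else
                mean(x$null_samples), x$p, x$n_reps))
  invisible(x)
}
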