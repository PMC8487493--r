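# Synthetic-data generator emulating the two-by-two geography x sex brain
# RNA-seq design: negative-binomial counts with gene-wise dispersion,
# planted geography- and sex-associated fold changes (geography effects
# outnumber sex effects; female geography effects outnumber male), planted
# correlated gene modules optionally tied to a trait through a latent
# factor, and planted candidate/pathway annotations. Ground truth is
# returned for parameter-recovery testing.

#' Simulation configuration
#'
#' Defaults reproduce the study design scaled to the desk: 16 samples in
#' four unbalanced groups (allopatric female 5, allopatric male 3,
#' sympatric female 4, sympatric male 4), lognormal library sizes,
#' normal log2 baseline abundances, a quadratic-plus-trend biological
#' coefficient of variation (phi = bcv0^2 + bcv_trend/mu), more planted
#' geography effects than sex effects and more female-geography effects
#' than male, ten 60-gene latent-factor modules (three tied to geography
#' with heterogeneous strength, one to sex, the rest free), and a 5%
#' candidate fraction.
#'
#' @param n_genes number of genes.
#' @param group_sizes named vector of samples per group; names
#'   `allopatric.female`, `allopatric.male`, `sympatric.female`,
#'   `sympatric.male`.
#' @param lib_size_mean,lib_size_cv expected total counts per sample and
#'   coefficient of variation (lognormal).
#' @param baseline_logmean mean and sd of the per-gene log2 relative
#'   abundance distribution.
#' @param bcv0,bcv_trend dispersion model: phi_g = bcv0^2 + bcv_trend /
#'   mu_g (mu_g = average expected count).
#' @param frac_de_geo_female,frac_de_geo_male,frac_de_geo_both,frac_de_sex
#'   fractions of genes with planted effects (disjoint gene sets).
#' @param lfc_magnitude absolute planted log2 fold change (sign random).
#' @param lfc_other_sex_frac geography effects scoped to one sex are
#'   sex-biased, not sex-exclusive: the other sex expresses this fraction
#'   of the planted fold change (default 0.5; set 0 for strictly
#'   sex-exclusive effects).
#' @param n_modules,module_sizes planted co-expression modules.
#' @param module_assoc per-module trait tie: `"geography"`, `"sex"` or
#'   `"none"`.
#' @param module_assoc_strength latent factor: z_s = a * trait_s +
#'   sqrt(1 - a^2) * noise; one `a` per module (recycled), negative for a
#'   module whose expression drops with the trait. Heterogeneous strengths
#'   and mixed signs keep same-trait modules distinguishable at 16 samples.
#' @param module_loading per-gene log2 loading on the module latent factor.
#' @param module_baseline_shift,module_baseline_sd_frac planted module genes
#'   draw their baseline abundance from the upper range of the baseline
#'   distribution (mean shifted by `module_baseline_shift` standard
#'   deviations, sd scaled by `module_baseline_sd_frac`): co-expression
#'   modules are detected among the most variable genes, so planted modules
#'   must live inside that selection for the emulation to be faithful.
#' @param frac_candidate fraction of genes given candidate annotations.
#' @param frac_decoy fraction of non-candidates given decoy annotations
#'   (matched by a broad keyword but excluded by its restriction).
#' @param pathway_n_per_module,pathway_synaptic_frac_assoc,
#'   pathway_synaptic_frac_other pathway-plan defaults used by
#'   [run_all()]: pathways per module and the synaptic fraction for
#'   geography-associated vs other modules.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(
    group_sizes = c(allopatric.female = 5L, allopatric.male = 3L,
                    sympatric.female = 4L, sympatric.male = 4L),
    lib_size_mean = 2e6, lib_size_cv = 0.3,
    baseline_logmean = c(mean = 3, sd = 2),
    bcv0 = 0.4, bcv_trend = 2,
    frac_de_geo_female = 0.05, frac_de_geo_male = 0.02,
    frac_de_geo_both = 0.03, frac_de_sex = 0.01,
    lfc_magnitude = 2, lfc_other_sex_frac = 0.5,
    n_genes = 7000L,
    n_modules = 10L, module_sizes = rep(60L, 10L),
    module_assoc = c("geography", "geography", "geography", "sex",
                     rep("none", 6L)),
    module_assoc_strength = c(0.9, 0.75, -0.75, 0.8, rep(0, 6L)),
    module_loading = 0.8,
    module_baseline_shift = 2, module_baseline_sd_frac = 0.5,
    frac_candidate = 0.05, frac_decoy = 0.02,
    pathway_n_per_module = 20L,
    pathway_synaptic_frac_assoc = 0.55,
    pathway_synaptic_frac_other = 0.10,
    seed = 1L) {
  fr <- c(frac_de_geo_female, frac_de_geo_male, frac_de_geo_both,
          frac_de_sex)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("DE fractions must lie in [0, 1] and sum to at most 1")
  if (frac_candidate < 0 || frac_candidate > 1)
    stop("frac_candidate must lie in [0, 1]")
  if (any(group_sizes < 1)) stop("every group needs at least one sample")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_modules > 0 && length(module_sizes) != n_modules)
    stop("module_sizes must have length n_modules")
  if (n_modules > 0 && length(module_assoc) != n_modules)
    stop("module_assoc must have length n_modules")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic dataset
#'
#' Draws NB counts with mean mu_gs = L_s * q_gs / sum_g q_gs, where
#' log2 q_gs is the gene baseline plus planted group fold changes plus the
#' module latent-factor contribution, and dispersion follows the configured
#' BCV model. Identical seeds give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample table), `truth` (per-gene ground truth: DE flags, true log2
#'   fold changes, module label, candidate flag).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, 0L))
  gs <- config$group_sizes
  geography <- rep(rep(c("allopatric", "sympatric"), times = c(sum(gs[1:2]),
                                                               sum(gs[3:4]))), 1)
  sex <- c(rep(c("female", "male"), times = gs[1:2]),
           rep(c("female", "male"), times = gs[3:4]))
  grp <- paste0(ifelse(geography == "sympatric", "S", "A"),
                ifelse(sex == "female", "F", "M"))
  ids <- paste0(grp, stats::ave(seq_along(grp), grp, FUN = seq_along))
  samples <- sample_table(ids, geography, sex)
  S <- nrow(samples)
  G <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(G))

  lib_sd <- sqrt(log(1 + config$lib_size_cv^2))
  lib <- stats::rlnorm(S, log(config$lib_size_mean) - lib_sd^2 / 2, lib_sd)
  baseline <- stats::rnorm(G, config$baseline_logmean[["mean"]],
                           config$baseline_logmean[["sd"]])

  # planted effects on disjoint gene blocks (shuffled order)
  n_gf <- round(config$frac_de_geo_female * G)
  n_gm <- round(config$frac_de_geo_male * G)
  n_gb <- round(config$frac_de_geo_both * G)
  n_sx <- round(config$frac_de_sex * G)
  perm <- sample.int(G)
  take <- function(n, used) perm[seq_len(n) + used]
  used <- 0L
  idx_gf <- take(n_gf, used); used <- used + n_gf
  idx_gm <- take(n_gm, used); used <- used + n_gm
  idx_gb <- take(n_gb, used); used <- used + n_gb
  idx_sx <- take(n_sx, used); used <- used + n_sx
  sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
  lfc_geo <- numeric(G)
  lfc_geo[idx_gf] <- sgn(n_gf) * config$lfc_magnitude
  lfc_geo[idx_gm] <- sgn(n_gm) * config$lfc_magnitude
  lfc_geo[idx_gb] <- sgn(n_gb) * config$lfc_magnitude
  lfc_sex <- numeric(G)
  lfc_sex[idx_sx] <- sgn(n_sx) * config$lfc_magnitude
  scope_f <- seq_len(G) %in% c(idx_gf, idx_gb)  # full-strength in females
  scope_m <- seq_len(G) %in% c(idx_gm, idx_gb)  # full-strength in males
  # sex-biased geography effects: the off-scope sex expresses a fraction
  w_f <- ifelse(scope_f, 1, ifelse(seq_len(G) %in% idx_gm,
                                   config$lfc_other_sex_frac, 0))
  w_m <- ifelse(scope_m, 1, ifelse(seq_len(G) %in% idx_gf,
                                   config$lfc_other_sex_frac, 0))

  # module membership from the remaining genes
  module <- rep(NA_character_, G)
  loading <- numeric(G)
  Z <- NULL
  if (config$n_modules > 0) {
    need <- sum(config$module_sizes)
    if (used + need > G)
      stop("not enough genes for the planted modules; raise n_genes")
    a_vec <- rep_len(config$module_assoc_strength, config$n_modules)
    Z <- matrix(0, S, config$n_modules)
    bl_mean <- config$baseline_logmean[["mean"]] +
      config$module_baseline_shift * config$baseline_logmean[["sd"]]
    bl_sd <- config$module_baseline_sd_frac * config$baseline_logmean[["sd"]]
    for (m in seq_len(config$n_modules)) {
      idx_m <- take(config$module_sizes[m], used)
      used <- used + config$module_sizes[m]
      module[idx_m] <- paste0("M", m)
      loading[idx_m] <- config$module_loading
      baseline[idx_m] <- stats::rnorm(length(idx_m), bl_mean, bl_sd)
      tr <- switch(config$module_assoc[m],
                   geography = as.numeric(samples$geography == "sympatric"),
                   sex = as.numeric(samples$sex == "female"),
                   none = NULL)
      a <- a_vec[m]
      z <- if (is.null(tr) || a == 0) stats::rnorm(S) else {
        t_std <- (tr - mean(tr)) / stats::sd(tr)
        a * t_std + sqrt(1 - a^2) * stats::rnorm(S)
      }
      Z[, m] <- z
    }
  }

  # expected relative abundance per sample
  is_sym <- samples$geography == "sympatric"
  is_fem <- samples$sex == "female"
  log2q <- matrix(baseline, G, S)
  for (s in seq_len(S)) {
    eff <- numeric(G)
    if (is_sym[s]) {
      eff <- eff + lfc_geo * (if (is_fem[s]) w_f else w_m)
    }
    if (is_fem[s]) eff <- eff + lfc_sex
    if (!is.null(Z)) {
      in_mod <- !is.na(module)
      eff[in_mod] <- eff[in_mod] +
        loading[in_mod] * Z[s, match(module[in_mod], paste0("M",
                                                            seq_len(config$n_modules)))]
    }
    log2q[, s] <- log2q[, s] + eff
  }
  q <- 2^log2q
  mu <- sweep(sweep(q, 2L, colSums(q), "/"), 2L, lib, "*")
  mu_bar <- rowMeans(mu)
  phi <- config$bcv0^2 + config$bcv_trend / pmax(mu_bar, 1e-8)
  counts <- matrix(0L, G, S, dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(S)) {
    counts[, s] <- if (max(phi) < 1e-12)
      stats::rpois(G, mu[, s]) else
        stats::rnbinom(G, size = 1 / pmax(phi, 1e-12), mu = mu[, s])
  }

  # candidate flags drawn over all genes
  n_cand <- round(config$frac_candidate * G)
  idx_cand <- sample.int(G, n_cand)
  truth <- data.frame(
    gene_id = gene_ids,
    is_de_geo_female = scope_f,
    is_de_geo_male = scope_m,
    is_de_sex = lfc_sex != 0,
    true_lfc_geo = lfc_geo,
    true_lfc_sex = lfc_sex,
    true_module = ifelse(is.na(module), "none", module),
    is_candidate = seq_len(G) %in% idx_cand,
    stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth,
       lib_sizes = stats::setNames(lib, samples$sample_id),
       dispersion = stats::setNames(phi, gene_ids), config = config)
}

#' Generate free-text annotations with planted candidates and decoys
#'
#' Every gene flagged as a candidate in the truth table receives an
#' annotation string containing a keyword of a (randomly assigned) rule; a
#' configurable fraction of non-candidates receives decoy strings that a
#' broad keyword matches but a restriction rule excludes; remaining genes
#' get neutral housekeeping-style annotations.
#'
#' @param truth truth table from [generate_dataset()].
#' @param rules keyword rules (default [default_keyword_rules()]).
#' @param frac_decoy decoy fraction among non-candidates.
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `terms` (pipe-separated strings).
#' @export
generate_annotations <- function(truth, rules = default_keyword_rules(),
                                 frac_decoy = 0.02, seed = 1L) {
  if (nrow(rules) == 0L) stop("keyword table must be nonempty")
  set.seed(.sub_seed(seed, 1L))
  G <- nrow(truth)
  neutral <- c("cytochrome c oxidase subunit", "60S ribosomal protein L7",
               "actin-related protein 2/3 complex", "heat shock protein 70",
               "zinc finger protein 91", "citrate synthase, mitochondrial",
               "elongation factor 1-alpha", "histone H2B type 1",
               "ubiquitin-conjugating enzyme E2", "tubulin beta chain")
  # matched by the broad "kinesin"/"synapt" keywords, removed by their
  # include/exclude restrictions
  decoys <- c("kinesin-like protein KIF23", "synaptojanin pseudogene")
  terms <- character(G)
  is_cand <- truth$is_candidate
  # candidate template: the rule family text always contains its keyword
  cand_rule <- sample.int(nrow(rules), sum(is_cand), replace = TRUE)
  mk_cand <- function(i) {
    rl <- rules[i, ]
    paste0(rl$family, ": ", rl$keyword, " homolog")
  }
  terms[is_cand] <- vapply(cand_rule, mk_cand, character(1))
  non <- which(!is_cand)
  n_dec <- round(frac_decoy * length(non))
  dec_idx <- if (n_dec > 0) sample(non, n_dec) else integer(0)
  terms[dec_idx] <- sample(decoys, n_dec, replace = TRUE)
  rest <- setdiff(non, dec_idx)
  terms[rest] <- sample(neutral, length(rest), replace = TRUE)
  extra <- sample(neutral, G, replace = TRUE)
  data.frame(gene_id = truth$gene_id,
             terms = paste(terms, extra, sep = "|"),
             stringsAsFactors = FALSE)
}

#' Generate a pathway table for a module partition
#'
#' Assigns each module the planned number of pathways, of which the planned
#' number are synaptic (their name or ancestor text contains "synap",
#' "neuro" or "neura"); the rest are unrelated processes.
#'
#' @param module_labels character vector of module names (the universe of
#'   modules the plan may reference).
#' @param pathway_plan data.frame with columns `module`, `n_pathways`,
#'   `n_synaptic`.
#' @param seed RNG seed.
#' @return data.frame `pathway_id`, `module`, `name_text`,
#'   `ancestor_child_text` with exactly the planned counts per module.
#' @export
generate_pathway_table <- function(module_labels, pathway_plan, seed = 1L) {
  bad <- setdiff(pathway_plan$module, module_labels)
  if (length(bad)) stop("pathway plan references unknown module(s): ",
                        paste(bad, collapse = ", "))
  if (any(pathway_plan$n_synaptic > pathway_plan$n_pathways))
    stop("n_synaptic cannot exceed n_pathways")
  set.seed(.sub_seed(seed, 2L))
  syn_names <- c("synaptic membrane", "chemical synaptic transmission",
                 "neurotransmitter secretion", "neuron projection",
                 "regulation of synapse assembly",
                 "neuromuscular junction development",
                 "postsynaptic density", "presynaptic membrane",
                 "neural crest cell migration")
  syn_anc <- c("synapse organization; cell junction",
               "neurotransmitter transport; secretion",
               "neuron differentiation; cell development")
  other_names <- c("citric acid cycle", "transcription factor binding",
                   "oxidative phosphorylation", "ribosome biogenesis",
                   "lipid metabolic process", "DNA repair",
                   "proteasome complex", "mRNA splicing",
                   "cell cycle checkpoint", "ion homeostasis")
  other_anc <- c("metabolic process; catalytic activity",
                 "gene expression; binding",
                 "cellular process; organelle organization")
  rows <- lapply(seq_len(nrow(pathway_plan)), function(i) {
    pl <- pathway_plan[i, ]
    n_syn <- pl$n_synaptic
    n_oth <- pl$n_pathways - n_syn
    data.frame(
      module = pl$module,
      name_text = c(sample(syn_names, n_syn, replace = TRUE),
                    sample(other_names, n_oth, replace = TRUE)),
      ancestor_child_text = c(sample(syn_anc, n_syn, replace = TRUE),
                              sample(other_anc, n_oth, replace = TRUE)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(pathway_id = sprintf("GO:%07d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to TSV files
#'
#' Writes `counts.tsv`, `samples.tsv`, `truth.tsv` and (if annotations are
#' supplied) `annotations.tsv` into `dir`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory.
#' @param annotations optional annotation table.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  utils::write.table(dataset$samples[, c("sample_id", "geography", "sex")],
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "truth.tsv"))
  if (!is.null(annotations)) {
    utils::write.table(annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, file.path(dir, "annotations.tsv"))
  }
  invisible(paths)
}
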