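# The synthetic-data generator: determinism, planted effect sizes, the NB
# mean-variance relation, module correlation structure, annotations and
# pathway tables.

test_that("identical seeds give bit-identical datasets", {
  cfg <- simulation_config(n_genes = 300, seed = 77,
                           n_modules = 2, module_sizes = c(40, 40),
                           module_assoc = c("geography", "none"),
                           module_assoc_strength = c(0.8, 0))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
  a1 <- generate_annotations(d1$truth, seed = 5)
  a2 <- generate_annotations(d2$truth, seed = 5)
  expect_identical(a1, a2)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(frac_de_geo_female = 0.7,
                                 frac_de_sex = 0.5), "sum")
  expect_error(simulation_config(frac_de_geo_female = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(group_sizes = c(
    allopatric.female = 0, allopatric.male = 3, sympatric.female = 4,
    sympatric.male = 4)), "at least one sample")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(n_modules = 2, module_sizes = 40L),
               "module_sizes")
})

test_that("the truth table is consistent with the generative model", {
  ds <- generate_dataset(simulation_config(n_genes = 2000, seed = 3))
  tr <- ds$truth
  expect_true(all(abs(tr$true_lfc_geo[tr$is_de_geo_female |
                                        tr$is_de_geo_male]) > 0))
  expect_true(all(tr$true_lfc_sex[!tr$is_de_sex] == 0))
  expect_true(all(tr$true_module %in% c("none", paste0("M", 1:10))))
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))
  # the design: 16 samples in the 5/3/4/4 group layout
  expect_equal(unname(table(ds$samples$group)[c("AF", "AM", "SF", "SM")]),
               c(5, 3, 4, 4), ignore_attr = TRUE)
})

test_that("planted female-geography fold changes appear in the group means", {
  cfg <- simulation_config(n_genes = 2000, frac_de_geo_female = 0.05,
                           frac_de_geo_male = 0, frac_de_geo_both = 0,
                           frac_de_sex = 0, lfc_other_sex_frac = 0,
                           n_modules = 0, module_sizes = integer(0),
                           module_assoc = character(0),
                           module_assoc_strength = 0, seed = 12)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  sf <- ds$samples$sample_id[ds$samples$group == "SF"]
  af <- ds$samples$sample_id[ds$samples$group == "AF"]
  cpm <- t(t(ds$counts) / colSums(ds$counts)) * 1e6
  flagged <- which(tr$is_de_geo_female & rowMeans(cpm) > 5)
  ratio <- log2((rowMeans(cpm[flagged, sf, drop = FALSE]) + 0.1) /
                  (rowMeans(cpm[flagged, af, drop = FALSE]) + 0.1))
  signed <- ratio * sign(tr$true_lfc_geo[flagged])
  # planted |lfc| = 2: average recovered effect near 2 (NB noise at n=4,5)
  expect_lt(abs(mean(signed) - 2), 0.3)
  expect_gt(mean(abs(ratio) > 1), 0.8)
})

test_that("counts follow Var = mu + phi mu^2 within sampling tolerance", {
  cfg <- simulation_config(n_genes = 4000, lib_size_cv = 0,
                           frac_de_geo_female = 0, frac_de_geo_male = 0,
                           frac_de_geo_both = 0, frac_de_sex = 0,
                           n_modules = 0, module_sizes = integer(0),
                           module_assoc = character(0),
                           module_assoc_strength = 0, seed = 9)
  ds <- generate_dataset(cfg)
  mu <- rowMeans(ds$counts)
  v <- apply(ds$counts, 1, var)
  phi <- ds$dispersion
  keep <- mu > 20
  ratio <- v[keep] / (mu[keep] + phi[keep] * mu[keep]^2)
  # per-gene variance at 15 df is noisy; the aggregate must center on the
  # chi-square(15)/15 reference (median qchisq(0.5, 15)/15)
  expect_lt(abs(median(ratio) - qchisq(0.5, 15) / 15), 0.1)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("planted modules are internally correlated above background by a margin", {
  ds <- generate_dataset(simulation_config(seed = 21))
  norm <- normalize_counts(ds$counts)
  tr <- ds$truth
  m1 <- intersect(tr$gene_id[tr$true_module == "M5"],
                  rownames(norm$log2_cpm))
  bg <- sample(intersect(tr$gene_id[tr$true_module == "none"],
                         rownames(norm$log2_cpm)), 60)
  r_within <- cor(t(norm$log2_cpm[m1, ]))
  r_between <- cor(t(norm$log2_cpm[m1, ]), t(norm$log2_cpm[bg, ]))
  expect_gt(mean(abs(r_within[upper.tri(r_within)])) -
              mean(abs(r_between)), 0.2)
})

test_that("annotation decoys match broad keywords but fail restrictions", {
  ds <- null_dataset(42)
  ann <- generate_annotations(ds$truth, frac_decoy = 0.05, seed = 2)
  decoys <- ann$gene_id[grepl("kinesin-like|synaptojanin pseudogene",
                              ann$terms)]
  expect_gt(length(decoys), 0)
  cs <- match_candidates(ann, default_keyword_rules(), ann$gene_id)
  expect_length(intersect(decoys, cs$gene_ids), 0)
  # every candidate annotation contains its matched keyword
  planted <- ds$truth$gene_id[ds$truth$is_candidate]
  expect_true(all(planted %in% cs$gene_ids))
})

test_that("pathway tables honour the plan exactly and validate modules", {
  plan <- data.frame(module = c("blue", "red"), n_pathways = c(10, 7),
                     n_synaptic = c(6, 0), stringsAsFactors = FALSE)
  tab <- generate_pathway_table(c("blue", "red"), plan, seed = 4)
  flagged <- flag_synaptic(tab)
  expect_equal(sum(flagged$is_synaptic[flagged$module == "blue"]), 6)
  expect_equal(sum(flagged$is_synaptic[flagged$module == "red"]), 0)
  expect_equal(as.vector(table(tab$module)[c("blue", "red")]), c(10, 7))
  expect_error(generate_pathway_table("blue", plan), "unknown module")
  expect_error(generate_pathway_table(
    c("blue", "red"), data.frame(module = "blue", n_pathways = 3,
                                 n_synaptic = 5)), "exceed")

  # zero synaptic fraction everywhere: concentration tests all null
  plan0 <- data.frame(module = paste0("m", 1:5), n_pathways = 10,
                      n_synaptic = 0)
  tab0 <- generate_pathway_table(paste0("m", 1:5), plan0, seed = 1)
  res0 <- per_module_concentration_test(tab0, n_reps = 200, seed = 1,
                                        use_bh = TRUE)
  expect_true(all(res0$p == 1))
})
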