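# Synaptic-pathway flagging and the four concentration randomization tests.

toy_table <- function(module_sizes, synaptic_counts, prefix = "mod") {
  stopifnot(length(module_sizes) == length(synaptic_counts))
  mods <- rep(paste0(prefix, seq_along(module_sizes)), module_sizes)
  syn <- unlist(mapply(function(n, k) c(rep(TRUE, k), rep(FALSE, n - k)),
                       module_sizes, synaptic_counts, SIMPLIFY = FALSE))
  data.frame(pathway_id = sprintf("GO:%07d", seq_along(mods)),
             module = mods,
             name_text = ifelse(syn, "chemical synaptic transmission",
                                "citric acid cycle"),
             ancestor_child_text = ifelse(syn, "synapse organization",
                                          "metabolic process"),
             stringsAsFactors = FALSE)
}

test_that("synaptic flagging uses the three keyword stems over both text fields", {
  tab <- data.frame(
    pathway_id = paste0("GO:", 1:5), module = "m",
    name_text = c("synaptic membrane", "citric acid cycle",
                  "Neuronal differentiation", "ion transport", ""),
    ancestor_child_text = c("", "transcription factor binding",
                            "", "neuromuscular junction; NEURAL crest", ""),
    stringsAsFactors = FALSE)
  out <- flag_synaptic(tab)
  expect_equal(out$is_synaptic, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("per-module concentration p-values match the hypergeometric tail at study scale", {
  # mirrors the strongest module's scale: 28 pathways, 15 synaptic, out of
  # 300 pathways with 36 synaptic in total
  sizes <- c(28, rep(17, 16))
  syn <- c(15, c(rep(2, 10), rep(1, 1), rep(0, 5)))
  total_syn <- sum(syn)
  tab <- toy_table(sizes, syn)
  res <- per_module_concentration_test(tab, n_reps = 10000, seed = 7,
                                       use_bh = TRUE)
  P <- nrow(tab)
  for (i in c(1, 2, 17)) {
    m <- paste0("mod", i)
    row <- res[res$module == m, ]
    exact <- phyper(row$n_synaptic - 1, total_syn, P - total_syn,
                    row$n_pathways, lower.tail = FALSE)
    se <- sqrt(exact * (1 - exact) / 10000)
    expect_lt(abs(row$p - exact), 3 * se + 1e-4)
  }
  # the concentrated module is overwhelmingly significant
  expect_lt(res$p[res$module == "mod1"], 0.01)
  expect_true(res$significant[res$module == "mod1"])
})

test_that("degenerate pathway tables give trivial p-values", {
  none <- toy_table(c(10, 10), c(0, 0))
  res <- per_module_concentration_test(none, n_reps = 200, seed = 1,
                                       use_bh = TRUE)
  expect_equal(res$p, c(1, 1))
  single <- toy_table(12, 5)
  res1 <- per_module_concentration_test(single, n_reps = 200, seed = 1,
                                        use_bh = TRUE)
  expect_equal(res1$p, 1)
  empty <- data.frame(pathway_id = character(), module = character(),
                      name_text = character(),
                      ancestor_child_text = character(),
                      stringsAsFactors = FALSE)
  expect_error(per_module_concentration_test(empty), "empty")
})

test_that("the overall concentration test matches exact enumeration on a 5-pathway toy", {
  tab <- toy_table(c(3, 2), c(2, 1))
  # exact null: permute the 5 pathways over the fixed module layout
  flags <- flag_synaptic(tab)$is_synaptic
  perms <- combn(5, 3)  # which pathways land in module 1
  exact_null <- apply(perms, 2, function(ix) sum(flags[ix]))
  obs <- 2
  exact <- mean(exact_null >= obs)
  res <- overall_concentration_test(tab, "mod1", n_reps = 10000, seed = 3)
  expect_equal(res$observed, obs)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$p - exact), 3 * se + 1e-9)
  expect_error(overall_concentration_test(tab, character(0)), "empty")
})

test_that("mean-per-significant-module test matches C(25,4) enumeration and flags planting", {
  sizes <- rep(12, 25)
  syn <- c(9, 8, 7, 6, rep(1, 21))
  tab <- toy_table(sizes, syn)
  sig <- paste0("mod", 1:4)
  res <- mean_per_significant_test(tab, sig, n_reps = 20000, seed = 5)
  counts <- tapply(flag_synaptic(tab)$is_synaptic, tab$module, sum)
  combos <- combn(25, 4)
  null_means <- colMeans(matrix(counts[paste0("mod",
                                              as.vector(combos))],
                                nrow = 4))
  exact <- mean(null_means >= res$observed - 1e-12)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$p - exact), 3 * se + 1e-4)
  expect_lt(res$p, 0.05)  # planted concentration detected

  # identical counts: p = 1 up to ties
  flat <- toy_table(rep(10, 6), rep(2, 6))
  res_flat <- mean_per_significant_test(flat, paste0("mod", 1:2),
                                        n_reps = 500, seed = 2)
  expect_equal(res_flat$p, 1)
  expect_error(mean_per_significant_test(flat, paste0("mod", 1:6)),
               "no null variability")
})

test_that("the geography ratio test is powered at study scale and symmetric under label swap", {
  # 25 modules, 4 geography-associated carrying most synaptic pathways
  sizes <- rep(12, 25)
  syn <- c(9, 8, 7, 6, rep(1, 21))
  tab <- toy_table(sizes, syn)
  geo <- paste0("mod", 1:4)
  res <- geo_ratio_test(tab, geo, n_reps = 10000, seed = 11)
  expect_gt(res$observed, 3)
  expect_lt(res$p, 0.05)

  flat <- toy_table(rep(10, 6), rep(3, 6))
  res_flat <- geo_ratio_test(flat, paste0("mod", 1:3), n_reps = 100,
                             seed = 1)
  expect_equal(res_flat$observed, 1)

  # swapping the designation inverts the statistic
  other <- setdiff(unique(tab$module), geo)
  res_swap <- geo_ratio_test(tab, other, n_reps = 100, seed = 1)
  expect_equal(res_swap$observed, 1 / res$observed, tolerance = 1e-12)

  zero <- toy_table(c(5, 5), c(3, 0))
  expect_error(geo_ratio_test(zero, "mod1"), "ratio undefined")
})

test_that("concentration tests are invariant to pathway ID relabeling", {
  tab <- toy_table(c(10, 8, 6), c(5, 2, 0))
  tab2 <- tab
  tab2$pathway_id <- sample(sprintf("GO:%07d", 900:923))
  r1 <- per_module_concentration_test(tab, n_reps = 500, seed = 9,
                                      use_bh = TRUE)
  r2 <- per_module_concentration_test(tab2, n_reps = 500, seed = 9,
                                      use_bh = TRUE)
  expect_equal(r1$p, r2$p)
})
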