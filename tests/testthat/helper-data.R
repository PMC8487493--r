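# Shared fixture builders. Everything is generated in code; heavier shared
# datasets are cached per test run.

quick_counts <- function(G = 100, S = 4, seed = 1, mu_fun = function(g)
  rexp(g, 1 / 100)) {
  set.seed(seed)
  m <- matrix(rnbinom(G * S, mu = rep(mu_fun(G), S), size = 5), G, S,
              dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:S)))
  storage.mode(m) <- "double"
  m
}

four_group_samples <- function() {
  sample_table(
    c(paste0("AF", 1:5), paste0("AM", 1:3), paste0("SF", 1:4),
      paste0("SM", 1:4)),
    rep(c("allopatric", "sympatric"), c(8, 8)),
    c(rep("female", 5), rep("male", 3), rep("female", 4), rep("male", 4)))
}

# null dataset reused by several calibration tests (2000 genes, 16 samples,
# BCV 0.4, no planted effects or modules)
.null_cache <- new.env(parent = emptyenv())
null_dataset <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.null_cache[[key]])) {
    cfg <- simulation_config(
      n_genes = 2000, frac_de_geo_female = 0, frac_de_geo_male = 0,
      frac_de_geo_both = 0, frac_de_sex = 0, n_modules = 0,
      module_sizes = integer(0), module_assoc = character(0),
      module_assoc_strength = 0, seed = seed)
    .null_cache[[key]] <- generate_dataset(cfg)
  }
  .null_cache[[key]]
}

# adjusted Rand index (independent implementation for recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
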