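# Transcriptome-wide DE-count ratio randomization tests.
#
# Each test works on a two-column 0/1 table (one row per gene): the observed
# statistic is the ratio of column sums, and null replicates independently
# swap each gene's pair of indicators with probability 1/2 (a horizontal
# shuffle of the table), then recompute the ratio.

#' Build a two-category DE indicator table
#'
#' @param A,B 0/1 (or logical) vectors of equal length, one entry per gene.
#' @return data.frame of class `de_indicator_table` with integer columns
#'   `A` and `B`.
#' @export
de_indicator_table <- function(A, B) {
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) != length(B)) stop("A and B must have equal length")
  if (!all(A %in% 0:1) || !all(B %in% 0:1))
    stop("indicators must be 0/1")
  structure(data.frame(A = A, B = B), class = c("de_indicator_table",
                                                "data.frame"))
}

#' Ratio of DE counts
#'
#' @param table a `de_indicator_table`.
#' @return sum(A) / sum(B).
#' @export
ratio_statistic <- function(table) {
  if (sum(table$B) == 0)
    stop("category B has no DE genes: the ratio is infinite; ",
         "swap categories or use a different contrast")
  sum(table$A) / sum(table$B)
}

#' Randomization test for a DE-count ratio
#'
#' One-sided test of whether category A holds more DE genes than category B.
#' Each null replicate swaps each gene's (A, B) indicator pair independently
#' with probability 1/2 and recomputes the ratio; p is the proportion of
#' null ratios greater than or equal to the observed ratio.
#'
#' @param table a `de_indicator_table`.
#' @param n_reps null replicates (default 10000).
#' @param seed RNG seed.
#' @param add_one use the (r + 1)/(N + 1) p-value estimator.
#' @return object of class `rand_test`: `observed`, `null_samples`, `p`,
#'   `n_reps`, `seed`.
#' @export
ratio_randomization_test <- function(table, n_reps = 10000L, seed = 1L,
                                     add_one = FALSE) {
  sA <- sum(table$A); sB <- sum(table$B)
  if (sA + sB == 0) stop("table has no DE genes in either category")
  if (sB == 0) stop("category B has no DE genes: observed ratio infinite")
  obs <- sA / sB
  d <- table$A - table$B
  n_up <- sum(d == 1L)   # rows contributing +1 to A
  n_dn <- sum(d == -1L)  # rows contributing +1 to B
  set.seed(seed)
  # swapping a discordant row moves one count between the columns; rows with
  # A == B are invariant, so the net transfer is a difference of binomials
  k <- stats::rbinom(n_reps, n_up, 0.5) - stats::rbinom(n_reps, n_dn, 0.5)
  null <- (sA - k) / (sB + k)
  null[sB + k == 0] <- Inf
  r <- sum(null >= obs - 1e-12)
  p <- if (add_one) (r + 1) / (n_reps + 1) else r / n_reps
  structure(list(observed = obs, null_samples = null, p = p,
                 n_reps = n_reps, seed = seed), class = "rand_test")
}

#' Assemble the three transcriptome-wide ratio-test tables
#'
#' From per-comparison DE results (see [run_comparisons()]) builds:
#' \itemize{
#' \item `geo_vs_sex`: A = DE by geography in females or males (union of the
#'   two within-sex geography comparisons), B = DE by sex in allopatry or
#'   sympatry (union of the two within-geography sex comparisons);
#' \item `female_vs_male_geo`: A = geography-DE in females, B = in males;
#' \item `sym_vs_allo_sex`: A = sex-DE in sympatry, B = in allopatry.
#' }
#'
#' @param de_results named list with elements `geo_female`, `geo_male`,
#'   `sex_allopatric`, `sex_sympatric` (each a `de_result`).
#' @return named list of three `de_indicator_table`s.
#' @export
build_comparison_tables <- function(de_results) {
  need <- c("geo_female", "geo_male", "sex_allopatric", "sex_sympatric")
  miss <- setdiff(need, names(de_results))
  if (length(miss)) stop("missing comparison(s): ",
                         paste(miss, collapse = ", "))
  ids <- de_results[[need[1]]]$gene_id
  sig <- lapply(need, function(nm) {
    d <- de_results[[nm]]
    if (!identical(d$gene_id, ids))
      stop("comparisons cover different gene sets")
    d$significant
  })
  names(sig) <- need
  list(
    geo_vs_sex = de_indicator_table(
      sig$geo_female | sig$geo_male,
      sig$sex_allopatric | sig$sex_sympatric),
    female_vs_male_geo = de_indicator_table(sig$geo_female, sig$geo_male),
    sym_vs_allo_sex = de_indicator_table(sig$sex_sympatric,
                                         sig$sex_allopatric))
}
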