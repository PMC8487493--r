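#' @keywords internal
"_PACKAGE"

# Shared argument checks used across the pipeline. All user-facing matrices
# are plain numeric matrices with gene IDs as rownames and sample IDs as
# colnames; sample metadata is a data.frame (see `sample_table()`).

.check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene IDs in `counts`")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample IDs in `counts`")
  if (any(counts < 0)) stop("`counts` contains negative entries")
  invisible(counts)
}

#' Construct a sample metadata table
#'
#' Builds the sample table used throughout the pipeline: one row per sample
#' with its geography (allopatric = ancestral, sympatric = reinforced), sex,
#' and the derived four-level group label.
#'
#' @param sample_id character vector of unique sample IDs.
#' @param geography character, `"allopatric"` or `"sympatric"` per sample.
#' @param sex character, `"female"` or `"male"` per sample.
#' @return data.frame with columns `sample_id`, `geography`, `sex`, `group`
#'   where `group` is one of `"AF"`, `"AM"`, `"SF"`, `"SM"`.
#' @export
sample_table <- function(sample_id, geography, sex) {
  geography <- match.arg(as.character(geography),
                         c("allopatric", "sympatric"), several.ok = TRUE)
  sex <- match.arg(as.character(sex), c("female", "male"), several.ok = TRUE)
  if (anyDuplicated(sample_id)) stop("duplicated sample IDs")
  if (length(geography) != length(sample_id) || length(sex) != length(sample_id))
    stop("`geography` and `sex` must match `sample_id` in length")
  group <- paste0(ifelse(geography == "sympatric", "S", "A"),
                  ifelse(sex == "female", "F", "M"))
  data.frame(sample_id = as.character(sample_id), geography = geography,
             sex = sex, group = group, stringsAsFactors = FALSE)
}

.check_samples <- function(counts, samples) {
  if (!all(c("sample_id", "geography", "sex", "group") %in% names(samples)))
    stop("`samples` must have columns sample_id, geography, sex, group")
  if (!setequal(samples$sample_id, colnames(counts)) ||
      length(samples$sample_id) != ncol(counts))
    stop("samples table must list every count column exactly once")
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}

# Derive a component seed from a base seed by a fixed offset, kept within
# 32-bit integer range so set.seed() accepts it on all platforms.
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647L)
}

# Quadratic refinement of a grid argmax: fit a parabola through the maximum
# grid point and its neighbours (in x = log(phi) space) and return the vertex.
.quad_refine <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(x)) return(x[i])
  x0 <- x[(i - 1L):(i + 1L)]; y0 <- y[(i - 1L):(i + 1L)]
  d1 <- (y0[3] - y0[1]) / (x0[3] - x0[1])
  d2 <- (y0[3] - 2 * y0[2] + y0[1]) / ((x0[2] - x0[1])^2)
  if (!is.finite(d2) || d2 >= 0) return(x0[2])
  v <- x0[2] - d1 / (2 * d2)
  max(min(v, x0[3]), x0[1])
}

#' Read a tab-separated count matrix
#'
#' @param path TSV file whose first column holds gene IDs and remaining
#'   columns one sample each.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  .check_count_matrix(m)
}

#' Read a sample metadata TSV (sample_id, geography, sex)
#' @param path TSV file path.
#' @return sample table as from [sample_table()].
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_table(df$sample_id, df$geography, df$sex)
}

#' Write a matrix as TSV with an ID first column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_name name for the ID column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
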