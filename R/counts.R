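#' Construct a count matrix object
#'
#' Bundles an integer miRNA-by-sample count matrix with a sample-to-condition
#' map. This is the entry point of the pipeline: rows are mature miRNA
#' identifiers (miRBase style, e.g. `"mmu-mir-30d-5p"`), columns are samples.
#'
#' @param counts Integer matrix (miRNAs x samples) with unique rownames and
#'   colnames. Values must be non-negative whole numbers.
#' @param groups Named character vector mapping every sample id to a condition
#'   label, or an unnamed vector of length `ncol(counts)` in column order.
#' @return An object of class `"count_matrix"`: a list with elements `counts`
#'   (integer matrix) and `groups` (named character vector).
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 40L), 2, 2,
#'             dimnames = list(c("mmu-mir-1", "mmu-mir-2"), c("s1", "s2")))
#' cm <- count_matrix(m, c(s1 = "control", s2 = "LTyr"))
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (miRNA ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate miRNA ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("unnamed groups must have one label per sample")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  groups <- stats::setNames(as.character(groups[colnames(counts)]), colnames(counts))
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "miRNAs x", ncol(x$counts), "samples\n")
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                   as.integer(table(x$groups))), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from a delimited file
#'
#' Expects a TSV/CSV with a header row of sample ids and miRNA ids in the
#' first column. Cells must be non-negative integers.
#'
#' @param path Path to the file. Delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param groups Sample-to-condition map passed on to [count_matrix()], or a
#'   path to a YAML file containing one `sample: condition` mapping.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, groups) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate miRNA ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells in ", path)
  rownames(m) <- ids
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- unlist(yaml::read_yaml(groups))
  count_matrix(m, groups)
}

#' Write a count matrix as TSV
#'
#' First column `mirna_id`, then one column per sample. Inverse of
#' [read_count_matrix()].
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(mirna_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Estimates one sequencing-depth factor per sample as the median, over miRNAs
#' expressed in every sample, of the ratio of the sample's count to the
#' miRNA's geometric mean across samples. Dividing each column by its factor
#' makes samples comparable without letting a few highly expressed miRNAs
#' dominate (as total-count scaling would).
#'
#' @param cm A `count_matrix`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(2L, 2L, 2L, 4L, 4L, 4L), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(count_matrix(m, c(a = "x", b = "y")))  # 0.707, 1.414
#' @export
size_factors <- function(cm) {
  counts <- cm$counts
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  log_gm <- rowMeans(log(counts))            # -Inf for any gene with a zero
  usable <- is.finite(log_gm)
  if (!any(usable))
    stop("no miRNA has positive counts in all samples; size factors undefined")
  sf <- apply(counts[usable, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - log_gm[usable])))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a count matrix by size factors
#'
#' @param cm A `count_matrix`.
#' @param sf Optional pre-computed size factors; defaults to
#'   [size_factors()] of `cm`.
#' @return An object of class `"normalized_matrix"`: list with `values`
#'   (numeric matrix, count / size factor), `size_factors`, and `groups`.
#' @export
normalize_counts <- function(cm, sf = size_factors(cm)) {
  sf <- sf[colnames(cm$counts)]
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be positive")
  values <- sweep(cm$counts, 2L, sf, "/")
  structure(list(values = values, size_factors = sf, groups = cm$groups),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "miRNAs x", ncol(x$values), "samples\n")
  cat("size factors:", paste(sprintf("%.3f", x$size_factors), collapse = " "), "\n")
  invisible(x)
}

#' Principal-component scores of samples
#'
#' Summarizes between-sample variation: each sample is projected onto the
#' first `k` principal components of the column-centered `log2(x + 1)`
#' expression matrix. The sign of each component is fixed by making its
#' largest-magnitude miRNA loading positive, so scores are reproducible
#' across platforms.
#'
#' @param nm A `normalized_matrix` (or bare numeric matrix, miRNAs x samples).
#' @param k Number of components, `1 <= k <= min(n_samples, n_mirnas)`.
#' @return Data frame with `sample_id`, score columns `PC1..PCk`, and an
#'   attribute `"var_explained"` (proportion per component).
#' @export
pca_scores <- function(nm, k = 2L) {
  values <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  x <- t(log2(values + 1))                    # samples x miRNAs
  if (k < 1L || k > min(dim(x)))
    stop("k must be in [1, ", min(dim(x)), "]")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                     # deterministic sign convention
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- data.frame(sample_id = rownames(x), scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(k)]
  out
}
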