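#' Normalize miRNA identifiers for cross-dialect matching
#'
#' Target-prediction tables and miRBase-style count matrices disagree on
#' case (`miR` vs `mir`) and on species prefixes (`mmu-`). Matching is done
#' on a lower-cased id with the species prefix removed.
#'
#' @param ids Character vector of miRNA ids.
#' @return Normalized ids (lower case, no 3-letter species prefix).
#' @export
normalize_mirna_id <- function(ids) {
  # strip a species code only when it precedes the mir/let stem, so bare
  # ids like "miR-99b-5p" are left intact
  sub("^[a-z]{3}-(?=(mir|let)\\b)", "", tolower(ids), perl = TRUE)
}

#' Read a miRNA-to-gene target table
#'
#' TSV with one predicted interaction per row. Column names are mapped via
#' `col_map` so TargetScan-style summary files can be consumed directly.
#' Duplicate (miRNA, gene) pairs are dropped.
#'
#' @param path Path to the TSV.
#' @param col_map Named character vector mapping the roles `mirna` and
#'   `gene` (and optionally `score`) to column names in the file.
#' @return Data frame with columns `mirna_id`, `gene_symbol` and optionally
#'   `score`.
#' @export
read_target_table <- function(path,
                              col_map = c(mirna = "miRNA", gene = "gene")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  need <- col_map[c("mirna", "gene")]
  if (!all(need %in% names(df)))
    stop("target table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(mirna_id = as.character(df[[need[["mirna"]]]]),
                    gene_symbol = as.character(df[[need[["gene"]]]]),
                    stringsAsFactors = FALSE)
  if ("score" %in% names(col_map) && col_map[["score"]] %in% names(df))
    out$score <- as.numeric(df[[col_map[["score"]]]])
  out[!duplicated(out[c("mirna_id", "gene_symbol")]), , drop = FALSE]
}

#' Keep target edges whose miRNA is differentially expressed
#'
#' Matching is case-insensitive and ignores the species prefix
#' (see [normalize_mirna_id()]).
#'
#' @param edges Data frame with `mirna_id`, `gene_symbol`.
#' @param de_mirnas Character vector of differentially expressed miRNA ids.
#' @return The matching subset of `edges`.
#' @export
filter_targets <- function(edges, de_mirnas) {
  keep <- normalize_mirna_id(edges$mirna_id) %in% normalize_mirna_id(de_mirnas)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes targeted by every miRNA of a cluster
#'
#' The intersection over cluster members of each member's predicted target
#' set. A member with no predicted targets makes the intersection empty; the
#' result is then flagged via the `"missing_members"` attribute.
#'
#' @param cluster_mirnas Non-empty character vector of miRNA ids.
#' @param edges Target table (`mirna_id`, `gene_symbol`).
#' @return Sorted character vector of common target genes, with attribute
#'   `"missing_members"` naming members absent from the table.
#' @export
common_targets <- function(cluster_mirnas, edges) {
  if (!length(cluster_mirnas)) stop("cluster must be non-empty")
  key <- normalize_mirna_id(edges$mirna_id)
  sets <- lapply(normalize_mirna_id(cluster_mirnas),
                 function(m) unique(edges$gene_symbol[key == m]))
  missing <- cluster_mirnas[lengths(sets) == 0L]
  common <- Reduce(intersect, sets)
  structure(sort(common), missing_members = missing)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE),
                        `[[`, character(1), 1L)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of the query genes with the
#' upper-tail hypergeometric probability `P(X >= k)` where `k` is the
#' overlap, `K` the set size, `n` the query size and `N` the universe size.
#' Query genes outside the universe are dropped with a warning. No
#' multiple-testing correction is applied by default, matching the
#' convention of reporting raw hypergeometric p-values below `alpha`;
#' `adjust = TRUE` adds a BH-adjusted column and filters on it instead.
#'
#' @param query_genes Character vector of genes of interest (e.g. cluster
#'   common targets).
#' @param gene_sets Named list of character vectors (from [read_gmt()]).
#' @param universe Character vector of all candidate genes; gene sets are
#'   intersected with it.
#' @param alpha Significance cut-off (default 0.05).
#' @param adjust Apply BH correction before calling significance?
#' @return Data frame with one row per set: `set_name`, `k` (overlap), `n`
#'   (query size), `K` (set size), `N` (universe size), `p_value`,
#'   (optionally `padj`) and `significant`; ordered by p-value.
#' @export
hypergeom_enrich <- function(query_genes, gene_sets, universe,
                             alpha = 0.05, adjust = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query_genes, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped")
  query <- unique(intersect(query_genes, universe))
  n <- length(query)
  big_n <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, set))
    big_k <- length(set)
    # upper tail P(X >= k); phyper is P(X <= q) so shift by one
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, big_k, big_n - big_k, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n = n, K = big_k, N = big_n,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj <- bh_adjust(out$p_value)
    out$significant <- out$padj < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
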