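#' Equal-frequency discretization
#'
#' Assigns each value to one of `nbins` bins so that bin occupancies are as
#' equal as possible. Binning is by rank quantiles; ties are broken by stable
#' order of occurrence, so a constant vector still splits evenly and the
#' result is deterministic.
#'
#' @param values Numeric vector, `length(values) >= nbins`.
#' @param nbins Number of bins, at least 2.
#' @return Integer vector of bin labels in `0:(nbins - 1)`.
#' @examples
#' equal_frequency_discretize(c(5, 1, 3, 2, 6, 4), 3)  # 2 0 1 0 2 1
#' @export
equal_frequency_discretize <- function(values, nbins = 3L) {
  n <- length(values)
  if (nbins < 2L) stop("nbins must be >= 2")
  if (nbins > n) stop("nbins (", nbins, ") exceeds number of values (", n, ")")
  r <- rank(values, ties.method = "first") - 1L   # 0-based rank, stable ties
  as.integer(floor(r * nbins / n))
}

#' Plug-in mutual information of two discrete label vectors
#'
#' Empirical mutual information in nats,
#' `I = sum p(x, y) * ln(p(x, y) / (p(x) p(y)))` over the observed joint
#' contingency table. Non-negative; zero when the empirical joint factorizes.
#'
#' @param bins_x,bins_y Equal-length vectors of discrete labels.
#' @return Mutual information in nats (non-negative scalar).
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # ln 2
#' @export
mutual_information <- function(bins_x, bins_y) {
  if (length(bins_x) != length(bins_y))
    stop("bins_x and bins_y must have equal length")
  n <- length(bins_x)
  joint <- table(bins_x, bins_y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Map mutual information to a correlation-like similarity in [0, 1)
#'
#' `s = sqrt(1 - exp(-2 I))`, the standard mapping that turns mutual
#' information into the absolute correlation it would correspond to for a
#' bivariate Gaussian. Strictly increasing in `I`, with `s(0) = 0` and
#' `s -> 1` as `I -> Inf`.
#'
#' @param i_nats Non-negative mutual information in nats (vectorized).
#' @return Similarity values in `[0, 1)`.
#' @export
mi_to_similarity <- function(i_nats) {
  if (any(i_nats < -1e-12)) stop("mutual information must be non-negative")
  sqrt(pmax(0, 1 - exp(-2 * pmax(0, i_nats))))
}

#' Mutual-information similarity matrix between miRNA profiles
#'
#' Discretizes each miRNA's normalized expression profile across samples into
#' `nbins` equal-frequency bins, computes pairwise plug-in mutual
#' information, and maps it to `[0, 1]` with [mi_to_similarity()]. Mutual
#' information is used instead of Pearson correlation because it also
#' captures non-linear, non-monotone co-expression.
#'
#' @param nm A `normalized_matrix` (from [normalize_counts()]) or a bare
#'   numeric matrix with miRNAs as rows.
#' @param nbins Bins for discretization; default `floor(sqrt(n_samples))`
#'   with a minimum of 2 (9 samples give 3 bins).
#' @return Symmetric numeric matrix with unit diagonal and miRNA ids as
#'   dimnames, of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(nm, nbins = NULL) {
  values <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  n_s <- ncol(values)
  if (is.null(nbins)) nbins <- max(2L, floor(sqrt(n_s)))
  if (n_s < nbins) stop("need at least nbins samples")
  n_g <- nrow(values)
  bins <- t(apply(values, 1L, equal_frequency_discretize, nbins = nbins))
  s <- diag(1, n_g)
  if (n_g >= 2L) {
    for (i in seq_len(n_g - 1L)) {
      for (j in (i + 1L):n_g) {
        s[i, j] <- s[j, i] <-
          mi_to_similarity(mutual_information(bins[i, ], bins[j, ]))
      }
    }
  }
  dimnames(s) <- list(rownames(values), rownames(values))
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Binarize a similarity matrix at a threshold
#'
#' `a_ij = 1` iff `i != j` and `s_ij > tau` (strict inequality); the diagonal
#' is zero.
#'
#' @param s Symmetric similarity matrix.
#' @param tau Threshold in `[0, 1]`.
#' @return Binary symmetric integer adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(s, tau) {
  stopifnot(tau >= 0, tau <= 1)
  a <- (unclass(s) > tau) * 1L
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  a
}

#' Average local clustering coefficient
#'
#' Watts-Strogatz definition: for each node with degree at least 2,
#' `C_i = (# edges among neighbours) / choose(deg_i, 2)`; nodes of degree
#' below 2 contribute 0. Returns the mean over all nodes in the matrix.
#'
#' @param a Binary symmetric adjacency matrix with zero diagonal.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(a) {
  n <- nrow(a)
  if (is.null(n) || n == 0L) stop("empty node set")
  a <- unclass(a)
  deg <- rowSums(a)
  # closed triples through node i = (A^2)_ii pairs => triangles*2 = (A^3)_ii
  tri2 <- diag(a %*% a %*% a)        # 2 * triangles incident to each node
  denom <- deg * (deg - 1)
  ci <- ifelse(deg >= 2, tri2 / denom, 0)
  mean(ci)
}

#' Clustering coefficient expected for a density-matched random graph
#'
#' Under an Erdos-Renyi model with the same node and edge counts, the
#' expected clustering coefficient equals the edge density
#' `p = 2 m / (n (n - 1))`.
#'
#' @param n_nodes Number of nodes (at least 2).
#' @param n_edges Number of edges.
#' @return Expected clustering coefficient in `[0, 1]`.
#' @export
expected_random_clustering <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) stop("edge count exceeds complete graph")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Scan similarity thresholds and select the cut-off for the adjacency matrix
#'
#' For each threshold `tau` on the grid, the similarity matrix is binarized
#' (strict `s > tau`), isolated nodes are dropped, and the gap
#' `d(tau) = |C(tau) - Cr(tau)|` between the network's average clustering
#' coefficient and the density-matched random expectation is computed. The
#' selected threshold `tau*` is the smallest grid value (with at least one
#' edge) whose gap strictly exceeds the gap at the next grid point — the
#' first local peak of the clustering signal above randomness.
#'
#' @param s Similarity matrix from [similarity_matrix()].
#' @param grid Ascending thresholds within `[0.01, 0.99]`; default
#'   `seq(0.01, 0.99, by = 0.01)`.
#' @return List of class `"threshold_scan"` with `scan` (data frame `tau`,
#'   `n_nodes`, `n_edges`, `C`, `Cr`, `d`) and `tau_star`.
#' @export
select_threshold <- function(s, grid = seq(0.01, 0.99, by = 0.01)) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly ascending")
  if (min(grid) < 0.01 - 1e-12 || max(grid) > 0.99 + 1e-12)
    stop("grid must lie within [0.01, 0.99]")
  nv <- length(grid)
  scan <- data.frame(tau = grid, n_nodes = 0L, n_edges = 0L,
                     C = 0, Cr = 0, d = 0)
  for (v in seq_len(nv)) {
    a <- adjacency_matrix(s, grid[v])
    deg <- rowSums(a)
    keep <- deg >= 1
    scan$n_nodes[v] <- sum(keep)
    scan$n_edges[v] <- sum(a) / 2L
    if (sum(keep) >= 2) {
      sub <- a[keep, keep, drop = FALSE]
      scan$C[v] <- clustering_coefficient(sub)
      scan$Cr[v] <- expected_random_clustering(sum(keep), sum(sub) / 2L)
    }
    scan$d[v] <- abs(scan$C[v] - scan$Cr[v])
  }
  eligible <- which(scan$n_edges[-nv] >= 1L &
                    scan$d[-nv] > scan$d[-1L])
  if (!length(eligible))
    stop("no_threshold: the |C - Cr| gap never strictly decreases along the ",
         "grid (degenerate similarity structure); inspect the scan and set ",
         "a threshold manually")
  structure(list(scan = scan, tau_star = grid[eligible[1L]]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("threshold_scan over", nrow(x$scan), "grid points; tau* =",
      x$tau_star, "\n")
  at <- which(x$scan$tau == x$tau_star)
  cat(sprintf("at tau*: %d nodes, %d edges, C = %.3f, Cr = %.3f, d = %.3f\n",
              x$scan$n_nodes[at], x$scan$n_edges[at], x$scan$C[at],
              x$scan$Cr[at], x$scan$d[at]))
  invisible(x)
}

#' Extract miRNA clusters from an adjacency matrix
#'
#' Connected components with at least two members are reported as clusters;
#' isolated nodes are listed as singletons. Clusters are ordered by
#' decreasing size, ties broken by the lexicographically first member.
#'
#' @param a Binary symmetric adjacency matrix with dimnames.
#' @return List of class `"cluster_set"` with `clusters` (list of character
#'   vectors, each sorted) and `singletons` (character vector).
#' @export
extract_clusters <- function(a) {
  a <- unclass(a)
  n <- nrow(a)
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- integer(n)                    # 0 = unvisited
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {             # breadth-first flood fill
      node <- queue[1L]; queue <- queue[-1L]
      nbrs <- which(a[node, ] != 0 & comp == 0L)
      comp[nbrs] <- ncomp
      queue <- c(queue, nbrs)
    }
  }
  groups <- split(ids, comp)
  sizes <- lengths(groups)
  clusters <- lapply(groups[sizes >= 2L], function(g) sort(g))
  first <- vapply(clusters, function(g) g[1L], character(1))
  ord <- order(-lengths(clusters), first)
  singles <- as.character(unlist(groups[sizes == 1L], use.names = FALSE))
  structure(list(clusters = unname(clusters[ord]), singletons = sort(singles)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      length(x$singletons), "singletons\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d] %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Run the full co-expression network construction on a normalized matrix
#'
#' Convenience chain: [similarity_matrix()] on the selected miRNAs,
#' [select_threshold()], [adjacency_matrix()] at `tau*`, and
#' [extract_clusters()].
#'
#' @param nm A `normalized_matrix` or bare matrix (miRNAs x samples).
#' @param mirnas Optional character vector restricting the network to these
#'   miRNA ids (e.g. the differentially expressed set).
#' @param nbins Discretization bins, passed to [similarity_matrix()].
#' @param grid Threshold grid, passed to [select_threshold()].
#' @return List with `similarity`, `scan` (a `threshold_scan`), `tau_star`,
#'   `adjacency` and `clusters` (a `cluster_set`).
#' @export
build_network <- function(nm, mirnas = NULL, nbins = NULL,
                          grid = seq(0.01, 0.99, by = 0.01)) {
  values <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  if (!is.null(mirnas)) {
    missing <- setdiff(mirnas, rownames(values))
    if (length(missing))
      stop("miRNA id(s) absent from matrix: ", paste(missing, collapse = ", "))
    values <- values[mirnas, , drop = FALSE]
  }
  s <- similarity_matrix(values, nbins = nbins)
  scan <- select_threshold(s, grid = grid)
  a <- adjacency_matrix(s, scan$tau_star)
  list(similarity = s, scan = scan, tau_star = scan$tau_star,
       adjacency = a, clusters = extract_clusters(a))
}

#' Write network artefacts as plain-text files
#'
#' Exports the similarity matrix and adjacency matrix as labeled TSV, the
#' threshold scan as TSV, the edge list as TSV (`source`, `target`,
#' `similarity`), and the clusters as JSON.
#'
#' @param net Result of [build_network()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. the contrast/block label.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  write_labeled_matrix(unclass(net$similarity), p("similarity.tsv"))
  write_labeled_matrix(unclass(net$adjacency), p("adjacency.tsv"))
  utils::write.table(net$scan$scan, p("scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  edge_df <- data.frame(
    source = rownames(net$adjacency)[edges[, 1L]],
    target = rownames(net$adjacency)[edges[, 2L]],
    similarity = net$similarity[edges],
    stringsAsFactors = FALSE)
  utils::write.table(edge_df, p("edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tau_star = net$tau_star,
                            clusters = net$clusters$clusters,
                            singletons = net$clusters$singletons),
                       p("clusters.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(similarity = p("similarity.tsv"), adjacency = p("adjacency.tsv"),
              scan = p("scan.tsv"), edges = p("edges.tsv"),
              clusters = p("clusters.json")))
}

write_labeled_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
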