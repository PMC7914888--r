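# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths: clustering
# coefficients by per-node neighbour-pair enumeration, components by
# union-find, BH by direct step-up enumeration, hypergeometric tails by
# summing binomial-coefficient terms.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

toy_count_matrix <- function(counts, groups) {
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(paste0("mmu-mir-t", seq_len(nrow(counts))),
                             paste0("s", seq_len(ncol(counts))))
  count_matrix(counts, stats::setNames(groups, colnames(counts)))
}

# average local clustering coefficient by explicit neighbour-pair counting
oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(a[i, ] == 1)
    if (length(nbrs) < 2) next
    pairs <- utils::combn(nbrs, 2)
    linked <- sum(apply(pairs, 2, function(p) a[p[1], p[2]] == 1))
    ci[i] <- linked / ncol(pairs)
  }
  mean(ci)
}

# connected components by union-find
oracle_components <- function(a) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (a[i, j] == 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(a), roots)
}

# full threshold scan re-implemented from scratch on top of the oracles
oracle_select_threshold <- function(s, grid = seq(0.01, 0.99, by = 0.01)) {
  d <- rep(NA_real_, length(grid))
  edges <- integer(length(grid))
  for (v in seq_along(grid)) {
    a <- (s > grid[v]) * 1L; diag(a) <- 0L
    deg <- rowSums(a)
    keep <- deg >= 1
    edges[v] <- sum(a) / 2
    if (sum(keep) >= 2) {
      sub <- a[keep, keep, drop = FALSE]
      cc <- oracle_clustering(sub)
      cr <- sum(sub) / (sum(keep) * (sum(keep) - 1))
      d[v] <- abs(cc - cr)
    } else d[v] <- 0
  }
  for (v in seq_len(length(grid) - 1))
    if (edges[v] >= 1 && d[v] > d[v + 1]) return(grid[v])
  NA_real_
}

# step-up BH by direct enumeration of the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  adj
}

# upper-tail hypergeometric P(X >= k) from binomial coefficients
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# symmetric random similarity matrix with unit diagonal
random_similarity <- function(n, seed) {
  set.seed(seed)
  s <- matrix(0, n, n)
  s[upper.tri(s)] <- round(stats::runif(n * (n - 1) / 2), 2)
  s <- s + t(s); diag(s) <- 1
  dimnames(s) <- list(paste0("m", seq_len(n)), paste0("m", seq_len(n)))
  s
}

# planted-structure similarity: two 4-cliques at s_in over a flat low
# background level (MI-derived similarities are quantized in practice, so a
# constant background tier is the realistic degenerate-free fixture)
planted_cliques_similarity <- function(s_in = 0.9, s_bg = 0.1, n_bg = 4) {
  n <- 8 + n_bg
  s <- matrix(s_bg, n, n)
  s[1:4, 1:4] <- s_in
  s[5:8, 5:8] <- s_in
  diag(s) <- 1
  dimnames(s) <- list(paste0("m", 1:n), paste0("m", 1:n))
  s
}
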