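test_that("equal-frequency discretization assigns rank-quantile bins", {
  expect_identical(equal_frequency_discretize(c(1, 2, 3, 4), 2),
                   c(0L, 0L, 1L, 1L))
  # rank quantiles: {1,2} -> 0, {3,4} -> 1, {5,6} -> 2
  expect_identical(equal_frequency_discretize(c(5, 1, 3, 2, 6, 4), 3),
                   c(2L, 0L, 1L, 0L, 2L, 1L))
  # constant vector: stable split by order of occurrence, equal occupancy
  lab <- equal_frequency_discretize(rep(7, 6), 2)
  expect_identical(lab, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_error(equal_frequency_discretize(1:3, 4), "exceeds")
  expect_error(equal_frequency_discretize(1:10, 1), ">= 2")
  # occupancies differ by at most one for arbitrary inputs
  set.seed(3)
  for (n in c(7, 9, 10, 23)) for (b in c(2, 3, 4)) {
    occ <- table(equal_frequency_discretize(runif(n), b))
    expect_lte(diff(range(occ)), 1)
    expect_identical(length(occ), as.integer(b))
  }
})

test_that("mutual information matches hand-computed joint tables", {
  # perfectly matched 2-bin labels over 4 samples: I = ln 2
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), log(2),
               tolerance = 1e-12)
  # uniform 2x2 joint table: independent, I = 0
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0,
               tolerance = 1e-12)
  # constant margin: I = 0
  expect_equal(mutual_information(rep(0, 5), c(0, 1, 2, 1, 0)), 0,
               tolerance = 1e-12)
  # asymmetric hand-computed table: joint counts [[2,1],[0,1]] over n = 4
  x <- c(0, 0, 0, 1); y <- c(0, 0, 1, 1)
  p <- matrix(c(2, 0, 1, 1) / 4, 2)
  manual <- sum(ifelse(p > 0, p * log(p / outer(rowSums(p), colSums(p))), 0))
  expect_equal(mutual_information(x, y), manual, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("similarity transform has the Gaussian closed form and is monotone", {
  expect_equal(mi_to_similarity(0), 0)
  expect_equal(mi_to_similarity(0.5), sqrt(1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(mi_to_similarity(0.5), 4), 0.7951)
  expect_lt(mi_to_similarity(0.2), mi_to_similarity(0.4))
  expect_error(mi_to_similarity(-0.1), "non-negative")
})

test_that("similarity matrix is symmetric, unit-diagonal, permutation-equivariant", {
  set.seed(9)
  values <- matrix(rlnorm(10 * 9, 4, 1), 10, 9,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:9)))
  s <- similarity_matrix(values, nbins = 3)
  expect_equal(unclass(s), t(unclass(s)), tolerance = 1e-12)
  expect_equal(unname(diag(s)), rep(1, 10))
  expect_true(all(s >= 0 & s <= 1))
  # permuting miRNA order permutes the matrix consistently
  perm <- sample(10)
  s2 <- similarity_matrix(values[perm, ], nbins = 3)
  expect_equal(unclass(s2), unclass(s)[perm, perm], tolerance = 1e-12)
  # identical rows with n divisible by nbins: I = ln(nbins)
  v2 <- rbind(a = 1:6, b = 1:6)
  s3 <- similarity_matrix(v2, nbins = 3)
  expect_equal(s3["a", "b"], sqrt(1 - 1 / 9), tolerance = 1e-12)
})

test_that("independent long profiles have low similarity", {
  set.seed(14)
  values <- matrix(rlnorm(2 * 1000, 4, 1), 2, 1000)
  rownames(values) <- c("a", "b")
  s <- similarity_matrix(values, nbins = 3)
  expect_lt(s["a", "b"], 0.3)
})

test_that("clustering coefficient matches enumeration and igraph", {
  tri <- matrix(0L, 3, 3); tri[upper.tri(tri)] <- 1L; tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri), 1)
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(clustering_coefficient(path3), 0)
  # 4-cycle plus one diagonal: (2/3 + 1 + 2/3 + 1) / 4 = 5/6
  a <- matrix(0L, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  expect_equal(clustering_coefficient(a), 5 / 6, tolerance = 1e-12)
  expect_equal(oracle_clustering(a), 5 / 6, tolerance = 1e-12)
  # random graphs against per-node enumeration and igraph
  skip_if_not_installed("igraph")
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    a <- a + t(a)
    expect_equal(clustering_coefficient(a), oracle_clustering(a),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ig <- igraph::transitivity(g, type = "local", isolates = "zero")
    ig[is.nan(ig)] <- 0                       # degree-1 nodes contribute 0
    expect_equal(clustering_coefficient(a), mean(ig), tolerance = 1e-12)
  }
})

test_that("random-graph expectation is the edge density", {
  expect_equal(expected_random_clustering(4, 6), 1)       # complete K4
  expect_equal(expected_random_clustering(4, 5), 5 / 6, tolerance = 1e-12)
  expect_equal(expected_random_clustering(10, 0), 0)
  expect_error(expected_random_clustering(4, 7), "exceeds")
  expect_error(expected_random_clustering(1, 0), "at least 2")
})

test_that("adjacency binarizes with a strict threshold and zero diagonal", {
  s <- matrix(c(1, 0.5, 0.9, 0.5, 1, 0.2, 0.9, 0.2, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacency_matrix(s, 0.5)
  expect_identical(a["a", "b"], 0L)           # boundary: strict inequality
  expect_identical(a["a", "c"], 1L)
  expect_identical(unname(diag(a)), rep(0L, 3))
  expect_identical(sum(adjacency_matrix(s, 0.95)), 0L)
  a0 <- adjacency_matrix(s, 0)
  expect_identical(sum(a0), 6L)               # complete minus diagonal
})

test_that("threshold selection recovers planted cliques and matches the oracle", {
  # two 4-cliques at s = 0.9 over background 0.1: tau* must separate them
  s <- planted_cliques_similarity(0.9, 0.1, n_bg = 4)
  scan <- select_threshold(s)
  expect_gt(scan$tau_star, 0.2)
  expect_lte(scan$tau_star, 0.9)
  expect_equal(scan$tau_star, oracle_select_threshold(s), tolerance = 1e-12)
  a <- adjacency_matrix(s, scan$tau_star)
  cl <- extract_clusters(a)
  expect_length(cl$clusters, 2)
  expect_identical(cl$clusters[[1]], paste0("m", 1:4))
  expect_identical(cl$clusters[[2]], paste0("m", 5:8))
  # scan bookkeeping invariants
  expect_true(all(scan$scan$C >= 0 & scan$scan$C <= 1))
  expect_true(all(scan$scan$Cr >= 0 & scan$scan$Cr <= 1))
  expect_equal(scan$scan$d, abs(scan$scan$C - scan$scan$Cr), tolerance = 1e-12)
  expect_true(scan$tau_star %in% scan$scan$tau)
  # degenerate: all off-diagonal similarities equal -> explicit error
  s_flat <- matrix(0.5, 4, 4); diag(s_flat) <- 1
  dimnames(s_flat) <- list(paste0("m", 1:4), paste0("m", 1:4))
  expect_error(select_threshold(s_flat), "no_threshold")
  expect_error(select_threshold(s, grid = c(0.5, 0.4)), "ascending")
})

test_that("select_threshold equals an independently coded brute-force scan", {
  for (seed in 1:20) {
    s <- random_similarity(10, seed)
    expected <- oracle_select_threshold(s)
    if (is.na(expected)) {
      expect_error(select_threshold(s), "no_threshold")
    } else {
      expect_equal(select_threshold(s)$tau_star, expected, tolerance = 1e-12)
    }
  }
})

test_that("threshold scan is invariant to miRNA ordering", {
  s <- random_similarity(12, 77)
  set.seed(8); perm <- sample(12)
  expect_equal(select_threshold(s)$tau_star,
               select_threshold(s[perm, perm])$tau_star, tolerance = 1e-12)
})

test_that("cluster extraction matches union-find and igraph components", {
  set.seed(19)
  for (i in 1:10) {
    n <- 30
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, 0.05)
    a <- a + t(a)
    dimnames(a) <- list(paste0("m", 1:n), paste0("m", 1:n))
    cl <- extract_clusters(a)
    comp <- oracle_components(a)
    expect_setequal(
      vapply(cl$clusters, paste, character(1), collapse = ","),
      vapply(Filter(function(g) length(g) >= 2, comp),
             function(g) paste(sort(g), collapse = ","), character(1)))
    expect_setequal(as.character(cl$singletons),
                    as.character(unlist(Filter(function(g) length(g) == 1,
                                               comp))))
    # clusters + singletons partition the node set
    expect_setequal(c(unlist(cl$clusters), cl$singletons), rownames(a))
  }
  skip_if_not_installed("igraph")
  a <- matrix(0L, 6, 6)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- a[4, 5] <- a[5, 4] <- 1L
  dimnames(a) <- list(paste0("m", 1:6), paste0("m", 1:6))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  memb <- igraph::components(g)$membership
  cl <- extract_clusters(a)
  expect_length(cl$clusters, sum(table(memb) >= 2))
  expect_identical(cl$singletons, "m6")
  # empty graph: all singletons
  a0 <- matrix(0L, 5, 5, dimnames = list(paste0("m", 1:5), paste0("m", 1:5)))
  cl0 <- extract_clusters(a0)
  expect_length(cl0$clusters, 0)
  expect_length(cl0$singletons, 5)
})

test_that("network files are written and re-readable", {
  s <- planted_cliques_similarity(0.9, 0.1)
  values_dir <- withr::local_tempdir()
  scan <- select_threshold(s)
  net <- list(similarity = s, scan = scan, tau_star = scan$tau_star,
              adjacency = adjacency_matrix(s, scan$tau_star),
              clusters = extract_clusters(adjacency_matrix(s, scan$tau_star)))
  paths <- write_network(net, values_dir, prefix = "toy")
  expect_true(all(file.exists(paths)))
  scan_back <- read.delim(paths[["scan"]])
  expect_equal(scan_back$tau, scan$scan$tau, tolerance = 1e-12)
  cl <- jsonlite::read_json(paths[["clusters"]], simplifyVector = TRUE)
  expect_equal(cl$tau_star, net$tau_star, tolerance = 1e-12)
})
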