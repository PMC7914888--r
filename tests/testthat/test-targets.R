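targets_path <- function() system.file("extdata", "synthetic_targets_mmu.tsv",
                                       package = "rcmir")
gmt_path <- function() system.file("extdata", "synthetic_pathways.gmt",
                                   package = "rcmir")

test_that("target filtering matches ids across case and prefix dialects", {
  edges <- data.frame(
    mirna_id = c("mmu-miR-129-3p", "mmu-miR-129-3p", "mmu-miR-99b-5p",
                 "mmu-miR-211-5p", "mmu-let-7a-5p"),
    gene_symbol = c("E2F2", "Cdkn1a", "E2F2", "Tyrp1", "Tyr"))
  expect_identical(nrow(filter_targets(edges, character(0))), 0L)
  two <- filter_targets(edges, c("mmu-miR-129-3p", "mmu-miR-211-5p"))
  expect_identical(sort(unique(two$mirna_id)),
                   c("mmu-miR-129-3p", "mmu-miR-211-5p"))
  expect_identical(nrow(two), 3L)
  # "mir" vs "miR" case difference and missing species prefix still match
  via_case <- filter_targets(edges, c("mmu-mir-129-3p", "miR-99b-5p"))
  expect_identical(nrow(via_case), 3L)
  expect_identical(normalize_mirna_id("mmu-miR-30d-5p"), "mir-30d-5p")
})

test_that("cluster common targets are the intersection over members", {
  edges <- data.frame(mirna_id = c("miR-A", "miR-A", "miR-B"),
                      gene_symbol = c("E2F2", "Cdkn1a", "E2F2"))
  expect_identical(as.character(common_targets("miR-A", edges)),
                   c("Cdkn1a", "E2F2"))
  expect_identical(as.character(common_targets(c("miR-A", "miR-B"), edges)),
                   "E2F2")
  # monotone: adding a member never grows the intersection
  set.seed(4)
  pool <- paste0("g", 1:15)
  big <- do.call(rbind, lapply(paste0("m", 1:5), function(m)
    data.frame(mirna_id = m, gene_symbol = sample(pool, 8))))
  for (k in 2:5) {
    smaller <- common_targets(paste0("m", 1:(k - 1)), big)
    larger <- common_targets(paste0("m", 1:k), big)
    expect_true(all(larger %in% smaller))
    # order-independence
    expect_identical(as.character(larger),
                     as.character(common_targets(rev(paste0("m", 1:k)), big)))
  }
  # member absent from the table: empty result, flagged
  res <- common_targets(c("miR-A", "miR-ghost"), edges)
  expect_length(res, 0)
  expect_identical(attr(res, "missing_members"), "miR-ghost")
  expect_error(common_targets(character(0), edges), "non-empty")
})

test_that("the senescence-induced over-expressed cluster shares E2F2", {
  # four co-expressed miRNAs reported together in the thymidine-analog
  # exposure share the cell-cycle activator E2F2 as predicted common target
  edges <- read_target_table(targets_path())
  cluster <- c("mmu-mir-129-3p", "mmu-mir-99b-5p", "mmu-mir-378-3p",
               "mmu-mir-30d-5p")
  expect_true("E2F2" %in% common_targets(cluster, edges))
  # and the let-7a/let-7b under-expressed pair shares the melanogenic and
  # cell-cycle panel
  pair <- common_targets(c("mmu-let-7a-5p", "mmu-let-7b-5p"), edges)
  expect_true(all(c("Tyr", "Ccnd1", "Cdk4", "E2F2", "E2F3", "Rb1") %in% pair))
})

test_that("hypergeometric enrichment matches exact combinatorial enumeration", {
  # closed form: N = 20, K = 5, n = 5, k = 3 -> 1126 / 15504
  universe <- paste0("g", 1:20)
  sets <- list(s1 = paste0("g", 1:5))
  query <- c(paste0("g", 1:3), paste0("g", 10:11))
  res <- hypergeom_enrich(query, sets, universe)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_tail(3, 5, 5, 20), tolerance = 1e-12)
  expect_identical(res$k, 3L)
  # no overlap -> p = 1; full overlap of the whole universe -> p = 1
  expect_equal(hypergeom_enrich(paste0("g", 10:14), sets, universe)$p_value, 1)
  expect_equal(hypergeom_enrich(universe, list(all = universe),
                                universe)$p_value, 1)
  # exhaustive small-case agreement with the enumeration oracle
  for (N in c(8, 12)) {
    uni <- paste0("u", 1:N)
    for (K in c(2, 5)) for (n in c(3, 6)) {
      if (n > N - K) next               # not enough non-set genes for k = 0
      st <- list(s = uni[1:K])
      for (k in 0:min(K, n)) {
        q <- c(uni[seq_len(k)],
               if (k < n) uni[(K + 1):(K + n - k)] else character(0))
        stopifnot(length(q) == n)
        got <- hypergeom_enrich(q, st, uni)$p_value
        want <- if (k == 0) 1 else oracle_hyper_tail(k, K, n, N)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
  # query genes outside the universe are dropped with a warning
  expect_warning(hypergeom_enrich(c("g1", "alien"), sets, universe),
                 "outside the universe")
  expect_error(hypergeom_enrich("g1", sets, character(0)), "empty universe")
})

test_that("GMT parsing and end-to-end enrichment of a cluster's targets", {
  sets <- read_gmt(gmt_path())
  expect_identical(names(sets)[1:2], c("cell_cycle", "melanogenesis"))
  expect_true("E2F2" %in% sets$cell_cycle)
  edges <- read_target_table(targets_path())
  universe <- unique(unlist(sets))
  query <- intersect(
    common_targets(c("mmu-let-7a-5p", "mmu-let-7b-5p"), edges), universe)
  res <- hypergeom_enrich(query, sets, universe)
  expect_true(res$significant[res$set_name == "cell_cycle"])
  expect_false(res$significant[res$set_name == "unrelated_metabolism"])
})
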