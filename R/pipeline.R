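#' Run the full analysis pipeline from a configuration
#'
#' Sequences the stages end-to-end: load (or simulate) counts, normalize,
#' differential expression per contrast, co-expression network per contrast
#' and expression block (over / under / all differentially expressed
#' miRNAs), target filtering, cluster common targets, gene-set enrichment,
#' and qPCR relative expression ratios. Every output is a plain-text file
#' under `out_dir`, and a JSON manifest records the configuration hash, the
#' seed and every file written, so identical configuration and seed
#' reproduce identical outputs.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   \describe{
#'     \item{counts, groups}{Count matrix TSV and sample-to-condition map
#'       (YAML path or named list). Alternatively `simulate:` with
#'       [sim_config()] fields to generate data instead.}
#'     \item{contrasts}{List of length-2 vectors `c(reference, test)`.}
#'     \item{de_alpha}{Adjusted-p cut-off for the DE stage (default 0.05).}
#'     \item{nbins}{Discretization bins (default `floor(sqrt(n_samples))`).}
#'     \item{blocks}{Subset of `c("over", "under", "all")` (default all
#'       three, giving the classical six similarity matrices for two
#'       contrasts).}
#'     \item{tau_grid}{`c(from, to, by)` for the threshold grid (default
#'       `c(0.01, 0.99, 0.01)`).}
#'     \item{targets, target_col_map}{Optional target-prediction TSV and
#'       column mapping for [read_target_table()].}
#'     \item{gene_sets, universe}{Optional GMT path and universe gene list
#'       (path to a one-gene-per-line file); enables enrichment of cluster
#'       common targets.}
#'     \item{qpcr}{Optional qPCR measurement TSV for [rer_table()].}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{out_dir}{Output directory.}
#'   }
#' @param out_dir Overrides `config$out_dir` when given.
#' @return Invisibly, a list with the in-memory results per stage and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else config_path <- NULL
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("stage config: no out_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(seed = seed, stages = list(), files = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  note <- function(...) manifest$files <<- c(manifest$files, ...)

  ## ---- counts ----
  cm <- stage("counts", {
    if (!is.null(config$simulate)) {
      sc <- do.call(sim_config, utils::modifyList(config$simulate,
                                                  list(seed = seed)))
      sim <- simulate_counts(sc)
      note(write_simulation(sim, sc, file.path(out_dir, "simulated")))
      sim$counts
    } else {
      if (is.null(config$counts)) stop("no counts path and no simulate block")
      if (!file.exists(config$counts)) stop("counts file not found: ",
                                            config$counts)
      read_count_matrix(config$counts, config$groups)
    }
  })

  ## ---- normalize + PCA ----
  nm <- stage("normalize", normalize_counts(cm))
  stage("normalize", {
    note(write_labeled_matrix(nm$values, file.path(out_dir, "normalized.tsv")))
    sfdf <- data.frame(sample_id = names(nm$size_factors),
                       size_factor = nm$size_factors,
                       group = nm$groups[names(nm$size_factors)])
    utils::write.table(sfdf, file.path(out_dir, "size_factors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out_dir, "size_factors.tsv"))
  })
  pca <- stage("pca", {
    k <- min(3L, ncol(nm$values), nrow(nm$values))
    sc <- pca_scores(nm, k = k)
    utils::write.table(sc, file.path(out_dir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out_dir, "pca_scores.tsv"))
    sc
  })

  ## ---- differential expression ----
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    conds <- unique(cm$groups)
    contrasts <- lapply(conds[-1L], function(g) c(conds[1L], g))
  }
  de_alpha <- if (is.null(config$de_alpha)) 0.05 else config$de_alpha
  sf <- size_factors(cm)
  de_list <- list()
  for (ct in contrasts) {
    ct <- unlist(ct)
    label <- paste0(ct[2L], "_vs_", ct[1L])
    de <- stage(paste0("de ", label), de_test(cm, ct, sf = sf))
    path <- file.path(out_dir, paste0("de_", label, ".tsv"))
    utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    de_list[[label]] <- de
  }

  ## ---- networks per contrast x block ----
  blocks <- if (is.null(config$blocks)) c("over", "under", "all") else
    config$blocks
  tg <- if (is.null(config$tau_grid)) c(0.01, 0.99, 0.01) else
    unlist(config$tau_grid)
  grid <- seq(tg[1L], tg[2L], by = tg[3L])
  networks <- list()
  for (label in names(de_list)) {
    for (blk in blocks) {
      ids <- de_mirnas(de_list[[label]], block = blk, alpha = de_alpha)
      key <- paste0(label, "_", blk)
      if (length(ids) < 3L) {
        manifest$stages[[paste0("network ", key)]] <-
          paste0("skipped: only ", length(ids), " miRNAs in block")
        next
      }
      s <- stage(paste0("similarity ", key),
                 similarity_matrix(nm$values[ids, , drop = FALSE],
                                   nbins = config$nbins))
      note(write_labeled_matrix(unclass(s),
                                file.path(out_dir,
                                          paste0(key, "_similarity.tsv"))))
      net <- tryCatch({
        scan <- select_threshold(s, grid = grid)
        a <- adjacency_matrix(s, scan$tau_star)
        list(similarity = s, scan = scan, tau_star = scan$tau_star,
             adjacency = a, clusters = extract_clusters(a))
      }, error = function(e) e)
      if (inherits(net, "error")) {
        manifest$stages[[paste0("network ", key)]] <-
          paste0("threshold selection failed: ", conditionMessage(net))
        next
      }
      note(write_network(net, out_dir, prefix = key))
      manifest$stages[[paste0("network ", key)]] <-
        paste0("tau* = ", net$tau_star, "; ",
               length(net$clusters$clusters), " clusters")
      networks[[key]] <- net
    }
  }

  ## ---- targets / enrichment ----
  targets_out <- NULL
  enrich_out <- NULL
  if (!is.null(config$targets)) {
    edges <- stage("targets", {
      cmap <- if (is.null(config$target_col_map))
        c(mirna = "miRNA", gene = "gene") else unlist(config$target_col_map)
      read_target_table(config$targets, col_map = cmap)
    })
    all_de <- unique(unlist(lapply(de_list, de_mirnas, block = "all",
                                   alpha = de_alpha)))
    filtered <- filter_targets(edges, all_de)
    utils::write.table(filtered, file.path(out_dir, "filtered_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out_dir, "filtered_targets.tsv"))
    common <- list()
    for (key in names(networks))
      for (i in seq_along(networks[[key]]$clusters$clusters)) {
        cl <- networks[[key]]$clusters$clusters[[i]]
        common[[paste0(key, "_cluster", i)]] <-
          list(mirnas = cl, common_targets = as.character(
            common_targets(cl, filtered)))
      }
    jsonlite::write_json(common, file.path(out_dir, "common_targets.json"),
                         auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, "common_targets.json"))
    targets_out <- list(filtered = filtered, common = common)

    if (!is.null(config$gene_sets)) {
      enrich_out <- stage("enrichment", {
        sets <- read_gmt(config$gene_sets)
        universe <- if (!is.null(config$universe))
          readLines(config$universe) else unique(edges$gene_symbol)
        query <- unique(filtered$gene_symbol)
        hypergeom_enrich(query, sets, universe, alpha = de_alpha)
      })
      utils::write.table(enrich_out, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note(file.path(out_dir, "enrichment.tsv"))
    }
  }

  ## ---- qPCR ----
  rer_out <- NULL
  if (!is.null(config$qpcr)) {
    rer_out <- stage("qpcr", rer_table(config$qpcr))
    utils::write.table(rer_out, file.path(out_dir, "rer.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out_dir, "rer.tsv"))
  }

  ## ---- manifest ----
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  manifest$package_version <- as.character(utils::packageVersion("rcmir"))
  manifest$files <- unname(manifest$files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(counts = cm, normalized = nm, pca = pca, de = de_list,
                 networks = networks, targets = targets_out,
                 enrichment = enrich_out, rer = rer_out,
                 manifest = manifest))
}
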