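#' Configuration for the synthetic small-RNA count generator
#'
#' Defines the statistical structure of a simulated experiment: negative
#' binomial counts over a set of conditions with replicates, optional
#' latent-factor co-expression clusters, planted log2 fold-change effects in
#' chosen conditions, and log-normal library-size variation. Defaults mirror a
#' typical small-RNA-seq perturbation design: three replicates for each of an
#' unexposed control and two exposures (L-Tyrosine and
#' 5-bromo-2'-deoxyuridine).
#'
#' @param n_mirnas Number of miRNAs to simulate.
#' @param n_samples_per_group Replicates per condition.
#' @param groups Character vector of condition labels; the first is the
#'   reference (control).
#' @param clusters List of planted co-expression clusters. Each element is a
#'   list with `members` (integer miRNA indices) and `loading` (numeric scalar
#'   or one value per member): member `g` in sample `s` has its mean
#'   multiplied by `2^(loading_g * z_s)` with a shared latent factor
#'   `z_s ~ N(0, 1)` per sample. Clusters must be disjoint.
#' @param de_effects List of planted differential-expression effects, each a
#'   list with `mirna` (index), `condition` (label in `groups`) and `lfc`
#'   (log2 fold change applied in that condition).
#' @param base_mean_range Length-2 positive range; per-miRNA baseline means
#'   are drawn log-uniformly from it.
#' @param dispersion Negative binomial dispersion `alpha > 0` in the
#'   `variance = mu + alpha * mu^2` parameterization. Values at or below
#'   `1e-8` are treated as the Poisson limit.
#' @param libsize_cv Coefficient of variation of the log-normal library-size
#'   factors (0 disables depth variation).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   simulated data exactly.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_mirnas = 50L,
                       n_samples_per_group = 3L,
                       groups = c("control", "LTyr", "BrdU"),
                       clusters = list(),
                       de_effects = list(),
                       base_mean_range = c(5, 5000),
                       dispersion = 0.1,
                       libsize_cv = 0.2,
                       seed = 1L) {
  stopifnot(n_mirnas >= 1, n_samples_per_group >= 1, length(groups) >= 1,
            length(base_mean_range) == 2L, all(base_mean_range > 0),
            dispersion > 0, libsize_cv >= 0)
  members <- unlist(lapply(clusters, `[[`, "members"))
  if (anyDuplicated(members))
    stop("planted clusters must be disjoint")
  if (length(members) && (any(members < 1) || any(members > n_mirnas)))
    stop("cluster member index out of range")
  for (cl in clusters)
    if (!all(is.finite(cl$loading))) stop("cluster loadings must be finite")
  for (de in de_effects) {
    if (!de$condition %in% groups)
      stop("de_effects condition not in groups: ", de$condition)
    if (de$mirna < 1 || de$mirna > n_mirnas)
      stop("de_effects miRNA index out of range")
  }
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 groups = groups, clusters = clusters, de_effects = de_effects,
                 base_mean_range = base_mean_range, dispersion = dispersion,
                 libsize_cv = libsize_cv, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a small-RNA count matrix with known structure
#'
#' Draws counts `K_gs ~ NB(mean = f_s * mu_g * 2^(loading_g * z_{s,c(g)})
#' * 2^(lfc_g[condition_s])`, `dispersion = alpha)` where `f_s` is a
#' log-normal library-size factor, `mu_g` a log-uniform baseline mean,
#' `z_{s,c}` a standard-normal latent factor shared by all members of planted
#' cluster `c` within sample `s`, and `lfc` the planted log2 fold change for
#' miRNAs flagged as differentially expressed in the sample's condition.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth`, a list holding
#'   `cluster_membership` (named integer vector, `NA` for unclustered
#'   miRNAs), `de_lfc` (data frame `mirna_id`, `condition`, `lfc`),
#'   `size_factors`, and `base_means`.
#' @examples
#' sim <- simulate_counts(sim_config(n_mirnas = 20, seed = 7))
#' dim(sim$counts$counts)
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_g <- cfg$n_mirnas
  n_per <- cfg$n_samples_per_group
  n_s <- n_per * length(cfg$groups)
  condition <- rep(cfg$groups, each = n_per)
  sample_ids <- paste0(condition, "_", rep(seq_len(n_per), length(cfg$groups)))
  mirna_ids <- sprintf("mmu-mir-sim-%03d", seq_len(n_g))

  mu <- exp(stats::runif(n_g, log(cfg$base_mean_range[1]),
                         log(cfg$base_mean_range[2])))
  # library-size factors: log-normal, E[f] = 1, CV as configured
  if (cfg$libsize_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$libsize_cv^2))
    sf <- stats::rlnorm(n_s, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else sf <- rep(1, n_s)

  log2_mean <- matrix(log2(mu), n_g, n_s)
  membership <- rep(NA_integer_, n_g)
  for (ci in seq_along(cfg$clusters)) {
    cl <- cfg$clusters[[ci]]
    load <- rep_len(cl$loading, length(cl$members))
    z <- stats::rnorm(n_s)                    # latent factor, one per sample
    log2_mean[cl$members, ] <- log2_mean[cl$members, , drop = FALSE] +
      outer(load, z)
    membership[cl$members] <- ci
  }
  de_rows <- lapply(cfg$de_effects, function(de) {
    cols <- which(condition == de$condition)
    log2_mean[de$mirna, cols] <<- log2_mean[de$mirna, cols] + de$lfc
    data.frame(mirna_id = mirna_ids[de$mirna], condition = de$condition,
               lfc = de$lfc, stringsAsFactors = FALSE)
  })

  mean_mat <- sweep(2^log2_mean, 2L, sf, "*")
  counts <- matrix(0L, n_g, n_s, dimnames = list(mirna_ids, sample_ids))
  if (cfg$dispersion <= 1e-8) {
    counts[] <- stats::rpois(n_g * n_s, lambda = mean_mat)
  } else {
    counts[] <- stats::rnbinom(n_g * n_s, mu = mean_mat,
                               size = 1 / cfg$dispersion)
  }
  names(membership) <- mirna_ids
  truth <- list(
    cluster_membership = membership,
    de_lfc = if (length(de_rows)) do.call(rbind, de_rows) else
      data.frame(mirna_id = character(), condition = character(),
                 lfc = numeric(), stringsAsFactors = FALSE),
    size_factors = stats::setNames(sf, sample_ids),
    base_means = stats::setNames(mu, mirna_ids))
  list(counts = count_matrix(counts, stats::setNames(condition, sample_ids)),
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Counts as TSV, ground truth as a JSON sidecar, configuration as YAML.
#'
#' @param sim Result of [simulate_counts()].
#' @param cfg The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"),
             groups = file.path(dir, "groups.yaml"))
  write_count_matrix(sim$counts, paths["counts"])
  truth <- sim$truth
  # named atomic vectors as JSON objects, not bare arrays
  for (f in c("cluster_membership", "size_factors", "base_means"))
    truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  yaml::write_yaml(unclass(cfg), paths["config"])
  yaml::write_yaml(as.list(sim$counts$groups), paths["groups"])
  invisible(paths)
}

#' Simulate a qPCR measurement table
#'
#' Builds Ct values whose efficiency-adjusted relative expression ratio
#' ([rer()]) recovers `true_ratios` exactly at zero noise: the reference gene
#' keeps a constant Ct across conditions, and the target's treated Ct is
#' shifted by `-log(ratio) / log(E_target)` cycles relative to control.
#'
#' @param true_ratios Named numeric vector of true expression ratios
#'   (treated relative to control), one per target.
#' @param efficiencies Amplification efficiencies in `(1, 2.2]`: either a
#'   single value for all assays, or a named vector covering each target and
#'   the reference.
#' @param reference_id Reference assay name (e.g. `"U6"` for miRNAs,
#'   `"GAPDH"` for mRNAs).
#' @param n_replicates Biological replicates per condition.
#' @param ct_noise_sd Standard deviation of Gaussian noise added to every Ct.
#' @param ct_base Baseline control Ct for every assay.
#' @param seed Integer seed.
#' @return Data frame with columns `target_id`, `reference_id`, `condition`,
#'   `replicate`, `ct`, `efficiency` — the input shape of [rer_table()].
#' @export
simulate_qpcr <- function(true_ratios, efficiencies = 2, reference_id = "U6",
                          n_replicates = 3L, ct_noise_sd = 0, ct_base = 25,
                          seed = 1L) {
  stopifnot(length(true_ratios) >= 1, ct_noise_sd >= 0)
  if (is.null(names(true_ratios)))
    names(true_ratios) <- paste0("target_", seq_along(true_ratios))
  targets <- names(true_ratios)
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(efficiencies, length(targets) + 1L),
                                    c(targets, reference_id))
  if (any(efficiencies <= 1) || any(efficiencies > 2.2))
    stop("amplification efficiencies must lie in (1, 2.2]")
  set.seed(seed)
  rows <- list()
  for (tg in targets) {
    e_t <- efficiencies[[tg]]
    # treated Ct lower than control by log_E(ratio) cycles => rER = ratio
    d_ct <- log(true_ratios[[tg]]) / log(e_t)
    for (cond in c("control", "treated")) {
      ct_t <- if (cond == "control") ct_base else ct_base - d_ct
      for (r in seq_len(n_replicates)) {
        noise <- if (ct_noise_sd > 0) stats::rnorm(1, 0, ct_noise_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tg, reference_id = reference_id,
          condition = cond, replicate = r, ct = ct_t + noise,
          efficiency = e_t, stringsAsFactors = FALSE)
      }
    }
  }
  # the reference assay is measured once per condition and replicate
  for (cond in c("control", "treated")) for (r in seq_len(n_replicates)) {
    noise <- if (ct_noise_sd > 0) stats::rnorm(1, 0, ct_noise_sd) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = reference_id, reference_id = reference_id,
      condition = cond, replicate = r, ct = ct_base + noise,
      efficiency = efficiencies[[reference_id]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an exponential growth curve
#'
#' Noiseless counts follow `n0 * 2^(t / doubling_time_h)`; multiplicative
#' log-normal noise with the given CV is applied on top.
#'
#' @param n0 Initial cell count.
#' @param doubling_time_h Population doubling time in hours.
#' @param times_h Numeric vector of observation times (hours).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Data frame with columns `time_h` and `cell_count`.
#' @export
simulate_growth <- function(n0, doubling_time_h, times_h, noise_cv = 0,
                            seed = 1L) {
  stopifnot(n0 > 0, doubling_time_h > 0, noise_cv >= 0)
  set.seed(seed)
  expected <- n0 * 2^(times_h / doubling_time_h)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    expected <- expected * stats::rlnorm(length(times_h), -sdlog^2 / 2, sdlog)
  }
  data.frame(time_h = times_h, cell_count = expected)
}
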