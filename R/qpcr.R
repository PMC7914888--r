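#' Efficiency-adjusted relative expression ratio (rER)
#'
#' Ratio of a target assay to a reference assay (e.g. GAPDH for mRNAs, U6
#' snRNA for miRNAs) between control and treated samples, with each assay's
#' own amplification efficiency:
#' `rER = E_target^(dCt_target) / E_ref^(dCt_ref)` where
#' `dCt = Ct_control - Ct_treated`. With this sign convention `rER > 1`
#' means the target is up-regulated in treated cells.
#'
#' @param e_target,e_ref Amplification efficiencies in `(1, 2.2]` (2 is
#'   perfect doubling per cycle).
#' @param ct_target_control,ct_target_treated,ct_ref_control,ct_ref_treated
#'   Mean threshold-cycle values.
#' @return Positive relative expression ratio.
#' @examples
#' rer(2, 2, 28, 25, 20, 19)  # 2^3 / 2^1 = 4
#' @export
rer <- function(e_target, e_ref, ct_target_control, ct_target_treated,
                ct_ref_control, ct_ref_treated) {
  if (e_target <= 1 || e_ref <= 1 || e_target > 2.2 || e_ref > 2.2)
    stop("amplification efficiencies must lie in (1, 2.2]")
  cts <- c(ct_target_control, ct_target_treated, ct_ref_control, ct_ref_treated)
  if (any(cts <= 0)) stop("Ct values must be positive")
  e_target^(ct_target_control - ct_target_treated) /
    e_ref^(ct_ref_control - ct_ref_treated)
}

#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution series, Ct regressed on log10(input) has slope
#' `-1 / log10(E)`; inverting gives `E = 10^(-1 / slope)`.
#'
#' @param slope Negative slope of the Ct vs log10-dilution regression.
#' @return Amplification efficiency (2 for a slope of -3.32).
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  10^(-1 / slope)
}

#' Relative expression ratios from a replicate qPCR measurement table
#'
#' Input is long format with one Ct per row: columns `target_id`,
#' `reference_id`, `condition` (`"control"` / `"treated"`), `replicate`,
#' `ct`, `efficiency`. Rows whose `target_id` equals a `reference_id` are
#' the reference measurements. For each target, rER is computed per
#' replicate pairing (replicate r of control against replicate r of
#' treated, using that pairing's reference Cts) and summarized as
#' mean +/- sd; alternatively Ct values are averaged over replicates first
#' and a single ratio reported (`aggregate = "mean_ct"`).
#'
#' @param measurements Data frame as described (or path to a TSV).
#' @param aggregate `"pairing"` (default) or `"mean_ct"`.
#' @return Data frame: `target_id`, `reference_id`, `rer_mean`, `rer_sd`,
#'   `n_replicates`.
#' @export
rer_table <- function(measurements, aggregate = c("pairing", "mean_ct")) {
  aggregate <- match.arg(aggregate)
  if (is.character(measurements))
    measurements <- utils::read.table(measurements, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  need <- c("target_id", "reference_id", "condition", "replicate", "ct",
            "efficiency")
  if (!all(need %in% names(measurements)))
    stop("measurement table lacks column(s): ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  m <- measurements[order(measurements$target_id, measurements$condition,
                          measurements$replicate), , drop = FALSE]
  refs <- unique(m$reference_id)
  targets <- setdiff(unique(m$target_id), refs)
  pick <- function(id, cond) m[m$target_id == id & m$condition == cond, ,
                               drop = FALSE]
  rows <- lapply(targets, function(tg) {
    ref <- unique(m$reference_id[m$target_id == tg])
    if (length(ref) != 1L)
      stop("target ", tg, " must map to exactly one reference")
    tc <- pick(tg, "control");  tt <- pick(tg, "treated")
    rc <- pick(ref, "control"); rt <- pick(ref, "treated")
    if (!nrow(rc) || !nrow(rt))
      stop("missing reference (", ref, ") measurements for target ", tg)
    if (!nrow(tc) || !nrow(tt))
      stop("missing control or treated measurements for target ", tg)
    e_t <- unique(c(tc$efficiency, tt$efficiency))
    e_r <- unique(c(rc$efficiency, rt$efficiency))
    if (length(e_t) != 1L || length(e_r) != 1L)
      stop("efficiency must be constant per assay (target ", tg, ")")
    if (aggregate == "mean_ct") {
      val <- rer(e_t, e_r, mean(tc$ct), mean(tt$ct), mean(rc$ct), mean(rt$ct))
      data.frame(target_id = tg, reference_id = ref, rer_mean = val,
                 rer_sd = 0, n_replicates = nrow(tc), stringsAsFactors = FALSE)
    } else {
      reps <- intersect(intersect(tc$replicate, tt$replicate),
                        intersect(rc$replicate, rt$replicate))
      if (!length(reps)) stop("no complete replicate pairing for target ", tg)
      vals <- vapply(reps, function(r) rer(
        e_t, e_r,
        tc$ct[tc$replicate == r], tt$ct[tt$replicate == r],
        rc$ct[rc$replicate == r], rt$ct[rt$replicate == r]), numeric(1))
      data.frame(target_id = tg, reference_id = ref,
                 rer_mean = mean(vals),
                 rer_sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 n_replicates = length(vals), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
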