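#' Instrument-selection configuration
#'
#' Defaults follow the standard loose-threshold design for microbiome
#' exposures: locus-wide significance p < 1e-5, stringent clumping
#' (r² < 0.001 within 10,000 kb), and removal of weak instruments with
#' F = beta²/se² below 10.
#'
#' @param p_threshold Significance threshold (records with p strictly below
#'   are kept).
#' @param clump_r2 Maximum r² allowed between retained instruments within the
#'   window.
#' @param clump_window_kb Clumping distance window in kilobases.
#' @param f_min Minimum instrument F-statistic retained.
#' @param blacklist Character vector of snp_ids to exclude (e.g. variants
#'   associated with confounders such as blood pressure or diabetes).
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                              clump_window_kb = 10000, f_min = 10,
                              blacklist = character()) {
  assert_scalar_number(p_threshold, "p_threshold", min = 1e-300, max = 1)
  assert_scalar_number(clump_r2, "clump_r2", min = 0, max = 1)
  assert_scalar_number(clump_window_kb, "clump_window_kb", min = 1e-9)
  assert_scalar_number(f_min, "f_min", min = 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 blacklist = as.character(blacklist)),
            class = "instrument_config")
}

#' Keep records below a p-value threshold
#'
#' @param stats A [summary_stats] object.
#' @param p_threshold Records with `pvalue < p_threshold` (strict) are kept.
#' @return A [summary_stats] subset, order preserved.
#' @export
select_by_pvalue <- function(stats, p_threshold = 1e-5) {
  assert_scalar_number(p_threshold, "p_threshold", min = 1e-300, max = 1)
  replace_records(stats, stats$records[stats$records$pvalue < p_threshold, , drop = FALSE])
}

#' Instrument-strength F-statistic
#'
#' F = beta² / se², the single-variant approximation to the first-stage F.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @return Non-negative F statistic(s).
#' @export
compute_f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop_usage("`se` must be > 0")
  (beta / se)^2
}

#' Remove weak instruments
#'
#' Records with F-statistic strictly below `f_min` are removed (F equal to
#' the threshold is retained).
#'
#' @param stats A [summary_stats] object.
#' @param f_min Minimum F retained.
#' @return A [summary_stats] subset.
#' @export
filter_weak_instruments <- function(stats, f_min = 10) {
  f <- compute_f_statistic(stats$records$beta, stats$records$se)
  replace_records(stats, stats$records[f >= f_min, , drop = FALSE])
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unprocessed record with the lowest p-value as an
#' index variant and removes every other unprocessed record on the same
#' chromosome within `clump_window_kb` of it whose r² with the index exceeds
#' `clump_r2`.  Ties on p-value are broken by (chrom, pos, snp_id) so the
#' result is invariant to input row order.  Pairs absent from `ld` count as
#' r² = 0 (kept); the number of such in-window missing pairs is reported as a
#' diagnostic message.
#'
#' @param stats A [summary_stats] object whose records carry `chrom`/`pos`.
#' @param ld An [ld_table] (or `NULL` for no LD information, in which case
#'   nothing is removed).
#' @param config An [instrument_config].
#' @return A [summary_stats] subset containing the index variants, in the
#'   original record order.
#' @export
clump <- function(stats, ld = NULL, config = instrument_config()) {
  rec <- stats$records
  if (nrow(rec) <= 1) return(stats)
  if (is.null(ld)) ld <- ld_table()
  if (any(is.na(rec$chrom) | is.na(rec$pos))) {
    stop_usage("clumping requires chrom and pos for every record")
  }
  window_bp <- config$clump_window_kb * 1000
  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$snp_id)
  active <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  missing_pairs <- 0L
  for (i in ord) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    near <- which(active & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_bp)
    if (length(near) == 0) next
    r2 <- ld_r2(ld, rec$snp_id[i], rec$snp_id[near])
    present <- ld_key(rec$snp_id[i], rec$snp_id[near]) %in% names(ld$map)
    missing_pairs <- missing_pairs + sum(!present)
    active[near[r2 > config$clump_r2]] <- FALSE
  }
  if (missing_pairs > 0) {
    message(sprintf("clump: %d in-window pair(s) had no LD entry; treated as r2 = 0",
                    missing_pairs))
  }
  replace_records(stats, rec[keep, , drop = FALSE])
}

#' Remove blacklisted variants
#'
#' @param stats A [summary_stats] object.
#' @param blacklist Character vector of snp_ids to exclude.
#' @return A [summary_stats] subset; the removal count is messaged.
#' @export
apply_blacklist <- function(stats, blacklist = character()) {
  drop <- stats$records$snp_id %in% blacklist
  if (any(drop)) {
    message(sprintf("apply_blacklist: removed %d variant(s)", sum(drop)))
  }
  replace_records(stats, stats$records[!drop, , drop = FALSE])
}

#' Full instrument-selection pipeline
#'
#' Applies, in order: p-value thresholding, greedy LD clumping, the
#' F-statistic filter, and the confounder blacklist, recording the record
#' count surviving each stage so either ordering convention can be audited.
#'
#' @param stats Exposure [summary_stats].
#' @param ld Optional [ld_table].
#' @param config An [instrument_config].
#' @return List with `instruments` (a [summary_stats] subset) and `counts`
#'   (named integer vector of per-stage record counts).
#' @export
select_instruments <- function(stats, ld = NULL, config = instrument_config()) {
  counts <- c(input = n_records(stats))
  stats <- select_by_pvalue(stats, config$p_threshold)
  counts["p_threshold"] <- n_records(stats)
  if (n_records(stats) > 0 && !any(is.na(stats$records$chrom) | is.na(stats$records$pos))) {
    stats <- clump(stats, ld, config)
  }
  counts["clump"] <- n_records(stats)
  stats <- filter_weak_instruments(stats, config$f_min)
  counts["f_filter"] <- n_records(stats)
  stats <- apply_blacklist(stats, config$blacklist)
  counts["blacklist"] <- n_records(stats)
  list(instruments = stats, counts = counts)
}
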