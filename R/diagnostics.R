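#' Cochran's Q heterogeneity test
#'
#' Q = sum of w_j (beta_j - beta_IVW)² over the per-variant Wald ratios,
#' centred on the fixed-effect IVW estimate (the definitional centre — the
#' random-effects scale is itself derived from this Q), with J - 1 degrees of
#' freedom and an upper-tail chi-square p-value.
#'
#' @param set A `harmonized_set` with at least 2 kept records.
#' @param se_order Wald-ratio SE order.
#' @return List of class `heterogeneity_result`: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(set, se_order = 1) {
  r <- ratio_estimates(set, se_order)
  J <- nrow(r)
  if (J < 2) stop_insufficient("Cochran's Q", 2, J)
  bhat <- ivw_point(r$beta_ratio, r$weight)
  Q <- sum(r$weight * (r$beta_ratio - bhat)^2)
  structure(list(Q = Q, df = J - 1,
                 pvalue = pchisq(Q, df = J - 1, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g, df = %d, p = %.3g\n", x$Q, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect with each variant excluded in turn, flagging
#' whether any exclusion changes the sign of the estimate or moves its
#' p-value across the 0.05 significance line relative to the full-set
#' estimate.
#'
#' @param set A `harmonized_set` with at least 3 kept records.
#' @param model IVW model used throughout (match the primary analysis).
#' @param se_order Wald-ratio SE order.
#' @return List of class `loo_result`: `full` (the full-set `mr_estimate`),
#'   `table` (one row per excluded variant: snp_id, beta, se, ci, pvalue),
#'   `sign_change`, `significance_change`.
#' @export
leave_one_out <- function(set, model = "fixed", se_order = 1) {
  J <- nrow(set$records)
  if (J < 3) stop_insufficient("leave-one-out", 3, J)
  full <- mr_ivw(set, model = model, se_order = se_order)
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(subset_set(set, -j), model = model, se_order = se_order)
    data.frame(snp_id = set$records$snp_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(
    list(full = full, table = tab,
         sign_change = any(sign(tab$beta) != sign(full$beta)),
         significance_change = any((tab$pvalue < 0.05) != (full$pvalue < 0.05))),
    class = "loo_result"
  )
}

#' Funnel-plot coordinates
#'
#' One point per kept variant: the Wald ratio against its precision
#' (1 / ratio SE).  Symmetry of the scatter about the pooled estimate is the
#' visual check for directional small-instrument bias; no statistics are
#' computed here.
#'
#' @param set A `harmonized_set` with at least 1 kept record.
#' @param se_order Wald-ratio SE order.
#' @return Data frame with `snp_id`, `beta_ratio`, `precision`.
#' @export
funnel_coordinates <- function(set, se_order = 1) {
  r <- ratio_estimates(set, se_order)
  if (nrow(r) < 1) stop_insufficient("funnel coordinates", 1, nrow(r))
  data.frame(snp_id = r$snp_id, beta_ratio = r$beta_ratio,
             precision = 1 / r$se_ratio, stringsAsFactors = FALSE)
}
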