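#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' p_(i) by m/i, take the running minimum from the largest rank down, cap at
#' 1, and return in input order (delegates to [stats::p.adjust]).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.04, 0.8))
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is_probability(pvalues))) {
    stop_usage("all p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Classify an exposure-outcome association
#'
#' Significant: p < 0.05 and q < 0.1.  Suggestive: p < 0.05 and q >= 0.1
#' (the q = 0.1 boundary is assigned conservatively to suggestive).
#' Otherwise null.
#'
#' @param p Primary (IVW) p-value(s).
#' @param q BH-adjusted q-value(s).
#' @return Character vector: `"significant"`, `"suggestive"` or `"null"`.
#' @export
classify_association <- function(p, q) {
  if (any(!is_probability(p)) || any(!is_probability(q))) {
    stop_usage("p and q must lie in (0, 1]")
  }
  ifelse(p < 0.05 & q < 0.1, "significant",
         ifelse(p < 0.05, "suggestive", "null"))
}

#' Pipeline configuration
#'
#' Bundles the instrument-selection and estimator settings for
#' [run_pair()]/[run_batch()].
#'
#' @param instrument An [instrument_config].
#' @param estimator An [estimator_config].
#' @param strict_strand Drop strand-complement matches during harmonization
#'   instead of resolving them.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(instrument = instrument_config(),
                      estimator = estimator_config(),
                      strict_strand = FALSE) {
  structure(list(instrument = instrument, estimator = estimator,
                 strict_strand = strict_strand),
            class = "mr_config")
}

# All estimators applicable at the available instrument count, as a single
# estimates table.  Both IVW models are always computed (reports pick the
# columns they need); Egger/median/mode need >= 3 and PRESSO >= 4 records.
estimate_all <- function(set, config) {
  est <- config$estimator
  J <- nrow(set$records)
  rows <- list()
  extras <- list(egger_intercept = NULL, presso = NULL)
  if (J == 1) {
    wr <- wald_ratio(set$records[1, , drop = FALSE], est$wald_se_order)
    rows$wald <- mr_estimate("wald", wr$beta_ratio, wr$se_ratio, 1L)
  }
  if (J >= 2) {
    rows$ivw_fixed <- mr_ivw(set, "fixed", est$wald_se_order)
    rows$ivw_random <- mr_ivw(set, "random", est$wald_se_order)
  }
  if (J >= 3) {
    eg <- mr_egger(set)
    rows$egger <- eg$slope
    extras$egger_intercept <- eg$intercept
    rows$weighted_median <- mr_weighted_median(set, est)
    rows$weighted_mode <- mr_weighted_mode(set, est)
  }
  if (J >= 4) {
    pr <- mr_presso(set, est)
    extras$presso <- pr
    if (!is.null(pr$estimate)) {
      rows$presso <- pr$estimate
      rows$presso$method <- "presso"
    }
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  list(estimates = estimates, extras = extras)
}

primary_estimate <- function(set, estimates, config) {
  model <- config$estimator$ivw_model
  if (model == "auto" && "ivw_fixed" %in% estimates$method) {
    q <- cochran_q(set, config$estimator$wald_se_order)
    model <- if (q$pvalue < 0.05) "random" else "fixed"
  }
  wanted <- switch(model, fixed = "ivw_fixed", random = "ivw_random", "wald")
  if (!wanted %in% estimates$method) wanted <- estimates$method[1]
  estimates[estimates$method == wanted, , drop = FALSE]
}

#' Run the full MR pipeline for one exposure-outcome pair
#'
#' Selects instruments from the exposure statistics, harmonizes them with the
#' outcome, computes every applicable causal estimator and the heterogeneity,
#' pleiotropy, PRESSO and leave-one-out diagnostics, and records whether all
#' methods agree in direction.  Pairs that end up with too few instruments
#' for any estimate are returned as skipped records rather than errors.
#'
#' @param exposure Exposure [summary_stats].
#' @param outcome Outcome [summary_stats].
#' @param ld Optional [ld_table] for clumping.
#' @param config An [mr_config].
#' @return An object of class `mr_pair_result`: status, per-stage instrument
#'   counts, the estimates table, diagnostics, minimum instrument F, drop
#'   log, and the primary estimate used for multiple-testing correction.
#' @export
run_pair <- function(exposure, outcome, ld = NULL, config = mr_config()) {
  skipped <- function(reason) {
    structure(list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
                   status = "skipped", reason = reason),
              class = "mr_pair_result")
  }
  sel <- select_instruments(exposure, ld, config$instrument)
  if (n_records(sel$instruments) == 0) {
    return(skipped("no instruments passed selection"))
  }
  set <- tryCatch(
    build_instrument_set(sel$instruments, outcome, strict = config$strict_strand),
    mrbiome_empty_set_error = function(e) NULL
  )
  if (is.null(set)) return(skipped("no harmonizable instruments"))

  fit <- estimate_all(set, config)
  J <- nrow(set$records)
  heterogeneity <- if (J >= 2) cochran_q(set, config$estimator$wald_se_order) else NULL
  loo <- if (J >= 3) {
    leave_one_out(set, model = "fixed", se_order = config$estimator$wald_se_order)
  }
  primary <- primary_estimate(set, fit$estimates, config)
  directions <- sign(fit$estimates$beta)
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         status = "ok", n_snp = J,
         counts = c(sel$counts, harmonized = J),
         estimates = fit$estimates,
         primary = primary,
         heterogeneity = heterogeneity,
         pleiotropy = fit$extras$egger_intercept,
         presso = fit$extras$presso,
         loo = loo,
         funnel = funnel_coordinates(set, config$estimator$wald_se_order),
         min_f = min(set$records$f_stat),
         direction_consistent = length(unique(directions[directions != 0])) <= 1,
         drop_log = set$drop_log,
         set = set),
    class = "mr_pair_result"
  )
}

#' @export
print.mr_pair_result <- function(x, ...) {
  cat(sprintf("<mr_pair_result> %s -> %s [%s]\n", x$exposure_id, x$outcome_id, x$status))
  if (x$status == "ok") {
    cat(sprintf("  %d instruments (min F = %.2f)\n", x$n_snp, x$min_f))
    print(x$estimates[, c("method", "n_snp", "beta", "se", "pvalue", "or",
                          "or_ci_low", "or_ci_high")], digits = 4)
    if (!is.null(x$heterogeneity)) print(x$heterogeneity)
    if (!is.null(x$pleiotropy)) print(x$pleiotropy)
  } else {
    cat(sprintf("  reason: %s\n", x$reason))
  }
  invisible(x)
}

#' Run a batch of exposures against one outcome with FDR classification
#'
#' Runs [run_pair()] for every exposure, then applies Benjamini-Hochberg
#' correction to the primary IVW p-values.  The FDR family is all exposures
#' tested against this outcome (taxa within one disease), and classification
#' is invariant to exposure ordering.
#'
#' @param exposures List of exposure [summary_stats] objects.
#' @param outcome Outcome [summary_stats].
#' @param ld Optional [ld_table].
#' @param config An [mr_config].
#' @return An object of class `mr_batch`: `pairs` (per-exposure
#'   `mr_pair_result`s) and `fdr` (exposure, outcome, pvalue, q, class).
#' @export
run_batch <- function(exposures, outcome, ld = NULL, config = mr_config()) {
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  if (length(exposures) < 1) stop_usage("need at least one exposure")
  pairs <- lapply(exposures, run_pair, outcome = outcome, ld = ld, config = config)
  ok <- vapply(pairs, function(p) p$status == "ok", logical(1))
  fdr <- data.frame(
    exposure = vapply(pairs, `[[`, "", "exposure_id"),
    outcome = outcome$trait_id,
    pvalue = NA_real_, q = NA_real_, class = NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(ok)) {
    p <- vapply(pairs[ok], function(x) x$primary$pvalue, numeric(1))
    q <- bh_fdr(p)
    fdr$pvalue[ok] <- p
    fdr$q[ok] <- q
    fdr$class[ok] <- classify_association(p, q)
    for (i in which(ok)) {
      pairs[[i]]$fdr <- fdr[i, , drop = FALSE]
    }
  }
  structure(list(pairs = pairs, fdr = fdr, outcome_id = outcome$trait_id,
                 config = config),
            class = "mr_batch")
}

#' @export
print.mr_batch <- function(x, ...) {
  cat(sprintf("<mr_batch> %d exposures -> %s\n", length(x$pairs), x$outcome_id))
  print(x$fdr, digits = 4)
  invisible(x)
}

#' Reverse-direction MR
#'
#' Re-runs the identical pipeline with the roles swapped: instruments are
#' selected for the disease trait and the taxon abundance becomes the
#' outcome, probing reverse causation for taxa with a forward signal.
#'
#' @param outcome_as_exposure The disease [summary_stats], now the exposure.
#' @param exposure_as_outcome The taxon [summary_stats], now the outcome.
#' @param ld Optional [ld_table].
#' @param config An [mr_config].
#' @return An `mr_pair_result` with attribute `direction = "reverse"`.
#' @export
run_reverse <- function(outcome_as_exposure, exposure_as_outcome, ld = NULL,
                        config = mr_config()) {
  res <- run_pair(outcome_as_exposure, exposure_as_outcome, ld = ld, config = config)
  attr(res, "direction") <- "reverse"
  res
}

METHOD_LABELS <- c(
  wald = "Wald ratio", ivw_fixed = "IVW (fixed)", ivw_random = "IVW (random)",
  egger = "MR-Egger (slope)", weighted_median = "Weighted median",
  weighted_mode = "Weighted mode", presso = "MR-PRESSO",
  presso_corrected = "MR-PRESSO (corrected)"
)

#' Flatten MR results into a publication-style table
#'
#' One row per (exposure, outcome, method) with the odds-ratio scale
#' estimate, Cochran's Q, the PRESSO global statistic, the Egger intercept
#' and the minimum instrument F — the layout of a standard MR results table.
#'
#' @param x An `mr_pair_result` or `mr_batch`.
#' @return Data frame ready for [write_results_table()].
#' @export
results_table <- function(x) {
  if (inherits(x, "mr_batch")) {
    out <- do.call(rbind, lapply(x$pairs, results_table))
    rownames(out) <- NULL
    return(out)
  }
  if (!inherits(x, "mr_pair_result")) stop_usage("expected mr_pair_result or mr_batch")
  if (x$status != "ok") {
    return(data.frame(exposure = x$exposure_id, outcome = x$outcome_id,
                      method = "skipped", n_snp = 0L, beta = NA_real_,
                      se = NA_real_, pvalue = NA_real_, or = NA_real_,
                      or_ci_low = NA_real_, or_ci_high = NA_real_,
                      cochran_q = NA_real_, cochran_q_pvalue = NA_real_,
                      presso_rss = NA_real_, presso_global_pvalue = NA_real_,
                      egger_intercept = NA_real_, egger_intercept_pvalue = NA_real_,
                      f_min = NA_real_, qvalue = NA_real_, class = NA_character_,
                      stringsAsFactors = FALSE))
  }
  est <- x$estimates
  data.frame(
    exposure = x$exposure_id, outcome = x$outcome_id,
    method = unname(METHOD_LABELS[est$method]),
    n_snp = est$n_snp, beta = est$beta, se = est$se, pvalue = est$pvalue,
    or = est$or, or_ci_low = est$or_ci_low, or_ci_high = est$or_ci_high,
    cochran_q = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$Q,
    cochran_q_pvalue = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$pvalue,
    presso_rss = if (is.null(x$presso)) NA_real_ else x$presso$rss_obs,
    presso_global_pvalue = if (is.null(x$presso)) NA_real_ else x$presso$global_pvalue,
    egger_intercept = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$intercept,
    egger_intercept_pvalue = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$pvalue,
    f_min = x$min_f,
    qvalue = if (is.null(x$fdr)) NA_real_ else x$fdr$q,
    class = if (is.null(x$fdr)) NA_character_ else x$fdr$class,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Reverse-MR report table
#'
#' Both fixed- and random-effects IVW rows on the beta scale with 95%
#' confidence bounds, the layout used when reporting reverse-direction
#' analyses.
#'
#' @param x An `mr_pair_result` from [run_reverse()].
#' @return Data frame: exposure, outcome, method, beta, se, ci_low, ci_high,
#'   pvalue.
#' @export
reverse_table <- function(x) {
  if (x$status != "ok") {
    return(data.frame(exposure = x$exposure_id, outcome = x$outcome_id,
                      method = "skipped", beta = NA_real_, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                      stringsAsFactors = FALSE))
  }
  est <- x$estimates[x$estimates$method %in% c("ivw_fixed", "ivw_random", "wald"), ]
  data.frame(exposure = x$exposure_id, outcome = x$outcome_id,
             method = unname(METHOD_LABELS[est$method]),
             beta = est$beta, se = est$se, ci_low = est$ci_low,
             ci_high = est$ci_high, pvalue = est$pvalue,
             stringsAsFactors = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and per-stage instrument counts of a run
#' as JSON so analyses can be audited and reproduced.
#'
#' @param path Output path.
#' @param config The [mr_config] used.
#' @param seed The RNG seed of the run.
#' @param counts Named count vector(s) (e.g. per-stage instrument counts).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, seed = NULL, counts = NULL) {
  manifest <- list(
    package = "mrbiome",
    version = as.character(utils::packageVersion("mrbiome")),
    seed = seed,
    config = unclass_deep(config),
    counts = as.list(counts)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
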