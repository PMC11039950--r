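# Leave-one-out IVW slopes for every variant at once, from the weighted
# cross-product sums (weights 1/sigma_y^2, i.e. the regression-through-origin
# form of the fixed-effect IVW estimate).
loo_slopes <- function(gamma, Gamma, w) {
  a <- gamma * Gamma * w
  b <- gamma^2 * w
  (sum(a) - a) / (sum(b) - b)
}

#' MR-PRESSO residual-sum-of-squares outlier analysis
#'
#' A simulation-based horizontal-pleiotropy framework with three parts:
#'
#' * **Global test** — each variant's observed residual is taken about its
#'   leave-one-out IVW slope, and the weighted residual sum of squares
#'   (weights 1/sigma_Y²) is compared with `presso_k` parametric simulations
#'   of the no-pleiotropy model.
#' * **Outlier test** — each variant's weighted squared residual is compared
#'   with its simulated distribution; p-values use the add-one rule
#'   (1 + count)/(K + 1) and are Bonferroni-adjusted across variants.
#' * **Distortion test** — the outlier-corrected IVW estimate is compared
#'   with the all-variant estimate, with a resampling p-value from random
#'   same-size exclusions.
#'
#' @param set A `harmonized_set` with at least 4 kept records.
#' @param config An [estimator_config] (`presso_k`, `presso_outlier_alpha`,
#'   `seed`).
#' @return List of class `presso_result`: `rss_obs`, `global_pvalue`,
#'   `outliers` (per-variant table), `n_outliers`, `estimate` (IVW on
#'   non-outliers when outliers were found, otherwise the all-variant IVW),
#'   `raw_estimate`, `distortion` (coefficient in percent and p-value, `NA`
#'   when no outliers), `k`, `n_snp`.  When every variant is flagged the
#'   corrected estimate is `NULL`.
#' @export
mr_presso <- function(set, config = estimator_config()) {
  rec <- set$records
  J <- nrow(rec)
  if (J < 4) stop_insufficient("MR-PRESSO", 4, J)
  K <- config$presso_k
  w <- 1 / rec$sigma_y^2

  b_loo <- loo_slopes(rec$gamma, rec$Gamma, w)
  resid <- rec$Gamma - b_loo * rec$gamma
  obs_stat <- w * resid^2
  rss_obs <- sum(obs_stat)

  sim <- with_preserved_seed(config$seed, {
    g_star <- matrix(rnorm(K * J, mean = rep(rec$gamma, each = K),
                           sd = rep(rec$sigma_x, each = K)), K, J)
    G_star <- matrix(rnorm(K * J, mean = rep(b_loo * rec$gamma, each = K),
                           sd = rep(rec$sigma_y, each = K)), K, J)
    wmat <- matrix(w, K, J, byrow = TRUE)
    a <- g_star * G_star * wmat
    b <- g_star^2 * wmat
    bloo_star <- (rowSums(a) - a) / (rowSums(b) - b)
    stat_star <- wmat * (G_star - bloo_star * g_star)^2
    list(rss = rowSums(stat_star),
         exceed = colSums(stat_star >= matrix(obs_stat, K, J, byrow = TRUE)))
  })

  global_pvalue <- (1 + sum(sim$rss >= rss_obs)) / (K + 1)
  p_snp <- (1 + sim$exceed) / (K + 1)
  p_adj <- pmin(1, p_snp * J)
  is_outlier <- p_adj < config$presso_outlier_alpha
  outliers <- data.frame(snp_id = rec$snp_id, obs_stat = obs_stat,
                         pvalue = p_snp, p_adj = p_adj,
                         is_outlier = is_outlier, stringsAsFactors = FALSE)

  raw_estimate <- mr_ivw(set, model = "fixed", se_order = config$wald_se_order)
  n_out <- sum(is_outlier)
  corrected <- NULL
  distortion <- list(coefficient = NA_real_, pvalue = NA_real_)
  if (n_out == 0) {
    corrected <- raw_estimate
  } else if (n_out < J - 1) {
    kept_set <- subset_set(set, !is_outlier)
    corrected <- mr_ivw(kept_set, model = "fixed", se_order = config$wald_se_order)
    b_all <- raw_estimate$beta
    b_corr <- corrected$beta
    d_obs <- 100 * (b_corr - b_all) / abs(b_corr)
    r <- ratio_estimates(set, config$wald_se_order)
    d_sim <- with_preserved_seed(config$seed, {
      vapply(seq_len(K), function(k) {
        drop <- sample.int(J, n_out)
        b_sub <- ivw_point(r$beta_ratio[-drop], r$weight[-drop])
        100 * (b_sub - b_all) / abs(b_sub)
      }, numeric(1))
    })
    distortion <- list(coefficient = d_obs,
                       pvalue = (1 + sum(abs(d_sim) >= abs(d_obs))) / (K + 1))
  }
  if (!is.null(corrected) && n_out > 0) corrected$method <- "presso_corrected"

  structure(
    list(rss_obs = rss_obs, global_pvalue = global_pvalue,
         outliers = outliers, n_outliers = n_out,
         estimate = corrected, raw_estimate = raw_estimate,
         distortion = distortion, k = K, n_snp = J),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.3g (K = %d, J = %d)\n",
              x$rss_obs, x$global_pvalue, x$k, x$n_snp))
  cat(sprintf("  outliers flagged: %d\n", x$n_outliers))
  if (is.null(x$estimate)) {
    cat("  corrected estimate undefined (all variants flagged)\n")
  } else if (x$n_outliers > 0) {
    cat(sprintf("  corrected beta = %.4g (distortion %.1f%%, p = %.3g)\n",
                x$estimate$beta, x$distortion$coefficient, x$distortion$pvalue))
  }
  invisible(x)
}
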