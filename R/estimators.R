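#' Estimator configuration
#'
#' Tuning constants for the stochastic estimators: the parametric bootstrap
#' behind the weighted-median and weighted-mode standard errors, the
#' mode-estimator bandwidth multiplier, and the PRESSO simulation count.
#'
#' @param n_boot Bootstrap iterations for median/mode standard errors
#'   (minimum 100).
#' @param seed Optional RNG seed; when set, each stochastic estimator runs
#'   under its own restored RNG state so results are reproducible and outer
#'   simulations are not perturbed.
#' @param phi Mode bandwidth multiplier (1 = modified Silverman rule).
#' @param presso_k PRESSO simulation count K (minimum 100).
#' @param presso_outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-variant outlier test.
#' @param ivw_model `"auto"` (random effects iff Cochran's Q p < 0.05),
#'   `"fixed"` or `"random"` — the model whose p-value feeds downstream
#'   multiple-testing correction.
#' @param wald_se_order 1 for the first-order ratio SE (sigma_y / |gamma|),
#'   2 to add the exposure-side term.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(n_boot = 1000, seed = NULL, phi = 1,
                             presso_k = 1000, presso_outlier_alpha = 0.05,
                             ivw_model = c("auto", "fixed", "random"),
                             wald_se_order = 1) {
  assert_scalar_number(n_boot, "n_boot", min = 100)
  assert_scalar_number(phi, "phi", min = 1e-9)
  assert_scalar_number(presso_k, "presso_k", min = 100)
  assert_scalar_number(presso_outlier_alpha, "presso_outlier_alpha", min = 0, max = 1)
  if (!wald_se_order %in% c(1, 2)) stop_usage("`wald_se_order` must be 1 or 2")
  structure(list(n_boot = as.integer(n_boot), seed = seed, phi = phi,
                 presso_k = as.integer(presso_k),
                 presso_outlier_alpha = presso_outlier_alpha,
                 ivw_model = match.arg(ivw_model),
                 wald_se_order = as.integer(wald_se_order)),
            class = "estimator_config")
}

# Single-row causal-estimate record shared by all methods.
mr_estimate <- function(method, beta, se, n_snp) {
  est <- data.frame(
    method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
    ci_low = beta - .z95 * se, ci_high = beta + .z95 * se,
    pvalue = 2 * pnorm(-abs(beta / se)),
    or = exp(beta), or_ci_low = exp(beta - .z95 * se),
    or_ci_high = exp(beta + .z95 * se),
    stringsAsFactors = FALSE
  )
  class(est) <- c("mr_estimate", "data.frame")
  est
}

#' Per-variant Wald ratio estimate
#'
#' beta_j = Gamma_j / gamma_j with first-order standard error
#' sigma_Yj / |gamma_j| (order 2 adds the exposure-noise term
#' Gamma² sigma_X² / gamma⁴).  The inverse-variance weight is 1/se².
#'
#' @param record One-row kept record from a harmonized set.
#' @param se_order 1 (default) or 2.
#' @return List with `snp_id`, `beta_ratio`, `se_ratio`, `weight`.
#' @export
wald_ratio <- function(record, se_order = 1) {
  if (record$gamma == 0) {
    mrb_error(sprintf("degenerate instrument %s: exposure effect is 0", record$snp_id),
              "mrbiome_degenerate_error")
  }
  r <- ratio_estimates_raw(record$gamma, record$sigma_x, record$Gamma,
                           record$sigma_y, se_order)
  list(snp_id = record$snp_id, beta_ratio = r$beta_ratio,
       se_ratio = r$se_ratio, weight = r$weight)
}

ratio_estimates_raw <- function(gamma, sigma_x, Gamma, sigma_y, se_order = 1) {
  beta_ratio <- Gamma / gamma
  se_ratio <- if (se_order == 1) {
    sigma_y / abs(gamma)
  } else {
    sqrt(sigma_y^2 / gamma^2 + Gamma^2 * sigma_x^2 / gamma^4)
  }
  list(beta_ratio = beta_ratio, se_ratio = se_ratio, weight = 1 / se_ratio^2)
}

# Ratio table for a whole set.
ratio_estimates <- function(set, se_order = 1) {
  rec <- set$records
  if (any(rec$gamma == 0)) {
    mrb_error("degenerate instrument: exposure effect is 0", "mrbiome_degenerate_error")
  }
  r <- ratio_estimates_raw(rec$gamma, rec$sigma_x, rec$Gamma, rec$sigma_y, se_order)
  data.frame(snp_id = rec$snp_id, beta_ratio = r$beta_ratio,
             se_ratio = r$se_ratio, weight = r$weight, stringsAsFactors = FALSE)
}

ivw_point <- function(beta_ratio, weight) sum(weight * beta_ratio) / sum(weight)

#' Inverse-variance weighted estimate
#'
#' Pools the per-variant Wald ratios by inverse-variance weighting, the
#' meta-analysis form of the two-sample MR estimate.  The fixed-effect SE is
#' (sum of weights)^(-1/2); the multiplicative random-effects SE scales it by
#' max(1, sqrt(Q / (J - 1))) and never shrinks below the fixed-effect SE;
#' `"auto"` selects random effects iff Cochran's Q has p < 0.05.  P-values
#' and confidence intervals use the normal distribution.
#'
#' @param set A `harmonized_set` with at least 2 kept records.
#' @param model `"fixed"`, `"random"` or `"auto"`.
#' @param se_order Wald-ratio SE order (see [wald_ratio]).
#' @return An `mr_estimate` row (method `ivw_fixed` or `ivw_random`).
#' @examples
#' set <- harmonized_set(gamma = c(0.10, 0.05), sigma_x = c(0.01, 0.01),
#'                       Gamma = c(0.05, 0.015), sigma_y = c(0.01, 0.01))
#' mr_ivw(set, "fixed")
#' @export
mr_ivw <- function(set, model = c("auto", "fixed", "random"), se_order = 1) {
  model <- match.arg(model)
  r <- ratio_estimates(set, se_order)
  J <- nrow(r)
  if (J < 2) stop_insufficient("IVW", 2, J)
  bhat <- ivw_point(r$beta_ratio, r$weight)
  se_fixed <- sqrt(1 / sum(r$weight))
  Q <- sum(r$weight * (r$beta_ratio - bhat)^2)
  if (model == "auto") {
    q_p <- pchisq(Q, df = J - 1, lower.tail = FALSE)
    model <- if (q_p < 0.05) "random" else "fixed"
  }
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  mr_estimate(paste0("ivw_", model), bhat, se, J)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome effects on the exposure
#' effects with a free intercept, each record first oriented so the exposure
#' effect is non-negative.  Weights are 1/sigma_Y²; both standard errors are
#' scaled by max(1, residual SD) (multiplicative random effects).  A nonzero
#' intercept indicates directional horizontal pleiotropy; the slope is the
#' pleiotropy-adjusted causal estimate.
#'
#' @param set A `harmonized_set` with at least 3 kept records.
#' @return List of class `mr_egger_result` with `slope` (an `mr_estimate`)
#'   and `intercept` (class `pleiotropy_result`: intercept, se, pvalue,
#'   n_snp).
#' @export
mr_egger <- function(set) {
  rec <- set$records
  J <- nrow(rec)
  if (J < 3) stop_insufficient("MR-Egger", 3, J)
  s <- ifelse(rec$gamma < 0, -1, 1)
  g <- rec$gamma * s
  G <- rec$Gamma * s
  w <- 1 / rec$sigma_y^2
  fit <- lm(G ~ g, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  se <- sqrt(diag(sm$cov.unscaled)) * scale
  b <- coef(fit)
  intercept <- structure(
    list(intercept = unname(b[1]), se = unname(se[1]),
         pvalue = 2 * pnorm(-abs(b[1] / se[1])), n_snp = J),
    class = "pleiotropy_result"
  )
  structure(list(slope = mr_estimate("egger", unname(b[2]), unname(se[2]), J),
                 intercept = intercept),
            class = "mr_egger_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept %.4g (se %.4g, p = %.3g, J = %d)\n",
              x$intercept, x$se, x$pvalue, x$n_snp))
  invisible(x)
}

# Weighted-median point estimate: the ratio value at the 50% point of the
# cumulative inverse-variance weight distribution, linearly interpolated
# between the bracketing order statistics.
weighted_median_point <- function(beta_ratio, weight) {
  o <- order(beta_ratio)
  b <- beta_ratio[o]
  u <- weight[o] / sum(weight)
  cs <- cumsum(u) - u / 2
  if (0.5 <= cs[1]) return(b[1])
  n <- length(b)
  if (0.5 >= cs[n]) return(b[n])
  k <- max(which(cs < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - cs[k]) / (cs[k + 1] - cs[k])
}

# Weighted-mode point estimate: argmax of a weighted Gaussian kernel density
# over the ratio estimates, evaluated on a 512-point grid spanning
# [min - 3h, max + 3h].  Bandwidth h = phi * 0.9 * min(sd, mad/0.6745) *
# J^(-1/5) (modified Silverman; R's mad() already rescales to
# SD-consistency).  Degenerate spreads fall back to the SD, and identical
# ratios return the common value.
weighted_mode_point <- function(beta_ratio, weight, phi = 1) {
  u <- weight / sum(weight)
  J <- length(beta_ratio)
  s <- suppressWarnings(min(sd(beta_ratio), mad(beta_ratio)))
  if (!is.finite(s) || s == 0) s <- sd(beta_ratio)
  if (!is.finite(s) || s == 0) return(beta_ratio[1])
  h <- phi * 0.9 * s * J^(-1 / 5)
  grid <- seq(min(beta_ratio) - 3 * h, max(beta_ratio) + 3 * h, length.out = 512)
  z <- outer(beta_ratio, grid, "-") / h
  dens <- colSums(u * dnorm(z))
  grid[which.max(dens)]
}

# Parametric bootstrap SE shared by the median and mode estimators: redraw
# (gamma, Gamma) from normals centred on the observed effects with the
# observed SEs, re-derive ratios and weights, and re-estimate.
bootstrap_se <- function(set, config, point_fun) {
  rec <- set$records
  J <- nrow(rec)
  n_boot <- config$n_boot
  with_preserved_seed(config$seed, {
    g <- matrix(rnorm(n_boot * J, mean = rep(rec$gamma, each = n_boot),
                      sd = rep(rec$sigma_x, each = n_boot)), n_boot, J)
    G <- matrix(rnorm(n_boot * J, mean = rep(rec$Gamma, each = n_boot),
                      sd = rep(rec$sigma_y, each = n_boot)), n_boot, J)
    est <- vapply(seq_len(n_boot), function(i) {
      r <- ratio_estimates_raw(g[i, ], rec$sigma_x, G[i, ], rec$sigma_y,
                               config$wald_se_order)
      point_fun(r$beta_ratio, r$weight)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median causal estimate
#'
#' Consistent when valid instruments carry at least half of the total
#' inverse-variance weight.  The standard error comes from a parametric
#' bootstrap (`n_boot` redraws of the per-variant effects).
#'
#' @param set A `harmonized_set` with at least 3 kept records.
#' @param config An [estimator_config].
#' @return An `mr_estimate` row (method `weighted_median`).
#' @export
mr_weighted_median <- function(set, config = estimator_config()) {
  r <- ratio_estimates(set, config$wald_se_order)
  if (nrow(r) < 3) stop_insufficient("weighted median", 3, nrow(r))
  beta <- weighted_median_point(r$beta_ratio, r$weight)
  se <- bootstrap_se(set, config, weighted_median_point)
  mr_estimate("weighted_median", beta, se, nrow(r))
}

#' Weighted-mode causal estimate
#'
#' Mode of the kernel-smoothed ratio distribution; consistent when the
#' largest cluster of similar ratio estimates comes from valid instruments
#' (ZEMPA).  Bandwidth h = phi * 0.9 * min(sd, mad) * J^(-1/5), argmax taken
#' on a 512-point grid spanning the ratios plus three bandwidths; the SE
#' uses the same parametric bootstrap as the weighted median.
#'
#' @param set A `harmonized_set` with at least 3 kept records.
#' @param config An [estimator_config]; `phi` scales the bandwidth.
#' @return An `mr_estimate` row (method `weighted_mode`).
#' @export
mr_weighted_mode <- function(set, config = estimator_config()) {
  r <- ratio_estimates(set, config$wald_se_order)
  if (nrow(r) < 3) stop_insufficient("weighted mode", 3, nrow(r))
  phi <- config$phi
  beta <- weighted_mode_point(r$beta_ratio, r$weight, phi)
  se <- bootstrap_se(set, config, function(b, w) weighted_mode_point(b, w, phi))
  mr_estimate("weighted_mode", beta, se, nrow(r))
}

#' Odds-ratio scale conversion
#'
#' @param beta Log odds ratio estimate(s).
#' @param se Standard error(s), >= 0.
#' @return List with `or`, `ci_low`, `ci_high` (95% Wald interval,
#'   exp-transformed).
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se < 0)) stop_usage("`se` must be >= 0")
  list(or = exp(beta), ci_low = exp(beta - .z95 * se),
       ci_high = exp(beta + .z95 * se))
}
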