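test_that("BH adjustment reproduces the hand-worked step-up example", {
  q <- bh_fdr(c(0.001, 0.02, 0.04, 0.8))
  expect_equal(q, c(0.004, 0.04, 0.04 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 0)), class = "mrbiome_usage_error")
  expect_error(bh_fdr(c(0.1, 1.2)), class = "mrbiome_usage_error")
})

test_that("association classes follow the p/q gates with q = 0.1 suggestive", {
  expect_equal(classify_association(4.3e-4, 0.02), "significant")
  expect_equal(classify_association(0.01, 0.5), "suggestive")
  expect_equal(classify_association(0.2, 0.05), "null")
  expect_equal(classify_association(0.01, 0.1), "suggestive")
  expect_equal(classify_association(c(0.01, 0.3), c(0.05, 0.05)),
               c("significant", "null"))
})

fast_config <- function(seed = 1) {
  mr_config(estimator = estimator_config(n_boot = 100, presso_k = 100, seed = seed))
}

test_that("run_pair produces a coherent full analysis for a causal pair", {
  sim <- simulate_pair(synthetic_config(J = 15, beta0 = -0.4, tau = 0.05,
                                        n_x = 5e5, n_y = 12682, seed = 61))
  res <- run_pair(sim$exposure, sim$outcome, config = fast_config())
  expect_equal(res$status, "ok")
  expect_equal(res$n_snp, 15)
  expect_setequal(res$estimates$method,
                  c("ivw_fixed", "ivw_random", "egger", "weighted_median",
                    "weighted_mode", "presso"))
  ivw <- res$estimates[res$estimates$method == "ivw_fixed", ]
  expect_lt(ivw$ci_high, 0)
  expect_true(res$direction_consistent)
  expect_true(all(res$estimates$beta < 0))
  expect_equal(res$min_f, min(res$set$records$f_stat))
  expect_gte(res$min_f, qnorm(5e-6, lower.tail = FALSE)^2)
})

test_that("a two-instrument pair reports IVW and Q but skips the J>=3 methods", {
  sim <- simulate_pair(synthetic_config(J = 2, beta0 = 0.2, seed = 62))
  res <- run_pair(sim$exposure, sim$outcome, config = fast_config())
  expect_equal(res$status, "ok")
  expect_setequal(res$estimates$method, c("ivw_fixed", "ivw_random"))
  expect_false(is.null(res$heterogeneity))
  expect_null(res$pleiotropy)
  expect_null(res$presso)
  expect_null(res$loo)
})

test_that("pairs without harmonizable instruments are skipped, not fatal", {
  sim <- simulate_pair(synthetic_config(J = 5, seed = 63))
  other <- simulate_pair(synthetic_config(J = 5, seed = 64))$outcome
  res <- run_pair(sim$exposure, other, config = fast_config())
  expect_equal(res$status, "skipped")
  expect_match(res$reason, "harmoniz")
})

test_that("batch FDR classification is exposure-order invariant", {
  cfgs <- c(
    list(synthetic_config(J = 12, beta0 = -0.6, tau = 0.05, n_x = 5e5,
                          n_y = 12682, seed = 65, exposure_id = "causal_taxon")),
    lapply(1:9, function(i) {
      synthetic_config(J = 12, beta0 = 0, tau = 0.05, n_x = 5e5, n_y = 12682,
                       seed = 165 + i, exposure_id = paste0("null_taxon", i))
    })
  )
  sims <- lapply(seq_along(cfgs), function(i) {
    s <- simulate_pair(cfgs[[i]])
    # namespace variant ids so independently simulated loci never collide
    s$exposure$records$snp_id <- paste0("t", i, "_", s$exposure$records$snp_id)
    s$outcome$records$snp_id <- paste0("t", i, "_", s$outcome$records$snp_id)
    s
  })
  exposures <- lapply(sims, `[[`, "exposure")
  # one outcome covering every exposure's variants (per-taxon effects were
  # generated against the same disease model)
  outcome <- summary_stats(
    do.call(rbind, lapply(sims, function(s) s$outcome$records)),
    trait_id = "disease", trait_type = "binary"
  )
  batch <- run_batch(exposures, outcome, config = fast_config())
  fdr <- batch$fdr
  expect_equal(fdr$class[fdr$exposure == "causal_taxon"], "significant")
  expect_true(all(fdr$class[fdr$exposure != "causal_taxon"] != "significant"))

  perm <- rev(seq_along(exposures))
  batch2 <- run_batch(exposures[perm], outcome, config = fast_config())
  reordered <- batch2$fdr[match(fdr$exposure, batch2$fdr$exposure), ]
  expect_equal(reordered$q, fdr$q)
  expect_equal(reordered$class, fdr$class)
})

test_that("single and duplicated exposures degenerate correctly under BH", {
  sim <- simulate_pair(synthetic_config(J = 8, beta0 = -0.3, seed = 66))
  one <- run_batch(list(sim$exposure), sim$outcome, config = fast_config())
  expect_equal(one$fdr$q, one$fdr$pvalue)

  five <- run_batch(rep(list(sim$exposure), 5), sim$outcome, config = fast_config())
  expect_equal(length(unique(five$fdr$q)), 1)
  expect_equal(five$fdr$q[1], five$fdr$pvalue[1])
})

test_that("reverse MR is the pipeline with roles swapped", {
  fwd <- simulate_pair(synthetic_config(J = 10, beta0 = 0, seed = 67,
                                        exposure_id = "disease",
                                        outcome_id = "taxon"))
  rev1 <- run_reverse(fwd$exposure, fwd$outcome, config = fast_config())
  plain <- run_pair(fwd$exposure, fwd$outcome, config = fast_config())
  expect_equal(attr(rev1, "direction"), "reverse")
  expect_equal(rev1$estimates, plain$estimates)
  tab <- reverse_table(rev1)
  expect_setequal(tab$method, c("IVW (fixed)", "IVW (random)"))
  expect_equal(tab$exposure, rep("disease", 2))
})

test_that("the run manifest records config, seed and counts as JSON", {
  path <- tempfile(fileext = ".json")
  cfg <- fast_config()
  write_manifest(path, cfg, seed = 7, counts = c(input = 10, kept = 8))
  m <- jsonlite::read_json(path)
  expect_equal(m$seed, 7)
  expect_equal(m$counts$kept, 8)
  expect_equal(m$config$instrument$p_threshold, 1e-5)
})
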