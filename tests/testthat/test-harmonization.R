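va <- function(snp = "rs1", ea, oa, beta = 0.1, se = 0.02, p = 1e-6, eaf = 0.3) {
  data.frame(snp_id = snp, chrom = "1", pos = 1000, effect_allele = ea,
             other_allele = oa, beta = beta, se = se, pvalue = p, eaf = eaf,
             n = 10000, stringsAsFactors = FALSE)
}

test_that("palindrome detection covers exactly the A/T and C/G pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
})

test_that("pairwise harmonization resolves all allele orientations", {
  # hand-enumerated orientation oracle for an A/G exposure with beta 0.1:
  # outcome alleles -> (action, harmonized outcome beta)
  exposure <- va(ea = "A", oa = "G", beta = 0.1)
  cases <- list(
    list(ea = "A", oa = "G", action = "kept", Gamma = -0.05),   # identity
    list(ea = "G", oa = "A", action = "flipped", Gamma = 0.05), # swap
    list(ea = "T", oa = "C", action = "kept", Gamma = -0.05),   # strand flip
    list(ea = "C", oa = "T", action = "flipped", Gamma = 0.05), # flip + swap
    list(ea = "A", oa = "C", action = "dropped_incompatible", Gamma = NA_real_)
  )
  for (cs in cases) {
    h <- harmonize_pair(exposure, va(ea = cs$ea, oa = cs$oa, beta = -0.05))
    expect_equal(h$action, cs$action)
    expect_equal(h$Gamma, cs$Gamma)
  }
  # for a C/T exposure, G/A is the strand complement of the identity
  # orientation (kept, no flip) while A/G complements the swap (flipped)
  h <- harmonize_pair(va(ea = "C", oa = "T", beta = 0.1),
                      va(ea = "G", oa = "A", beta = -0.05))
  expect_equal(h$action, "kept")
  expect_equal(h$Gamma, -0.05)
  h <- harmonize_pair(va(ea = "C", oa = "T", beta = 0.1),
                      va(ea = "A", oa = "G", beta = -0.05))
  expect_equal(h$action, "flipped")
  expect_equal(h$Gamma, 0.05)

  # palindromic exposures are always dropped, whatever the frequency
  h <- harmonize_pair(va(ea = "A", oa = "T"), va(ea = "A", oa = "T", eaf = 0.1))
  expect_equal(h$action, "dropped_palindromic")

  # strict mode refuses strand-complement rescues
  h <- harmonize_pair(exposure, va(ea = "T", oa = "C"), strict = TRUE)
  expect_equal(h$action, "dropped_incompatible")

  expect_error(harmonize_pair(va("rs1", "A", "G"), va("rs2", "A", "G")),
               "mismatch", class = "mrbiome_usage_error")
})

test_that("swap harmonization reflects the effect-allele frequency", {
  h <- harmonize_pair(va(ea = "A", oa = "G"), va(ea = "G", oa = "A", eaf = 0.3))
  expect_equal(h$eaf_outcome, 0.7)
})

test_that("instrument sets join on snp_id and account for every input", {
  sim <- simulate_pair(synthetic_config(J = 5, beta0 = 0.2, seed = 21))
  set <- build_instrument_set(sim$exposure, sim$outcome)
  expect_equal(nrow(set$records), 5)

  # one instrument missing from the outcome
  out <- sim$outcome
  out$records <- out$records[-3, ]
  set4 <- build_instrument_set(sim$exposure, out)
  expect_equal(nrow(set4$records), 4)
  expect_equal(set4$drop_log$action[3], "dropped_unmatched")

  # conservation: |kept| + |dropped| = |instruments|
  expect_equal(nrow(set4$records) + sum(set4$drop_log$action != "kept"), 5)

  # all instruments unharmonizable -> informative empty-set error
  out$records <- out$records[0, ]
  expect_error(build_instrument_set(sim$exposure, out),
               class = "mrbiome_empty_set_error")
})

test_that("injected stressors produce exactly the ground-truth actions", {
  cfg <- synthetic_config(J = 10, beta0 = -0.3, frac_palindromic = 0.2,
                          frac_strandflip = 0.1, frac_swapped = 0.1, seed = 22)
  sim <- simulate_pair(cfg)
  set <- build_instrument_set(sim$exposure, sim$outcome)
  expect_equal(nrow(set$records), 8)
  merged <- merge(set$drop_log, sim$truth$records, by = "snp_id")
  expect_equal(merged$action == "kept" | merged$action == "flipped",
               merged$expected_action != "dropped_palindromic")
  # strand flips stay "kept", swaps are "flipped", palindromes are dropped
  for (i in seq_len(nrow(merged))) {
    expect_equal(merged$action[i], merged$expected_action[i])
  }
})

test_that("harmonization is idempotent and coding-invariant on kept records", {
  sim <- simulate_pair(synthetic_config(J = 8, beta0 = 0.2, frac_swapped = 0.25,
                                        seed = 23))
  set1 <- build_instrument_set(sim$exposure, sim$outcome)

  # flipping both outcome alleles and the beta sign is a no-op after
  # harmonization (allele coding is arbitrary)
  out2 <- sim$outcome
  out2$records$beta <- -out2$records$beta
  tmp <- out2$records$effect_allele
  out2$records$effect_allele <- out2$records$other_allele
  out2$records$other_allele <- tmp
  out2$records$eaf <- 1 - out2$records$eaf
  set2 <- build_instrument_set(sim$exposure, out2)
  expect_equal(set2$records[c("snp_id", "gamma", "Gamma")],
               set1$records[c("snp_id", "gamma", "Gamma")])

  # re-harmonizing the kept records against themselves changes nothing
  as_stats <- function(rec, beta, se, id) {
    summary_stats(data.frame(snp_id = rec$snp_id, chrom = "1",
                             pos = seq_len(nrow(rec)),
                             effect_allele = "A", other_allele = "G",
                             beta = beta, se = se, pvalue = 1e-8,
                             eaf = 0.3, n = 1e4, stringsAsFactors = FALSE), id)
  }
  exp2 <- as_stats(set1$records, set1$records$gamma, set1$records$sigma_x, "e")
  out3 <- as_stats(set1$records, set1$records$Gamma, set1$records$sigma_y, "o")
  set3 <- build_instrument_set(exp2, out3)
  expect_equal(set3$records$gamma, set1$records$gamma)
  expect_equal(set3$records$Gamma, set1$records$Gamma)
  expect_true(all(set3$drop_log$action == "kept"))
})
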