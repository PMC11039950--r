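# Independent oracles and small fixture builders shared across tests.

# Build a harmonized set straight from aligned effect vectors.
make_set <- function(gamma, sigma_x, Gamma, sigma_y, ...) {
  harmonized_set(gamma, sigma_x, Gamma, sigma_y, ...)
}

# A set whose inverse-variance ratio weights are exactly `weight` and whose
# ratio estimates are exactly `ratio`: gamma = 1 so beta_ratio = Gamma and
# weight = 1/sigma_y^2.
set_from_ratios <- function(ratio, weight) {
  make_set(gamma = rep(1, length(ratio)), sigma_x = rep(0.01, length(ratio)),
           Gamma = ratio, sigma_y = 1 / sqrt(weight))
}

# Brute-force greedy clumping oracle: explicit loop over p-ordered records.
brute_force_clump <- function(records, ld, r2_max, window_kb) {
  ord <- order(records$pvalue, records$chrom, records$pos, records$snp_id)
  remaining <- records[ord, , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$snp_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    same_chr <- remaining$chrom == idx$chrom
    in_window <- abs(remaining$pos - idx$pos) <= window_kb * 1000
    r2 <- ld_r2(ld, idx$snp_id, remaining$snp_id)
    remaining <- remaining[!(same_chr & in_window & r2 > r2_max), , drop = FALSE]
  }
  sort(kept)
}

# Brute-force Benjamini-Hochberg step-up oracle: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / rank(j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Density-argmax oracle for the weighted mode on an explicit grid.
wmode_oracle <- function(ratio, weight, phi = 1) {
  u <- weight / sum(weight)
  s <- min(sd(ratio), mad(ratio))
  if (s == 0) s <- sd(ratio)
  h <- phi * 0.9 * s * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(u * dnorm(g, mean = ratio, sd = h)),
                 numeric(1))
  grid[which.max(dens)]
}

# Write a small delimited table and return its path.
write_fixture <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Minimal valid record table for io tests.
demo_records <- function(n = 3) {
  data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1000,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    beta = seq_len(n) / 50,
    se = rep(0.01, n),
    pvalue = 10^(-6 - seq_len(n)),
    eaf = rep(0.3, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
}

# Calibration-study scenarios: strong instruments (large exposure GWAS) with
# a case-control-sized outcome, the conditions under which estimator
# behaviour is isolated from instrument-selection effects.
calib_config <- function(J = 50, ...) {
  synthetic_config(J = J, tau = 0.05, n_x = 5e5, n_y = 12682, ...)
}
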