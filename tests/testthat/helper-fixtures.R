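# Fixture builders and independent oracles used across the suite.

# Harmonized set straight from effect vectors (bypasses harmonize()).
hset_manual <- function(bx, by, sx, sy, snp = sprintf("s%02d", seq_along(bx)),
                        eaf_exp = NA_real_, n_exposure = 13266L,
                        n_outcome = 166401L, case_fraction = 5731 / 166401) {
  harmonized_set(data.frame(snp = snp, beta_exp = bx, se_exp = sx,
                            beta_out = by, se_out = sy, eaf_exp = eaf_exp),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction = case_fraction)
}

# The two-instrument hand example: weights (1, 4), ratios (0.5, 0.3).
two_snp_hset <- function(sx = 0.02) {
  hset_manual(bx = c(0.1, 0.2), by = c(0.05, 0.06), sx = rep(sx, 2),
              sy = c(0.1, 0.1))
}

# Random valid canonical summary-statistics table.
random_sumstats <- function(n, seed, name = "trait", type = "continuous",
                            cf = if (type == "binary") 0.03 else NULL,
                            frac_na_eaf = 0.2) {
  set.seed(seed)
  ea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1L), "")
  eaf <- runif(n)
  eaf[runif(n) < frac_na_eaf] <- NA
  sumstats_table(
    data.frame(snp = sprintf("rs%05d", sample.int(99999L, n)),
               chr = as.character(sample.int(22L, n, replace = TRUE)),
               pos = sample.int(2e8L, n), ea = ea, oa = oa, eaf = eaf,
               beta = rnorm(n), se = runif(n, 0.01, 0.5),
               pval = pmax(runif(n), 1e-12),
               n = sample(1000:20000, n, replace = TRUE)),
    trait_name = name, trait_type = type, case_fraction = cf)
}

# Independent IVW oracle: weighted zero-intercept regression via lm().
ivw_oracle <- function(bx, by, sy) {
  fit <- stats::lm(by ~ bx - 1, weights = 1 / sy^2)
  c(theta = unname(stats::coef(fit)[1L]),
    se_fixed = 1 / sqrt(sum(bx^2 / sy^2)))
}

# Independent clumping oracle: literal repeated application of the rule on
# an r2 matrix, using different data structures than clump().
clump_oracle <- function(df, r2m, r2_thresh, window_kb) {
  alive <- rep(TRUE, nrow(df))
  kept <- logical(nrow(df))
  rank_key <- order(df$pval, df$snp)
  while (any(alive)) {
    idx <- rank_key[match(TRUE, alive[rank_key])]
    kept[idx] <- TRUE
    alive[idx] <- FALSE
    for (j in which(alive)) {
      if (df$chr[j] == df$chr[idx] &&
          abs(df$pos[j] - df$pos[idx]) <= window_kb * 1000 &&
          r2m[df$snp[j], df$snp[idx]] >= r2_thresh) {
        alive[j] <- FALSE
      }
    }
  }
  sort(df$snp[kept])
}

# Scrambled replicate seeds (consecutive integer seeds give a slightly
# shrunken empirical null, so simulation loops use derived seeds).
rep_seed <- function(base, i) mrpanel:::derive_seed(base, i)

binom_band <- function(p0, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p0 + c(-1, 1) * z * sqrt(p0 * (1 - p0) / n)
}
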