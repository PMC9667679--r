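test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_snps = 50, theta = 0, seed = 314)
  a <- simulate_instrument_panel(cfg)
  b <- simulate_instrument_panel(cfg)
  expect_identical(a, b)
  st1 <- simulate_study(5, causal_indices = 2, config = sim_config(n_snps = 8, theta = 0.3, seed = 9))
  st2 <- simulate_study(5, causal_indices = 2, config = sim_config(n_snps = 8, theta = 0.3, seed = 9))
  expect_identical(st1$truth, st2$truth)
  expect_identical(as.data.frame(st1$outcome), as.data.frame(st2$outcome))
})

test_that("standard errors are positive, shrink with sample size, and grow as MAF -> 0", {
  cfg <- sim_config(n_snps = 40, seed = 5)
  small <- simulate_instrument_panel(cfg)
  cfg_big <- cfg; cfg_big$n_exposure <- 4L * cfg$n_exposure
  big <- simulate_instrument_panel(cfg_big)
  expect_true(all(small$exposure$se > 0) && all(small$outcome$se > 0))
  # same seed => same MAF draws, so the comparison is elementwise
  expect_true(all(big$exposure$se < small$exposure$se))
  maf <- pmin(small$exposure$eaf, 1 - small$exposure$eaf)
  expect_true(all(diff(small$exposure$se[order(maf)]) <= 0))
})

test_that("IVW on generated panels recovers the causal effect without bias", {
  # exposure GWAS large enough that regression dilution from noisy
  # instrument effects is negligible
  nrep <- 200
  est <- vapply(seq_len(nrep), function(i) {
    sim <- simulate_instrument_panel(
      sim_config(n_snps = 100, theta = 0.3, n_exposure = 200000L,
                 seed = rep_seed(51, i)))
    unname(ivw_oracle(sim$exposure$beta, sim$outcome$beta, sim$outcome$se)["theta"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se + 1e-3)
})

test_that("balanced pleiotropy has mean-zero direct effects on the invalid set", {
  rs <- unlist(lapply(1:500, function(i) {
    sim <- simulate_instrument_panel(
      sim_config(n_snps = 20, pleiotropy_mode = "balanced", pleio_sd = 0.05,
                 pleio_fraction = 0.3, seed = rep_seed(61, i)))
    expect_length(sim$truth$invalid_set, round(0.3 * 20))
    expect_true(all(sim$truth$r[-sim$truth$invalid_set] == 0))
    sim$truth$r[sim$truth$invalid_set]
  }))
  expect_lt(abs(mean(rs)), 3 * 0.05 / sqrt(length(rs)))
})

test_that("IVW 95% CI coverage under no pleiotropy is nominal", {
  nrep <- 500
  cover <- vapply(seq_len(nrep), function(i) {
    sim <- simulate_instrument_panel(
      sim_config(n_snps = 50, theta = 0.3, seed = rep_seed(71, i)))
    hs <- harmonize(sim$exposure, sim$outcome)
    res <- mr_ivw(hs)
    res$ci_low < exp(0.3) && exp(0.3) < res$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("directional pleiotropy biases IVW and is flagged by the Egger intercept", {
  # every instrument carries a directional direct effect of about twice the
  # outcome-side standard error; the intercept should detect it often
  res <- vapply(1:100, function(i) {
    sim <- simulate_instrument_panel(
      sim_config(n_snps = 50, theta = 0.3, pleiotropy_mode = "directional",
                 pleio_mean = 0.042, pleio_sd = 0.01, pleio_fraction = 1,
                 seed = rep_seed(81, i)))
    hs <- harmonize(sim$exposure, sim$outcome)
    c(ivw = mr_ivw(hs)$beta,
      hit = mr_egger(hs)$extras$intercept_p < 0.05)
  }, numeric(2))
  expect_gt(mean(res["ivw", ]), 0.4)        # upward bias (true effect 0.3)
  expect_gt(mean(res["hit", ]), 0.5)        # intercept rejection rate
})

test_that("LD blocks share signals, carry the requested r2, and clump to one SNP per block", {
  one <- simulate_ld_blocks(3, within_r2 = 0.8, config = sim_config(seed = 2))
  expect_equal(one$ld$n_pairs, 3L)
  expect_equal(unique(one$ld$r2), 0.8)

  two <- simulate_ld_blocks(c(2, 2), within_r2 = 0.5,
                            config = sim_config(seed = 3, gamma_sd = 0.3))
  clumped <- clump(two$exposure, two$ld, r2_thresh = 0.001, window_kb = 10000)
  expect_equal(nrow(clumped), 2L)
  # block members share one causal signal
  expect_lt(abs(diff(two$truth$gamma[two$truth$block == 1])), 0.15)

  free <- simulate_ld_blocks(c(2, 2), within_r2 = 0, config = sim_config(seed = 4))
  expect_equal(nrow(clump(free$exposure, free$ld)), 4L)
  expect_error(simulate_ld_blocks(integer(0), 0.5), "non-empty")
})

test_that("multi-exposure studies have the requested shape and null calibration", {
  st <- simulate_study(119, causal_indices = 1,
                       config = sim_config(n_snps = 4, theta = 0.3, seed = 12))
  expect_length(st$exposures, 119L)
  thetas <- vapply(st$truth, `[[`, numeric(1), "theta")
  expect_equal(which(thetas != 0), c(taxon_001 = 1L))
  expect_equal(nrow(st$outcome), 119L * 4L)
  expect_false(anyDuplicated(st$outcome$snp) > 0)

  # all-null panels: unfiltered per-exposure IVW rejects at about 5%
  pv <- unlist(lapply(1:4, function(r) {
    stn <- simulate_study(100, config = sim_config(n_snps = 10, seed = rep_seed(91, r)))
    vapply(stn$exposures, function(e) {
      o <- stn$outcome[match(e$snp, stn$outcome$snp), ]
      s <- ivw_oracle(e$beta, o$beta, o$se)
      2 * pnorm(-abs(s["theta"] / s["se_fixed"]))
    }, numeric(1))
  }))
  band <- binom_band(0.05, length(pv))
  expect_gte(mean(pv < 0.05), band[1])
  expect_lte(mean(pv < 0.05), band[2])
})
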