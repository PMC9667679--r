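make_cand <- function(pval, eaf = rep(0.3, length(pval)),
                      pos = seq_along(pval) * 1000L) {
  if (!length(pval)) return(sumstats_table(data.frame(), trait_name = "taxon"))
  sumstats_table(data.frame(snp = sprintf("rs%d", seq_along(pval)),
                            chr = "1", pos = pos, ea = "A", oa = "G",
                            eaf = eaf, beta = 0.1, se = 0.02, pval = pval,
                            n = 13266L),
                 trait_name = "taxon")
}

test_that("candidate selection applies the p-value and MAF rules with flagged missing frequencies", {
  tab <- make_cand(c(1e-6, 2e-5, 1e-4))
  expect_equal(select_candidates(tab)$snp, "rs1")

  # MAF exactly at the cutoff is removed (the rule is <=)
  tab2 <- make_cand(c(1e-6, 1e-6, 1e-6), eaf = c(0.99, 0.995, 0.3))
  expect_equal(select_candidates(tab2)$snp, "rs3")
  expect_equal(select_candidates(tab2, maf_min = 0.004)$snp,
               c("rs1", "rs2", "rs3"))

  tab3 <- make_cand(c(1e-6, 1e-6), eaf = c(NA, 0.3))
  sel3 <- select_candidates(tab3)
  expect_equal(sel3$snp, c("rs1", "rs2"))
  expect_equal(attr(sel3, "flagged_missing_eaf"), "rs1")

  empty <- select_candidates(make_cand(numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("greedy clumping keeps the lowest-p SNP per linked window", {
  tab <- make_cand(c(1e-8, 1e-7, 1e-6), pos = c(1e6, 2e6, 3e6))
  ld <- ld_table(c("rs1", "rs1"), c("rs2", "rs3"), c(0.5, 0.0005))
  expect_equal(clump(tab, ld)$snp, c("rs1", "rs3"))
  # no LD at all: everything survives
  expect_equal(clump(tab, ld_table())$snp, c("rs1", "rs2", "rs3"))
  # strong LD but outside the window: both survive
  far <- make_cand(c(1e-8, 1e-7), pos = c(1e6, 21e6))
  ld2 <- ld_table("rs1", "rs2", 0.9)
  expect_equal(clump(far, ld2)$snp, c("rs1", "rs2"))
  # inside the window the weaker one is discarded
  near <- make_cand(c(1e-8, 1e-7), pos = c(1e6, 9e6))
  expect_equal(clump(near, ld2)$snp, "rs1")
})

test_that("clumping output is a subset whose removals are justified", {
  for (case in 1:20) {
    set.seed(case)
    n <- sample(3:12, 1)
    tab <- make_cand(pmax(runif(n, 0, 1e-5), 1e-12),
                     pos = sort(sample.int(3e7, n)))
    cmb <- t(combn(tab$snp, 2))
    r2 <- ifelse(runif(nrow(cmb)) < 0.5, 0, runif(nrow(cmb)))
    ld <- ld_table(cmb[, 1], cmb[, 2], r2)
    kept <- clump(tab, ld)
    expect_true(all(kept$snp %in% tab$snp))
    dropped <- setdiff(tab$snp, kept$snp)
    for (d in dropped) {
      i <- match(d, tab$snp)
      just <- vapply(kept$snp, function(k) {
        j <- match(k, tab$snp)
        tab$chr[i] == tab$chr[j] && abs(tab$pos[i] - tab$pos[j]) <= 1e7 &&
          ld_lookup(ld, d, k) >= 0.001 && tab$pval[j] <= tab$pval[i]
      }, logical(1))
      expect_true(any(just))
    }
  }
})

test_that("harmonization resolves orientation, strand, and palindromes by frequency", {
  out_tab <- function(ea, oa, beta, eaf = 0.3) {
    sumstats_table(data.frame(snp = "rs1", chr = "1", pos = 100L, ea = ea,
                              oa = oa, eaf = eaf, beta = beta, se = 0.05,
                              pval = 0.5, n = 166401L),
                   trait_name = "pe", trait_type = "binary",
                   case_fraction = 0.034)
  }
  exp_tab <- function(ea = "A", oa = "G", eaf = 0.2) {
    sumstats_table(data.frame(snp = "rs1", chr = "1", pos = 100L, ea = ea,
                              oa = oa, eaf = eaf, beta = 0.1, se = 0.02,
                              pval = 1e-6, n = 13266L),
                   trait_name = "taxon")
  }
  # swapped alleles: outcome beta is negated, eaf mirrored
  h <- harmonize(exp_tab(), out_tab("G", "A", beta = 0.05, eaf = 0.7))
  expect_equal(h$pairs$action, "flipped")
  expect_equal(h$pairs$beta_out, -0.05)
  expect_equal(h$pairs$eaf_out, 0.3)
  # complementary strand, same orientation
  h2 <- harmonize(exp_tab(), out_tab("T", "C", beta = 0.05))
  expect_equal(h2$pairs$action, "kept")
  expect_equal(h2$pairs$beta_out, 0.05)
  # palindromic, frequencies on opposite sides: flipped
  h3 <- harmonize(exp_tab("A", "T", eaf = 0.20),
                  out_tab("A", "T", beta = 0.05, eaf = 0.79))
  expect_equal(h3$pairs$action, "flipped")
  expect_equal(h3$pairs$beta_out, -0.05)
  # palindromic with ambiguous frequency: dropped
  h4 <- harmonize(exp_tab("C", "G", eaf = 0.2),
                  out_tab("C", "G", beta = 0.05, eaf = 0.50))
  expect_equal(h4$audit$action, "dropped_palindromic")
  expect_equal(nrow(h4$pairs), 0L)
  # palindromic, same side of 0.5: kept as is
  h5 <- harmonize(exp_tab("A", "T", eaf = 0.20),
                  out_tab("A", "T", beta = 0.05, eaf = 0.25))
  expect_equal(h5$pairs$action, "kept")
  expect_equal(h5$pairs$beta_out, 0.05)
  # incompatible allele pair
  h6 <- harmonize(exp_tab(), out_tab("A", "C", beta = 0.05))
  expect_equal(h6$audit$action, "dropped_incompatible")
  # absent from outcome
  out_none <- out_tab("A", "G", 0.05)
  out_none$snp <- "rs999"
  h7 <- harmonize(exp_tab(), out_none)
  expect_equal(h7$audit$action, "dropped_missing")
})

test_that("harmonization is an involution and invariant to joint allele flips", {
  sim <- simulate_instrument_panel(sim_config(n_snps = 15, theta = 0.2, seed = 33))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # already-aligned data: nothing changes
  expect_true(all(h1$pairs$action == "kept"))
  expect_equal(h1$pairs$beta_out, sim$outcome$beta[match(h1$pairs$snp, sim$outcome$snp)])
  # flip both alleles, the beta sign, and the frequency of outcome records:
  # the harmonized (beta_exp, beta_out) pairs must be unchanged
  flipped <- as.data.frame(sim$outcome)
  tmp <- flipped$ea; flipped$ea <- flipped$oa; flipped$oa <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  out2 <- sumstats_table(flipped, trait_name = "outcome",
                         trait_type = "binary", case_fraction = 0.034)
  h2 <- harmonize(sim$exposure, out2)
  expect_true(all(h2$pairs$action == "flipped"))
  expect_equal(h2$pairs$beta_out, h1$pairs$beta_out)
  expect_equal(h2$pairs$eaf_out, h1$pairs$eaf_out)
})

test_that("instrument strength follows the F formula with a t-statistic fallback", {
  expect_equal(round(f_statistic(0.01, 13266, 13), 2), 10.30)
  expect_equal(f_statistic(0, 13266, 13), 0)
  # one SNP with MAF 0.25 and effect 0.1 explains 2*0.25*0.75*0.01
  h <- hset_manual(bx = 0.1, by = 0.05, sx = 0.02, sy = 0.1, eaf_exp = 0.25)
  s <- instrument_strength(h)
  expect_equal(s$r2, 0.00375)
  expect_equal(s$f_stat, f_statistic(0.00375, 13266, 1))
  # missing frequency: per-SNP fallback t^2 / (t^2 + N - 2)
  h2 <- hset_manual(bx = 0.1, by = 0.05, sx = 0.02, sy = 0.1)
  tt <- (0.1 / 0.02)^2
  expect_equal(instrument_strength(h2)$r2, tt / (tt + 13266 - 2))
  expect_error(instrument_strength(h, n = 2), "insufficient sample size")
})

test_that("power approximation has the right null limit and monotonicity", {
  expect_equal(mr_power(166401, 0.034, r2 = 0.01, theta = 0), 0.025)
  p1 <- mr_power(166401, 5731 / 166401, r2 = 0.002, theta = log(0.76))
  expect_equal(p1, 0.1475539, tolerance = 1e-6)
  thetas <- seq(0, 1, by = 0.1)
  pw <- vapply(thetas, function(t) mr_power(1e5, 0.1, 0.01, t), numeric(1))
  expect_true(all(diff(pw) >= 0))
  ns <- c(1e4, 5e4, 1e5, 5e5)
  pw_n <- vapply(ns, function(n) mr_power(n, 0.1, 0.01, 0.2), numeric(1))
  expect_true(all(diff(pw_n) >= 0))
  expect_error(mr_power(1e5, 0.1, 0, 0.2), "r2")
})
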