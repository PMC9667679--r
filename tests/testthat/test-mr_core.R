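test_that("Wald ratio arithmetic, sign invariance, and null-instrument guard", {
  h <- hset_manual(bx = 0.1, by = 0.05, sx = 0.02, sy = 0.1)
  w <- wald_ratio(h)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 1.0)
  neg <- hset_manual(bx = -0.1, by = -0.05, sx = 0.02, sy = 0.1)
  expect_equal(wald_ratio(neg)$beta, w$beta)
  expect_error(wald_ratio(hset_manual(0, 0.05, 0.02, 0.1)), "null instrument")
})

test_that("IVW matches hand arithmetic and the weighted-regression oracle", {
  h <- two_snp_hset()
  res <- mr_ivw(h, mode = "fixed")
  expect_equal(res$beta, 0.34)
  expect_equal(res$se, 0.4472136, tolerance = 1e-7)
  expect_equal(res$extras$Q, 0.032)
  orc <- ivw_oracle(h$pairs$beta_exp, h$pairs$beta_out, h$pairs$se_out)
  expect_equal(res$beta, unname(orc["theta"]))
  expect_equal(res$se, unname(orc["se_fixed"]))
  # result container invariants
  expect_equal(res$or_, exp(res$beta))
  expect_true(res$ci_low < res$or_ && res$or_ < res$ci_high)
  # equal ratios: estimate is the common ratio, Q = 0, mre floor inactive
  eq <- hset_manual(bx = c(0.1, 0.2), by = c(0.05, 0.1), sx = c(0.02, 0.02),
                    sy = c(0.1, 0.3))
  expect_equal(mr_ivw(eq)$beta, 0.5)
  expect_equal(mr_ivw(eq)$extras$Q, 0)
  expect_equal(mr_ivw(eq)$se, mr_ivw(eq, mode = "fixed")$se)
  # single pair reduces to the Wald ratio
  one <- hset_manual(0.1, 0.05, 0.02, 0.1)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(one)$se)
  # random panels: fixed IVW equals the precision-weighted mean of ratios
  for (i in 1:10) {
    set.seed(400 + i)
    J <- sample(3:20, 1)
    hh <- hset_manual(bx = rnorm(J, 0.1, 0.05) + 0.01, by = rnorm(J, 0.03, 0.02),
                      sx = runif(J, 0.01, 0.05), sy = runif(J, 0.02, 0.2))
    ratios <- hh$pairs$beta_out / hh$pairs$beta_exp
    w <- hh$pairs$beta_exp^2 / hh$pairs$se_out^2
    expect_equal(mr_ivw(hh, mode = "fixed")$beta, sum(w * ratios) / sum(w))
  }
})

test_that("maximum likelihood matches its limits and a grid-search oracle", {
  # negligible exposure error: equals fixed-effect IVW
  h0 <- two_snp_hset(sx = 1e-8)
  expect_equal(mr_ml(h0)$beta, mr_ivw(h0, mode = "fixed")$beta, tolerance = 1e-6)
  # moderate exposure error: matches dense grid search on the profile
  h <- two_snp_hset(sx = 0.02)
  res <- mr_ml(h)
  grid <- seq(-1, 1.5, by = 1e-5)
  nll <- vapply(grid, function(t) {
    sum((h$pairs$beta_out - t * h$pairs$beta_exp)^2 /
          (2 * (h$pairs$se_out^2 + t^2 * h$pairs$se_exp^2)))
  }, numeric(1))
  expect_equal(res$beta, grid[which.min(nll)], tolerance = 1e-4)
  # single pair reduces to the Wald ratio
  one <- hset_manual(0.1, 0.05, 0.02, 0.1)
  expect_equal(mr_ml(one)$beta, 0.5)
})

test_that("Egger recovers an exact affine relation and is orientation-invariant", {
  bx <- c(0.1, 0.2, 0.3)
  h <- hset_manual(bx = bx, by = 0.1 + 0.5 * bx, sx = rep(0.02, 3),
                   sy = rep(0.1, 3))
  res <- mr_egger(h)
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_equal(res$extras$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(res$extras$sigma, 0, tolerance = 1e-7)
  # zero residuals: the SE floor falls back to the fixed-effect SE (finite)
  expect_true(is.finite(res$se) && res$se > 0)
  # negating one pair changes nothing (orientation convention)
  h2 <- hset_manual(bx = c(-0.1, 0.2, 0.3), by = c(-(0.1 + 0.05), 0.2, 0.25),
                    sx = rep(0.02, 3), sy = rep(0.1, 3))
  h3 <- hset_manual(bx = c(0.1, 0.2, 0.3), by = c(0.1 + 0.05, 0.2, 0.25),
                    sx = rep(0.02, 3), sy = rep(0.1, 3))
  expect_equal(mr_egger(h2)$beta, mr_egger(h3)$beta)
  expect_equal(mr_egger(h2)$extras$egger_intercept,
               mr_egger(h3)$extras$egger_intercept)
  expect_error(mr_egger(two_snp_hset()), "insufficient")
})

test_that("weighted median interpolates the spec'd cumulative-weight formula", {
  expect_equal(mrpanel:::weighted_median_est(c(0.1, 0.2, 0.3), c(1, 1, 1)), 0.2)
  expect_equal(mrpanel:::weighted_median_est(c(0.1, 0.2, 0.3), c(1, 1, 2)),
               0.2333333, tolerance = 1e-6)
  # order of input does not matter
  expect_equal(mrpanel:::weighted_median_est(c(0.3, 0.1, 0.2), c(2, 1, 1)),
               0.2333333, tolerance = 1e-6)
  h <- hset_manual(bx = c(0.1, 0.12, 0.2), by = c(0.03, 0.02, 0.05),
                   sx = rep(0.02, 3), sy = rep(0.05, 3))
  a <- mr_wmedian(h, n_boot = 500, seed = 7)
  b <- mr_wmedian(h, n_boot = 500, seed = 7)
  expect_identical(a, b)
  c2 <- mr_wmedian(h, n_boot = 1000, seed = 7)
  c3 <- mr_wmedian(h, n_boot = 1000, seed = 8)
  expect_lt(abs(c2$se - c3$se) / c2$se, 0.2)
})

test_that("weighted mode finds the dominant ratio cluster", {
  # degenerate: identical ratios
  h0 <- hset_manual(bx = c(0.1, 0.2, 0.4), by = c(0.04, 0.08, 0.16),
                    sx = rep(0.02, 3), sy = rep(0.1, 3))
  expect_equal(mr_wmode(h0, n_boot = 50, seed = 1)$beta, 0.4)
  # a tight cluster plus one outlier: the mode stays with the cluster
  ratios <- c(0.30, 0.31, 0.32, 2.0)
  h <- hset_manual(bx = rep(0.1, 4), by = 0.1 * ratios, sx = rep(0.02, 4),
                   sy = rep(0.05, 4))
  est <- mr_wmode(h, n_boot = 50, seed = 1)$beta
  expect_gte(est, 0.29); expect_lte(est, 0.33)
  # scaling all weights leaves the estimate unchanged
  expect_equal(mrpanel:::weighted_mode_est(ratios, c(1, 1, 1, 1)),
               mrpanel:::weighted_mode_est(ratios, c(2, 2, 2, 2)))
})

test_that("Cochran's Q matches hand arithmetic and the mre-floor cross-check", {
  h <- two_snp_hset()
  q <- cochran_q(h)
  expect_equal(q$q_stat, 0.032)
  expect_equal(q$df, 1L)
  eq <- hset_manual(bx = c(0.1, 0.2), by = c(0.05, 0.1), sx = c(0.02, 0.02),
                    sy = c(0.1, 0.1))
  expect_equal(cochran_q(eq)$q_stat, 0)
  expect_equal(cochran_q(eq)$pvalue, 1)
  # mre-floor internals agree with Q: se_mre / se_fixed = max(1, sqrt(Q/(J-1)))
  set.seed(11)
  hh <- hset_manual(bx = rnorm(8, 0.1, 0.03), by = rnorm(8, 0.05, 0.05),
                    sx = rep(0.02, 8), sy = runif(8, 0.05, 0.2))
  qq <- cochran_q(hh)
  ratio <- mr_ivw(hh)$se / mr_ivw(hh, mode = "fixed")$se
  expect_equal(ratio, max(1, sqrt(qq$q_stat / qq$df)))
})

test_that("leave-one-out isolates influential instruments", {
  eq <- hset_manual(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.1, 0.2),
                    sx = rep(0.02, 3), sy = rep(0.1, 3))
  lo <- leave_one_out(eq)
  expect_equal(nrow(lo), 3L)
  expect_equal(lo$beta, rep(0.5, 3))
  expect_equal(lo$snp, eq$pairs$snp)
  # an extreme outlier: omitting it moves the estimate toward the others,
  # and each row equals a direct IVW on the corresponding 2-SNP subset
  out <- hset_manual(bx = c(0.1, 0.2, 0.1), by = c(0.05, 0.1, 0.3),
                     sx = rep(0.02, 3), sy = rep(0.1, 3))
  lo2 <- leave_one_out(out)
  full <- mr_ivw(out)$beta
  expect_lt(abs(lo2$beta[3] - 0.5), abs(full - 0.5))
  for (j in 1:3) {
    sub <- out; sub$pairs <- out$pairs[-j, ]
    expect_equal(lo2$beta[j], mr_ivw(sub)$beta)
    expect_equal(lo2$se[j], mr_ivw(sub)$se)
  }
})

test_that("every estimator is invariant to jointly negating any instrument pair", {
  set.seed(21)
  J <- 8
  bx <- rnorm(J, 0.12, 0.04); by <- 0.4 * bx + rnorm(J, 0, 0.03)
  sx <- rep(0.02, J); sy <- runif(J, 0.05, 0.15)
  h1 <- hset_manual(bx, by, sx, sy)
  flip <- c(rep(-1, 3), rep(1, J - 3))
  h2 <- hset_manual(flip * bx, flip * by, sx, sy)
  expect_equal(mr_ivw(h1)$beta, mr_ivw(h2)$beta)
  expect_equal(mr_ml(h1)$beta, mr_ml(h2)$beta)
  expect_equal(mr_egger(h1)$beta, mr_egger(h2)$beta)
  expect_equal(mr_wmedian(h1, n_boot = 50, seed = 3)$beta,
               mr_wmedian(h2, n_boot = 50, seed = 3)$beta)
  expect_equal(mr_wmode(h1, n_boot = 50, seed = 3)$beta,
               mr_wmode(h2, n_boot = 50, seed = 3)$beta)
  expect_equal(cml_ma_bic(h1, n_starts = 3, seed = 3)$ma_theta,
               cml_ma_bic(h2, n_starts = 3, seed = 3)$ma_theta)
})
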