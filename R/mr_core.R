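# Core two-sample MR estimators and diagnostics. All operate on the
# harmonized (beta_exp, beta_out) pairs of a "harmonized_set" and are
# invariant to jointly negating any instrument's pair.

#' Construct an MR estimate
#'
#' @param method Estimator label.
#' @param n_snp Number of instruments used.
#' @param beta Causal estimate (log-odds per exposure SD for a binary
#'   outcome).
#' @param se Standard error (> 0).
#' @param pvalue Two-sided p-value; defaults to the normal test, or a t test
#'   when `df` is given.
#' @param df Degrees of freedom for a t-based p-value (used by MR-Egger).
#' @param extras Method-specific named list (e.g. Egger intercept, bootstrap
#'   seed).
#' @return A list of class `"mr_result"` with `beta`, `se`, `or_`,
#'   `ci_low`/`ci_high` (`exp(beta -+ 1.96 se)`), `pvalue`, `extras`.
#' @export
mr_result <- function(method, n_snp, beta, se, pvalue = NULL, df = NULL,
                      extras = list()) {
  beta <- unname(beta); se <- unname(se)
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  z <- beta / se
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
              else 2 * stats::pt(-abs(z), df = df)
  }
  structure(list(method = method, n_snp = as.integer(n_snp), beta = beta,
                 se = se, or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se), pvalue = pvalue,
                 extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pvalue))
  invisible(x)
}

pairs_of <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  hset$pairs
}

require_pairs <- function(hset, k, what) {
  p <- pairs_of(hset)
  if (nrow(p) < k) {
    stop_mr("insufficient instruments for %s (need >= %d, have %d)",
            what, k, nrow(p))
  }
  p
}

#' Wald ratio estimate for a single instrument
#'
#' `theta_j = beta_out / beta_exp` with first-order delta-method standard
#' error `se_out / |beta_exp|`.
#'
#' @param pair One-row data frame with `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` (e.g. one row of a harmonized set's `pairs`), or a
#'   `"harmonized_set"` with exactly one pair.
#' @return An `"mr_result"`.
#' @export
wald_ratio <- function(pair) {
  if (inherits(pair, "harmonized_set")) pair <- require_pairs(pair, 1L, "Wald ratio")
  stopifnot(nrow(pair) == 1L)
  if (pair$beta_exp == 0) stop_mr("null instrument: beta_exp = 0")
  mr_result("wald", 1L, pair$beta_out / pair$beta_exp,
            pair$se_out / abs(pair$beta_exp))
}

# shared sums for IVW-type computations; robust to beta_exp = 0 (weight 0)
ivw_sums <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  theta <- sum(bx * by / sy^2) / sum(w)
  list(w = w, theta = theta, se_fixed = 1 / sqrt(sum(w)),
       q = sum((by - theta * bx)^2 / sy^2))
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted combination of per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2` (equivalently, weighted zero-intercept regression
#' of outcome on exposure effects). `"fixed"` uses the fixed-effect standard
#' error `(sum w)^(-1/2)`; the default `"mre-floor"` multiplies it by
#' `max(1, sqrt(Q / (J - 1)))` — multiplicative random effects with a
#' fixed-effect floor.
#'
#' @param hset A `"harmonized_set"` (a single pair defers to [wald_ratio()]).
#' @param mode `"mre-floor"` or `"fixed"`.
#' @return An `"mr_result"`; `extras` carries Cochran's `Q` and the mode.
#' @export
mr_ivw <- function(hset, mode = c("mre-floor", "fixed")) {
  mode <- match.arg(mode)
  p <- require_pairs(hset, 1L, "IVW")
  if (nrow(p) == 1L) {
    res <- wald_ratio(p)
    res$method <- "ivw"
    return(res)
  }
  s <- ivw_sums(p$beta_exp, p$beta_out, p$se_out)
  if (!any(s$w > 0)) stop_mr("all IVW weights are zero")
  J <- nrow(p)
  se <- if (mode == "mre-floor") s$se_fixed * max(1, sqrt(s$q / (J - 1)))
        else s$se_fixed
  mr_result("ivw", J, s$theta, se, extras = list(Q = s$q, mode = mode))
}

# Profile negative log-likelihood in theta: true instrument effects are
# profiled out exactly, leaving sum (by - theta*bx)^2 / (2 (sy^2 + theta^2 sx^2)).
ml_profile_nll <- function(theta, bx, by, sx, sy) {
  sum((by - theta * bx)^2 / (2 * (sy^2 + theta^2 * sx^2)))
}

#' Maximum-likelihood estimate
#'
#' Joint Gaussian likelihood of the observed exposure and outcome effects
#' given true per-SNP effects `g_j` and a causal slope, assuming no
#' heterogeneity or pleiotropy. The `g_j` are profiled out in closed form and
#' the slope is found by 1-D optimization initialized at the IVW estimate;
#' the standard error comes from the curvature of the profile likelihood at
#' the optimum.
#'
#' @param hset A `"harmonized_set"` (a single pair defers to [wald_ratio()]).
#' @return An `"mr_result"`.
#' @export
mr_ml <- function(hset) {
  p <- require_pairs(hset, 1L, "maximum likelihood")
  if (nrow(p) == 1L) {
    res <- wald_ratio(p)
    res$method <- "ml"
    return(res)
  }
  bx <- p$beta_exp; by <- p$beta_out; sx <- p$se_exp; sy <- p$se_out
  init <- ivw_sums(bx, by, sy)
  width <- 10 * max(init$se_fixed, abs(init$theta), 0.5)
  opt <- stats::optimize(ml_profile_nll, init$theta + c(-width, width),
                         bx = bx, by = by, sx = sx, sy = sy, tol = 1e-10)
  theta <- opt$minimum
  h <- 1e-4 * max(1, abs(theta))
  d2 <- (ml_profile_nll(theta + h, bx, by, sx, sy) -
         2 * opt$objective +
         ml_profile_nll(theta - h, bx, by, sx, sy)) / h^2
  if (!is.finite(d2) || d2 <= 0) {
    stop_mr("maximum likelihood did not converge: non-positive curvature %.3g at theta = %.4g",
            d2, theta)
  }
  mr_result("ml", nrow(p), theta, 1 / sqrt(d2),
            extras = list(neg2ll = 2 * opt$objective))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept, each pair first oriented so `beta_exp >= 0` (the intercept is
#' not orientation-invariant; a fixed convention is required). Weights are
#' `1 / se_out^2`; coefficient standard errors are scaled by
#' `max(1, residual sigma)` and tested against a t distribution with `J - 2`
#' degrees of freedom. A non-zero intercept estimates average directional
#' pleiotropy.
#'
#' @param hset A `"harmonized_set"` with at least 3 pairs.
#' @return An `"mr_result"`; `extras` carries `egger_intercept`,
#'   `intercept_se`, `intercept_p`, and the residual `sigma`.
#' @export
mr_egger <- function(hset) {
  p <- require_pairs(hset, 3L, "MR-Egger")
  flip <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- flip * p$beta_exp; by <- flip * p$beta_out
  w <- 1 / p$se_out^2
  J <- nrow(p)
  X <- cbind(1, bx)
  xtwx <- crossprod(X, X * w)
  coefs <- unname(drop(solve(xtwx, crossprod(X, by * w))))
  resid <- by - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (J - 2)
  se_fixed <- unname(sqrt(diag(solve(xtwx))))
  se_used <- se_fixed * max(1, sqrt(sigma2))
  mr_result("egger", J, coefs[2L], se_used[2L], df = J - 2,
            extras = list(egger_intercept = coefs[1L],
                          intercept_se = se_used[1L],
                          intercept_p = 2 * stats::pt(-abs(coefs[1L] / se_used[1L]),
                                                      df = J - 2),
                          sigma = sqrt(sigma2)))
}

# Interpolated weighted median of ratios at standardized cumulative weight 0.5.
weighted_median_est <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

ratios_weights <- function(p, what) {
  if (any(p$beta_exp == 0)) stop_mr("null instrument (beta_exp = 0) in %s", what)
  list(ratios = p$beta_out / p$beta_exp, w = p$beta_exp^2 / p$se_out^2)
}

# Parametric bootstrap dispersion shared by the median and mode estimators.
# The median uses the plain SD of the bootstrap estimates. The mode uses the
# MAD: its bootstrap distribution is multimodal, and occasional jumps between
# density peaks inflate the SD several-fold relative to the estimator's true
# sampling spread, while the MAD tracks it closely.
boot_se <- function(p, estimator, n_boot, seed, scale = c("sd", "mad")) {
  scale <- match.arg(scale)
  ests <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(p), p$beta_exp, p$se_exp)
      by <- stats::rnorm(nrow(p), p$beta_out, p$se_out)
      bx[bx == 0] <- .Machine$double.eps
      estimator(by / bx, bx^2 / p$se_out^2)
    }, numeric(1))
  })
  if (scale == "sd") stats::sd(ests) else stats::mad(ests)
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of per-SNP Wald ratios: ratios are
#' sorted, weights `se_wald^(-2)` normalized, and the estimate is the linear
#' interpolation of ratios at standardized cumulative weight 0.5. Consistent
#' when at least half the total weight comes from valid instruments. The
#' standard error is the SD of the estimate over `n_boot` seeded parametric
#' resamples of the summary statistics.
#'
#' @param hset A `"harmonized_set"` with at least 3 pairs.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return An `"mr_result"`; `extras` records `n_boot` and `seed`.
#' @export
mr_wmedian <- function(hset, n_boot = 1000L, seed = 1L) {
  p <- require_pairs(hset, 3L, "weighted median")
  rw <- ratios_weights(p, "weighted median")
  est <- weighted_median_est(rw$ratios, rw$w)
  se <- boot_se(p, weighted_median_est, n_boot, seed)
  mr_result("wmedian", nrow(p), est, se,
            extras = list(n_boot = n_boot, seed = seed))
}

# Mode of the weighted normal-kernel density of ratios on a 512-point grid.
weighted_mode_est <- function(ratios, w, phi = 1) {
  J <- length(ratios)
  spread <- min(stats::sd(ratios), stats::mad(ratios))
  h <- phi * 0.9 * spread * J^(-1/5)
  if (!is.finite(h) || h <= 0) {
    h <- phi * 0.9 * stats::sd(ratios) * J^(-1/5)
    if (!is.finite(h) || h <= 0) return(ratios[1L])
  }
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512L)
  dens <- drop(stats::dnorm(outer(grid, ratios, "-") / h) %*% w)
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Mode-based estimate: the argmax of a weighted normal-kernel density of the
#' Wald ratios with bandwidth `phi * 0.9 * min(sd, mad) * J^(-1/5)`,
#' evaluated on a 512-point grid spanning the ratios plus three bandwidths.
#' Weights are `se_wald^(-2)`; consistent when the largest homogeneous
#' cluster of instruments is valid. The standard error is the MAD of the
#' estimate over seeded parametric resamples (the mode's bootstrap
#' distribution is multimodal, so a robust scale is used).
#'
#' @param hset A `"harmonized_set"` with at least 3 pairs.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return An `"mr_result"`.
#' @export
mr_wmode <- function(hset, phi = 1, n_boot = 1000L, seed = 1L) {
  p <- require_pairs(hset, 3L, "weighted mode")
  rw <- ratios_weights(p, "weighted mode")
  est <- weighted_mode_est(rw$ratios, rw$w, phi)
  se <- boot_se(p, function(r, w) weighted_mode_est(r, w, phi), n_boot, seed,
                scale = "mad")
  mr_result("wmode", nrow(p), est, se,
            extras = list(phi = phi, n_boot = n_boot, seed = seed))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` with IVW weights and the
#' fixed-effect IVW estimate; the p-value is the chi-square upper tail with
#' `J - 1` degrees of freedom.
#'
#' @param hset A `"harmonized_set"` with at least 2 pairs.
#' @return A list of class `"heterogeneity_result"`: `q_stat`, `df`,
#'   `pvalue`.
#' @export
cochran_q <- function(hset) {
  p <- require_pairs(hset, 2L, "Cochran's Q")
  s <- ivw_sums(p$beta_exp, p$beta_out, p$se_out)
  structure(list(q_stat = s$q, df = nrow(p) - 1L,
                 pvalue = stats::pchisq(s$q, df = nrow(p) - 1L,
                                        lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f (df %d), p = %.3g\n", x$q_stat, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn, flagging
#' single SNPs that drive the pooled estimate.
#'
#' @param hset A `"harmonized_set"` with at least 3 pairs.
#' @param mode IVW mode, as in [mr_ivw()].
#' @return A data frame (one row per omitted SNP, in input order) with
#'   columns `snp`, `n_snp`, `beta`, `se`, `or_`, `ci_low`, `ci_high`,
#'   `pvalue`.
#' @export
leave_one_out <- function(hset, mode = c("mre-floor", "fixed")) {
  mode <- match.arg(mode)
  p <- require_pairs(hset, 3L, "leave-one-out")
  rows <- lapply(seq_len(nrow(p)), function(j) {
    sub <- hset
    sub$pairs <- p[-j, , drop = FALSE]
    res <- mr_ivw(sub, mode = mode)
    data.frame(snp = p$snp[j], n_snp = res$n_snp, beta = res$beta,
               se = res$se, or_ = res$or_, ci_low = res$ci_low,
               ci_high = res$ci_high, pvalue = res$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
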