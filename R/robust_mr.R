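# Outlier- and pleiotropy-robust estimation: MR-PRESSO (global, outlier,
# distortion tests) and constrained maximum likelihood with BIC model
# averaging (cML-MA-BIC).

# Leave-one-out fixed-effect IVW slopes from precomputed sums; works on a
# matrix of simulated panels (rows = simulations) as well as a single vector.
loo_thetas <- function(bx, by, sy) {
  if (is.matrix(bx)) {
    gy <- sweep(bx * by, 2L, sy^2, "/")
    gg <- sweep(bx^2, 2L, sy^2, "/")
    (rowSums(gy) - gy) / (rowSums(gg) - gg)
  } else {
    gy <- bx * by / sy^2
    gg <- bx^2 / sy^2
    (sum(gy) - gy) / (sum(gg) - gg)
  }
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Compares the observed leave-one-out residual sum of squares
#' `RSS = sum_j (beta_out_j - theta_{-j} * beta_exp_j)^2 / se_out_j^2`
#' against a parametric null built by `n_sim` seeded draws
#' `beta_exp* ~ N(beta_exp, se_exp^2)`,
#' `beta_out* ~ N(theta_{-j} * beta_exp, se_out^2)`, recomputing the RSS
#' (including the leave-one-out slopes) on each draw. The global p-value is
#' `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`. Each SNP's observed residual is
#' compared with its own simulated residual distribution; instruments with
#' per-SNP p below `sig / J` (Bonferroni) form the outlier set. When
#' outliers are found, a corrected IVW estimate excluding them is returned
#' together with a distortion test comparing the raw-minus-corrected shift
#' against shifts from removing random subsets of the same size.
#'
#' @param hset A `"harmonized_set"` with at least 4 pairs.
#' @param n_sim Number of null simulations (default 1000).
#' @param sig Significance level for the outlier test before Bonferroni
#'   correction (default 0.05).
#' @param seed Simulation seed; identical seeds give bit-identical results.
#' @return A list of class `"presso_result"`: `global_rss`, `global_p`,
#'   `per_snp_p` (named), `outlier_set` (indices), `outlier_snps`,
#'   `raw_estimate`, `corrected_estimate` (or `NULL`), `distortion_p` (or
#'   `NULL`), `n_sim`, `sig`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000L, sig = 0.05, seed = 1L) {
  p <- require_pairs(hset, 4L, "MR-PRESSO")
  J <- nrow(p)
  bx <- p$beta_exp; by <- p$beta_out; sx <- p$se_exp; sy <- p$se_out
  w <- 1 / sy^2

  th_loo <- loo_thetas(bx, by, sy)
  res_obs <- w * (by - th_loo * bx)^2
  rss_obs <- sum(res_obs)

  out <- with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(n_sim * J, rep(bx, each = n_sim),
                                  rep(sx, each = n_sim)), n_sim, J)
    by_sim <- matrix(stats::rnorm(n_sim * J, rep(th_loo * bx, each = n_sim),
                                  rep(sy, each = n_sim)), n_sim, J)
    th_sim <- loo_thetas(bx_sim, by_sim, sy)
    res_sim <- sweep((by_sim - th_sim * bx_sim)^2, 2L, sy^2, "/")
    rss_sim <- rowSums(res_sim)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    per_snp_p <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1)
    outlier_set <- which(per_snp_p < sig / J)

    raw <- mr_ivw(hset)
    corrected <- NULL
    distortion_p <- NULL
    if (length(outlier_set) && (J - length(outlier_set)) >= 2L) {
      sub <- hset
      sub$pairs <- p[-outlier_set, , drop = FALSE]
      corrected <- mr_ivw(sub)
      d_obs <- raw$beta - corrected$beta
      d_null <- vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(J, length(outlier_set))
        keep <- setdiff(seq_len(J), drop_idx)
        raw$beta - sum(bx[keep] * by[keep] / sy[keep]^2) /
          sum(bx[keep]^2 / sy[keep]^2)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
    list(global_p = global_p, per_snp_p = per_snp_p,
         outlier_set = outlier_set, raw = raw, corrected = corrected,
         distortion_p = distortion_p)
  })

  names(out$per_snp_p) <- p$snp
  structure(list(global_rss = rss_obs, global_p = out$global_p,
                 per_snp_p = out$per_snp_p, outlier_set = out$outlier_set,
                 outlier_snps = p$snp[out$outlier_set],
                 raw_estimate = out$raw, corrected_estimate = out$corrected,
                 distortion_p = out$distortion_p,
                 n_sim = as.integer(n_sim), sig = sig, seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4f, global p = %.4g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outlier_set)) {
    cat("  outliers:", paste(x$outlier_snps, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_p))
    cat("  corrected "); print(x$corrected_estimate)
  } else {
    cat("  no significant outliers detected\n")
  }
  invisible(x)
}

# cML objective: sum (bx-b)^2/(2 sx^2) + (by - theta b - r)^2/(2 sy^2)
cml_objective <- function(theta, b, r, bx, by, sx, sy) {
  sum((bx - b)^2 / (2 * sx^2) + (by - theta * b - r)^2 / (2 * sy^2))
}

# One descent run from a starting slope. Alternates two exact steps: (1)
# given the current slope and true effects, declare the k largest
# standardized residuals invalid; (2) given that selection, minimize the
# objective exactly — the invalid residuals are absorbed by r, the valid
# true effects are profiled out in closed form, and the slope solves the
# resulting 1-D profile problem. Each step is an exact minimization, so the
# objective is monotone non-increasing and the selection can change only
# finitely many times.
cml_descend <- function(theta0, k, bx, by, sx, sy, tol, max_iter) {
  J <- length(bx)
  theta <- theta0
  b <- bx
  r <- numeric(J)
  trace <- numeric(0)
  converged <- FALSE
  sel_prev <- NULL
  for (it in seq_len(max_iter)) {
    resid <- (by - theta * b) / sy
    sel <- if (k > 0L) sort(order(abs(resid), decreasing = TRUE)[seq_len(k)])
           else integer(0)
    valid <- if (k > 0L) setdiff(seq_len(J), sel) else seq_len(J)
    f <- function(th) ml_profile_nll(th, bx[valid], by[valid], sx[valid], sy[valid])
    init <- sum(bx[valid] * by[valid] / sy[valid]^2) /
      sum(bx[valid]^2 / sy[valid]^2)
    se0 <- 1 / sqrt(sum(bx[valid]^2 / sy[valid]^2))
    width <- 10 * max(se0, abs(init), 0.5)
    theta_new <- stats::optimize(f, init + c(-width, width), tol = 1e-10)$minimum
    b <- (bx / sx^2 + theta_new * by / sy^2) / (1 / sx^2 + theta_new^2 / sy^2)
    b[sel] <- bx[sel]
    r[] <- 0
    r[sel] <- by[sel] - theta_new * bx[sel]
    trace <- c(trace, cml_objective(theta_new, b, r, bx, by, sx, sy))
    if (is.finite(theta_new) && identical(sel, sel_prev) &&
        abs(theta_new - theta) < max(tol, 1e-10)) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
    sel_prev <- sel
  }
  list(theta = theta, b = b, r = r, converged = converged,
       objective = cml_objective(theta, b, r, bx, by, sx, sy), trace = trace)
}

#' Constrained maximum likelihood with a fixed number of invalid instruments
#'
#' Minimizes the joint Gaussian objective over the causal slope, true
#' instrument effects, and direct effects `r_j`, subject to exactly `k`
#' non-zero `r_j`. Coordinate descent: the `k` instruments with the largest
#' standardized residuals are declared invalid and their residuals absorbed,
#' then the true effects and the slope are updated in closed form.
#' Restarted from the IVW estimate plus seeded perturbations (SD half the
#' IVW standard error); the best converged objective wins. The standard
#' error comes from the curvature of the valid-set profile likelihood at the
#' optimum.
#'
#' @param hset A `"harmonized_set"`.
#' @param k Number of invalid instruments, `0 <= k <= J - 2`.
#' @param n_starts Number of random restarts (default 10).
#' @param tol Convergence tolerance on the slope (default 1e-8).
#' @param max_iter Iteration cap per start (default 500).
#' @param seed Seed for the restart perturbations.
#' @return A list: `theta`, `se`, `neg2ll`, `invalid_set` (indices),
#'   `invalid_snps`, `converged`, `k`, `obj_trace` (objective per iteration
#'   of the winning start, non-increasing).
#' @export
cml_fixed_k <- function(hset, k, n_starts = 10L, tol = 1e-8, max_iter = 500L,
                        seed = 1L) {
  p <- require_pairs(hset, 2L, "cML")
  J <- nrow(p)
  k <- as.integer(k)
  if (k < 0L || k > J - 2L) stop_mr("k outside range 0..J-2 (J = %d, k = %d)", J, k)
  bx <- p$beta_exp; by <- p$beta_out; sx <- p$se_exp; sy <- p$se_out
  init <- ivw_sums(bx, by, sy)
  starts <- with_seed(seed, {
    c(init$theta,
      if (n_starts > 1L) init$theta +
        stats::rnorm(n_starts - 1L, 0, 0.5 * init$se_fixed))
  })
  best <- NULL
  for (th0 in starts) {
    run <- cml_descend(th0, k, bx, by, sx, sy, tol, max_iter)
    if (run$converged && (is.null(best) || run$objective < best$objective)) {
      best <- run
    }
  }
  if (is.null(best)) {
    stop_mr("cML (k = %d) failed to converge in %d iterations from %d starts",
            k, max_iter, length(starts))
  }
  invalid <- sort(which(best$r != 0))
  valid <- setdiff(seq_len(J), invalid)
  # curvature of the valid-set profile likelihood
  g <- function(th) ml_profile_nll(th, bx[valid], by[valid], sx[valid], sy[valid])
  h <- 1e-4 * max(1, abs(best$theta))
  d2 <- (g(best$theta + h) - 2 * g(best$theta) + g(best$theta - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) {
    1 / sqrt(d2)
  } else {
    warning("cML profile curvature not positive; falling back to valid-set IVW SE",
            call. = FALSE)
    ivw_sums(bx[valid], by[valid], sy[valid])$se_fixed
  }
  list(theta = best$theta, se = se, neg2ll = 2 * best$objective,
       invalid_set = invalid, invalid_snps = p$snp[invalid],
       converged = TRUE, k = k, obj_trace = best$trace)
}

#' cML with BIC model averaging (cML-MA-BIC)
#'
#' Runs [cml_fixed_k()] for every admissible number of invalid instruments
#' `K = 0..J-2`, scores each by `BIC_K = -2 loglik_K + K log(n_effective)`,
#' and averages the slopes with weights proportional to
#' `exp(-(BIC_K - min BIC)/2)`. The model-averaged variance adds the
#' between-model spread: `se_MA^2 = sum rho_K (se_K^2 + (theta_K -
#' theta_MA)^2)`. Unlike Egger-type corrections this requires no
#' instrument-strength-independent-pleiotropy (InSIDE) assumption.
#'
#' @param hset A `"harmonized_set"` with at least 3 pairs.
#' @param n_effective Effective sample size for the BIC penalty; defaults to
#'   the smaller of the exposure and outcome sample sizes recorded in
#'   `hset`.
#' @param n_starts,tol,max_iter,seed Passed to [cml_fixed_k()]; each `K`
#'   gets a derived sub-seed.
#' @return A list of class `"cml_result"`: `per_k` (data frame `k`, `theta`,
#'   `se`, `neg2ll`, `bic`, `weight`), `invalid_sets`, `ma_theta`, `ma_se`,
#'   `ma_p`, `n_effective`, `seed`.
#' @export
cml_ma_bic <- function(hset, n_effective = NULL, n_starts = 10L, tol = 1e-8,
                       max_iter = 500L, seed = 1L) {
  p <- require_pairs(hset, 3L, "cML-MA")
  J <- nrow(p)
  n_effective <- n_effective %||% suppressWarnings(
    min(hset$n_exposure, hset$n_outcome, na.rm = TRUE))
  if (!is.finite(n_effective) || n_effective <= 0) {
    stop_mr("cML-MA requires a positive n_effective (none recorded in the harmonized set)")
  }
  ks <- 0:(J - 2L)
  fits <- lapply(ks, function(k) {
    cml_fixed_k(hset, k, n_starts = n_starts, tol = tol, max_iter = max_iter,
                seed = derive_seed(seed, k))
  })
  neg2ll <- vapply(fits, `[[`, numeric(1), "neg2ll")
  bic <- neg2ll + ks * log(n_effective)
  wts <- exp(-(bic - min(bic)) / 2)
  wts <- wts / sum(wts)
  thetas <- vapply(fits, `[[`, numeric(1), "theta")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  ma_theta <- sum(wts * thetas)
  ma_se <- sqrt(sum(wts * (ses^2 + (thetas - ma_theta)^2)))
  structure(list(per_k = data.frame(k = ks, theta = thetas, se = ses,
                                    neg2ll = neg2ll, bic = bic, weight = wts),
                 invalid_sets = lapply(fits, `[[`, "invalid_set"),
                 ma_theta = ma_theta, ma_se = ma_se,
                 ma_p = 2 * stats::pnorm(-abs(ma_theta / ma_se)),
                 n_effective = n_effective, seed = as.integer(seed)),
            class = "cml_result")
}

#' @export
print.cml_result <- function(x, ...) {
  best <- x$per_k$k[which.min(x$per_k$bic)]
  cat(sprintf("cML-MA-BIC: theta = %.4f (SE %.4f), p = %.3g; BIC-best K = %d; weight on K=0: %.2f\n",
              x$ma_theta, x$ma_se, x$ma_p, best, x$per_k$weight[1L]))
  invisible(x)
}

#' Convert a cML-MA result to an `"mr_result"`
#' @param x A `"cml_result"`.
#' @param n_snp Number of instruments (defaults to rows of `per_k` + 1).
#' @export
as_mr_result <- function(x, n_snp = nrow(x$per_k) + 1L) {
  stopifnot(inherits(x, "cml_result"))
  mr_result("cml", n_snp, x$ma_theta, x$ma_se, pvalue = x$ma_p,
            extras = list(weight_k0 = x$per_k$weight[1L],
                          bic_best_k = x$per_k$k[which.min(x$per_k$bic)],
                          seed = x$seed))
}
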