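#' Fit the two-sample MR estimator ensemble
#'
#' The central fitting function: runs the requested causal-effect estimators
#' on a harmonized instrument set and bundles them with heterogeneity,
#' pleiotropy, and influence diagnostics in one model object.
#'
#' Available methods: `"ivw"` ([mr_ivw()]), `"ml"` ([mr_ml()]), `"egger"`
#' ([mr_egger()]), `"wmedian"` ([mr_wmedian()]), `"wmode"` ([mr_wmode()]),
#' `"cml"` ([cml_ma_bic()]), `"wald"` ([wald_ratio()], single instrument).
#' Methods whose minimum instrument count exceeds the available pairs are
#' skipped with a message recorded in `$skipped`. MR-PRESSO runs as a
#' diagnostic when `run_presso = TRUE` and at least 4 pairs are available.
#'
#' @param hset A `"harmonized_set"` (from [harmonize()] or
#'   [harmonized_set()]).
#' @param methods Character vector of estimator names.
#' @param run_presso Run the MR-PRESSO diagnostic (default `TRUE`).
#' @param n_boot Bootstrap resamples for the median/mode standard errors.
#' @param presso_nsim MR-PRESSO null simulations.
#' @param ivw_mode `"mre-floor"` or `"fixed"` (see [mr_ivw()]).
#' @param phi Weighted-mode bandwidth multiplier.
#' @param cml_n_starts Restarts for the cML coordinate descent.
#' @param n_effective Effective sample size for the cML BIC penalty
#'   (defaults to the smaller recorded GWAS size).
#' @param seed Integer seed driving every stochastic component (bootstraps,
#'   PRESSO simulations, cML restarts) through derived sub-seeds.
#' @return An object of class `"mr_fit"`: a list with `estimates` (named
#'   list of [mr_result()]s), `heterogeneity` ([cochran_q()], when J >= 2),
#'   `presso`, `loo` ([leave_one_out()], when J >= 3), `harmonized`,
#'   `skipped`, and `seed`. Methods: `print`, `summary`, `coef`, `confint`,
#'   `residuals`, `plot`.
#' @examples
#' sim <- simulate_instrument_panel(sim_config(n_snps = 12, theta = 0.3, seed = 42))
#' hset <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(hset, methods = c("ivw", "ml", "egger"), seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(hset,
                   methods = c("ivw", "ml", "egger", "wmedian", "wmode", "cml"),
                   run_presso = TRUE, n_boot = 1000L, presso_nsim = 1000L,
                   ivw_mode = c("mre-floor", "fixed"), phi = 1,
                   cml_n_starts = 10L, n_effective = NULL, seed = 1L) {
  stopifnot(inherits(hset, "harmonized_set"))
  ivw_mode <- match.arg(ivw_mode)
  J <- n_instruments(hset)
  if (J < 1L) stop_mr("harmonized set has no analyzable instrument pairs")
  estimates <- list()
  skipped <- character(0)
  for (mth in methods) {
    res <- tryCatch(
      fit_one_method(hset, mth, n_boot = n_boot, ivw_mode = ivw_mode,
                     phi = phi, cml_n_starts = cml_n_starts,
                     n_effective = n_effective,
                     seed = derive_seed(seed, match(mth, METHOD_NAMES))),
      error = function(e) conditionMessage(e))
    if (inherits(res, "mr_result")) estimates[[mth]] <- res
    else skipped[mth] <- res
  }
  het <- if (J >= 2L) cochran_q(hset) else NULL
  presso <- NULL
  if (isTRUE(run_presso) && J >= 4L) {
    presso <- mr_presso(hset, n_sim = presso_nsim,
                        seed = derive_seed(seed, match("presso", METHOD_NAMES)))
  }
  loo <- if (J >= 3L) leave_one_out(hset, mode = ivw_mode) else NULL
  structure(list(estimates = estimates, heterogeneity = het, presso = presso,
                 loo = loo, harmonized = hset, skipped = skipped,
                 seed = as.integer(seed)),
            class = "mr_fit")
}

METHOD_NAMES <- c("wald", "ivw", "ml", "egger", "wmedian", "wmode", "cml",
                  "presso")

# Single-method dispatch shared by mr_fit() and the panel pipeline.
fit_one_method <- function(hset, method, n_boot = 1000L,
                           ivw_mode = "mre-floor", phi = 1,
                           cml_n_starts = 10L, n_effective = NULL, seed = 1L) {
  switch(method,
    wald    = wald_ratio(hset),
    ivw     = mr_ivw(hset, mode = ivw_mode),
    ml      = mr_ml(hset),
    egger   = mr_egger(hset),
    wmedian = mr_wmedian(hset, n_boot = n_boot, seed = seed),
    wmode   = mr_wmode(hset, phi = phi, n_boot = n_boot, seed = seed),
    cml     = as_mr_result(
      cml_ma_bic(hset, n_effective = n_effective, n_starts = cml_n_starts,
                 seed = seed),
      n_snp = n_instruments(hset)),
    stop_mr("unknown method '%s'", method))
}

estimates_frame <- function(fit) {
  rows <- lapply(fit$estimates, function(r) {
    data.frame(method = r$method, n_snp = r$n_snp, beta = r$beta, se = r$se,
               or_ = r$or_, ci_low = r$ci_low, ci_high = r$ci_high,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$harmonized$exposure_name, x$harmonized$outcome_name,
              n_instruments(x$harmonized)))
  df <- estimates_frame(x)
  df$beta <- round(df$beta, digits + 1L)
  df$se <- round(df$se, digits + 1L)
  for (col in c("or_", "ci_low", "ci_high")) df[[col]] <- round(df[[col]], digits)
  df$pvalue <- signif(df$pvalue, digits)
  print(df, row.names = FALSE)
  if (length(x$skipped)) {
    cat("skipped:", paste(sprintf("%s (%s)", names(x$skipped), x$skipped),
                          collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$heterogeneity)) {
    cat(sprintf("Heterogeneity: Q = %.3f (df %d), p = %.3g\n",
                fit$heterogeneity$q_stat, fit$heterogeneity$df,
                fit$heterogeneity$pvalue))
  }
  eg <- fit$estimates$egger
  if (!is.null(eg)) {
    cat(sprintf("Egger intercept: %.4f (SE %.4f), p = %.3g\n",
                eg$extras$egger_intercept, eg$extras$intercept_se,
                eg$extras$intercept_p))
  }
  if (!is.null(fit$presso)) {
    cat(sprintf("MR-PRESSO global p = %.3g; %d outlier(s)\n",
                fit$presso$global_p, length(fit$presso$outlier_set)))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- if (missing(parm)) object$estimates else object$estimates[parm]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- t(vapply(est, function(r) r$beta + c(-1, 1) * z * r$se, numeric(2)))
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  p <- object$harmonized$pairs
  theta <- if (!is.null(object$estimates$ivw)) object$estimates$ivw$beta
           else ivw_sums(p$beta_exp, p$beta_out, p$se_out)$theta
  r <- (p$beta_out - theta * p$beta_exp) / p$se_out
  names(r) <- p$snp
  r
}

#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$harmonized$pairs
  flip <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- flip * p$beta_exp; by <- flip * p$beta_out
  graphics::plot(bx, by, pch = 19,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", ...)
  graphics::segments(bx, by - 1.96 * p$se_out, bx, by + 1.96 * p$se_out,
                     col = "grey60")
  graphics::segments(bx - 1.96 * p$se_exp, by, bx + 1.96 * p$se_exp, by,
                     col = "grey60")
  cols <- stats::setNames(seq_along(x$estimates) + 1L, names(x$estimates))
  for (nm in names(x$estimates)) {
    r <- x$estimates[[nm]]
    a <- if (nm == "egger") r$extras$egger_intercept else 0
    graphics::abline(a = a, b = r$beta, col = cols[nm], lwd = 1.5)
  }
  graphics::legend("topleft", legend = names(x$estimates),
                   col = cols, lwd = 1.5, bty = "n")
  invisible(x)
}
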