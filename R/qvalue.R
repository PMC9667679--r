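#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the grid
#' `lambda = 0.05, 0.10, ..., 0.95` as `#\{p > lambda\} / (m (1 - lambda))`,
#' smooths the estimates with a cubic smoothing spline (3 df), and takes the
#' fitted value at `lambda = 0.95`, clamped to (0, 1]. q-values follow the
#' step-down recursion on descending p-values:
#' `q_(m) = pi0 * p_(m)`, `q_(i) = min(pi0 * m * p_(i) / i, q_(i+1))`.
#' With `method = "fixed_pi0_1"` the null proportion is forced to 1, which
#' reproduces Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param method `"smoother"` (default) or `"fixed_pi0_1"`.
#' @return A list of class `"qvalue_result"`: `pi0`, `qvalues` (aligned to
#'   the input), `lambda_grid`, `method`.
#' @export
qvalues <- function(pvals, method = c("smoother", "fixed_pi0_1")) {
  method <- match.arg(method)
  if (!length(pvals)) stop_mr("empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop_mr("p-values must lie in (0,1]")
  }
  m <- length(pvals)
  lambda <- seq(0.05, 0.95, by = 0.05)
  if (method == "fixed_pi0_1") {
    pi0 <- 1
  } else {
    pi0_raw <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_raw, df = 3)
    pi0 <- stats::predict(fit, x = 0.95)$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  ord <- order(pvals, decreasing = TRUE)
  p_desc <- pvals[ord]
  q_desc <- numeric(m)
  q_desc[1L] <- pi0 * p_desc[1L]
  if (m > 1L) {
    for (i in 2:m) {
      rank_i <- m - i + 1L
      q_desc[i] <- min(pi0 * m * p_desc[i] / rank_i, q_desc[i - 1L])
    }
  }
  q <- numeric(m)
  q[ord] <- q_desc
  structure(list(pi0 = pi0, qvalues = q, lambda_grid = lambda,
                 method = method),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("q-values (%s): m = %d, pi0 = %.3f, min q = %.3g\n",
              x$method, length(x$qvalues), x$pi0, min(x$qvalues)))
  invisible(x)
}

#' Classify an association from its p- and q-value
#'
#' `"significant"` when `p < p_thresh` and `q < q_thresh`; `"suggestive"`
#' when `p < p_thresh` but `q >= q_thresh`; `"null"` otherwise. Defaults
#' implement the q < 0.1 discovery rule with a p < 0.05 suggestive band.
#'
#' @param pvalue,qvalue Numeric vectors in \[0, 1\] (recycled).
#' @param q_thresh FDR threshold (default 0.1).
#' @param p_thresh Nominal threshold (default 0.05).
#' @return Character vector of classifications.
#' @export
classify_association <- function(pvalue, qvalue, q_thresh = 0.1, p_thresh = 0.05) {
  stopifnot(all(pvalue >= 0 & pvalue <= 1, na.rm = TRUE),
            all(qvalue >= 0 & qvalue <= 1, na.rm = TRUE))
  ifelse(pvalue < p_thresh & qvalue < q_thresh, "significant",
         ifelse(pvalue < p_thresh, "suggestive", "null"))
}
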