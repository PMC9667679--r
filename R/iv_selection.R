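#' Select candidate instruments by p-value and MAF
#'
#' Keeps SNPs associated with the exposure below the locus-wide significance
#' threshold and with minor allele frequency strictly above `maf_min`
#' (the filter removes MAF <= `maf_min`). Rows with missing allele frequency
#' are kept (frequency unknown) and flagged in the `"flagged_missing_eaf"`
#' attribute of the result.
#'
#' @param x A [sumstats_table()].
#' @param p_thresh Significance threshold (default `1e-5`, locus-wide).
#' @param maf_min MAF cutoff (default `0.01`).
#' @return A filtered `"sumstats"` table.
#' @export
select_candidates <- function(x, p_thresh = 1e-5, maf_min = 0.01) {
  stopifnot(inherits(x, "sumstats"))
  if (p_thresh <= 0 || p_thresh >= 1 || maf_min <= 0 || maf_min >= 1) {
    stop_mr("thresholds must lie in (0,1)")
  }
  maf <- pmin(x$eaf, 1 - x$eaf)
  # tolerance guards the boundary against floating-point noise in 1 - eaf
  keep <- x$pval < p_thresh & (is.na(maf) | maf - maf_min > 1e-12)
  res <- sumstats_table(as.data.frame(x)[keep, , drop = FALSE],
                        trait_name = trait_name(x), trait_type = trait_type(x),
                        case_fraction = case_fraction(x))
  attr(res, "flagged_missing_eaf") <- x$snp[keep & is.na(maf)]
  res
}

# genomic ordering of (chr, pos): numeric chromosomes first, then others
genomic_order <- function(chr, pos) {
  num <- suppressWarnings(as.numeric(chr))
  order(is.na(num), num, chr, pos)
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by lexicographic SNP
#' id), repeatedly takes the best remaining SNP as an index, and discards all
#' remaining SNPs on the same chromosome within `window_kb` kilobases whose
#' r-squared with the index is at least `r2_thresh`. Index SNPs form the
#' result, returned in genomic order.
#'
#' @param x A [sumstats_table()] with `chr`/`pos` available.
#' @param ld An [ld_table()]; absent pairs count as r-squared 0.
#' @param r2_thresh Clumping r-squared threshold (default `0.001`).
#' @param window_kb Window half-width in kilobases (default `10000`).
#' @return The retained `"sumstats"` rows in genomic order.
#' @export
clump <- function(x, ld, r2_thresh = 0.001, window_kb = 10000) {
  stopifnot(inherits(x, "sumstats"), inherits(ld, "ld_table"))
  df <- as.data.frame(x)
  if (nrow(df) == 0L) return(x)
  if (anyNA(df$chr) || anyNA(df$pos)) {
    stop_mr("clumping requires chr and pos for every candidate SNP")
  }
  window_bp <- window_kb * 1000
  remaining <- df[order(df$pval, df$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining)) {
    idx <- remaining[1L, ]
    kept <- c(kept, idx$snp)
    remaining <- remaining[-1L, , drop = FALSE]
    if (nrow(remaining)) {
      in_window <- remaining$chr == idx$chr &
        abs(remaining$pos - idx$pos) <= window_bp
      linked <- in_window &
        ld_lookup(ld, remaining$snp, idx$snp) >= r2_thresh
      remaining <- remaining[!linked, , drop = FALSE]
    }
  }
  out <- df[df$snp %in% kept, , drop = FALSE]
  out <- out[genomic_order(out$chr, out$pos), , drop = FALSE]
  res <- sumstats_table(out, trait_name = trait_name(x),
                        trait_type = trait_type(x),
                        case_fraction = case_fraction(x))
  attr(res, "flagged_missing_eaf") <- attr(x, "flagged_missing_eaf")
  res
}

# ---- harmonization ----------------------------------------------------------

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Construct a harmonized instrument set directly
#'
#' Assembles a `"harmonized_set"` from already-paired instrument effects —
#' the container every estimator consumes. [harmonize()] builds one from raw
#' exposure/outcome tables; this constructor serves pre-harmonized data (e.g.
#' published per-SNP instrument tables).
#'
#' @param pairs Data frame with at least `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; optionally `eaf_exp`, `eaf_out`, `chr`, `pos`,
#'   `ea`, `oa`, `pval_exp`, `pval_out`, `action`.
#' @param exposure_name,outcome_name Trait labels.
#' @param n_exposure,n_outcome Sample sizes (used for instrument strength and
#'   cML's effective sample size).
#' @param case_fraction Outcome case fraction, if binary.
#' @param audit Optional full audit table (defaults to `pairs`).
#' @return An object of class `"harmonized_set"`.
#' @export
harmonized_set <- function(pairs, exposure_name = "exposure",
                           outcome_name = "outcome", n_exposure = NA_integer_,
                           n_outcome = NA_integer_, case_fraction = NULL,
                           audit = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  needed <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(needed, names(pairs))
  if (length(miss)) stop_mr("pairs lacks column(s): %s", paste(miss, collapse = ", "))
  for (col in c("eaf_exp", "eaf_out", "pval_exp", "pval_out")) {
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  }
  if (is.null(pairs$action)) pairs$action <- "kept"
  if (anyDuplicated(pairs$snp)) stop_mr("duplicate snp ids in harmonized pairs")
  if (any(pairs$se_exp <= 0) || any(pairs$se_out <= 0)) {
    stop_mr("all standard errors must be > 0")
  }
  rownames(pairs) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 pairs = pairs, audit = audit %||% pairs,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction = case_fraction),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  acts <- table(x$audit$action)
  cat(sprintf("Harmonized set: %s -> %s, %d analyzable instrument pair(s)\n",
              x$exposure_name, x$outcome_name, nrow(x$pairs)))
  cat("  audit:", paste(sprintf("%s=%d", names(acts), as.integer(acts)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Number of instrument pairs in a harmonized set
#' @param hset A `"harmonized_set"`.
#' @export
n_instruments <- function(hset) nrow(hset$pairs)

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs each exposure instrument with the outcome record for the same SNP
#' and expresses both effects on the exposure's effect allele:
#' \itemize{
#'   \item same allele pair, same orientation: kept unchanged;
#'   \item same pair with effect/other swapped: outcome beta negated and
#'     `eaf_out` replaced by `1 - eaf_out` (`action = "flipped"`);
#'   \item complementary-strand pair (e.g. A/G vs T/C): alleles re-complemented,
#'     then handled as above;
#'   \item palindromic pair (A/T or C/G): the strand is inferred from allele
#'     frequencies — dropped when either frequency falls in the ambiguity
#'     window (or is missing); kept when both frequencies sit on the same side
#'     of 0.5; flipped when on opposite sides;
#'   \item incompatible allele pairs are dropped.
#' }
#' Instruments absent from the outcome are dropped (no proxy search). All
#' decisions, including drops, are recorded in the audit table.
#'
#' @param exposure_ivs Selected exposure instruments ([sumstats_table()]).
#' @param outcome Outcome [sumstats_table()].
#' @param ambiguity Palindrome ambiguity window on allele frequency
#'   (default `c(0.42, 0.58)`, inclusive).
#' @return A `"harmonized_set"`; `pairs` holds actions `kept`/`flipped`,
#'   `audit` additionally records `dropped_palindromic`,
#'   `dropped_incompatible`, and `dropped_missing`.
#' @export
harmonize <- function(exposure_ivs, outcome, ambiguity = c(0.42, 0.58)) {
  stopifnot(inherits(exposure_ivs, "sumstats"), inherits(outcome, "sumstats"))
  ex <- as.data.frame(exposure_ivs)
  ou <- as.data.frame(outcome)
  m <- match(ex$snp, ou$snp)

  J <- nrow(ex)
  action <- character(J)
  beta_out <- se_out <- eaf_out <- pval_out <- rep(NA_real_, J)

  in_window <- function(f) !is.na(f) & f >= ambiguity[1] & f <= ambiguity[2]

  for (i in seq_len(J)) {
    j <- m[i]
    if (is.na(j)) { action[i] <- "dropped_missing"; next }
    ea <- ex$ea[i]; oa <- ex$oa[i]
    ea2 <- ou$ea[j]; oa2 <- ou$oa[j]
    b <- ou$beta[j]; f <- ou$eaf[j]
    se_out[i] <- ou$se[j]; pval_out[i] <- ou$pval[j]

    if (is_palindromic(ea, oa)) {
      same_pair <- (ea2 == ea && oa2 == oa) || (ea2 == oa && oa2 == ea)
      if (!same_pair) { action[i] <- "dropped_incompatible"; next }
      # align outcome labels to the exposure's effect allele first
      if (ea2 == oa) { b <- -b; f <- if (is.na(f)) NA_real_ else 1 - f }
      fe <- ex$eaf[i]
      if (is.na(fe) || is.na(f) || in_window(fe) || in_window(f)) {
        action[i] <- "dropped_palindromic"; next
      }
      if (sign(fe - 0.5) == sign(f - 0.5)) {
        # same strand: label alignment already matched frequencies
        flipped <- ea2 == oa
      } else {
        # opposite strand: the label match was spurious; flip once more
        b <- -b; f <- 1 - f
        flipped <- ea2 != oa
      }
      action[i] <- if (flipped) "flipped" else "kept"
      beta_out[i] <- b; eaf_out[i] <- f
      next
    }

    # non-palindromic: resolve strand by allele labels
    if (!((ea2 %in% c(ea, oa)) && (oa2 %in% c(ea, oa)) && ea2 != oa2)) {
      ea2c <- unname(COMPLEMENT[ea2]); oa2c <- unname(COMPLEMENT[oa2])
      if ((ea2c %in% c(ea, oa)) && (oa2c %in% c(ea, oa)) && ea2c != oa2c) {
        ea2 <- ea2c; oa2 <- oa2c
      } else {
        action[i] <- "dropped_incompatible"; next
      }
    }
    if (ea2 == ea) {
      action[i] <- "kept"
    } else {
      action[i] <- "flipped"
      b <- -b; f <- if (is.na(f)) NA_real_ else 1 - f
    }
    beta_out[i] <- b; eaf_out[i] <- f
  }

  audit <- data.frame(snp = ex$snp, chr = ex$chr, pos = ex$pos,
                      ea = ex$ea, oa = ex$oa,
                      beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
                      pval_exp = ex$pval,
                      beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
                      pval_out = pval_out, action = action,
                      stringsAsFactors = FALSE)
  pairs <- audit[audit$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(pairs) <- NULL
  harmonized_set(pairs,
                 exposure_name = trait_name(exposure_ivs),
                 outcome_name = trait_name(outcome),
                 n_exposure = stats::median(ex$n, na.rm = TRUE),
                 n_outcome = stats::median(ou$n, na.rm = TRUE),
                 case_fraction = case_fraction(outcome),
                 audit = audit)
}

# ---- instrument strength & power -------------------------------------------

#' F statistic from variance explained
#'
#' `F = R2 * (N - 1 - K) / ((1 - R2) * K)`, the joint instrument-strength
#' statistic for `K` instruments explaining a fraction `R2` of exposure
#' variance in a sample of size `N`. Values above 10 are conventionally taken
#' to rule out weak-instrument bias.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Exposure sample size.
#' @param k Number of instruments.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(r2 >= 0, r2 < 1, k >= 1)
  r2 * (n - 1 - k) / ((1 - r2) * k)
}

#' Instrument strength of a harmonized set
#'
#' Variance explained is accumulated per SNP as `2 p (1 - p) beta^2` (the
#' standardized-exposure convention, `p` the effect-allele frequency), with
#' the t-statistic fallback `t^2 / (t^2 + N - 2)` for SNPs lacking a
#' frequency; the F statistic then follows [f_statistic()].
#'
#' @param hset A `"harmonized_set"`.
#' @param n Exposure sample size (defaults to the set's recorded size).
#' @return A list of class `"strength_result"`: `r2`, `f_stat`, `n`, `k`.
#' @export
instrument_strength <- function(hset, n = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs
  k <- nrow(p)
  if (k < 1L) stop_mr("no instrument pairs")
  n <- n %||% hset$n_exposure
  if (is.na(n) || n <= k + 1) stop_mr("insufficient sample size (need N > K + 1)")
  tt <- (p$beta_exp / p$se_exp)^2
  r2_snp <- ifelse(!is.na(p$eaf_exp),
                   2 * p$eaf_exp * (1 - p$eaf_exp) * p$beta_exp^2,
                   tt / (tt + n - 2))
  r2 <- sum(r2_snp)
  if (r2 >= 1) stop_mr("variance explained reached %.3f; check effect scaling", r2)
  structure(list(r2 = r2, f_stat = f_statistic(r2, n, k),
                 n = as.integer(n), k = as.integer(k)),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("Instrument strength: R2 = %.4g, F = %.2f (N = %d, K = %d)\n",
              x$r2, x$f_stat, x$n, x$k))
  invisible(x)
}

#' Approximate power of a two-sample MR test with a binary outcome
#'
#' The standard normal approximation
#' `power = Phi(|theta| * sqrt(N * R2 * v * (1 - v)) - z_{1-alpha/2})`
#' for an outcome GWAS of `n_outcome` subjects with case fraction `v`, with
#' instruments explaining `r2` of the exposure and a true log-odds effect
#' `theta` per exposure SD.
#'
#' @param n_outcome Outcome sample size.
#' @param case_fraction Case fraction in (0, 1).
#' @param r2 Exposure variance explained by the instruments (> 0).
#' @param theta True causal effect on the log-odds scale.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, case_fraction, r2, theta, alpha = 0.05) {
  if (r2 <= 0) stop_mr("r2 must be > 0")
  stopifnot(case_fraction > 0, case_fraction < 1, alpha > 0, alpha < 1)
  ncp <- abs(theta) * sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}
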