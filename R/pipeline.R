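# Panel orchestration: instrument selection -> harmonization -> estimator
# ensemble across many exposures, per-method q-value FDR, classification,
# bidirectional analysis, and table exports.

#' Panel analysis configuration
#'
#' Collects every threshold and seed the pipeline uses. Defaults implement
#' the conventional many-taxa screen settings: locus-wide instrument
#' selection at p < 1e-5, clumping at r-squared < 0.001 in a 10,000 kb
#' window, MAF > 0.01, palindrome ambiguity window \[0.42, 0.58\], FDR
#' discovery at q < 0.1 with a p < 0.05 suggestive band.
#'
#' @param p_thresh Instrument p-value threshold.
#' @param maf_min MAF cutoff (SNPs with MAF <= this are removed).
#' @param clump_r2,clump_kb Clumping threshold and window.
#' @param ambiguity Palindrome ambiguity window.
#' @param methods Estimators to run per exposure (see [mr_fit()]).
#' @param run_presso Run MR-PRESSO diagnostics where >= 4 instruments.
#' @param run_loo Keep leave-one-out tables for export.
#' @param n_boot,presso_nsim Bootstrap/simulation sizes.
#' @param min_snps Minimum instruments for the full ensemble; exposures with
#'   fewer get Wald (1 SNP) or IVW (2 SNPs) only, flagged.
#' @param q_thresh,p_sig Classification thresholds.
#' @param qvalue_method `"smoother"` or `"fixed_pi0_1"` (see [qvalues()]).
#' @param primary_method Method defining panel "hits" (reverse-analysis
#'   triggers).
#' @param ivw_mode,phi,cml_n_starts Estimator options.
#' @param seed Master seed; every stochastic step derives a sub-seed.
#' @return A list of class `"mr_config"`.
#' @export
mr_config <- function(p_thresh = 1e-5, maf_min = 0.01, clump_r2 = 0.001,
                      clump_kb = 10000, ambiguity = c(0.42, 0.58),
                      methods = c("ivw", "ml", "egger", "wmedian", "wmode", "cml"),
                      run_presso = TRUE, run_loo = TRUE,
                      n_boot = 1000L, presso_nsim = 1000L, min_snps = 3L,
                      q_thresh = 0.1, p_sig = 0.05,
                      qvalue_method = c("smoother", "fixed_pi0_1"),
                      primary_method = "ivw",
                      ivw_mode = c("mre-floor", "fixed"), phi = 1,
                      cml_n_starts = 10L, seed = 1L) {
  structure(list(p_thresh = p_thresh, maf_min = maf_min, clump_r2 = clump_r2,
                 clump_kb = clump_kb, ambiguity = ambiguity, methods = methods,
                 run_presso = run_presso, run_loo = run_loo,
                 n_boot = as.integer(n_boot),
                 presso_nsim = as.integer(presso_nsim),
                 min_snps = as.integer(min_snps), q_thresh = q_thresh,
                 p_sig = p_sig, qvalue_method = match.arg(qvalue_method),
                 primary_method = primary_method,
                 ivw_mode = match.arg(ivw_mode), phi = phi,
                 cml_n_starts = as.integer(cml_n_starts),
                 seed = as.integer(seed)),
            class = "mr_config")
}

# Analyze one already-harmonized exposure; returns rows + detail record.
analyze_exposure <- function(hset, config, exposure_seed, direction) {
  J <- n_instruments(hset)
  methods <- if (J >= config$min_snps) config$methods
             else if (J >= 2L) intersect(c("ivw"), c(config$methods, "ivw"))
             else "wald"
  fit <- mr_fit(hset, methods = methods,
                run_presso = config$run_presso && J >= 4L,
                n_boot = config$n_boot, presso_nsim = config$presso_nsim,
                ivw_mode = config$ivw_mode, phi = config$phi,
                cml_n_starts = config$cml_n_starts, seed = exposure_seed)
  strength <- tryCatch(instrument_strength(hset), error = function(e) NULL)
  het <- fit$heterogeneity
  eg <- fit$estimates$egger
  rows <- estimates_frame(fit)
  rows <- data.frame(exposure = hset$exposure_name,
                     outcome = hset$outcome_name,
                     direction = direction,
                     rows,
                     f_stat = if (is.null(strength)) NA_real_ else strength$f_stat,
                     q_stat = if (is.null(het)) NA_real_ else het$q_stat,
                     q_df = if (is.null(het)) NA_integer_ else het$df,
                     q_pvalue = if (is.null(het)) NA_real_ else het$pvalue,
                     egger_intercept = if (is.null(eg)) NA_real_ else eg$extras$egger_intercept,
                     egger_intercept_p = if (is.null(eg)) NA_real_ else eg$extras$intercept_p,
                     presso_global_p = if (is.null(fit$presso)) NA_real_ else fit$presso$global_p,
                     flag = if (J < config$min_snps) "few_instruments" else "",
                     seed = exposure_seed,
                     stringsAsFactors = FALSE)
  list(rows = rows, fit = fit)
}

# Per-method q-values across exposures (the FDR family is one method x all
# exposures, never pooled across methods), then classification.
apply_fdr <- function(rows, config) {
  rows$qvalue <- NA_real_
  for (mth in unique(rows$method)) {
    idx <- which(rows$method == mth)
    rows$qvalue[idx] <- qvalues(rows$pvalue[idx],
                                method = config$qvalue_method)$qvalues
  }
  rows$classification <- classify_association(rows$pvalue, rows$qvalue,
                                              q_thresh = config$q_thresh,
                                              p_thresh = config$p_sig)
  rows
}

#' Run the MR pipeline across an exposure panel
#'
#' For each exposure: select candidate instruments ([select_candidates()]),
#' clump ([clump()]), harmonize against the outcome ([harmonize()]), and run
#' the configured estimator ensemble with diagnostics. Exposures whose
#' harmonized set is empty are skipped with a logged reason; exposures with
#' 1-2 instruments are analyzed with Wald/IVW only and flagged. After all
#' exposures, q-values are computed per method across exposures and each row
#' is classified as significant / suggestive / null.
#'
#' @param exposures A list of exposure [sumstats_table()]s (or a single one).
#' @param outcome The outcome [sumstats_table()].
#' @param ld An [ld_table()] for clumping (`NULL` for no LD information).
#' @param config An [mr_config()].
#' @param direction Direction label stamped on rows (default `"forward"`).
#' @return A data frame of class `"panel_report"`: one row per exposure x
#'   method with estimate, diagnostics, q-value and classification columns.
#'   Attributes: `config`, `details` (per-exposure `"mr_fit"` objects),
#'   `skipped` (data frame of exposure/reason).
#' @export
run_mr_panel <- function(exposures, outcome, ld = NULL, config = mr_config(),
                         direction = "forward") {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (!length(exposures)) stop_mr("empty exposure panel")
  stopifnot(inherits(outcome, "sumstats"))
  ld <- ld %||% ld_table()
  all_rows <- list()
  details <- list()
  skipped <- data.frame(exposure = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_along(exposures)) {
    exp_i <- exposures[[i]]
    name_i <- trait_name(exp_i) %||% sprintf("exposure_%03d", i)
    cand <- select_candidates(exp_i, p_thresh = config$p_thresh,
                              maf_min = config$maf_min)
    if (!nrow(cand)) {
      skipped <- rbind(skipped, data.frame(exposure = name_i,
                                           reason = "no instruments at p threshold"))
      next
    }
    ivs <- clump(cand, ld, r2_thresh = config$clump_r2,
                 window_kb = config$clump_kb)
    hset <- harmonize(ivs, outcome, ambiguity = config$ambiguity)
    if (!n_instruments(hset)) {
      skipped <- rbind(skipped, data.frame(exposure = name_i,
                                           reason = "no harmonizable instruments"))
      next
    }
    res <- analyze_exposure(hset, config, derive_seed(config$seed, i),
                            direction)
    all_rows[[name_i]] <- res$rows
    details[[name_i]] <- res$fit
  }
  if (!length(all_rows)) stop_mr("no analyzable exposures in the panel")
  rows <- do.call(rbind, all_rows)
  rownames(rows) <- NULL
  rows <- apply_fdr(rows, config)
  structure(rows, class = c("panel_report", "data.frame"),
            config = config, details = details, skipped = skipped)
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("MR panel report: %d rows (%d exposure(s) x methods), %d significant, %d suggestive\n",
              nrow(x), length(unique(x$exposure)),
              sum(x$classification == "significant"),
              sum(x$classification == "suggestive")))
  print(utils::head(as.data.frame(x)[, c("exposure", "method", "n_snp", "or_",
                                         "ci_low", "ci_high", "pvalue",
                                         "qvalue", "classification")], 12L),
        row.names = FALSE)
  if (nrow(x) > 12L) cat(sprintf("... %d more rows\n", nrow(x) - 12L))
  invisible(x)
}

#' Panel hits under the primary method
#' @param report A `"panel_report"`.
#' @param config The report's config (defaults to its attribute).
#' @return Character vector of exposure names whose primary-method row is
#'   classified other than `"null"`.
#' @export
panel_hits <- function(report, config = attr(report, "config")) {
  pm <- report$method == config$primary_method
  unique(report$exposure[pm & report$classification != "null"])
}

#' Bidirectional panel analysis
#'
#' Runs the forward panel, then — for every forward hit under the primary
#' method — a reverse analysis with the roles swapped: instruments are
#' selected from the outcome GWAS with the same criteria and tested against
#' the hit exposure's summary statistics, with an identical estimator
#' configuration. Reverse q-values are computed across the reverse analyses
#' per method.
#'
#' @param exposures,outcome,config As in [run_mr_panel()].
#' @param ld_exposures LD table for clumping exposure instruments.
#' @param ld_outcome LD table for clumping outcome instruments (reverse
#'   direction).
#' @return A list with `forward` and `reverse` panel reports (`reverse` is
#'   `NULL` when the forward panel has no hits).
#' @export
run_bidirectional <- function(exposures, outcome, ld_exposures = NULL,
                              ld_outcome = NULL, config = mr_config()) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  forward <- run_mr_panel(exposures, outcome, ld = ld_exposures,
                          config = config, direction = "forward")
  hits <- panel_hits(forward, config)
  if (!length(hits)) {
    return(list(forward = forward, reverse = NULL))
  }
  nm <- vapply(exposures, function(e) trait_name(e) %||% "", character(1))
  rev_rows <- list()
  rev_details <- list()
  rev_skipped <- list()
  rev_config <- config
  rev_config$seed <- derive_seed(config$seed, 999983L)
  for (h in hits) {
    target <- exposures[[match(h, nm)]]
    rep_h <- tryCatch(
      run_mr_panel(list(outcome), target, ld = ld_outcome,
                   config = rev_config, direction = "reverse"),
      error = function(e) conditionMessage(e))
    if (is.character(rep_h)) {
      rev_skipped[[h]] <- data.frame(exposure = h, reason = rep_h)
      next
    }
    rev_rows[[h]] <- as.data.frame(rep_h)
    rev_details[[h]] <- attr(rep_h, "details")[[1L]]
  }
  reverse <- NULL
  if (length(rev_rows)) {
    rows <- do.call(rbind, rev_rows)
    rownames(rows) <- NULL
    rows <- apply_fdr(rows, rev_config)  # FDR family: reverse analyses per method
    reverse <- structure(rows, class = c("panel_report", "data.frame"),
                         config = rev_config, details = rev_details,
                         skipped = do.call(rbind, rev_skipped) %||%
                           data.frame(exposure = character(),
                                      reason = character()))
  }
  list(forward = forward, reverse = reverse)
}

#' Export a panel report and its diagnostics as delimited tables
#'
#' Writes, under `out_dir`: `results.tsv` (the report), `heterogeneity.tsv`
#' (Cochran's Q per exposure), `pleiotropy.tsv` (Egger intercepts),
#' `presso.tsv` (global/outlier/distortion tests), `leave_one_out.tsv`,
#' `scatter_data.tsv` (per-SNP harmonized effects for plotting), and
#' `run_metadata.yaml` (package version, seed, config and its checksum).
#' Numbers are serialized at full double precision, so re-reading
#' `results.tsv` reproduces the report exactly.
#'
#' @param report A `"panel_report"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "panel_report"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop_mr("cannot create directory '%s'", out_dir)
  details <- attr(report, "details")
  config <- attr(report, "config")
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_full(df, path)
    paths <<- c(paths, path)
  }
  wr(as.data.frame(report), "results.tsv")

  one_per_exposure <- !duplicated(report$exposure)
  wr(data.frame(exposure = report$exposure, direction = report$direction,
                q_stat = report$q_stat, df = report$q_df,
                pvalue = report$q_pvalue)[one_per_exposure, ],
     "heterogeneity.tsv")
  wr(data.frame(exposure = report$exposure, direction = report$direction,
                egger_intercept = report$egger_intercept,
                intercept_p = report$egger_intercept_p)[one_per_exposure, ],
     "pleiotropy.tsv")

  presso_rows <- lapply(names(details), function(nm) {
    pr <- details[[nm]]$presso
    if (is.null(pr)) return(NULL)
    data.frame(exposure = nm, global_rss = pr$global_rss,
               global_p = pr$global_p,
               n_outliers = length(pr$outlier_set),
               outliers = paste(pr$outlier_snps, collapse = ","),
               distortion_p = pr$distortion_p %||% NA_real_,
               n_sim = pr$n_sim, seed = pr$seed, stringsAsFactors = FALSE)
  })
  wr(do.call(rbind, presso_rows) %||%
       data.frame(exposure = character(), global_rss = numeric(),
                  global_p = numeric(), n_outliers = integer(),
                  outliers = character(), distortion_p = numeric(),
                  n_sim = integer(), seed = integer()),
     "presso.tsv")

  loo_rows <- lapply(names(details), function(nm) {
    lo <- details[[nm]]$loo
    if (is.null(lo)) return(NULL)
    cbind(data.frame(exposure = nm, stringsAsFactors = FALSE), lo)
  })
  wr(do.call(rbind, loo_rows) %||%
       data.frame(exposure = character(), snp = character()),
     "leave_one_out.tsv")

  scatter_rows <- lapply(names(details), function(nm) {
    pr <- details[[nm]]$harmonized$pairs
    data.frame(exposure = nm, snp = pr$snp, beta_exp = pr$beta_exp,
               se_exp = pr$se_exp, beta_out = pr$beta_out,
               se_out = pr$se_out, stringsAsFactors = FALSE)
  })
  wr(do.call(rbind, scatter_rows), "scatter_data.tsv")

  meta <- list(package = "mrpanel",
               version = as.character(utils::packageVersion("mrpanel")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = config$seed,
               config = unclass(config),
               config_checksum = config_checksum(unclass(config)),
               skipped = attr(report, "skipped"))
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  paths <- c(paths, meta_path)
  invisible(paths)
}

#' Re-read an exported results table
#' @param path Path to a `results.tsv` written by [render_report()].
#' @return The report as a plain data frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
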