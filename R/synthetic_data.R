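#' Configuration for the synthetic two-sample GWAS generator
#'
#' Holds the ground-truth parameters of the generative model behind
#' [simulate_instrument_panel()] and friends. Defaults mirror the study shape
#' the package targets: a standardized continuous exposure measured in a
#' 13,266-sample GWAS (a MiBioGen-scale genus abundance) and a binary outcome
#' measured in 166,401 subjects with 5,731 cases (a FinnGen-scale disease
#' phenotype), with effects on the log-odds scale.
#'
#' @param n_snps Number of instruments J.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param theta True causal effect of the exposure on the outcome log-odds.
#' @param gamma_sd Scale of true instrument effects: each SNP's effect allele
#'   is oriented to the exposure-increasing allele, so true effects are
#'   half-normal magnitudes `|Normal(0, gamma_sd^2)|`.
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"`, or
#'   `"correlated"` — the distribution of direct (pleiotropic) effects on the
#'   invalid-instrument subset.
#' @param pleio_mean,pleio_sd Mean/SD of pleiotropic effects (directional
#'   modes use `pleio_mean`; balanced is mean-zero).
#' @param pleio_fraction Fraction of invalid instruments in \[0, 1\].
#' @param inside_corr Slope linking pleiotropic effects to instrument effects
#'   under `"correlated"` (an InSIDE violation).
#' @param maf_range Interval within (0, 0.5\] from which minor allele
#'   frequencies are drawn.
#' @param seed Integer seed; identical configs generate bit-identical data.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 20L,
                       n_exposure = 13266L,
                       n_outcome = 166401L,
                       case_fraction = 5731 / 166401,
                       theta = 0,
                       gamma_sd = 0.1,
                       pleiotropy_mode = c("none", "balanced", "directional", "correlated"),
                       pleio_mean = 0,
                       pleio_sd = 0.05,
                       pleio_fraction = 0,
                       inside_corr = 0,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = as.integer(n_exposure),
              n_outcome = as.integer(n_outcome), case_fraction = case_fraction,
              theta = theta, gamma_sd = gamma_sd,
              pleiotropy_mode = pleiotropy_mode, pleio_mean = pleio_mean,
              pleio_sd = pleio_sd, pleio_fraction = pleio_fraction,
              inside_corr = inside_corr, maf_range = as.double(maf_range),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 1L) stop_mr("n_snps must be >= 1")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1) {
    stop_mr("case_fraction must lie in (0,1)")
  }
  if (cfg$pleio_fraction < 0 || cfg$pleio_fraction > 1) {
    stop_mr("pleio_fraction must lie in [0,1]")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_mr("maf_range must be an interval within (0, 0.5]")
  }
  if (cfg$gamma_sd <= 0) stop_mr("gamma_sd must be > 0")
  invisible(cfg)
}

# Draw true pleiotropic effects r_j for the invalid set under the config's mode.
draw_pleiotropy <- function(cfg, gamma, invalid) {
  r <- numeric(length(gamma))
  m <- length(invalid)
  if (m == 0L || cfg$pleiotropy_mode == "none") return(r)
  r[invalid] <- switch(cfg$pleiotropy_mode,
    balanced    = stats::rnorm(m, 0, cfg$pleio_sd),
    directional = stats::rnorm(m, cfg$pleio_mean, cfg$pleio_sd),
    correlated  = cfg$inside_corr * gamma[invalid] + stats::rnorm(m, 0, cfg$pleio_sd))
  r
}

# Non-palindromic allele pairs (effect allele first) available to the generator.
NONPALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

# Shared core: given true per-SNP parameters, draw the observed two-sample
# summary statistics. Assumes the RNG state is already seeded by the caller.
simulate_observed <- function(cfg, snp, chr, pos, maf, gamma, r) {
  J <- length(snp)
  v <- cfg$case_fraction
  Gamma <- cfg$theta * gamma + r
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome * v * (1 - v))
  beta_x <- stats::rnorm(J, gamma, se_x)
  beta_y <- stats::rnorm(J, Gamma, se_y)
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE), , drop = FALSE]
  eaf <- ifelse(stats::runif(J) < 0.5, maf, 1 - maf)
  pclamp <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  exposure <- sumstats_table(
    data.frame(snp = snp, chr = chr, pos = pos, ea = pair[, 1L], oa = pair[, 2L],
               eaf = eaf, beta = beta_x, se = se_x, pval = pclamp(beta_x / se_x),
               n = cfg$n_exposure),
    trait_name = "exposure", trait_type = "continuous")
  outcome <- sumstats_table(
    data.frame(snp = snp, chr = chr, pos = pos, ea = pair[, 1L], oa = pair[, 2L],
               eaf = eaf, beta = beta_y, se = se_y, pval = pclamp(beta_y / se_y),
               n = cfg$n_outcome),
    trait_name = "outcome", trait_type = "binary", case_fraction = v)
  list(exposure = exposure, outcome = outcome)
}

#' Simulate a two-sample instrument panel with known ground truth
#'
#' Generates matched exposure/outcome GWAS summary statistics for `n_snps`
#' independent SNPs under a linear structural model: true instrument effects
#' are half-normal magnitudes (effect alleles oriented to the
#' exposure-increasing allele), true outcome effects are
#' `theta * gamma_j + r_j` with `r_j` the pleiotropic direct effect, and
#' observed betas are drawn around the truth with the standard GWAS standard
#' errors `se_x = (2 MAF (1-MAF) N_x)^(-1/2)` and
#' `se_y = (2 MAF (1-MAF) N_y v (1-v))^(-1/2)`.
#'
#' @param config A [sim_config()].
#' @return A list with components `exposure` and `outcome`
#'   ([sumstats_table()]s sharing SNP ids, positions, alleles and frequencies)
#'   and `truth` (class `"sim_truth"`: `theta`, `gamma`, `r`, `invalid_set`,
#'   `seed`).
#' @export
simulate_instrument_panel <- function(config) {
  validate_sim_config(config)
  J <- config$n_snps
  with_seed(config$seed, {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- abs(stats::rnorm(J, 0, config$gamma_sd))
    m <- round(config$pleio_fraction * J)
    invalid <- if (config$pleiotropy_mode == "none" || m == 0L) integer(0)
               else sort(sample.int(J, m))
    r <- draw_pleiotropy(config, gamma, invalid)
    snp <- sprintf("rs%06d", seq_len(J))
    obs <- simulate_observed(config, snp, chr = rep("1", J),
                             pos = as.integer(seq_len(J)) * 21000000L,
                             maf = maf, gamma = gamma, r = r)
    truth <- structure(list(theta = config$theta, gamma = gamma, r = r,
                            invalid_set = invalid, seed = config$seed),
                       class = "sim_truth")
    c(obs, list(truth = truth))
  })
}

#' Simulate instrument panels with block LD structure
#'
#' SNPs are grouped into blocks; all within-block pairs share r-squared
#' `within_r2` and across-block pairs are unlinked (absent from the LD table,
#' hence r-squared 0). Block members share one causal signal: their true
#' instrument effects equal the block effect plus noise of SD `gamma_sd / 10`.
#' Positions place every block inside one clumping window (members
#' `positions_spacing` bp apart, blocks far beyond the window).
#'
#' @param block_sizes Integer vector of block sizes (at least one block).
#' @param within_r2 Within-block r-squared in \[0, 1\].
#' @param positions_spacing Base-pair spacing between members of a block.
#' @param config A [sim_config()].
#' @return A list `exposure`, `outcome`, `ld` ([ld_table()]), `truth`.
#' @export
simulate_ld_blocks <- function(block_sizes, within_r2, positions_spacing = 10000,
                               config = sim_config()) {
  if (!length(block_sizes)) stop_mr("block_sizes must be non-empty")
  if (within_r2 < 0 || within_r2 > 1) stop_mr("within_r2 must lie in [0,1]")
  block_sizes <- as.integer(block_sizes)
  J <- sum(block_sizes)
  cfg <- config
  cfg$n_snps <- J
  validate_sim_config(cfg)
  block <- rep(seq_along(block_sizes), block_sizes)
  with_seed(cfg$seed, {
    maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
    block_gamma <- abs(stats::rnorm(length(block_sizes), 0, cfg$gamma_sd))
    gamma <- abs(block_gamma[block] + stats::rnorm(J, 0, cfg$gamma_sd / 10))
    m <- round(cfg$pleio_fraction * J)
    invalid <- if (cfg$pleiotropy_mode == "none" || m == 0L) integer(0)
               else sort(sample.int(J, m))
    r <- draw_pleiotropy(cfg, gamma, invalid)
    snp <- sprintf("rs%06d", seq_len(J))
    # members sit positions_spacing apart; blocks 30 Mb apart (beyond any
    # 10,000-kb window)
    within_idx <- sequence(block_sizes) - 1L
    pos <- as.integer((block - 1L) * 3e7 + 1e6 + within_idx * positions_spacing)
    obs <- simulate_observed(cfg, snp, chr = rep("1", J), pos = pos,
                             maf = maf, gamma = gamma, r = r)
    pairs_a <- character(0); pairs_b <- character(0)
    if (within_r2 > 0) {
      for (bl in seq_along(block_sizes)) {
        ids <- snp[block == bl]
        if (length(ids) >= 2L) {
          cmb <- utils::combn(ids, 2L)
          pairs_a <- c(pairs_a, cmb[1L, ]); pairs_b <- c(pairs_b, cmb[2L, ])
        }
      }
    }
    ld <- ld_table(pairs_a, pairs_b, rep(within_r2, length(pairs_a)))
    truth <- structure(list(theta = cfg$theta, gamma = gamma, r = r,
                            invalid_set = invalid, seed = cfg$seed,
                            block = block),
                       class = "sim_truth")
    c(obs, list(ld = ld, truth = truth))
  })
}

#' Simulate a multi-exposure study
#'
#' Builds independent instrument panels for `n_exposures` exposures against a
#' single shared outcome GWAS, emulating a many-taxa screen. Exposures listed
#' in `causal_indices` receive the template's `theta`; all others are null.
#' SNP sets are disjoint across exposures, and the outcome table is the union
#' of all panels' outcome records.
#'
#' @param n_exposures Number of exposure panels.
#' @param causal_indices Integer indices (within `1:n_exposures`) of truly
#'   causal exposures.
#' @param config Template [sim_config()]; each exposure gets a sub-seed
#'   derived from `config$seed`.
#' @return A list with `exposures` (named list of [sumstats_table()]s),
#'   `outcome` (one [sumstats_table()]), and `truth` (named list of
#'   `"sim_truth"` objects).
#' @export
simulate_study <- function(n_exposures, causal_indices = integer(0),
                           config = sim_config()) {
  n_exposures <- as.integer(n_exposures)
  stopifnot(n_exposures >= 1L)
  causal_indices <- as.integer(causal_indices)
  if (length(causal_indices) && (min(causal_indices) < 1L || max(causal_indices) > n_exposures)) {
    stop_mr("causal_indices must lie within 1..n_exposures")
  }
  exposures <- vector("list", n_exposures)
  truths <- vector("list", n_exposures)
  outcome_parts <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    cfg_i <- config
    cfg_i$theta <- if (i %in% causal_indices) config$theta else 0
    cfg_i$seed <- derive_seed(config$seed, i)
    panel <- simulate_instrument_panel(cfg_i)
    name_i <- sprintf("taxon_%03d", i)
    # disjoint snp ids across exposures
    ids <- sprintf("rs%03d_%05d", i, seq_len(cfg_i$n_snps))
    exp_i <- panel$exposure; out_i <- panel$outcome
    exp_i$snp <- ids; out_i$snp <- ids
    attr(exp_i, "trait_name") <- name_i
    exposures[[i]] <- exp_i
    truths[[i]] <- panel$truth
    outcome_parts[[i]] <- as.data.frame(out_i)
  }
  names(exposures) <- names(truths) <- sprintf("taxon_%03d", seq_len(n_exposures))
  outcome <- sumstats_table(do.call(rbind, outcome_parts),
                            trait_name = "outcome", trait_type = "binary",
                            case_fraction = config$case_fraction)
  list(exposures = exposures, outcome = outcome, truth = truths)
}

#' Write a simulation ground truth as a sidecar TSV
#' @param truth A `"sim_truth"` object.
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  J <- length(truth$gamma)
  write_tsv_full(data.frame(snp = seq_len(J), gamma_true = truth$gamma,
                            r_true = truth$r,
                            invalid = seq_len(J) %in% truth$invalid_set),
                 path)
}
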