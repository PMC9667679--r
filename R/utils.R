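# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state on
#' exit, so seeded internals (bootstraps, simulation nulls) never disturb the
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed from a base seed and integer stream ids.
# Keeps results inside the 32-bit signed range R's set.seed() accepts.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ids) {
    s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

# Simple rolling checksum for run metadata (config fingerprinting).
config_checksum <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

# Format numerics so that read-back reproduces the double bit-for-bit.
format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

# Write a data.frame as TSV at full double precision.
write_tsv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    out[[j]] <- format_full(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

stop_mr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
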