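#' @section Canonical summary-statistics schema:
#' All modules exchange per-SNP GWAS association records through one canonical
#' tab-delimited layout with columns `snp, chr, pos, ea, oa, eaf, beta, se,
#' pval, n` ("NA" for missing). `ea`/`oa` are single upper-case bases and must
#' differ; `se > 0`; `pval` in (0, 1]; `eaf` in \[0, 1\] when present.
#' Positions are 1-based; the genome build is opaque metadata (clumping only
#' uses distances).
#' @name sumstats-schema
#' @keywords internal
NULL

CANONICAL_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                    "pval", "n")
MANDATORY_COLS <- c("snp", "ea", "oa", "beta", "se", "pval")
BASES <- c("A", "C", "G", "T")

.pkg_env <- new.env(parent = emptyenv())

# ---- dialects ---------------------------------------------------------------

load_builtin_dialects <- function() {
  path <- system.file("extdata", "dialects.yaml", package = "mrpanel")
  if (!nzchar(path)) return(invisible(NULL))
  maps <- yaml::read_yaml(path)
  for (nm in names(maps)) .pkg_env$dialects[[nm]] <- maps[[nm]]
  invisible(NULL)
}

get_dialects <- function() {
  if (is.null(.pkg_env$dialects)) {
    .pkg_env$dialects <- list()
    load_builtin_dialects()
  }
  .pkg_env$dialects
}

#' Register or list summary-statistics dialects
#'
#' A dialect is a named map from canonical fields (`snp, chr, pos, ea, oa,
#' eaf, beta, se, pval, n`) to the column names used in a file. Built-in
#' dialects (`canonical`, `mibiogen-like`, `finngen-like`) are loaded from the
#' package's `extdata/dialects.yaml`. Map entries may be `NULL` for columns a
#' dialect does not carry (they are read as missing).
#'
#' @param name Dialect name.
#' @param map Named list mapping canonical field names to file column names.
#' @return `register_dialect()` returns the map invisibly;
#'   `sumstats_dialects()` returns the names of registered dialects.
#' @export
register_dialect <- function(name, map) {
  stopifnot(is.character(name), length(name) == 1L, is.list(map))
  unknown <- setdiff(names(map), CANONICAL_COLS)
  if (length(unknown)) {
    stop_mr("unknown canonical fields in dialect map: %s",
            paste(unknown, collapse = ", "))
  }
  get_dialects()
  .pkg_env$dialects[[name]] <- map
  invisible(map)
}

#' @rdname register_dialect
#' @export
sumstats_dialects <- function() names(get_dialects())

dialect_map <- function(dialect) {
  maps <- get_dialects()
  if (is.null(maps[[dialect]])) {
    stop_mr("unregistered dialect '%s' (registered: %s)", dialect,
            paste(names(maps), collapse = ", "))
  }
  maps[[dialect]]
}

# ---- sumstats table ---------------------------------------------------------

#' Construct a validated summary-statistics table
#'
#' @param records Data frame with (a subset of) the canonical columns
#'   `snp, chr, pos, ea, oa, eaf, beta, se, pval, n`. Missing optional columns
#'   are filled with `NA`.
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` (e.g. standardized taxon abundance) or
#'   `"binary"` (disease, effects on the log-odds scale).
#' @param case_fraction Case fraction in (0, 1); required exactly when
#'   `trait_type = "binary"`.
#' @param validate If `TRUE` (default) reject the table when any row violates
#'   the per-SNP invariants.
#' @return A data frame of class `"sumstats"` with trait metadata attached as
#'   attributes (`trait_name`, `trait_type`, `case_fraction`).
#' @export
sumstats_table <- function(records, trait_name, trait_type = c("continuous", "binary"),
                           case_fraction = NULL, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary") {
    if (is.null(case_fraction) || !is.finite(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1) {
      stop_mr("binary traits require case_fraction in (0,1)")
    }
  } else if (!is.null(case_fraction)) {
    stop_mr("case_fraction is only meaningful for binary traits")
  }
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(CANONICAL_COLS, names(df))) df[[col]] <- rep(NA, nrow(df))
  df <- df[CANONICAL_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  df$pos <- as.integer(df$pos)
  df$n <- as.integer(df$n)
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.double(df[[col]])
  rownames(df) <- NULL

  if (validate && nrow(df)) {
    bad <- validate_snp_rows(df)
    if (nrow(bad)) {
      stop_mr("invalid summary-statistics rows:\n%s",
              paste(sprintf("  row %d: %s", bad$row, bad$message), collapse = "\n"))
    }
    if (anyDuplicated(df$snp)) {
      stop_mr("duplicated snp ids: %s",
              paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
    }
  }
  structure(df,
            class = c("sumstats", "data.frame"),
            trait_name = trait_name,
            trait_type = trait_type,
            case_fraction = case_fraction)
}

# Per-row invariant checks; returns data.frame(row, message).
validate_snp_rows <- function(df) {
  msgs <- list()
  add <- function(rows, what) {
    if (length(rows)) msgs[[length(msgs) + 1L]] <<- data.frame(row = rows, message = what)
  }
  add(which(is.na(df$snp) | !nzchar(df$snp)), "missing snp id")
  add(which(!(df$ea %in% BASES)), "effect allele not a single A/C/G/T base")
  add(which(!(df$oa %in% BASES)), "other allele not a single A/C/G/T base")
  add(which(df$ea == df$oa), "effect and other allele identical")
  add(which(is.na(df$beta) | !is.finite(df$beta)), "beta missing or non-finite")
  add(which(is.na(df$se) | !(df$se > 0)), "se missing or not > 0")
  add(which(is.na(df$pval) | df$pval <= 0 | df$pval > 1), "pval not in (0,1]")
  add(which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)), "eaf outside [0,1]")
  add(which(!is.na(df$pos) & df$pos < 1L), "pos not a positive 1-based coordinate")
  add(which(!is.na(df$n) & df$n < 1L), "n not a positive integer")
  if (!length(msgs)) return(data.frame(row = integer(), message = character()))
  out <- do.call(rbind, msgs)
  out[order(out$row), , drop = FALSE]
}

trait_name <- function(x) attr(x, "trait_name")
trait_type <- function(x) attr(x, "trait_type")
case_fraction <- function(x) attr(x, "case_fraction")

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics: %s (%s%s), %d SNPs\n",
              trait_name(x), trait_type(x),
              if (identical(trait_type(x), "binary"))
                sprintf(", case fraction %.4f", case_fraction(x)) else "",
              nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# ---- read / write -----------------------------------------------------------

#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics file in a registered dialect and
#' returns a validated [sumstats_table()]. Rows violating per-SNP invariants
#' (bad alleles, non-positive SE, p-values outside (0,1], unparseable
#' numbers) are dropped with a row-numbered warning.
#'
#' @param path File path.
#' @param dialect Registered dialect name (see [sumstats_dialects()]).
#' @param trait_name,trait_type,case_fraction Trait metadata
#'   (see [sumstats_table()]).
#' @param n Sample size used to fill the `n` column when the dialect carries
#'   none (e.g. `finngen-like`).
#' @param sep Field separator (default tab).
#' @return A `"sumstats"` table.
#' @export
read_sumstats <- function(path, dialect = "canonical", trait_name = basename(path),
                          trait_type = c("continuous", "binary"),
                          case_fraction = NULL, n = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_mr("file not found: %s", path)
  map <- dialect_map(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  present <- names(map)[!vapply(map, is.null, logical(1))]
  missing_cols <- present[!unlist(map[present]) %in% names(raw)]
  missing_mandatory <- intersect(missing_cols, MANDATORY_COLS)
  if (length(missing_mandatory)) {
    stop_mr("format error: file '%s' lacks mandatory column(s) %s (dialect '%s')",
            path,
            paste(sprintf("'%s' (expected '%s')", missing_mandatory,
                          unlist(map[missing_mandatory])), collapse = ", "),
            dialect)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in CANONICAL_COLS) {
    col <- map[[field]]
    df[[field]] <- if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA_character_
  }
  # parse numerics, tracking unparseable (non-missing but non-numeric) entries
  parse_fail <- rep(FALSE, nrow(df))
  for (field in c("pos", "eaf", "beta", "se", "pval", "n")) {
    val <- suppressWarnings(as.numeric(df[[field]]))
    parse_fail <- parse_fail | (!is.na(df[[field]]) & is.na(val))
    df[[field]] <- val
  }
  if (is.null(map[["n"]]) && !is.null(n)) df$n <- as.integer(n)

  keep <- rep(TRUE, nrow(df))
  notes <- character(0)
  if (any(parse_fail)) {
    notes <- c(notes, sprintf("row %d: unparseable numeric field",
                              which(parse_fail)))
    keep[parse_fail] <- FALSE
  }
  if (any(keep)) {
    sub <- df[keep, , drop = FALSE]
    sub$ea <- toupper(as.character(sub$ea))
    sub$oa <- toupper(as.character(sub$oa))
    bad <- validate_snp_rows(sub)
    if (nrow(bad)) {
      orig_rows <- which(keep)[bad$row]
      notes <- c(notes, sprintf("row %d: %s", orig_rows, bad$message))
      keep[orig_rows] <- FALSE
    }
  }
  if (length(notes)) {
    warning(sprintf("read_sumstats('%s'): rejected %d row(s):\n%s",
                    path, sum(!keep), paste("  ", notes, collapse = "\n")),
            call. = FALSE)
  }
  sumstats_table(df[keep, , drop = FALSE], trait_name = trait_name,
                 trait_type = trait_type, case_fraction = case_fraction)
}

#' Write GWAS summary statistics
#'
#' Serializes a [sumstats_table()] in a registered dialect. Doubles are
#' written with 17 significant digits so `read_sumstats(write_sumstats(t))`
#' reproduces `t` bit-for-bit; missing values are written as `"NA"`.
#'
#' @param x A `"sumstats"` table.
#' @param path Output path.
#' @param dialect Registered dialect name; fields the dialect does not carry
#'   are omitted from the file.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, dialect = "canonical") {
  stopifnot(inherits(x, "sumstats"))
  map <- dialect_map(dialect)
  fields <- names(map)[!vapply(map, is.null, logical(1))]
  out <- data.frame(row.names = seq_len(nrow(x)))
  for (field in fields) out[[map[[field]]]] <- format_full(x[[field]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_mr("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

# ---- LD tables --------------------------------------------------------------

#' Pairwise LD (r-squared) lookup table
#'
#' Stores precomputed r-squared values between SNP pairs with a symmetric
#' lookup contract: `r2(a, b) = r2(b, a)`, `r2(a, a) = 1`, and absent pairs
#' return 0. Self-pairs are never stored.
#'
#' @param snp_a,snp_b Character vectors of SNP ids.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return An object of class `"ld_table"`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  snp_a <- as.character(snp_a); snp_b <- as.character(snp_b)
  r2 <- as.double(r2)
  if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
    stop_mr("r2 values must lie in [0,1]; offending entries: %s",
            paste(which(is.na(r2) | r2 < 0 | r2 > 1), collapse = ", "))
  }
  self <- snp_a == snp_b
  snp_a <- snp_a[!self]; snp_b <- snp_b[!self]; r2 <- r2[!self]
  keys <- c(paste0(snp_a, "\r", snp_b), paste0(snp_b, "\r", snp_a))
  vals <- c(r2, r2)
  dup <- duplicated(keys)
  structure(list(keys = keys[!dup], r2 = vals[!dup], n_pairs = length(r2)),
            class = "ld_table")
}

#' @rdname ld_table
#' @param path Three-column delimited file (`snp_a`, `snp_b`, `r2`).
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop_mr("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_mr("LD file must have columns snp_a, snp_b, r2")
  ld_table(df[[1L]], df[[2L]], as.double(df[[3L]]))
}

#' @rdname ld_table
#' @param ld An `"ld_table"`.
#' @param a,b SNP id vectors (recycled to a common length).
#' @return `ld_lookup()` returns the vector of r-squared values.
#' @export
ld_lookup <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- ld$r2[match(paste0(a, "\r", b), ld$keys)]
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table: %d stored pairs (symmetric lookup, absent pair => r2 = 0)\n",
              x$n_pairs))
  invisible(x)
}

#' Write an LD table
#' @param ld An `"ld_table"`.
#' @param path Output path.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  parts <- strsplit(ld$keys, "\r", fixed = TRUE)
  a <- vapply(parts, `[[`, "", 1L); b <- vapply(parts, `[[`, "", 2L)
  keep <- a < b
  write_tsv_full(data.frame(snp_a = a[keep], snp_b = b[keep], r2 = ld$r2[keep]),
                 path)
}
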