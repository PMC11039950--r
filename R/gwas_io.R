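#' Construct a summary-statistics object
#'
#' A `summary_stats` object holds one trait's GWAS summary statistics: one row
#' per variant with alleles, effect size, standard error, p-value and optional
#' effect-allele frequency and sample size.  For a continuous exposure the
#' `beta` column is the effect per standard deviation of the trait; for a
#' binary outcome it is the log odds ratio.
#'
#' @param records Data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_id Character label for the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param meta Optional list of cohort metadata (population, case/control
#'   counts, ...).
#' @param policy Row-validation policy: `"skip"` drops malformed rows with a
#'   message, `"strict"` raises an error naming the first offending row.
#'
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                          meta = list(), policy = c("skip", "strict")) {
  trait_type <- match.arg(trait_type)
  policy <- match.arg(policy)
  records <- validate_records(records, policy = policy, context = trait_id)
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         records = records, meta = meta),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s (%s): %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  if (nrow(x$records) > 0) print(head(x$records, 5))
  invisible(x)
}

#' Number of variant records in a summary-statistics object
#' @param x A `summary_stats` object.
#' @return Integer count.
#' @export
n_records <- function(x) nrow(x$records)

# Replace the record table, preserving trait identity/metadata.
replace_records <- function(stats, records) {
  stats$records <- records
  stats
}

RECORD_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "pvalue", "eaf", "n")

# Validate a raw record table into the canonical VariantAssociation layout:
# single-base upper-case distinct alleles, se > 0, p in (0,1], eaf in (0,1)
# when present, unique snp_id.
validate_records <- function(df, policy = "skip", context = "summary statistics") {
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("missing required column(s) in %s: %s",
                        context, paste(missing, collapse = ", ")))
  }
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "pvalue")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "eaf", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  reason <- flag(!(df$effect_allele %in% bases), "effect_allele is not a single A/C/G/T base")
  reason <- flag(!(df$other_allele %in% bases), "other_allele is not a single A/C/G/T base")
  reason <- flag(df$effect_allele == df$other_allele, "effect and other allele are identical")
  reason <- flag(!is.finite(df$beta), "beta is not a finite number")
  reason <- flag(!is.finite(df$se) | df$se <= 0, "se is not > 0")
  reason <- flag(!is_probability(df$pvalue), "pvalue is outside (0, 1]")
  reason <- flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf is outside (0, 1)")
  reason <- flag(duplicated(df$snp_id), "duplicated snp_id")

  bad <- !is.na(reason)
  if (any(bad)) {
    if (policy == "strict") {
      i <- which(bad)[1]
      stop_format(sprintf("invalid row %d in %s: %s", i, context, reason[i]))
    }
    message(sprintf("dropped %d invalid row(s) while validating %s (e.g. row %d: %s)",
                    sum(bad), context, which(bad)[1], reason[which(bad)[1]]))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, RECORD_COLUMNS]
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop_format(sprintf("empty file: %s", path))
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a TSV or CSV table of per-variant associations with a configurable
#' column mapping, validates every row, and returns a [summary_stats] object.
#' The delimiter is auto-detected (tab vs comma) unless `delim` is given.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list mapping canonical field names (`snp`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`,
#'   `n`) to the column names used in the file.  Only entries that differ from
#'   the canonical names need to be supplied.
#' @param trait_type `"continuous"` or `"binary"` (binary betas are log odds
#'   ratios).
#' @param trait_id Trait label; defaults to the file name.
#' @param delim Field delimiter override; `NULL` auto-detects tab vs comma.
#' @param policy `"skip"` (drop malformed rows, log a count) or `"strict"`.
#' @param meta Optional metadata list.
#'
#' @return A [summary_stats] object with row order preserved.
#' @export
read_summary_stats <- function(path, column_map = list(),
                               trait_type = c("continuous", "binary"),
                               trait_id = NULL, delim = NULL,
                               policy = c("skip", "strict"), meta = list()) {
  trait_type <- match.arg(trait_type)
  policy <- match.arg(policy)
  trait_id <- trait_id %||% basename(path)
  delim <- delim %||% detect_delim(path)

  map <- list(snp = "snp_id", chrom = "chrom", pos = "pos",
              effect_allele = "effect_allele", other_allele = "other_allele",
              beta = "beta", se = "se", pvalue = "pvalue", eaf = "eaf", n = "n")
  unknown <- setdiff(names(column_map), names(map))
  if (length(unknown) > 0) {
    stop_usage(sprintf("unknown column_map field(s): %s", paste(unknown, collapse = ", ")))
  }
  map <- modifyList(map, column_map)

  raw <- read.delim(path, sep = delim, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (field in required) {
    if (!map[[field]] %in% names(raw)) {
      stop_format(sprintf("column '%s' (mapped from field '%s') not found in %s",
                          map[[field]], field, path))
    }
  }
  out <- data.frame(snp_id = raw[[map$snp]], stringsAsFactors = FALSE)
  for (field in c("chrom", "pos", "effect_allele", "other_allele",
                  "beta", "se", "pvalue", "eaf", "n")) {
    src <- map[[field]]
    out[[field]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  summary_stats(out, trait_id = trait_id, trait_type = trait_type,
                meta = meta, policy = policy)
}

#' Build a pairwise LD lookup table
#'
#' Stores pairwise r-squared values between variants.  Lookups are symmetric,
#' a variant with itself has r² = 1, and a pair absent from the table is
#' treated as unlinked (r² = 0) — the convention for sparse pairwise LD dumps.
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(pairs = data.frame(snp_a = character(), snp_b = character(),
                                        r2 = numeric())) {
  required <- c("snp_a", "snp_b", "r2")
  if (!all(required %in% names(pairs))) {
    stop_format("LD table needs columns snp_a, snp_b, r2")
  }
  pairs$snp_a <- as.character(pairs$snp_a)
  pairs$snp_b <- as.character(pairs$snp_b)
  pairs$r2 <- suppressWarnings(as.numeric(pairs$r2))
  if (any(!is.finite(pairs$r2) | pairs$r2 < -1e-9 | pairs$r2 > 1 + 1e-9)) {
    stop_format("r2 values must lie in [0, 1]")
  }
  pairs$r2 <- pmin(pmax(pairs$r2, 0), 1)
  self <- pairs$snp_a == pairs$snp_b
  if (any(self & abs(pairs$r2 - 1) > 1e-9)) {
    stop_format("self-pair r2 must equal 1 when present")
  }
  key <- ld_key(pairs$snp_a, pairs$snp_b)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- setNames(pairs$r2[!dup], key[!dup])
    if (any(abs(pairs$r2[dup] - first[key[dup]]) > 1e-9)) {
      stop_format("conflicting duplicate r2 entries for the same pair")
    }
    pairs <- pairs[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  structure(list(map = setNames(pairs$r2, key), pairs = pairs), class = "ld_table")
}

ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a three-column LD table (snp_a, snp_b, r2)
#'
#' @param path Path to a delimited file with header `snp_a`, `snp_b`, `r2`.
#' @param delim Delimiter override (auto-detected by default).
#' @return An [ld_table] object.
#' @export
read_ld_table <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  raw <- read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE)
  ld_table(raw)
}

#' Look up pairwise r-squared values
#'
#' @param ld An [ld_table].
#' @param a,b Variant id vectors (recycled to common length).
#' @return Numeric vector of r² values; missing pairs return 0 and `a == b`
#'   returns 1.
#' @export
ld_r2 <- function(ld, a, b) {
  if (!inherits(ld, "ld_table")) stop_usage("`ld` must be an ld_table")
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  r2 <- unname(ld$map[ld_key(a, b)])
  r2[is.na(r2)] <- 0
  r2[a == b] <- 1
  r2
}

#' Write an MR results table to a delimited file
#'
#' One row per exposure-outcome-method combination, mirroring the layout of a
#' published MR results table (odds ratio with confidence interval, Cochran's
#' Q, PRESSO global test, Egger intercept, minimum instrument F).  Values
#' round-trip through [read_results_table()] at better than 6 significant
#' digits.
#'
#' @param rows Data frame of results (see [results_table()]).
#' @param path Output path; tab-separated.
#' @return Invisibly, `rows`.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop_usage("`rows` must be a data frame")
  con <- tryCatch(file(path, "w"), error = function(e) {
    mrb_error(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
              "mrbiome_io_error")
  })
  on.exit(close(con))
  write.table(format_table_for_io(rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(rows)
}

# Format numerics at full double precision so a write -> read cycle is the
# identity well past 6 significant digits.
format_table_for_io <- function(rows) {
  for (col in names(rows)) {
    if (is.numeric(rows[[col]])) {
      rows[[col]] <- vapply(rows[[col]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = NA)
      }, character(1))
    }
  }
  rows
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the tab-separated results file.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
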