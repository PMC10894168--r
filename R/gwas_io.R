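#' Default column mapping for summary-statistics files
#'
#' Maps the package's canonical field names to the column headers expected in
#' a tab-delimited summary-statistics file. Override individual entries to
#' read files with non-standard headers, e.g.
#' `default_column_map(snp = "rsid", pval = "p_value")`.
#'
#' @param ... named character overrides, one per canonical field. Valid field
#'   names are `snp`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`.
#' @return named character vector mapping canonical field -> file column.
#' @export
default_column_map <- function(...) {
  map <- c(
    snp = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) {
      stop("unknown column-map field(s): ", paste(bad, collapse = ", "))
    }
    map[names(dots)] <- dots
  }
  map
}

# fields that must be present and parseable for a usable record
.mandatory_fields <- c("snp", "effect_allele", "other_allele",
                       "beta", "se", "pval")
.numeric_fields <- c("pos", "eaf", "beta", "se", "pval", "n")

#' Construct a variant-association table
#'
#' Validates and classes a data frame of per-variant GWAS summary statistics.
#' One row per variant; `beta` is the additive per-allele effect of
#' `effect_allele` (log-odds for case-control outcomes), `se` its standard
#' error, `eaf` the effect-allele frequency.
#'
#' @param df data frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval` and optionally `chrom`, `pos`, `eaf`, `n`.
#' @return the validated data frame, classed `"variant_assoc"`.
#' @export
variant_assoc <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.mandatory_fields, names(df))
  if (length(missing)) {
    stop("variant_assoc is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  ok <- .valid_variant_rows(df)
  if (!all(ok)) {
    stop("invalid variant record(s): ",
         paste(utils::head(df$snp[!ok], 5L), collapse = ", "))
  }
  if (anyDuplicated(df$snp)) {
    stop("duplicate snp id(s): ",
         paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
  }
  class(df) <- c("variant_assoc", "data.frame")
  df
}

# row-wise invariant check shared by the constructor and the reader
.valid_variant_rows <- function(df) {
  ok <- !is.na(df$snp) & nzchar(df$snp) &
    df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1
  if ("eaf" %in% names(df)) {
    ok <- ok & (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  }
  if ("pos" %in% names(df)) {
    ok <- ok & (is.na(df$pos) | df$pos >= 1)
  }
  if ("n" %in% names(df)) {
    ok <- ok & (is.na(df$n) | df$n > 0)
  }
  ok
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-bearing tab-delimited file into a [variant_assoc()] table.
#' Rows whose numeric fields do not parse, or that violate the record
#' invariants (`se > 0`, `0 < pval <= 1`, `0 < eaf < 1`, valid distinct
#' alleles), are skipped; the skip count is reported via a message and stored
#' in the `"n_skipped"` attribute. Allele strings are uppercased.
#'
#' @param path file path.
#' @param column_map canonical-field -> header mapping, see
#'   [default_column_map()].
#' @return a `variant_assoc` data frame with attribute `n_skipped`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("no data rows in summary-statistics file: ", path)
  }
  for (field in .mandatory_fields) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("mandatory column '", column_map[[field]] %||% field,
           "' (field ", field, ") not found in ", path)
    }
  }
  present <- names(column_map)[unlist(column_map) %in% names(raw)]
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in present) {
    v <- raw[[column_map[[field]]]]
    if (field %in% .numeric_fields) {
      v <- suppressWarnings(as.numeric(v))
    }
    df[[field]] <- v
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  ok <- .valid_variant_rows(df)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message("read_summary_stats: skipped ", n_skipped,
            " unparseable/invalid row(s) in ", basename(path))
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no valid rows after parsing: ", path)
  }
  rownames(df) <- NULL
  out <- variant_assoc(df)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Numeric fields are written with 17 significant digits so that a
#' read/write/read cycle reproduces the doubles bit-exactly.
#'
#' @param x a `variant_assoc` data frame.
#' @param path output file path.
#' @param column_map canonical-field -> header mapping used for the header
#'   row.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, column_map = default_column_map()) {
  fields <- intersect(names(column_map), names(x))
  out <- x[, fields, drop = FALSE]
  for (field in intersect(fields, .numeric_fields)) {
    out[[field]] <- sprintf("%.17g", out[[field]])
  }
  names(out) <- unname(column_map[fields])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a square LD matrix of pairwise r-squared values
#'
#' Expects a tab-delimited file with variant ids as both the header row and
#' the first column. Validates symmetry, a unit diagonal and entries in
#' `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

#' Write an LD matrix to a tab-delimited file
#'
#' @param m square numeric matrix with variant-id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  validate_ld_matrix(m)
  out <- data.frame(SNP = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate an r-squared LD matrix
#'
#' @param m matrix to check.
#' @return `m`, invisibly; errors if invalid.
#' @export
validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("LD matrix must be square")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("LD matrix must carry identical variant-id row and column names")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("LD r-squared entries must lie in [0, 1]")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("LD matrix must be symmetric")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop("LD matrix must have a unit diagonal")
  }
  invisible(m)
}

#' Load the packaged drug-target instrument table
#'
#' Returns the published LDL-cholesterol instrument variants for one
#' drug-target gene (33 for PCSK9, 19 for HMGCR, 6 for NPC1L1), exactly as
#' printed: rsID, GRCh37 chromosome/position, alleles, effect-allele
#' frequency, beta, standard error, p-value and the exposure GWAS sample
#' size (440,546). The printed instrument-strength F statistic is carried in
#' column `f_printed` for cross-checks against [f_statistic_from_r2()].
#'
#' @param target one of `"PCSK9"`, `"HMGCR"`, `"NPC1L1"`.
#' @return a `variant_assoc` data frame with extra column `f_printed`.
#' @export
load_instrument_fixture <- function(target) {
  valid <- c("PCSK9", "HMGCR", "NPC1L1")
  if (length(target) != 1L || !target %in% valid) {
    stop("unknown target '", paste(target, collapse = ","),
         "'; valid targets: ", paste(valid, collapse = ", "))
  }
  path <- system.file("extdata",
                      sprintf("ldl_instruments_%s.tsv", tolower(target)),
                      package = "drugtargetmr", mustWork = TRUE)
  out <- read_summary_stats(path)
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  out$f_printed <- as.numeric(raw[["F_PRINTED"]])
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables by rsID and re-expresses every outcome record on the
#' exposure's effect allele. When the outcome's alleles are swapped relative
#' to the exposure, the outcome beta is negated and its EAF replaced by
#' `1 - eaf` (`action = "flipped"`). Palindromic variants (A/T or C/G),
#' whose strand is ambiguous across datasets, are retained only when both
#' EAFs fall outside the ambiguity window `[0.5 - w, 0.5 + w]` and lie on
#' the same side of 0.5; otherwise `action = "dropped_palindromic"`. Allele
#' sets matching neither orientation get `action = "dropped_mismatch"`.
#' Dropped rows are returned for audit but must not enter estimation; every
#' estimator in this package discards them.
#'
#' @param exposure,outcome `variant_assoc` tables keyed by unique rsID.
#' @param palindromic_eaf_window half-width `w` of the EAF ambiguity window
#'   around 0.5; in `[0, 0.5)`. Default 0.08.
#' @return data frame of class `"harmonized_pairs"` with columns `snp`,
#'   `effect_allele`, `other_allele`, `exposure_beta`, `exposure_se`,
#'   `exposure_eaf`, `exposure_pval`, `exposure_n`, `outcome_beta`,
#'   `outcome_se`, `outcome_eaf` and `action`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome),
            palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  if (anyDuplicated(exposure$snp)) {
    stop("duplicate snp id(s) in exposure: ambiguous join")
  }
  if (anyDuplicated(outcome$snp)) {
    stop("duplicate snp id(s) in outcome: ambiguous join")
  }
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  n <- length(shared)
  grab <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_real_, n)
  pairs <- data.frame(
    snp = shared,
    effect_allele = toupper(ex$effect_allele),
    other_allele = toupper(ex$other_allele),
    exposure_beta = ex$beta,
    exposure_se = ex$se,
    exposure_eaf = grab(ex, "eaf"),
    exposure_pval = ex$pval,
    exposure_n = grab(ex, "n"),
    outcome_beta = ou$beta,
    outcome_se = ou$se,
    outcome_eaf = grab(ou, "eaf"),
    action = rep("dropped_mismatch", n),
    stringsAsFactors = FALSE
  )
  o_ea <- toupper(ou$effect_allele)
  o_oa <- toupper(ou$other_allele)

  same <- o_ea == pairs$effect_allele & o_oa == pairs$other_allele
  swapped <- o_ea == pairs$other_allele & o_oa == pairs$effect_allele
  pairs$action[same] <- "kept"
  pairs$action[swapped & !same] <- "flipped"
  flip <- pairs$action == "flipped"
  pairs$outcome_beta[flip] <- -pairs$outcome_beta[flip]
  pairs$outcome_eaf[flip] <- 1 - pairs$outcome_eaf[flip]

  pal <- .is_palindromic(pairs$effect_allele, pairs$other_allele)
  if (any(pal)) {
    w <- palindromic_eaf_window
    ex_eaf <- pairs$exposure_eaf
    ou_eaf <- pairs$outcome_eaf
    unambiguous <- !is.na(ex_eaf) & !is.na(ou_eaf) &
      abs(ex_eaf - 0.5) > w & abs(ou_eaf - 0.5) > w &
      sign(ex_eaf - 0.5) == sign(ou_eaf - 0.5)
    drop_pal <- pal & pairs$action %in% c("kept", "flipped") & !unambiguous
    pairs$action[drop_pal] <- "dropped_palindromic"
  }
  class(pairs) <- c("harmonized_pairs", "data.frame")
  pairs
}

.is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(a1) & !is.na(a2) & comp[a1] == a2
}

#' Keep only harmonized pairs usable for estimation
#'
#' @param pairs output of [harmonize()].
#' @return the subset with `action` in `{"kept", "flipped"}`.
#' @export
retained_pairs <- function(pairs) {
  out <- pairs[pairs$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
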