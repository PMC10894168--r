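#' Read a variant-to-trait association table
#'
#' Tab-delimited file with columns `SNP`, `TRAIT`, `P`: one row per
#' variant-trait association, typically exported from a curated
#' genotype-phenotype catalogue. Used to screen instruments for horizontal
#' pleiotropy without any web access.
#'
#' @param path file path.
#' @return data frame with columns `snp`, `trait`, `pval`.
#' @export
read_trait_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("SNP", "TRAIT", "P")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("trait table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    snp = raw$SNP, trait = raw$TRAIT,
    pval = suppressWarnings(as.numeric(raw$P)),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$pval) | out$pval <= 0 | out$pval > 1
  if (any(bad)) {
    message("read_trait_table: dropped ", sum(bad), " invalid row(s)")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Screen instruments for trait-mediated pleiotropy
#'
#' Removes a harmonized pair when the trait table records an association
#' between its rsID and any excluded trait at `pval < p_threshold`
#' (strict). Trait matching is a case-insensitive substring test of each
#' excluded-trait label against the table's trait labels, so
#' `"smoking"` matches `"Current tobacco smoking"`.
#'
#' @param pairs harmonized pairs ([harmonize()]).
#' @param trait_table data frame from [read_trait_table()] (columns `snp`,
#'   `trait`, `pval`).
#' @param excluded_traits character vector of trait labels to screen
#'   against; default `c("smoking", "psoriasis")`, the established risk
#'   factors for the psoriatic-arthritis outcome.
#' @param p_threshold strict association cutoff; default 1e-5.
#' @return list with `kept` (pairs retained), `removed` (pairs removed) and
#'   `reasons` (data frame `snp`, `trait`, `pval`, one row per triggering
#'   association).
#' @export
screen_instruments <- function(pairs, trait_table,
                               excluded_traits = c("smoking", "psoriasis"),
                               p_threshold = 1e-5) {
  stopifnot(is.data.frame(pairs), p_threshold > 0, p_threshold <= 1)
  if (is.null(trait_table) || nrow(trait_table) == 0L) {
    return(list(kept = pairs, removed = pairs[0, , drop = FALSE],
                reasons = data.frame(snp = character(), trait = character(),
                                     pval = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  if (length(excluded_traits) == 0L) {
    warning("screen_instruments: empty excluded-trait list; screen is a no-op")
    return(list(kept = pairs, removed = pairs[0, , drop = FALSE],
                reasons = data.frame(snp = character(), trait = character(),
                                     pval = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  trait_lc <- tolower(trait_table$trait)
  matched <- Reduce(`|`, lapply(tolower(excluded_traits), function(ex) {
    grepl(ex, trait_lc, fixed = TRUE)
  }))
  hits <- trait_table[matched & trait_table$pval < p_threshold &
                        trait_table$snp %in% pairs$snp, , drop = FALSE]
  remove <- pairs$snp %in% hits$snp
  list(
    kept = pairs[!remove, , drop = FALSE],
    removed = pairs[remove, , drop = FALSE],
    reasons = hits[order(hits$snp, hits$trait), , drop = FALSE]
  )
}
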