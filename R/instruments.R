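#' Define a cis gene region
#'
#' A named window on GRCh37 used for cis-instrument selection: the gene body
#' plus a symmetric flank (default 100 kb each side).
#'
#' @param name target label, e.g. `"PCSK9"`.
#' @param chrom chromosome label.
#' @param gene_start,gene_end 1-based gene boundaries, `gene_start <=
#'   gene_end`.
#' @param flank bases added on each side; `>= 0`.
#' @return list of class `"gene_region"`.
#' @export
gene_region <- function(name, chrom, gene_start, gene_end, flank = 1e5) {
  stopifnot(gene_start <= gene_end, flank >= 0)
  structure(
    list(name = name, chrom = as.character(chrom),
         gene_start = gene_start, gene_end = gene_end, flank = flank,
         window_start = gene_start - flank, window_end = gene_end + flank),
    class = "gene_region"
  )
}

#' GRCh37 regions of the three lipid-lowering drug-target genes
#'
#' PCSK9 (chr1:55,505,221-55,530,525), HMGCR (chr5:74,632,154-74,657,929)
#' and NPC1L1 (chr7:44,552,134-44,580,914), each extended by `flank` bases.
#'
#' @param flank flank applied to each gene; default 100 kb.
#' @return named list of [gene_region()] objects.
#' @export
drug_target_regions <- function(flank = 1e5) {
  list(
    PCSK9 = gene_region("PCSK9", "1", 55505221, 55530525, flank),
    HMGCR = gene_region("HMGCR", "5", 74632154, 74657929, flank),
    NPC1L1 = gene_region("NPC1L1", "7", 44552134, 44580914, flank)
  )
}

#' Greedy LD clumping of candidate variants
#'
#' PLINK-style greedy thinning: candidates are ranked by ascending p-value
#' (ties broken by ascending position, then rsID); the best remaining
#' variant is kept and all remaining variants with `r2 >= r2_threshold`
#' against it are discarded, until none remain. Output order is selection
#' order, so retained variants are pairwise below the threshold.
#'
#' @param candidates `variant_assoc` table.
#' @param ld square r-squared matrix covering every candidate rsID.
#' @param r2_threshold exclusive upper bound on pairwise r-squared; in
#'   `(0, 1]`.
#' @return the retained subset of `candidates`, in selection order.
#' @export
clump <- function(candidates, ld, r2_threshold) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  validate_ld_matrix(ld)
  missing <- setdiff(candidates$snp, rownames(ld))
  if (length(missing)) {
    stop("candidate variant(s) missing from LD matrix: ",
         paste(missing, collapse = ", "))
  }
  pos <- if ("pos" %in% names(candidates)) candidates$pos else
    rep(NA_real_, nrow(candidates))
  ord <- order(candidates$pval, pos, candidates$snp)
  remaining <- ord
  keep <- integer(0)
  while (length(remaining)) {
    best <- remaining[1L]
    keep <- c(keep, best)
    r2 <- ld[candidates$snp[best], candidates$snp[remaining]]
    remaining <- remaining[r2 < r2_threshold & remaining != best]
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select cis instruments for a drug-target gene region
#'
#' Keeps variants with `pval < p_threshold` (strict, matching the
#' genome-wide significance convention P < 5e-8) whose position lies inside
#' the flanked region window (inclusive on both boundaries), then LD-clumps
#' the survivors at `r2_threshold`.
#'
#' @param exposure `variant_assoc` table with `chrom` and `pos` columns.
#' @param region a [gene_region()].
#' @param p_threshold strict p-value cutoff; default 5e-8.
#' @param ld r-squared matrix covering the selected variants, or `NULL` to
#'   skip clumping (candidates assumed independent).
#' @param r2_threshold clumping threshold; default 0.3.
#' @return `variant_assoc` subset of selected instruments.
#' @export
select_cis_instruments <- function(exposure, region, p_threshold = 5e-8,
                                   ld = NULL, r2_threshold = 0.3) {
  stopifnot(inherits(region, "gene_region"),
            p_threshold > 0, p_threshold < 1)
  if (!all(c("chrom", "pos") %in% names(exposure))) {
    stop("exposure table needs chrom and pos columns for cis selection")
  }
  hit <- as.character(exposure$chrom) == region$chrom &
    exposure$pos >= region$window_start &
    exposure$pos <= region$window_end &
    exposure$pval < p_threshold
  hit[is.na(hit)] <- FALSE
  sel <- exposure[hit, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no variant passes selection for region ", region$name,
         " (chr", region$chrom, ":", region$window_start, "-",
         region$window_end, ", p < ", format(p_threshold), ")")
  }
  rownames(sel) <- NULL
  if (!is.null(ld)) sel <- clump(sel, ld, r2_threshold)
  sel
}

#' Genome-wide LDL instrument excluding the drug-target regions
#'
#' Keeps genome-wide-significant variants lying outside every flanked
#' drug-target window, then clumps at a stringent threshold (default
#' r-squared < 0.001) to approximate independence.
#'
#' @param exposure `variant_assoc` table with `chrom` and `pos`.
#' @param drug_regions list of [gene_region()] windows to exclude.
#' @param ld r-squared matrix, or `NULL` to skip clumping.
#' @param p_threshold strict p-value cutoff; default 5e-8.
#' @param r2_threshold clumping threshold; default 0.001.
#' @return `variant_assoc` subset.
#' @export
select_genomewide_ldl_instruments <- function(exposure,
                                              drug_regions = drug_target_regions(),
                                              ld = NULL,
                                              p_threshold = 5e-8,
                                              r2_threshold = 0.001) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (nrow(exposure) == 0L) {
    stop("no variant passes selection for the genome-wide LDL instrument: ",
         "empty exposure table")
  }
  if (!all(c("chrom", "pos") %in% names(exposure))) {
    stop("exposure table needs chrom and pos columns")
  }
  inside_any <- rep(FALSE, nrow(exposure))
  for (region in drug_regions) {
    inside <- as.character(exposure$chrom) == region$chrom &
      exposure$pos >= region$window_start &
      exposure$pos <= region$window_end
    inside[is.na(inside)] <- FALSE
    inside_any <- inside_any | inside
  }
  hit <- !inside_any & exposure$pval < p_threshold
  hit[is.na(hit)] <- FALSE
  sel <- exposure[hit, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no variant passes selection for the genome-wide LDL instrument")
  }
  rownames(sel) <- NULL
  if (!is.null(ld)) sel <- clump(sel, ld, r2_threshold)
  sel
}

#' Instrument-strength F statistic from beta and its standard error
#'
#' The Wald form `beta^2 / se^2`, i.e. the squared z score. F > 10 is the
#' conventional weak-instrument cutoff.
#'
#' @param beta,se numeric vectors; `se > 0`.
#' @return numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("f_statistic: se must be finite and > 0")
  }
  (beta / se)^2
}

#' Instrument-strength F statistic from variance explained
#'
#' Uses the variance in the exposure explained by the variant,
#' `R2 = 2 * eaf * (1 - eaf) * beta^2` (beta on the standardized scale),
#' giving `F = (n - 2) * R2 / (1 - R2)`. With the exposure GWAS sample size
#' n = 440,546 this form reproduces the published per-variant F column of
#' the packaged instrument table.
#'
#' @param beta per-allele effect.
#' @param eaf effect-allele frequency in `(0, 1)`.
#' @param n exposure sample size, `> 2`.
#' @return numeric vector of F values.
#' @export
f_statistic_from_r2 <- function(beta, eaf, n) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("f_statistic_from_r2: eaf must lie in (0, 1)")
  }
  if (any(!is.finite(n)) || any(n <= 2)) {
    stop("f_statistic_from_r2: n must be > 2")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  (n - 2) * r2 / (1 - r2)
}

#' Build a harmonized instrument set for one drug target
#'
#' Runs cis selection, harmonization against the outcome, per-variant F
#' computation (both the `beta^2/se^2` ratio form and the
#' variance-explained form are recorded) and, optionally, the weak-
#' instrument F > `weak_f_threshold` filter using the configured formula.
#'
#' @param target label for the set.
#' @param exposure,outcome `variant_assoc` tables.
#' @param region [gene_region()] for cis selection.
#' @param ld r-squared matrix or `NULL`.
#' @param p_threshold,r2_threshold selection thresholds (defaults 5e-8,
#'   0.3).
#' @param palindromic_eaf_window see [harmonize()].
#' @param f_formula which F enters filtering and `mean_f`: `"r2"`
#'   (variance-explained; reproduces the published table) or `"ratio"`.
#' @param f_filter drop instruments with F `<= weak_f_threshold`? Default
#'   `FALSE` (the packaged table contains no weak instrument); turn on for
#'   synthetic pipelines.
#' @param weak_f_threshold weak-instrument cutoff, default 10.
#' @param exposure_n sample size used by the variance-explained F when the
#'   exposure table has no `n` column; default 440,546.
#' @return list of class `"instrument_set"`: `target`, `pairs` (retained
#'   harmonized pairs with `f_ratio`, `f_r2`, `f_stat` columns), `dropped`,
#'   `f_formula`, `mean_f`, `n_selected`, `n_retained`.
#' @export
build_instrument_set <- function(target, exposure, outcome, region, ld = NULL,
                                 p_threshold = 5e-8, r2_threshold = 0.3,
                                 palindromic_eaf_window = 0.08,
                                 f_formula = c("r2", "ratio"),
                                 f_filter = FALSE, weak_f_threshold = 10,
                                 exposure_n = 440546) {
  f_formula <- match.arg(f_formula)
  sel <- select_cis_instruments(exposure, region, p_threshold, ld,
                                r2_threshold)
  pairs <- harmonize(sel, outcome, palindromic_eaf_window)
  kept <- retained_pairs(pairs)
  dropped <- pairs[!pairs$action %in% c("kept", "flipped"), , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no instrument retained for target ", target,
         " after harmonization")
  }
  n_eff <- ifelse(is.na(kept$exposure_n), exposure_n, kept$exposure_n)
  kept$f_ratio <- f_statistic(kept$exposure_beta, kept$exposure_se)
  kept$f_r2 <- f_statistic_from_r2(kept$exposure_beta, kept$exposure_eaf,
                                   n_eff)
  kept$f_stat <- if (f_formula == "r2") kept$f_r2 else kept$f_ratio
  n_weak <- 0L
  if (isTRUE(f_filter)) {
    weak <- kept$f_stat <= weak_f_threshold
    n_weak <- sum(weak)
    kept <- kept[!weak, , drop = FALSE]
    if (nrow(kept) == 0L) {
      stop("no instrument with F > ", weak_f_threshold, " for target ",
           target)
    }
  }
  if (nrow(kept) < 3L) {
    warning("target ", target, ": only ", nrow(kept), " instrument(s); ",
            "MR-Egger/median/mode estimates are unreliable")
  }
  rownames(kept) <- NULL
  structure(
    list(target = target, region = region, pairs = kept, dropped = dropped,
         f_formula = f_formula, mean_f = mean(kept$f_stat),
         n_selected = nrow(sel), n_retained = nrow(kept),
         n_weak_removed = n_weak),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", x$target, "\n")
  cat("  selected:", x$n_selected, " retained:", x$n_retained,
      " dropped in harmonization:", nrow(x$dropped),
      " weak removed:", x$n_weak_removed, "\n")
  cat("  mean F (", x$f_formula, " formula): ",
      format(x$mean_f, digits = 4), "\n", sep = "")
  invisible(x)
}
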