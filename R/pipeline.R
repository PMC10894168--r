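#' Assemble a study run configuration
#'
#' Collects every input path, threshold and estimator setting for
#' [run_study()]. Inputs may be file paths (tab-delimited, read with the
#' default column map) or in-memory tables.
#'
#' @param exposure exposure GWAS summary statistics: path or
#'   `variant_assoc` table (required).
#' @param outcome primary outcome GWAS: path or table (required).
#' @param validation optional validation outcome GWAS: path or table.
#' @param ld optional r-squared LD matrix: path or matrix. Without it,
#'   selection skips clumping.
#' @param trait_table optional variant-trait association table for the
#'   pleiotropy screen: path or data frame.
#' @param control_outcome optional positive-control outcome GWAS: path or
#'   table.
#' @param control_scenario optional named list of arguments for
#'   [simulate_outcome_for()] (e.g. `list(causal_effect = 0.4)`) used to
#'   synthesize a positive-control outcome when none is supplied.
#' @param regions named list of [gene_region()] windows; defaults to the
#'   three drug-target genes.
#' @param excluded_traits traits for the screen; default smoking and
#'   psoriasis.
#' @param p_threshold genome-wide significance cutoff; default 5e-8.
#' @param r2_threshold_cis,r2_threshold_genomewide clumping thresholds;
#'   defaults 0.3 and 0.001.
#' @param trait_p_threshold screen cutoff; default 1e-5.
#' @param palindromic_eaf_window see [harmonize()]; default 0.08.
#' @param f_formula,f_filter,exposure_n see [build_instrument_set()].
#' @param include_ldl also analyze the genome-wide LDL instrument
#'   (excluding the drug-target regions)? Default `TRUE`.
#' @param n_boot bootstrap replicates for median/mode SEs; default 2000.
#' @param bandwidth_factor weighted-mode bandwidth multiplier; default 1.
#' @param seed master seed (mandatory).
#' @param out_dir optional directory for tab-delimited tables, the JSON
#'   summary and figures.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(exposure, outcome, validation = NULL, ld = NULL,
                       trait_table = NULL, control_outcome = NULL,
                       control_scenario = NULL,
                       regions = drug_target_regions(),
                       excluded_traits = c("smoking", "psoriasis"),
                       p_threshold = 5e-8, r2_threshold_cis = 0.3,
                       r2_threshold_genomewide = 0.001,
                       trait_p_threshold = 1e-5,
                       palindromic_eaf_window = 0.08,
                       f_formula = "r2", f_filter = FALSE,
                       exposure_n = 440546, include_ldl = TRUE,
                       n_boot = 2000, bandwidth_factor = 1, seed,
                       out_dir = NULL) {
  if (missing(seed) || !is.finite(seed)) stop("run_config: seed is mandatory")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a JSON file
#'
#' File-path fields are resolved relative to the JSON file's directory.
#' Regions may be given as a list of `{name, chrom, gene_start, gene_end,
#' flank}` objects.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (field in c("exposure", "outcome", "validation", "ld", "trait_table",
                  "control_outcome", "out_dir")) {
    if (!is.null(raw[[field]]) && is.character(raw[[field]]) &&
        !file.exists(raw[[field]])) {
      raw[[field]] <- file.path(base, raw[[field]])
    }
  }
  if (!is.null(raw$regions)) {
    rg <- raw$regions
    raw$regions <- stats::setNames(
      lapply(seq_len(nrow(rg)), function(i) {
        gene_region(rg$name[i], rg$chrom[i], rg$gene_start[i],
                    rg$gene_end[i], rg$flank[i] %||% 1e5)
      }),
      rg$name
    )
  }
  do.call(run_config, raw)
}

# resolve a config input that may be a path or an in-memory object
.resolve_stats <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  read_summary_stats(x)
}
.resolve_ld <- function(x) {
  if (is.null(x) || is.matrix(x)) return(x)
  read_ld_matrix(x)
}
.resolve_traits <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  read_trait_table(x)
}

# deterministic per-analysis bootstrap seed below 2^31
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% (.Machine$integer.max - 1)) + 1L
}

# estimator suite for one harmonized, screened instrument set
.analyze_pairs <- function(pairs, exposure_label, outcome_label, cfg, k) {
  ests <- list(
    to_odds_ratio(ivw_mre(pairs)),
    to_odds_ratio(mr_egger(pairs)),
    to_odds_ratio(weighted_median(pairs, n_boot = cfg$n_boot,
                                  seed = .derive_seed(cfg$seed, k))),
    to_odds_ratio(weighted_mode(pairs,
                                bandwidth_factor = cfg$bandwidth_factor,
                                n_boot = cfg$n_boot,
                                seed = .derive_seed(cfg$seed, k + 1L)))
  )
  tab <- do.call(rbind, lapply(ests, as.data.frame))
  tab <- cbind(data.frame(exposure = exposure_label,
                          outcome = outcome_label,
                          stringsAsFactors = FALSE), tab)
  # headline orientation: OR for genetically proxied target inhibition
  # (per unit exposure decrease) is the reciprocal of the per-unit-increase OR
  tab$or_inhibition <- exp(-tab$beta)
  list(estimates = tab, loo = leave_one_out(pairs))
}

# instrument construction + screen + estimation for one exposure/outcome cell
.run_cell <- function(exposure_label, outcome_label, exposure, outcome,
                      cfg, traits, k) {
  if (exposure_label == "LDL") {
    sel <- select_genomewide_ldl_instruments(
      exposure, cfg$regions, cfg$ld_resolved, cfg$p_threshold,
      cfg$r2_threshold_genomewide
    )
    pairs <- harmonize(sel, outcome, cfg$palindromic_eaf_window)
    kept <- retained_pairs(pairs)
    if (nrow(kept) == 0L) stop("no instrument retained for LDL")
    n_eff <- ifelse(is.na(kept$exposure_n), cfg$exposure_n, kept$exposure_n)
    kept$f_ratio <- f_statistic(kept$exposure_beta, kept$exposure_se)
    kept$f_r2 <- f_statistic_from_r2(kept$exposure_beta, kept$exposure_eaf,
                                     n_eff)
    kept$f_stat <- if (cfg$f_formula == "r2") kept$f_r2 else kept$f_ratio
    if (isTRUE(cfg$f_filter)) {
      kept <- kept[kept$f_stat > 10, , drop = FALSE]
    }
    iset <- list(target = "LDL", pairs = kept,
                 dropped = pairs[!pairs$action %in% c("kept", "flipped"), ,
                                 drop = FALSE],
                 f_formula = cfg$f_formula, mean_f = mean(kept$f_stat),
                 n_selected = nrow(sel), n_retained = nrow(kept),
                 n_weak_removed = 0L)
    class(iset) <- "instrument_set"
  } else {
    iset <- build_instrument_set(
      exposure_label, exposure, outcome, cfg$regions[[exposure_label]],
      cfg$ld_resolved, cfg$p_threshold, cfg$r2_threshold_cis,
      cfg$palindromic_eaf_window, cfg$f_formula, cfg$f_filter,
      exposure_n = cfg$exposure_n
    )
  }
  screened <- screen_instruments(iset$pairs, traits, cfg$excluded_traits,
                                 cfg$trait_p_threshold)
  analysis <- .analyze_pairs(screened$kept, exposure_label, outcome_label,
                             cfg, k)
  list(
    instruments = iset,
    screen = screened,
    estimates = analysis$estimates,
    leave_one_out = analysis$loo,
    log = list(
      n_selected = iset$n_selected,
      n_dropped_harmonization = nrow(iset$dropped),
      n_weak_removed = iset$n_weak_removed,
      n_screen_removed = nrow(screened$removed),
      n_final = nrow(screened$kept),
      mean_f = iset$mean_f
    )
  )
}

#' Run the full drug-target MR study
#'
#' For each drug-target gene (and, optionally, the genome-wide LDL
#' instrument excluding those genes) against the primary and, when
#' supplied, validation outcome: instrument selection and clumping,
#' harmonization, the pleiotropy screen, all four estimators on the
#' odds-ratio scale, Cochran's Q, the Egger intercept and leave-one-out.
#' A failing target is recorded under `errors` and the remaining targets
#' still run. With `out_dir` set, writes per-cell instrument and
#' leave-one-out tables, a combined estimates table and a JSON summary
#' (deterministic for a fixed config and seed).
#'
#' @param config a [run_config()] or path to a JSON config.
#' @return list of class `"study_report"`: `estimates` (one row per
#'   exposure x outcome x method), `cells` (per-cell details), `errors`,
#'   `log`, `seed`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  exposure <- .resolve_stats(cfg$exposure)
  outcomes <- list(primary = .resolve_stats(cfg$outcome))
  if (!is.null(cfg$validation)) {
    outcomes$validation <- .resolve_stats(cfg$validation)
  } else {
    warning("no validation outcome configured; primary-only report")
  }
  cfg$ld_resolved <- .resolve_ld(cfg$ld)
  traits <- .resolve_traits(cfg$trait_table)

  exposure_labels <- c(names(cfg$regions),
                       if (isTRUE(cfg$include_ldl)) "LDL")
  cells <- list()
  errors <- list()
  estimates <- list()
  k <- 0L
  for (outcome_label in names(outcomes)) {
    for (exposure_label in exposure_labels) {
      k <- k + 2L
      cell_id <- paste(exposure_label, outcome_label, sep = ".")
      res <- tryCatch(
        .run_cell(exposure_label, outcome_label, exposure,
                  outcomes[[outcome_label]], cfg, traits, k),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors[[cell_id]] <- paste0("target ", exposure_label, ", outcome ",
                                    outcome_label, ": ",
                                    conditionMessage(res))
        next
      }
      cells[[cell_id]] <- res
      estimates[[cell_id]] <- res$estimates
    }
  }
  report <- structure(
    list(
      estimates = if (length(estimates)) do.call(rbind, c(estimates, list(make.row.names = FALSE))) else NULL,
      cells = cells,
      errors = errors,
      log = lapply(cells, `[[`, "log"),
      seed = cfg$seed
    ),
    class = "study_report"
  )
  if (!is.null(cfg$control_outcome) || !is.null(cfg$control_scenario)) {
    ctrl <- tryCatch(run_positive_control(config), error = function(e) e)
    if (inherits(ctrl, "error")) {
      report$errors$positive_control <- conditionMessage(ctrl)
    } else {
      report$positive_control <- list(pass = ctrl$pass,
                                      per_target_pass = ctrl$per_target_pass)
    }
  }
  if (!is.null(cfg$out_dir)) write_study_report(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("MR study report:", length(x$cells), "analysis cell(s),",
      length(x$errors), "error(s)\n")
  if (!is.null(x$estimates)) {
    print(x$estimates[, c("exposure", "outcome", "method", "n_snps", "or",
                          "or_ci_low", "or_ci_high", "pval")],
          row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("errors:\n")
    for (e in x$errors) cat("  -", e, "\n")
  }
  invisible(x)
}

# stable JSON-ready summary of a study report
.report_summary <- function(report) {
  list(
    seed = report$seed,
    n_cells = length(report$cells),
    estimates = report$estimates,
    log = report$log,
    errors = unlist(report$errors %||% list()),
    positive_control = report$positive_control %||% NULL
  )
}

#' Write a study report to disk
#'
#' Emits `estimates.tsv`, per-cell `instruments_<cell>.tsv` and
#' `leave_one_out_<cell>.tsv`, and a `summary.json` that is byte-identical
#' across reruns with the same config and seed.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$estimates)) {
    utils::write.table(report$estimates, file.path(out_dir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cell_id in names(report$cells)) {
    cell <- report$cells[[cell_id]]
    utils::write.table(cell$instruments$pairs,
                       file.path(out_dir, paste0("instruments_", cell_id,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cell$leave_one_out,
                       file.path(out_dir, paste0("leave_one_out_", cell_id,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(.report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Run the positive-control analysis
#'
#' Estimates each exposure's effect on the positive-control outcome (a
#' disease with an established causal LDL link, e.g. coronary artery
#' disease) and flags the run as passing when every exposure's genetically
#' proxied inhibition is protective (inhibition OR < 1, i.e. a positive
#' per-unit-increase log-odds estimate). The control outcome comes from
#' `config$control_outcome` or is synthesized from
#' `config$control_scenario`.
#'
#' @param config a [run_config()] (or JSON path) with `control_outcome` or
#'   `control_scenario` set.
#' @return list of class `"control_report"`: `estimates` (IVW per
#'   exposure), `pass` (logical), `per_target_pass`.
#' @export
run_positive_control <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  exposure <- .resolve_stats(cfg$exposure)
  cfg$ld_resolved <- .resolve_ld(cfg$ld)
  control <- .resolve_stats(cfg$control_outcome)
  if (is.null(control)) {
    if (is.null(cfg$control_scenario)) {
      stop("run_positive_control needs control_outcome or control_scenario")
    }
    args <- cfg$control_scenario
    args$exposure <- exposure
    if (is.null(args$seed)) args$seed <- .derive_seed(cfg$seed, 997L)
    control <- do.call(simulate_outcome_for, args)
  }
  traits <- .resolve_traits(cfg$trait_table)
  exposure_labels <- c(names(cfg$regions),
                       if (isTRUE(cfg$include_ldl)) "LDL")
  rows <- list()
  per_target <- logical(0)
  errors <- list()
  for (exposure_label in exposure_labels) {
    res <- tryCatch(
      .run_cell(exposure_label, "positive_control", exposure, control, cfg,
                traits, 600L + 2L * length(rows)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[exposure_label]] <- conditionMessage(res)
      next
    }
    ivw <- res$estimates[res$estimates$method == "IVW-MRE", , drop = FALSE]
    rows[[exposure_label]] <- ivw
    per_target[exposure_label] <- ivw$or_inhibition < 1
  }
  structure(
    list(
      estimates = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL,
      per_target_pass = per_target,
      pass = length(per_target) > 0 && all(per_target),
      errors = errors
    ),
    class = "control_report"
  )
}

#' @export
print.control_report <- function(x, ...) {
  cat("Positive-control analysis:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!is.null(x$estimates)) {
    print(x$estimates[, c("exposure", "n_snps", "or_inhibition", "pval")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Render forest and leave-one-out figures for a study report
#'
#' One forest-style figure per outcome (odds ratio and 95% CI per exposure
#' and method, log x-axis) and one leave-one-out figure per analysis cell,
#' written as PDFs under `out_dir`. Any plotting failure is caught and
#' reported as a warning; rendering never aborts the run.
#'
#' @param report a `study_report`.
#' @param out_dir output directory for figures.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  est <- report$estimates
  if (!is.null(est)) {
    for (outcome_label in unique(est$outcome)) {
      sub <- est[est$outcome == outcome_label, , drop = FALSE]
      path <- file.path(out_dir, paste0("forest_", outcome_label, ".pdf"))
      ok <- .safe_pdf(path, 7, 1 + 0.4 * nrow(sub), function() {
        labels <- paste(sub$exposure, sub$method, sep = " / ")
        y <- rev(seq_len(nrow(sub)))
        xlim <- range(c(sub$or_ci_low, sub$or_ci_high, 1), finite = TRUE)
        graphics::plot(sub$or, y, log = "x", xlim = xlim, pch = 15,
                       yaxt = "n", ylab = "", xlab = "Odds ratio (95% CI)",
                       main = paste("Outcome:", outcome_label))
        graphics::segments(sub$or_ci_low, y, sub$or_ci_high, y)
        graphics::abline(v = 1, lty = 2, col = "grey40")
        graphics::axis(2, at = y, labels = labels, las = 1, cex.axis = 0.6)
      })
      if (ok) written <- c(written, path)
    }
  }
  for (cell_id in names(report$cells)) {
    loo <- report$cells[[cell_id]]$leave_one_out
    path <- file.path(out_dir, paste0("leave_one_out_", cell_id, ".pdf"))
    ok <- .safe_pdf(path, 6, 1 + 0.25 * nrow(loo), function() {
      y <- rev(seq_len(nrow(loo)))
      graphics::plot(loo$beta, y, pch = 16, yaxt = "n", ylab = "",
                     xlab = "IVW beta omitting variant",
                     xlim = range(c(loo$ci_low, loo$ci_high), finite = TRUE),
                     main = cell_id)
      graphics::segments(loo$ci_low, y, loo$ci_high, y)
      graphics::abline(v = 0, lty = 2, col = "grey40")
      graphics::axis(2, at = y, labels = loo$snp_omitted, las = 1,
                     cex.axis = 0.5)
    })
    if (ok) written <- c(written, path)
  }
  invisible(written)
}

# open a pdf device, run the plotting closure, always close the device;
# failures become warnings so rendering never aborts a run
.safe_pdf <- function(path, width, height, fun) {
  tryCatch({
    grDevices::pdf(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    TRUE
  }, error = function(e) {
    warning("plot failed for ", basename(path), ": ", conditionMessage(e))
    FALSE
  })
}
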