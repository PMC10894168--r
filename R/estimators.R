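#' @title MR estimators and diagnostics
#' @description Per-variant Wald ratios, the inverse-variance-weighted
#'   estimator with multiplicative random effects, MR-Egger, weighted
#'   median, weighted mode, Cochran's Q, leave-one-out and odds-ratio
#'   conversion. All estimators take harmonized pairs ([harmonize()]) and
#'   silently discard rows whose `action` marks them dropped.
#' @name estimators
NULL

# common entry: coerce/validate pairs, drop non-retained rows
.mr_pairs <- function(pairs, min_n, caller) {
  if ("action" %in% names(pairs)) pairs <- retained_pairs(pairs)
  need <- c("snp", "exposure_beta", "exposure_se", "outcome_beta",
            "outcome_se")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop(caller, ": pairs are missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(pairs) < min_n) {
    extra <- if (identical(caller, "ivw_mre"))
      "; use wald_ratios() for a single-instrument analysis" else ""
    stop(caller, " needs at least ", min_n, " harmonized pairs, got ",
         nrow(pairs), extra)
  }
  pairs
}

.mr_estimate <- function(method, beta, se, pval, n_snps,
                         ci_low, ci_high, ...) {
  structure(
    c(list(method = method, beta = beta, se = se,
           ci_low = ci_low, ci_high = ci_high, pval = pval,
           n_snps = n_snps), list(...)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$q_stat) && is.finite(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.4g (df %d), p = %.3g\n",
                x$q_stat, x$n_snps - as.integer(x$method == "Egger") - 1L,
                x$q_pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.4g, 95%% CI [%.4g, %.4g]\n",
                x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    q_stat = x$q_stat %||% NA_real_, q_pval = x$q_pval %||% NA_real_,
    egger_intercept = x$egger_intercept %||% NA_real_,
    egger_intercept_se = x$egger_intercept_se %||% NA_real_,
    egger_intercept_pval = x$egger_intercept_pval %||% NA_real_,
    or = x$or %||% exp(x$beta),
    or_ci_low = x$or_ci_low %||% exp(x$ci_low),
    or_ci_high = x$or_ci_high %||% exp(x$ci_high),
    stringsAsFactors = FALSE
  )
}

#' Per-variant Wald ratio estimates
#'
#' `ratio = outcome_beta / exposure_beta`, with the first-order delta-method
#' standard error `outcome_se / |exposure_beta|` (exposure uncertainty
#' ignored, appropriate for strong instruments) and inverse-variance weight
#' `1 / ratio_se^2`.
#'
#' @param pairs harmonized pairs.
#' @return data frame with columns `snp`, `ratio`, `ratio_se`, `weight`.
#' @export
wald_ratios <- function(pairs) {
  pairs <- .mr_pairs(pairs, 1L, "wald_ratios")
  zero <- pairs$exposure_beta == 0
  if (any(zero)) {
    stop("wald_ratios: zero exposure beta for variant(s): ",
         paste(pairs$snp[zero], collapse = ", "))
  }
  ratio_se <- pairs$outcome_se / abs(pairs$exposure_beta)
  data.frame(
    snp = pairs$snp,
    ratio = pairs$outcome_beta / pairs$exposure_beta,
    ratio_se = ratio_se,
    weight = 1 / ratio_se^2,
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Weighted through-origin regression of the outcome effects on the
#' exposure effects with weights `1 / outcome_se^2` (equivalently the
#' inverse-variance-weighted mean of the Wald ratios). The fixed-effect
#' standard error is inflated by the square root of the dispersion
#' `Q / (J - 1)`, floored at 1 so the random-effects SE never undercuts the
#' fixed-effect one. P-values are two-sided normal; the 95% CI is
#' `beta +/- 1.96 * se` on the log scale.
#'
#' @param pairs harmonized pairs, at least 2.
#' @return an `mr_estimate` with heterogeneity fields `q_stat`, `q_pval`,
#'   `dispersion`.
#' @export
ivw_mre <- function(pairs) {
  pairs <- .mr_pairs(pairs, 2L, "ivw_mre")
  w <- 1 / pairs$outcome_se^2
  g <- pairs$exposure_beta
  G <- pairs$outcome_beta
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- sqrt(1 / sum(w * g^2))
  q <- cochran_q(pairs)
  phi <- q$q_stat / (nrow(pairs) - 1L)
  se <- se_fixed * sqrt(max(1, phi))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("IVW-MRE", beta, se, pval, nrow(pairs),
               beta - 1.96 * se, beta + 1.96 * se,
               q_stat = q$q_stat, q_pval = q$q_pval, dispersion = phi,
               se_fixed = se_fixed)
}

#' Cochran's Q heterogeneity of the Wald ratios
#'
#' `Q = sum w_j (b_j - b_ivw)^2` over the per-variant ratio estimates
#' `b_j` with weights `w_j = 1 / ratio_se_j^2`, where `b_ivw` is the
#' fixed-effect IVW mean; p-value from chi-squared with `J - 1` degrees of
#' freedom.
#'
#' @param pairs harmonized pairs, at least 2.
#' @return list with `q_stat`, `q_pval`, `df`.
#' @export
cochran_q <- function(pairs) {
  pairs <- .mr_pairs(pairs, 2L, "cochran_q")
  wr <- wald_ratios(pairs)
  b_ivw <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - b_ivw)^2)
  df <- nrow(wr) - 1L
  list(q_stat = q, q_pval = stats::pchisq(q, df, lower.tail = FALSE),
       df = df)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1 / outcome_se^2`, after orienting each pair
#' so the exposure effect is non-negative. The slope is the causal
#' estimate; a non-zero intercept indicates directional pleiotropy.
#' Standard errors carry a multiplicative dispersion `RSS_w / (J - 2)`
#' floored at 1; p-values and CIs use the t distribution with `J - 2`
#' degrees of freedom.
#'
#' @param pairs harmonized pairs, at least 3.
#' @return an `mr_estimate` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `q_stat` (Rucker's Q about the Egger fit) and
#'   `q_pval`.
#' @export
mr_egger <- function(pairs) {
  pairs <- .mr_pairs(pairs, 3L, "mr_egger")
  flip <- sign(pairs$exposure_beta)
  flip[flip == 0] <- 1
  g <- pairs$exposure_beta * flip
  G <- pairs$outcome_beta * flip
  w <- 1 / pairs$outcome_se^2
  J <- length(g)

  sw <- sum(w); sx <- sum(w * g); sy <- sum(w * G)
  sxx <- sum(w * g^2); sxy <- sum(w * g * G)
  den <- sw * sxx - sx^2
  if (den <= 0) stop("mr_egger: degenerate design (no spread in exposure betas)")
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / sw
  resid <- G - intercept - slope * g
  rss <- sum(w * resid^2)
  phi <- rss / (J - 2L)
  scale <- sqrt(max(1, phi))
  se_slope <- sqrt(sw / den) * scale
  se_int <- sqrt(sxx / den) * scale
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2L)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2L)
  tq <- stats::qt(0.975, df = J - 2L)
  .mr_estimate("Egger", slope, se_slope, p_slope, J,
               slope - tq * se_slope, slope + tq * se_slope,
               egger_intercept = intercept, egger_intercept_se = se_int,
               egger_intercept_pval = p_int,
               q_stat = rss,
               q_pval = stats::pchisq(rss, J - 2L, lower.tail = FALSE),
               dispersion = phi)
}

# parametric bootstrap SE shared by weighted median and mode: resample
# exposure and outcome betas from normals centred on the observed values
.ratio_bootstrap <- function(pairs, point_fun, n_boot, seed) {
  if (n_boot < 1L) return(NA_real_)
  set.seed(seed)
  J <- nrow(pairs)
  reps <- vapply(seq_len(n_boot), function(i) {
    g <- stats::rnorm(J, pairs$exposure_beta, pairs$exposure_se)
    G <- stats::rnorm(J, pairs$outcome_beta, pairs$outcome_se)
    g[g == 0] <- .Machine$double.eps
    point_fun(G / g, (pairs$outcome_se / abs(g))^2)
  }, numeric(1))
  stats::sd(reps)
}

# interpolated weighted median of ratios b with precision weights (1/se^2)
.weighted_median_point <- function(b, inv_var) {
  ord <- order(b)
  b <- b[ord]
  w <- inv_var[ord] / sum(inv_var)
  p <- cumsum(w) - w / 2
  stats::approx(p, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Interpolated median of the Wald ratios under inverse-variance weights:
#' consistent as long as valid instruments carry more than half the total
#' weight. The standard error comes from a parametric bootstrap that
#' resamples the exposure and outcome betas from normal distributions with
#' their reported SEs.
#'
#' @param pairs harmonized pairs, at least 3.
#' @param n_boot bootstrap replicates (default 2000); `0` skips the
#'   bootstrap and returns `NA` for `se`, CI and p (point estimate only,
#'   useful inside simulation loops).
#' @param seed RNG seed for the bootstrap; required for reproducibility.
#' @return an `mr_estimate`.
#' @export
weighted_median <- function(pairs, n_boot = 2000, seed) {
  pairs <- .mr_pairs(pairs, 3L, "weighted_median")
  if (n_boot >= 1L && missing(seed)) stop("weighted_median: seed is required")
  wr <- wald_ratios(pairs)
  beta <- .weighted_median_point(wr$ratio, wr$weight)
  se <- .ratio_bootstrap(pairs, .weighted_median_point,
                         n_boot, if (n_boot >= 1L) seed else 0L)
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("WeightedMedian", beta, se, pval, nrow(pairs),
               beta - 1.96 * se, beta + 1.96 * se)
}

# mode of the weighted kernel-smoothed density of ratios; bandwidth follows
# the modified Silverman rule used by the mode-based estimate
.weighted_mode_point <- function(b, inv_var, bandwidth_factor = 1) {
  w <- inv_var / sum(inv_var)
  s <- 0.9 * min(stats::sd(b), stats::mad(b)) / length(b)^(1 / 5)
  h <- max(1e-8, bandwidth_factor * s)
  d <- stats::density(b, weights = w, bw = h, n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted mode estimator
#'
#' Mode of the inverse-variance-weighted kernel-smoothed empirical density
#' of the Wald ratios (Gaussian kernel; bandwidth from a scaled
#' median-absolute-deviation rule times `bandwidth_factor`): consistent
#' when the largest homogeneous cluster of instruments is valid. Bootstrap
#' SE as in [weighted_median()].
#'
#' @param pairs harmonized pairs, at least 3.
#' @param bandwidth_factor multiplier on the default bandwidth; default 1.
#' @param n_boot bootstrap replicates (default 2000); `0` for point
#'   estimate only.
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
weighted_mode <- function(pairs, bandwidth_factor = 1, n_boot = 2000, seed) {
  pairs <- .mr_pairs(pairs, 3L, "weighted_mode")
  if (n_boot >= 1L && missing(seed)) stop("weighted_mode: seed is required")
  wr <- wald_ratios(pairs)
  beta <- .weighted_mode_point(wr$ratio, wr$weight, bandwidth_factor)
  se <- .ratio_bootstrap(
    pairs,
    function(b, v) .weighted_mode_point(b, v, bandwidth_factor),
    n_boot, if (n_boot >= 1L) seed else 0L
  )
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("WeightedMode", beta, se, pval, nrow(pairs),
               beta - 1.96 * se, beta + 1.96 * se)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW multiplicative-random-effects estimate omitting each
#' variant in turn, in input order.
#'
#' @param pairs harmonized pairs, at least 3.
#' @return data frame with one row per omitted variant: `snp_omitted`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
leave_one_out <- function(pairs) {
  pairs <- .mr_pairs(pairs, 3L, "leave_one_out")
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    est <- ivw_mre(pairs[-j, , drop = FALSE])
    data.frame(snp_omitted = pairs$snp[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert a log-odds MR estimate to the odds-ratio scale
#'
#' Exponentiates the point estimate and the log-scale CI endpoints; the
#' input estimate is returned with `or`, `or_ci_low`, `or_ci_high` filled
#' in.
#'
#' @param est an `mr_estimate` whose `beta` is on the log-odds scale.
#' @return the estimate with odds-ratio fields set.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}
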