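#' Describe a synthetic two-sample GWAS scenario
#'
#' Collects the generative parameters for a two-sample summary-statistics
#' simulation with known ground truth. Defaults mirror the study design the
#' package targets: an LDL exposure GWAS of 440,546 individuals and a
#' case-control outcome of 1,637 cases / 212,242 controls, with instrument
#' effect sizes in the range of published cis LDL instruments.
#'
#' @param n_variants number of instruments; default 30.
#' @param causal_effect true causal effect `b` (outcome log-odds per unit
#'   exposure); default -0.5.
#' @param exposure_n exposure GWAS sample size; default 440,546.
#' @param n_cases,n_controls outcome case-control design; defaults 1,637 /
#'   212,242.
#' @param eaf_range interval the effect-allele frequencies are drawn from;
#'   default `c(0.1, 0.9)`.
#' @param exposure_effect_range interval for the true exposure effects
#'   `gamma` (drawn uniformly, oriented positive, i.e. effect alleles coded
#'   exposure-increasing); default `c(0.02, 0.1)`.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct outcome effects
#'   `alpha ~ N(0, sd)`) or `"directional"` (`alpha ~ N(mean, sd)`).
#' @param pleiotropy_mean mean direct effect under `"directional"`; default
#'   0.02.
#' @param pleiotropy_sd SD of the direct effects; default 0.02.
#' @param ld_block_sizes integer block sizes summing to `n_variants` for
#'   [simulate_ld_matrix()]; default all singletons (no LD).
#' @param ld_within_r2 within-block r-squared in `[0, 1]`; default 0.9.
#' @param seed master RNG seed (mandatory).
#' @return list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_variants = 30, causal_effect = -0.5,
                               exposure_n = 440546, n_cases = 1637,
                               n_controls = 212242,
                               eaf_range = c(0.1, 0.9),
                               exposure_effect_range = c(0.02, 0.1),
                               pleiotropy_mode = c("none", "balanced",
                                                   "directional"),
                               pleiotropy_mean = 0.02, pleiotropy_sd = 0.02,
                               ld_block_sizes = NULL, ld_within_r2 = 0.9,
                               seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed) || !is.finite(seed)) stop("scenario seed is mandatory")
  stopifnot(n_variants >= 1, exposure_n > 2, n_cases > 0, n_controls > 0,
            length(eaf_range) == 2, length(exposure_effect_range) == 2)
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] >= eaf_range[2]) {
    stop("eaf_range must be an increasing interval inside (0, 1)")
  }
  if (is.null(ld_block_sizes)) ld_block_sizes <- rep(1L, n_variants)
  if (sum(ld_block_sizes) != n_variants) {
    stop("ld_block_sizes must sum to n_variants")
  }
  if (ld_within_r2 < 0 || ld_within_r2 > 1) {
    stop("ld_within_r2 must lie in [0, 1]")
  }
  structure(
    list(n_variants = as.integer(n_variants), causal_effect = causal_effect,
         exposure_n = exposure_n, n_cases = n_cases, n_controls = n_controls,
         eaf_range = eaf_range,
         exposure_effect_range = exposure_effect_range,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         ld_block_sizes = as.integer(ld_block_sizes),
         ld_within_r2 = ld_within_r2, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

# three independent sub-streams (truth, exposure noise, outcome noise)
# derived from the master seed, honouring the two-sample assumption
.scenario_streams <- function(seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

# two-sided normal p-value floored at the smallest normalized double so
# extreme z scores never underflow the (0, 1] p-value invariant
.two_sided_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# GWAS standard error of a per-allele effect under the standard
# approximation se = 1 / sqrt(2 p (1-p) n_eff)
.gwas_se <- function(eaf, n_eff) 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Per variant `j`: draws `eaf_j` and a positive exposure effect `gamma_j`,
#' sets the exposure SE to `1 / sqrt(2 eaf_j (1 - eaf_j) n_x)` and the
#' outcome SE to the same form with the effective case-control size
#' `n_cases n_controls / (n_cases + n_controls)`, adds a direct
#' (pleiotropic) outcome effect `alpha_j` per the scenario mode, and
#' observes `beta_x ~ N(gamma_j, se_x)` and
#' `beta_y ~ N(b gamma_j + alpha_j, se_y)` from two independent RNG
#' streams. P-values are two-sided normal. Variant effect alleles are
#' non-palindromic (A/G) so harmonization keeps every variant.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `exposure` and `outcome` (`variant_assoc` tables
#'   sharing rsIDs) and `truth` (list: `causal_effect`, `gamma`, `alpha`,
#'   `eaf`).
#' @export
simulate_two_sample <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  streams <- .scenario_streams(scenario$seed)
  J <- scenario$n_variants

  set.seed(streams[1])
  eaf <- stats::runif(J, scenario$eaf_range[1], scenario$eaf_range[2])
  gamma <- stats::runif(J, scenario$exposure_effect_range[1],
                        scenario$exposure_effect_range[2])
  alpha <- switch(scenario$pleiotropy_mode,
    none = rep(0, J),
    balanced = stats::rnorm(J, 0, scenario$pleiotropy_sd),
    directional = stats::rnorm(J, scenario$pleiotropy_mean,
                               scenario$pleiotropy_sd)
  )

  se_x <- .gwas_se(eaf, scenario$exposure_n)
  # doubles: integer case/control counts overflow 32-bit multiplication
  n_eff <- as.numeric(scenario$n_cases) * as.numeric(scenario$n_controls) /
    (as.numeric(scenario$n_cases) + as.numeric(scenario$n_controls))
  se_y <- .gwas_se(eaf, n_eff)

  set.seed(streams[2])
  beta_x <- stats::rnorm(J, gamma, se_x)
  set.seed(streams[3])
  beta_y <- stats::rnorm(J, scenario$causal_effect * gamma + alpha, se_y)

  snp <- sprintf("rs9%07d", seq_len(J))
  # synthetic chromosome 2 keeps simulated variants clear of the real
  # drug-target windows on chromosomes 1, 5 and 7
  base <- data.frame(
    snp = snp, chrom = "2", pos = 1e6 + 1000 * seq_len(J),
    effect_allele = "A", other_allele = "G",
    stringsAsFactors = FALSE
  )
  exposure <- base
  exposure$eaf <- eaf
  exposure$beta <- beta_x
  exposure$se <- se_x
  exposure$pval <- .two_sided_p(beta_x / se_x)
  exposure$n <- scenario$exposure_n
  outcome <- base
  outcome$eaf <- eaf
  outcome$beta <- beta_y
  outcome$se <- se_y
  outcome$pval <- .two_sided_p(beta_y / se_y)
  outcome$n <- scenario$n_cases + scenario$n_controls
  list(
    exposure = variant_assoc(exposure),
    outcome = variant_assoc(outcome),
    truth = list(causal_effect = scenario$causal_effect, gamma = gamma,
                 alpha = alpha, eaf = eaf, snp = snp)
  )
}

#' Simulate a case-control outcome for an existing exposure table
#'
#' Complements [simulate_two_sample()] when the exposure variants are fixed
#' in advance (e.g. the packaged instrument table): treats the exposure
#' betas as the true per-allele exposure effects `gamma_j`, forms the true
#' outcome effect `b * gamma_j + alpha_j`, derives the outcome SE from the
#' effect-allele frequency and the effective case-control sample size, and
#' draws observed outcome betas. Alleles and rsIDs are copied from the
#' exposure so harmonization keeps every variant.
#'
#' @param exposure `variant_assoc` table with an `eaf` column.
#' @param causal_effect true causal effect `b` (log-odds per unit
#'   exposure).
#' @param n_cases,n_controls outcome design; defaults 1,637 / 212,242.
#' @param pleiotropy_mode,pleiotropy_mean,pleiotropy_sd direct-effect model
#'   as in [synthetic_scenario()].
#' @param seed RNG seed (mandatory).
#' @return `variant_assoc` outcome table with attribute `truth`.
#' @export
simulate_outcome_for <- function(exposure, causal_effect,
                                 n_cases = 1637, n_controls = 212242,
                                 pleiotropy_mode = c("none", "balanced",
                                                     "directional"),
                                 pleiotropy_mean = 0.02,
                                 pleiotropy_sd = 0.02, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("seed is mandatory")
  if (!"eaf" %in% names(exposure) || anyNA(exposure$eaf)) {
    stop("exposure table needs a complete eaf column")
  }
  J <- nrow(exposure)
  set.seed(seed)
  alpha <- switch(pleiotropy_mode,
    none = rep(0, J),
    balanced = stats::rnorm(J, 0, pleiotropy_sd),
    directional = stats::rnorm(J, pleiotropy_mean, pleiotropy_sd)
  )
  n_eff <- as.numeric(n_cases) * as.numeric(n_controls) /
    (as.numeric(n_cases) + as.numeric(n_controls))
  se_y <- .gwas_se(exposure$eaf, n_eff)
  beta_y <- stats::rnorm(J, causal_effect * exposure$beta + alpha, se_y)
  out <- data.frame(
    snp = exposure$snp,
    chrom = if ("chrom" %in% names(exposure)) exposure$chrom else NA,
    pos = if ("pos" %in% names(exposure)) exposure$pos else NA,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    eaf = exposure$eaf, beta = beta_y, se = se_y,
    pval = .two_sided_p(beta_y / se_y),
    n = n_cases + n_controls,
    stringsAsFactors = FALSE
  )
  out <- variant_assoc(out)
  attr(out, "truth") <- list(causal_effect = causal_effect, alpha = alpha)
  out
}

#' Simulate a block-diagonal LD matrix for a scenario
#'
#' Variants within a block share the scenario's `ld_within_r2`; variants in
#' different blocks have r-squared 0; the diagonal is 1.
#'
#' @param scenario a [synthetic_scenario()].
#' @return square r-squared matrix with the scenario's rsIDs as dimnames.
#' @export
simulate_ld_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  J <- scenario$n_variants
  block <- rep(seq_along(scenario$ld_block_sizes), scenario$ld_block_sizes)
  m <- outer(block, block, function(a, b) {
    ifelse(a == b, scenario$ld_within_r2, 0)
  })
  diag(m) <- 1
  ids <- sprintf("rs9%07d", seq_len(J))
  dimnames(m) <- list(ids, ids)
  validate_ld_matrix(m)
  m
}

#' Simulate a positive-control outcome
#'
#' Generates outcome summary statistics under a strong known causal effect
#' of the exposure (e.g. LDL raising harming coronary-artery-disease risk,
#' `b > 0`), for end-to-end direction-of-effect checks: genetically proxied
#' inhibition of an LDL-raising pathway should then show a protective odds
#' ratio.
#'
#' @param scenario a [synthetic_scenario()] with nonzero `causal_effect`;
#'   a zero effect is allowed (to exercise the failure path of the control
#'   check) but flagged with a warning.
#' @return `variant_assoc` outcome table (same rsIDs as
#'   [simulate_two_sample()] under the same scenario).
#' @export
simulate_positive_control <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$causal_effect == 0) {
    warning("positive-control scenario has a null causal effect; ",
            "the control check is expected to fail")
  }
  simulate_two_sample(scenario)$outcome
}
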