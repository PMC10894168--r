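# builders and independent oracles shared across test files

# minimal variant table; vectors are recycled to the longest
make_variants <- function(snp, beta, se, pval = 1e-10, eaf = 0.3,
                          chrom = "1", pos = seq_along(snp) * 1000 + 55405221,
                          ea = "A", oa = "G", n = 440546) {
  variant_assoc(data.frame(
    snp = snp, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE
  ))
}

# harmonized-pairs table straight from exposure/outcome effects
make_pairs <- function(g, G, sy, sx = 0.01, snp = sprintf("rs%d", seq_along(g))) {
  structure(
    data.frame(
      snp = snp, effect_allele = "A", other_allele = "G",
      exposure_beta = g, exposure_se = sx, exposure_eaf = 0.3,
      exposure_pval = 1e-10, exposure_n = 440546,
      outcome_beta = G, outcome_se = sy, outcome_eaf = 0.3,
      action = "kept", stringsAsFactors = FALSE
    ),
    class = c("harmonized_pairs", "data.frame")
  )
}

# independent greedy-clumping trace: explicit step-by-step simulation,
# sharing no code with clump()
oracle_clump <- function(candidates, ld, r2_threshold) {
  df <- as.data.frame(candidates)
  df <- df[order(df$pval, df$pos, df$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(df) > 0) {
    best <- df$snp[1]
    kept <- c(kept, best)
    drop <- vapply(df$snp, function(s) {
      s == best || ld[best, s] >= r2_threshold
    }, logical(1))
    df <- df[!drop, , drop = FALSE]
  }
  kept
}

# independent fixed-effect IVW by explicit sums
oracle_ivw_fixed <- function(g, G, sy) {
  w <- 1 / sy^2
  sum(w * g * G) / sum(w * g^2)
}

# independent weighted-mode oracle: direct Gaussian kernel sum on a fine grid
oracle_mode_grid <- function(b, weights, bw) {
  w <- weights / sum(weights)
  grid <- seq(min(b) - 4 * bw, max(b) + 4 * bw, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, b, bw)), numeric(1))
  grid[which.max(dens)]
}

# full LD matrix from a named square of values (default independence)
make_ld <- function(ids, entries = NULL) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  if (!is.null(entries)) {
    for (e in entries) {
      m[e[[1]], e[[2]]] <- as.numeric(e[[3]])
      m[e[[2]], e[[1]]] <- as.numeric(e[[3]])
    }
  }
  m
}

# combined exposure table: the three packaged instrument sets plus synthetic
# genome-wide variants on another chromosome
combined_exposure <- function(n_extra = 40, seed = 7) {
  fix <- do.call(rbind, lapply(c("PCSK9", "HMGCR", "NPC1L1"), function(t) {
    d <- load_instrument_fixture(t)
    d$f_printed <- NULL
    as.data.frame(d)
  }))
  sim <- simulate_two_sample(synthetic_scenario(n_variants = n_extra,
                                                seed = seed))
  variant_assoc(rbind(fix, as.data.frame(sim$exposure)))
}
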