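test_that("wald_ratios implements the first-order delta method", {
  wr <- wald_ratios(make_pairs(g = c(0.5, -0.5, 0.5),
                               G = c(0.25, 0.25, 0), sy = 0.1))
  expect_equal(wr$ratio, c(0.5, -0.5, 0))
  expect_equal(wr$ratio_se, rep(0.2, 3))
  expect_equal(wr$weight, rep(25, 3))
  expect_error(wald_ratios(make_pairs(g = c(0.5, 0), G = c(0.1, 0.1),
                                      sy = 0.1)), "rs2")
})

test_that("ivw_mre matches closed forms and floors the dispersion", {
  # equal weights: weighted mean of 0.5 and 0.3
  est <- ivw_mre(make_pairs(g = c(1, 1), G = c(0.5, 0.3), sy = 0.1))
  expect_equal(est$beta, 0.4)

  # perfect proportionality: beta = c, Q = 0, se floored at fixed-effect
  est2 <- ivw_mre(make_pairs(g = c(1, 2, 3), G = 0.7 * c(1, 2, 3), sy = 0.1))
  expect_equal(est2$beta, 0.7)
  expect_equal(est2$q_stat, 0)
  expect_equal(est2$se, est2$se_fixed)
  expect_equal(est2$q_pval, 1)

  # duplicated single pair: estimate equals the Wald ratio
  est3 <- ivw_mre(make_pairs(g = c(0.5, 0.5), G = c(0.2, 0.2), sy = 0.1))
  expect_equal(est3$beta, 0.4)

  expect_error(ivw_mre(make_pairs(g = 1, G = 0.5, sy = 0.1)), "wald_ratios")
})

test_that("IVW identities: weighted mean of ratios, sign invariance, floor", {
  set.seed(202)
  for (rep in 1:50) {
    J <- sample(3:25, 1)
    pairs <- make_pairs(g = runif(J, 0.02, 0.2) * sample(c(-1, 1), J, TRUE),
                        G = rnorm(J, 0, 0.1), sy = runif(J, 0.02, 0.2))
    est <- ivw_mre(pairs)
    wr <- wald_ratios(pairs)
    expect_equal(est$beta, sum(wr$weight * wr$ratio) / sum(wr$weight),
                 tolerance = 1e-12)
    # flipping gamma and Gamma of one variant leaves the estimate unchanged
    flip <- pairs
    flip$exposure_beta[1] <- -flip$exposure_beta[1]
    flip$outcome_beta[1] <- -flip$outcome_beta[1]
    expect_equal(ivw_mre(flip)$beta, est$beta, tolerance = 1e-12)
    # random-effects SE never undercuts the fixed-effect SE
    expect_gte(est$se, est$se_fixed * (1 - 1e-12))
  }
})

test_that("cochran_q matches a direct sum of squares and its scaling law", {
  g <- c(1, 1, 1); G <- c(0.5, 0.3, 0.1); sy <- c(0.1, 0.2, 0.1)
  q <- cochran_q(make_pairs(g = g, G = G, sy = sy))
  b <- G / g
  w <- (g / sy)^2
  b_fix <- sum(w * b) / sum(w)
  expect_equal(q$q_stat, sum(w * (b - b_fix)^2))
  expect_equal(q$df, 2L)
  expect_equal(q$q_pval, pchisq(q$q_stat, 2, lower.tail = FALSE))

  # identical ratios: no heterogeneity
  q0 <- cochran_q(make_pairs(g = c(1, 2), G = c(0.4, 0.8), sy = 0.1))
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_pval, 1)

  # doubling every outcome SE quarters the weights, so Q scales by 1/4
  q2 <- cochran_q(make_pairs(g = g, G = G, sy = 2 * sy))
  expect_equal(q2$q_stat, q$q_stat / 4)
})

test_that("mr_egger fits exactly through collinear points and shifts correctly", {
  pairs <- make_pairs(g = c(1, 2, 3), G = c(0.6, 1.1, 1.6), sy = 0.1)
  est <- mr_egger(pairs)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.1, tolerance = 1e-12)
  expect_equal(est$q_stat, 0, tolerance = 1e-20)

  # no pleiotropy: intercept 0
  prop <- mr_egger(make_pairs(g = c(1, 2, 3), G = 0.5 * c(1, 2, 3), sy = 0.1))
  expect_equal(prop$egger_intercept, 0, tolerance = 1e-12)

  # adding d to every outcome effect moves only the intercept
  shift <- pairs
  shift$outcome_beta <- shift$outcome_beta + 0.3
  est_s <- mr_egger(shift)
  expect_equal(est_s$beta, est$beta, tolerance = 1e-12)
  expect_equal(est_s$egger_intercept, est$egger_intercept + 0.3,
               tolerance = 1e-12)

  # orientation: pairs are flipped to gamma >= 0 before fitting
  neg <- pairs
  neg$exposure_beta <- -neg$exposure_beta
  neg$outcome_beta <- -neg$outcome_beta
  expect_equal(mr_egger(neg)$beta, est$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$egger_intercept, est$egger_intercept,
               tolerance = 1e-12)

  expect_error(mr_egger(make_pairs(g = c(1, 2), G = c(0.5, 1), sy = 0.1)),
               "at least 3")
})

test_that("weighted_median interpolates the cumulative-weight midpoints", {
  # equal weights, ratios {0.1, 0.2, 0.3}: midpoints 1/6, 1/2, 5/6 -> 0.2
  est <- weighted_median(make_pairs(g = c(1, 1, 1), G = c(0.1, 0.2, 0.3),
                                    sy = 0.1), n_boot = 0)
  expect_equal(est$beta, 0.2)
  expect_true(is.na(est$se))

  # all ratios equal c: estimate c with a tiny bootstrap SE
  flat <- make_pairs(g = rep(1, 5), G = rep(0.25, 5), sy = 0.001,
                     sx = 0.001)
  est_f <- weighted_median(flat, n_boot = 500, seed = 9)
  expect_equal(est_f$beta, 0.25)
  expect_lt(est_f$se, 0.01)

  # a variant holding most of the weight dominates despite outliers
  dom <- make_pairs(g = c(1, 1, 1), G = c(1, 10, 11),
                    sy = c(0.02, 1.4, 1.4))  # weights ~ 0.98, 0.01, 0.01
  est_d <- weighted_median(dom, n_boot = 0)
  expect_lt(abs(est_d$beta - 1), 0.25)
  # with equal weights the same ratios give the interpolated plain median
  eq <- weighted_median(make_pairs(g = c(1, 1, 1), G = c(1, 10, 11),
                                   sy = 0.1), n_boot = 0)
  expect_equal(eq$beta, 10)
})

test_that("weighted_mode finds the density argmax of the ratio cluster", {
  # cluster of three at 0.5 versus a lone outlier at 5
  pairs <- make_pairs(g = rep(1, 4), G = c(0.5, 0.5, 0.5, 5), sy = 0.1)
  est <- weighted_mode(pairs, n_boot = 0)
  expect_lt(abs(est$beta - 0.5), 0.05)

  # grid oracle on a jittered cluster with the same bandwidth rule
  set.seed(77)
  b <- c(rnorm(8, 0.4, 0.02), rnorm(3, 1.5, 0.02))
  pairs2 <- make_pairs(g = rep(1, 11), G = b, sy = 0.1)
  est2 <- weighted_mode(pairs2, n_boot = 0)
  bw <- 0.9 * min(sd(b), mad(b)) / 11^(1 / 5)
  expect_equal(est2$beta, oracle_mode_grid(b, rep(1, 11), bw),
               tolerance = 0.02)

  # unequal weights favoring cluster A pull the mode into cluster A
  b3 <- c(-0.5, -0.48, -0.52, 0.5, 0.48, 0.52)
  sy3 <- c(0.05, 0.05, 0.05, 0.2, 0.2, 0.2)
  est3 <- weighted_mode(make_pairs(g = rep(1, 6), G = b3, sy = sy3),
                        n_boot = 0)
  expect_lt(abs(est3$beta + 0.5), 0.1)

  # single tight cluster: estimate within a bandwidth of the mean
  est4 <- weighted_mode(make_pairs(g = rep(1, 5),
                                   G = c(0.3, 0.31, 0.29, 0.3, 0.32),
                                   sy = 0.1), n_boot = 0)
  expect_lt(abs(est4$beta - 0.304), 0.05)

  expect_error(weighted_mode(make_pairs(g = c(1, 1), G = c(1, 1), sy = 0.1),
                             n_boot = 0), "at least 3")
})

test_that("leave_one_out returns one IVW fit per omitted variant", {
  set.seed(11)
  J <- 8
  g <- runif(J, 0.05, 0.2)
  pairs <- make_pairs(g = g, G = -0.5 * g + rnorm(J, 0, 0.005), sy = 0.05)
  loo <- leave_one_out(pairs)
  expect_equal(nrow(loo), J)
  expect_equal(loo$snp_omitted, pairs$snp)
  # homogeneous effects: every leave-one-out beta inside every interval
  expect_true(all(outer(loo$beta, loo$ci_low, `>=`) &
                    outer(loo$beta, loo$ci_high, `<=`)))

  # a gross outlier shifts the estimate most when omitted
  out_pairs <- pairs
  out_pairs$outcome_beta[3] <- 0.5
  loo_o <- leave_one_out(out_pairs)
  full <- ivw_mre(out_pairs)$beta
  shifts <- abs(loo_o$beta - full)
  expect_equal(which.max(shifts), 3L)
  # verified against a direct recomputation without variant 3
  expect_equal(loo_o$beta[3],
               oracle_ivw_fixed(out_pairs$exposure_beta[-3],
                                out_pairs$outcome_beta[-3],
                                out_pairs$outcome_se[-3]))
})

test_that("to_odds_ratio exponentiates the log-scale estimate and CI", {
  est <- ivw_mre(make_pairs(g = c(1, 1), G = c(0.5, 0.3), sy = 0.1))
  or <- to_odds_ratio(est)
  expect_equal(or$or, exp(est$beta))
  expect_equal(or$or_ci_low, exp(est$ci_low))
  expect_equal(or$or_ci_high, exp(est$ci_high))
  expect_lt(or$or_ci_low, or$or_ci_high)

  null <- est; null$beta <- 0
  expect_equal(to_odds_ratio(null)$or, 1)
  shifted <- est; shifted$beta <- -0.673
  expect_equal(to_odds_ratio(shifted)$or, 0.51, tolerance = 0.01)
})

test_that("estimators ignore rows harmonization marked as dropped", {
  pairs <- make_pairs(g = c(1, 1, 1, 1), G = c(0.5, 0.3, 0.4, 99), sy = 0.1)
  pairs$action[4] <- "dropped_palindromic"
  est <- ivw_mre(pairs)
  expect_equal(est$n_snps, 3L)
  expect_equal(est$beta, 0.4)
})
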