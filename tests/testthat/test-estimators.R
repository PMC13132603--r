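test_that("wald_ratio computes by/bx with delta-method SE", {
  est <- wald_ratio(bx = 0.1, se_x = 0.01, by = 0.02, se_y = 0.01)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.01),
               class = "mrmediate_domain_error")
  # CI and OR scale are consistent with the point estimate
  expect_equal(est$ci_low, est$beta - 1.959964 * est$se)
  expect_equal(est$odds_ratio, exp(est$beta))
  expect_equal(est$or_ci_high, exp(est$ci_high))
})

test_that("ivw matches the weighted-regression-through-origin solution", {
  h <- make_h(bx = c(0.1, 0.2), se_x = c(0.01, 0.01),
              by = c(0.02, 0.06), se_y = c(0.01, 0.02))
  est <- ivw(h, model = "fixed")
  expect_equal(est$beta, 0.25)
  expect_equal(est$se, 0.070711, tolerance = 1e-5)

  h0 <- make_h(bx = c(0.1, 0.2, 0.3), se_x = 0.01, by = c(0, 0, 0),
               se_y = c(0.01, 0.02, 0.01))
  expect_equal(ivw(h0)$beta, 0)

  expect_error(ivw(make_h(0.1, 0.01, 0.02, 0.01)),
               class = "mrmediate_domain_error")
})

test_that("ivw and mr_egger agree with a generic WLS oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(4:30, 1)
    bx <- rnorm(k, 0, 0.1); bx[abs(bx) < 1e-3] <- 0.05
    by <- 0.3 * bx + rnorm(k, 0, 0.02)
    se_y <- runif(k, 0.005, 0.05)
    h <- make_h(bx, rep(0.01, k), by, se_y)
    w <- 1 / se_y^2

    fit0 <- wls_oracle(by, cbind(bx), w, intercept = FALSE)
    expect_equal(ivw(h, model = "fixed")$beta, unname(coef(fit0)[1]),
                 tolerance = 1e-10)

    fit1 <- wls_oracle(by, cbind(bx), w, intercept = TRUE)
    e <- mr_egger(h)
    expect_equal(e$beta, unname(coef(fit1)["x1"]), tolerance = 1e-10)
    expect_equal(e$intercept, unname(coef(fit1)["(Intercept)"]),
                 tolerance = 1e-10)
    # when the residual dispersion exceeds 1 the SEs match lm's as well
    sigma2 <- sum(w * resid(fit1)^2) / (k - 2)
    if (sigma2 > 1) {
      expect_equal(e$se, unname(sqrt(diag(vcov(fit1)))["x1"]),
                   tolerance = 1e-8)
    }
  }
})

test_that("mr_egger recovers an exact linear law and enforces preconditions", {
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h <- make_h(bx, 0.01, by = 0.01 + 0.3 * bx, se_y = c(0.01, 0.02, 0.01, 0.03))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0.01, tolerance = 1e-12)
  expect_error(mr_egger(make_h(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               class = "mrmediate_domain_error")
})

test_that("weighted_median interpolates the cumulative-weight grid", {
  # all ratios equal: estimate is that ratio
  h_eq <- make_h(bx = c(0.1, 0.2, 0.4), se_x = 0.01,
                 by = 0.25 * c(0.1, 0.2, 0.4), se_y = 0.01)
  expect_equal(weighted_median(h_eq, n_boot = 50, seed = 1)$beta, 0.25)

  # equal weights, ratios (0.1, 0.2, 0.9): median lands on the middle ratio
  h_mid <- make_h(bx = c(1, 1, 1), se_x = 0.01, by = c(0.1, 0.2, 0.9),
                  se_y = c(0.02, 0.02, 0.02))
  expect_equal(weighted_median(h_mid, n_boot = 50, seed = 1)$beta, 0.2)

  # unequal weights: matches the hand interpolation oracle
  bx <- c(1, 1, 1); se_y <- c(0.02, 0.01, 0.015)
  by <- c(0.1, 0.2, 0.35)
  ratio <- by / bx
  w <- bx^2 / se_y^2; w <- w / sum(w)
  ord <- order(ratio)
  s <- cumsum(w[ord]) - w[ord] / 2
  expected <- approx(s, ratio[ord], xout = 0.5)$y
  h <- make_h(bx, 0.01, by, se_y)
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, expected)
})

test_that("weighted_median is permutation-invariant and bounded by the ratios", {
  set.seed(5)
  k <- 9
  bx <- runif(k, 0.05, 0.3); by <- 0.2 * bx + rnorm(k, 0, 0.02)
  se_y <- runif(k, 0.01, 0.03)
  h <- make_h(bx, 0.01, by, se_y)
  est <- weighted_median(h, n_boot = 50, seed = 2)$beta
  perm <- sample(k)
  h_p <- make_h(bx[perm], 0.01, by[perm], se_y[perm])
  expect_equal(weighted_median(h_p, n_boot = 50, seed = 2)$beta, est)
  expect_gte(est, min(by / bx))
  expect_lte(est, max(by / bx))
})

test_that("mode_estimate finds the dominant ratio cluster", {
  # identical ratios: degenerate bandwidth returns the common ratio
  h_eq <- make_h(bx = c(0.1, 0.2, 0.4), se_x = 0.01,
                 by = 0.3 * c(0.1, 0.2, 0.4), se_y = 0.01)
  expect_equal(mode_estimate(h_eq, n_boot = 20, seed = 1)$beta, 0.3)

  # tight cluster at ~0.2 plus one outlier at 0.95: mode sits in the cluster
  h_cl <- make_h(bx = rep(1, 4), se_x = 0.01,
                 by = c(0.20, 0.21, 0.19, 0.95), se_y = rep(0.02, 4))
  m <- mode_estimate(h_cl, weighted = FALSE, n_boot = 20, seed = 1)$beta
  expect_lt(abs(m - 0.20), 0.05)

  # nearly all weight on one variant drags the weighted mode to its ratio
  h_w <- make_h(bx = rep(1, 3), se_x = 0.01, by = c(0.5, 0.1, 0.12),
                se_y = c(0.001, 1, 1))
  mw <- mode_estimate(h_w, weighted = TRUE, n_boot = 20, seed = 1)$beta
  expect_lt(abs(mw - 0.5), 0.02)

  # very large bandwidth: estimate approaches the center of the ratios
  h_b <- make_h(bx = rep(1, 5), se_x = 0.01,
                by = c(0.1, 0.15, 0.2, 0.25, 0.3), se_y = 0.02)
  mb <- mode_estimate(h_b, weighted = FALSE, phi = 100, n_boot = 20,
                      seed = 1)$beta
  expect_lt(abs(mb - 0.2), 0.03)

  expect_error(mode_estimate(make_h(c(1, 1), 0.01, c(0.1, 0.2), 0.02),
                             n_boot = 20, seed = 1),
               class = "mrmediate_domain_error")
})

test_that("run_all_methods applies the SNP-count rules and the majority sign rule", {
  h1 <- make_h(0.1, 0.01, 0.02, 0.01)
  r1 <- run_all_methods(h1, seed = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$method, "wald")

  h2 <- make_h(c(0.1, 0.2), 0.01, c(0.02, 0.05), c(0.01, 0.02))
  r2 <- run_all_methods(h2, seed = 1)
  expect_equal(r2$method, "ivw")

  # strong positive simulated effect: all five methods agree in sign
  sim <- simulate_gwas_triplet(sim_config(seed = 21))
  iv <- select_instruments(sim$exposure, sim$ld)
  expo <- as_summary_stats(
    as.data.frame(sim$exposure)[sim$exposure$variant_id %in% iv$variant_id, ],
    "exposure")
  h <- harmonize(expo, sim$outcome)
  r5 <- run_all_methods(h, seed = 4, n_boot = 100)
  expect_equal(nrow(r5), 5L)
  expect_true(all(r5$beta > 0))
  expect_true(attr(r5, "direction_consistent"))
  expect_true(all(r5$se > 0))
  expect_true(all(r5$pval >= 0 & r5$pval <= 1))

  # a null does not crash the battery
  simn <- simulate_gwas_triplet(sim_config(beta2 = 0, beta4 = 0, direct = 0,
                                           seed = 22))
  ivn <- select_instruments(simn$exposure, simn$ld)
  expon <- as_summary_stats(
    as.data.frame(simn$exposure)[simn$exposure$variant_id %in% ivn$variant_id, ],
    "exposure")
  hn <- harmonize(expon, simn$outcome)
  expect_no_error(run_all_methods(hn, seed = 4, n_boot = 50))
})

test_that("wald ratio coincides with a singleton IVW fit", {
  # the IVW normal equations on one variant reduce to by/bx with se_y/|bx|
  bx <- 0.15; by <- 0.03; se_y <- 0.02
  w <- wald_ratio(bx, 0.01, by, se_y)
  expect_equal(w$beta, (bx * by / se_y^2) / (bx^2 / se_y^2))
  expect_equal(w$se, sqrt(1 / (bx^2 / se_y^2)))
})
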