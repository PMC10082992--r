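test_that("Wald ratios follow the delta-method arithmetic", {
  h <- harmonized_set(0.1, 0.01, 0.02, 0.005)
  wr <- wald_ratios(h)
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.05)
  h2 <- harmonized_set(-0.1, 0.01, 0.02, 0.005)
  expect_equal(wald_ratios(h2)$beta, -0.2)
  # vectorized ratios equal a scalar loop
  set.seed(1)
  h5 <- random_h(5, seed = 1)
  wr5 <- wald_ratios(h5)
  for (j in 1:5) {
    expect_equal(wr5$beta[j], h5$beta_out[j] / h5$beta_exp[j])
    expect_equal(wr5$se[j], h5$se_out[j] / abs(h5$beta_exp[j]))
  }
  # zero exposure effects are excluded with a warning
  h0 <- harmonized_set(c(0.1, 0), c(0.01, 0.01), c(0.02, 0.01),
                       c(0.005, 0.005))
  expect_warning(wr0 <- wald_ratios(h0), "zero exposure")
  expect_equal(nrow(wr0), 1L)
})

test_that("IVW equals the weighted-least-squares oracle", {
  for (seed in 1:5) {
    h <- random_h(8, seed = seed, het = 0.01)
    fit <- mr_fit(h, "ivw", random_effects = FALSE)
    oracle <- wls_oracle(h$beta_exp, h$beta_out, h$se_out)
    expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-12)
    expect_equal(fit$se, as.numeric(sqrt(vcov(oracle)) /
                                      summary(oracle)$sigma),
                 tolerance = 1e-12)
  }
})

test_that("IVW handles perfect proportionality and the J = 2 floor", {
  bx <- c(0.1, 0.2, 0.15, 0.08, 0.3)
  h <- harmonized_set(bx, rep(0.01, 5), 0.5 * bx, rep(0.01, 5))
  fit <- mr_fit(h, "ivw")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$overdispersion, 0)
  # random-effects SE never drops below the fixed-effect SE
  expect_equal(fit$se, mr_fit(h, "ivw", random_effects = FALSE)$se)
  expect_error(mr_fit(harmonized_set(0.1, 0.01, 0.05, 0.01), "ivw"),
               "wald")
})

test_that("random-effects IVW inflates the SE under overdispersion", {
  h <- random_h(20, seed = 3, het = 0.05)
  fe <- mr_fit(h, "ivw", random_effects = FALSE)
  re <- mr_fit(h, "ivw", random_effects = TRUE)
  expect_gt(re$overdispersion, 1)
  expect_equal(re$se, fe$se * sqrt(re$overdispersion))
})

test_that("MR-Egger recovers an exact affine relationship", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- harmonized_set(bx, rep(0.01, 5), 0.03 + 0.4 * bx, rep(0.01, 5))
  fit <- mr_fit(h, "egger")
  expect_equal(fit$intercept, 0.03, tolerance = 1e-12)
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_equal(heterogeneity(h)$q_prime, 0, tolerance = 1e-10)
  expect_error(mr_fit(harmonized_set(bx[1:2], rep(0.01, 2), bx[1:2],
                                     rep(0.01, 2)), "egger"),
               "insufficient SNPs")
})

test_that("MR-Egger equals the weighted-regression oracle after orientation", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    J <- 10
    bx <- rnorm(J, 0.1, 0.08)           # mixed signs
    byse <- runif(J, 0.005, 0.02)
    by <- 0.02 + 0.4 * bx + rnorm(J, 0, 0.01)
    h <- harmonized_set(bx, runif(J, 0.005, 0.02), by, byse)
    s <- ifelse(bx < 0, -1, 1)
    oracle <- wls_oracle(s * bx, s * by, byse, intercept = TRUE)
    fit <- mr_fit(h, "egger", random_effects = FALSE)
    expect_equal(unname(coef(oracle)), c(fit$intercept, fit$beta),
                 tolerance = 1e-12)
    se_or <- unname(sqrt(diag(vcov(oracle))) / summary(oracle)$sigma)
    expect_equal(c(fit$intercept_se, fit$se), se_or, tolerance = 1e-12)
  }
})

test_that("weighted median reduces to known cases and its definition", {
  # all ratios equal: estimate is that constant
  bx <- c(0.1, 0.2, 0.4)
  h <- harmonized_set(bx, rep(0.01, 3), 0.7 * bx, c(0.01, 0.02, 0.005))
  fit <- mr_fit(h, "weighted_median", n_boot = 200, seed = 1)
  expect_equal(fit$beta, 0.7, tolerance = 1e-12)
  # equal weights, odd J: the middle order statistic
  h2 <- harmonized_set(rep(1, 5), rep(0.01, 5), c(0.30, 0.10, 0.50,
                                                  0.20, 0.40),
                       rep(0.01, 5))
  fit2 <- mr_fit(h2, "weighted_median", n_boot = 200, seed = 1)
  expect_equal(fit2$beta, 0.30, tolerance = 1e-12)
  # 4-SNP definitional oracle: manual cumulative-midpoint interpolation
  h4 <- harmonized_set(c(0.1, 0.2, 0.25, 0.5), c(0.01, 0.01, 0.01, 0.01),
                       c(0.02, 0.09, 0.05, 0.2),
                       c(0.004, 0.012, 0.006, 0.02))
  ratio <- h4$beta_out / h4$beta_exp
  w <- (h4$beta_exp / h4$se_out)^2
  ord <- order(ratio)
  r <- ratio[ord]; wn <- w[ord] / sum(w)
  pj <- cumsum(wn) - wn / 2
  k <- max(which(pj < 0.5))
  manual <- r[k] + (r[k + 1] - r[k]) * (0.5 - pj[k]) / (pj[k + 1] - pj[k])
  fit4 <- mr_fit(h4, "weighted_median", n_boot = 200, seed = 9)
  expect_equal(fit4$beta, manual, tolerance = 1e-12)
  expect_error(mr_fit(harmonized_set(0.1, 0.01, 0.1, 0.01),
                      "weighted_median"), "at least 3")
})

test_that("weighted median equals IVW when all ratios coincide", {
  bx <- c(0.08, 0.12, 0.2, 0.33)
  h <- harmonized_set(bx, rep(0.01, 4), 0.25 * bx, rep(0.01, 4))
  wm <- mr_fit(h, "weighted_median", n_boot = 200, seed = 5)
  ivw <- mr_fit(h, "ivw")
  expect_equal(wm$beta, ivw$beta, tolerance = 1e-10)
})

test_that("heterogeneity statistics nest correctly", {
  h <- random_h(10, seed = 11, het = 0.02)
  het <- heterogeneity(h)
  expect_gte(het$q, het$q_prime)
  expect_gte(het$q_prime, 0)
  expect_equal(het$df_q, 9)
  expect_equal(het$df_qp, 8)
  # direct summation oracle for Q on a 4-SNP instance
  h4 <- random_h(4, seed = 2, het = 0.01)
  ivw <- mr_fit(h4, "ivw")
  q_manual <- sum((h4$beta_out - ivw$beta * h4$beta_exp)^2 / h4$se_out^2)
  expect_equal(heterogeneity(h4)$q, q_manual)
  # exact proportionality: Q = Q' = 0, p_diff = 1
  bx <- c(0.1, 0.2, 0.3, 0.15)
  hp <- harmonized_set(bx, rep(0.01, 4), 0.5 * bx, rep(0.01, 4))
  hetp <- heterogeneity(hp)
  expect_equal(hetp$q, 0, tolerance = 1e-10)
  expect_equal(hetp$p_diff, 1)
})

test_that("the Ruecker rule requires both conditions to switch", {
  h <- random_h(10, seed = 4, het = 0.01)
  rk <- mr_rucker(h)
  expect_s3_class(rk, "mr_rucker")
  manual <- rk$p_diff < 0.05 && rk$intercept_p < 0.1
  expect_equal(rk$chosen_method, if (manual) "MR-Egger" else "IVW")
  # force the two boundary cases via thresholds
  rk2 <- mr_rucker(h, p_diff_threshold = 1.1 * rk$p_diff,
                   intercept_threshold = 0.5 * rk$intercept_p)
  expect_equal(rk2$chosen_method, "IVW")   # intercept condition fails
  rk3 <- mr_rucker(h, p_diff_threshold = 1.1 * rk$p_diff,
                   intercept_threshold = 1.1 * rk$intercept_p)
  expect_equal(rk3$chosen_method, "MR-Egger")
})

test_that("rescaling the exposure rescales estimates and preserves Q", {
  h <- random_h(12, seed = 6, het = 0.02)
  c_scale <- 4
  h2 <- h
  h2$beta_exp <- c_scale * h2$beta_exp
  h2$se_exp <- c_scale * h2$se_exp
  for (m in c("ivw", "egger")) {
    f1 <- mr_fit(h, m); f2 <- mr_fit(h2, m)
    expect_equal(f2$beta, f1$beta / c_scale, tolerance = 1e-10)
    expect_equal(f2$pvalue, f1$pvalue, tolerance = 1e-10)
  }
  het1 <- heterogeneity(h); het2 <- heterogeneity(h2)
  expect_equal(het2$q, het1$q, tolerance = 1e-10)
  expect_equal(het2$q_prime, het1$q_prime, tolerance = 1e-10)
  wm1 <- mr_fit(h, "weighted_median", n_boot = 100, seed = 3)
  wm2 <- mr_fit(h2, "weighted_median", n_boot = 100, seed = 3)
  expect_equal(wm2$beta, wm1$beta / c_scale, tolerance = 1e-10)
})

test_that("leave-one-out produces J re-estimates and finds planted outliers", {
  h <- random_h(3, seed = 8)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 3L)
  expect_true(all(vapply(seq_len(3), function(j)
    mr_fit(retained(h)[-j, ], "ivw")$beta == loo$beta[j], logical(1))))
  # homogeneous data: every estimate inside the full fixed-effect CI
  hh <- random_h(15, seed = 9, het = 0)
  full <- mr_fit(hh, "ivw", random_effects = FALSE)
  loo2 <- leave_one_out(hh, random_effects = FALSE)
  expect_true(all(loo2$beta > full$ci_low & loo2$beta < full$ci_high))
  # planted outlier: largest shift when the outlier is excluded
  ho <- random_h(15, seed = 10, het = 0)
  ho$beta_out[7] <- ho$beta_out[7] + 12 * ho$se_out[7]
  full_o <- mr_fit(ho, "ivw")
  loo3 <- leave_one_out(ho)
  shifts <- abs(loo3$beta - full_o$beta)
  expect_equal(which.max(shifts), 7L)
  expect_error(leave_one_out(random_h(2, seed = 1)), "at least 3")
})

test_that("aggregate Steiger directionality is antisymmetric", {
  h <- harmonized_set(beta_exp = c(0.1, 0.08, 0.12),
                      se_exp = rep(0.01, 3),
                      beta_out = c(0.01, 0.008, 0.012),
                      se_out = rep(0.01, 3), n_exp = 30000,
                      n_out = 30000)
  st <- steiger_directionality(h)
  expect_equal(st$verdict, "valid")
  # swap roles
  h_rev <- harmonized_set(h$beta_out, h$se_out, h$beta_exp, h$se_exp,
                          n_exp = 30000, n_out = 30000)
  st_rev <- steiger_directionality(h_rev)
  expect_equal(st_rev$verdict, "reversed")
  expect_equal(st_rev$z, -st$z, tolerance = 1e-12)
  # equal totals: z = 0, p = 1
  he <- harmonized_set(0.1, 0.01, 0.1, 0.01, n_exp = 1000, n_out = 1000)
  ste <- steiger_directionality(he)
  expect_equal(ste$z, 0)
  expect_equal(ste$p, 1)
})

test_that("mr_fit objects expose standard accessors", {
  h <- random_h(6, seed = 12)
  fit <- mr_fit(h, "egger")
  expect_named(coef(fit), c("intercept", "beta"))
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_low, fit$ci_high))
  expect_length(residuals(fit, h), 6L)
  expect_output(print(fit), "MR-Egger")
})
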