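test_that("the Wald ratio is exact arithmetic with ratio invariance", {
  p <- tibble::tibble(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.25, se_out = 0.1)
  w <- mr_wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)

  p0 <- dplyr::mutate(p, beta_out = 0)
  w0 <- mr_wald_ratio(p0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)

  flipped <- dplyr::mutate(p, beta_exp = -beta_exp, beta_out = -beta_out)
  expect_equal(mr_wald_ratio(flipped)$beta, w$beta)
  expect_equal(mr_wald_ratio(flipped)$se, w$se)

  expect_error(mr_wald_ratio(dplyr::mutate(p, beta_exp = 0)), "nonzero")
})

test_that("IVW reduces to the Wald ratio for one variant and to the common slope under homogeneity", {
  p <- fixture_pairs(1, seed = 2)
  expect_equal(mr_ivw(p)$beta, mr_wald_ratio(p)$beta)
  expect_equal(mr_ivw(p)$se, mr_wald_ratio(p)$se)

  exact <- fixture_pairs(6, slope = 0.7, noise = 0, seed = 3)
  fit <- mr_ivw(exact)
  expect_equal(fit$beta, 0.7)
  expect_equal(fit$extra$q, 0, tolerance = 1e-20)
  expect_equal(fit$se, fit$extra$se_fixed)
})

test_that("IVW matches the normal-equations oracle and ignores pair order", {
  p <- fixture_pairs(8, seed = 4)
  fit <- mr_ivw(p)
  orc <- oracle_ivw(p$beta_exp, p$beta_out, p$se_out)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-12)
  expect_equal(fit$extra$se_fixed, orc$se_fixed, tolerance = 1e-12)
  expect_equal(fit$se, orc$se_re, tolerance = 1e-12)

  perm <- p[sample.int(nrow(p)), ]
  expect_equal(mr_ivw(perm)$beta, fit$beta)
  expect_equal(mr_ivw(perm)$se, fit$se)
  expect_error(mr_ivw(p[0, ]), "at least")
})

test_that("MR-Egger recovers exact fits and matches the WLS oracle", {
  exact <- fixture_pairs(5, slope = 0.4, noise = 0, seed = 5)
  eg <- mr_egger(exact)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-12)

  noisy <- fixture_pairs(5, seed = 6)
  eg2 <- mr_egger(noisy)
  orc <- oracle_egger(noisy$beta_exp, noisy$beta_out, noisy$se_out)
  expect_equal(eg2$slope$beta, orc$slope, tolerance = 1e-12)
  expect_equal(eg2$intercept$beta, orc$intercept, tolerance = 1e-12)
  expect_equal(eg2$slope$se, orc$se_slope, tolerance = 1e-12)
  expect_equal(eg2$intercept$se, orc$se_intercept, tolerance = 1e-12)

  # adding a constant to every outcome effect moves the intercept, not much the slope
  shifted <- dplyr::mutate(exact, beta_out = beta_out * sign(beta_exp) + 0.05,
                           beta_exp = abs(beta_exp))
  eg3 <- mr_egger(shifted)
  expect_equal(eg3$intercept$beta, 0.05, tolerance = 1e-10)
  expect_equal(eg3$slope$beta, 0.4, tolerance = 1e-10)

  # orientation invariance: negating one pair changes nothing
  neg <- noisy
  neg$beta_exp[2] <- -neg$beta_exp[2]
  neg$beta_out[2] <- -neg$beta_out[2]
  expect_equal(mr_egger(neg)$slope$beta, eg2$slope$beta)
  expect_error(mr_egger(noisy[1:2, ]), "at least 3")
})

test_that("planted directional pleiotropy drives the Egger intercept test", {
  hits <- vapply(1:100, function(i) {
    sim <- simulate_triple(sim_config(n_snps = 30, n_med_snps = 0,
                                      theta_total = 0.2,
                                      frac_pleiotropic = 0.9,
                                      pleiotropy_mean = 0.06,
                                      pleiotropy_sd = 0.01,
                                      frac_palindromic = 0,
                                      frac_strand_flipped = 0,
                                      seed = 5000 + i))
    pairs <- harmonize(sim$exposure, sim$outcome)
    mr_egger(pairs)$intercept$pvalue < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("the weighted median interpolates standardized cumulative weights", {
  eq <- tibble::tibble(beta_exp = 1, se_exp = 0.1,
                       beta_out = c(1, 2, 9), se_out = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 2)

  # dominant-weight pair: its ratio is returned
  dom <- tibble::tibble(beta_exp = c(0.1, 0.4, 0.1), se_exp = 0.01,
                        beta_out = c(0.1 * 1, 0.4 * 2, 0.1 * 3), se_out = 0.1)
  expect_equal(mr_weighted_median(dom, n_boot = 50, seed = 1)$beta, 2)

  p <- fixture_pairs(7, seed = 7)
  got <- mr_weighted_median(p, n_boot = 50, seed = 1)$beta
  orc <- oracle_weighted_median(p$beta_out / p$beta_exp,
                                p$beta_exp^2 / p$se_out^2)
  expect_equal(got, orc, tolerance = 1e-10)

  a <- mr_weighted_median(p, n_boot = 200, seed = 42)
  b <- mr_weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(p[1:2, ]), "at least 3")
})

test_that("all estimators agree on an exact line through the origin", {
  exact <- fixture_pairs(9, slope = -0.3, noise = 0, seed = 8)
  expect_equal(mr_ivw(exact)$beta, -0.3)
  expect_equal(mr_egger(exact)$slope$beta, -0.3, tolerance = 1e-12)
  expect_equal(mr_weighted_median(exact, n_boot = 50, seed = 1)$beta, -0.3,
               tolerance = 1e-12)
})

test_that("odds-ratio forms are exact exp-transforms of the estimate", {
  p <- fixture_pairs(6, seed = 9)
  for (est in list(mr_ivw(p), mr_weighted_median(p, n_boot = 50, seed = 1))) {
    expect_identical(est$or_, exp(est$beta))
    expect_identical(est$ci_low, exp(est$beta - 1.96 * est$se))
    expect_identical(est$ci_high, exp(est$beta + 1.96 * est$se))
    expect_true(est$ci_low < est$or_ && est$or_ < est$ci_high)
  }
  eg <- mr_egger(p)$slope
  crit <- qt(0.975, eg$df)
  expect_identical(eg$ci_low, exp(eg$beta - crit * eg$se))
  expect_identical(eg$ci_high, exp(eg$beta + crit * eg$se))
})

test_that("mr_all returns one tidy row per applicable method", {
  p <- fixture_pairs(6, seed = 10)
  tb <- mr_all(p, n_boot = 50, seed = 1)
  expect_setequal(tb$method, c("ivw", "egger_slope", "egger_intercept",
                               "weighted_median"))
  one <- mr_all(p[1, ])
  expect_setequal(one$method, c("wald", "ivw"))
})
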