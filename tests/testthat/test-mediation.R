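test_that("effect decomposition reproduces the published arithmetic", {
  # total -0.507 with indirect -0.054 (= 0.2 * -0.27)
  d1 <- mediate_decompose(-0.507, beta1 = 0.2, beta2 = -0.27)
  expect_equal(d1$indirect, -0.054)
  expect_equal(d1$direct, -0.453)
  expect_equal(d1$proportion_pct, 10.65)
  expect_true(d1$congruent)

  # total 0.249 with indirect 0.029 (= 0.1 * 0.29)
  d2 <- mediate_decompose(0.249, beta1 = 0.1, beta2 = 0.29)
  expect_equal(d2$direct, 0.220)

  d0 <- mediate_decompose(0.5, beta1 = 0.3, beta2 = 0)
  expect_equal(d0$indirect, 0)
  expect_equal(d0$direct, 0.5)
  expect_equal(d0$proportion, 0)

  expect_error(mediate_decompose(0, 0.1, 0.1), "nonzero")
})

test_that("decomposition identities hold to full precision", {
  withr::with_seed(23, {
    for (i in 1:50) {
      bt <- rnorm(1); b1 <- rnorm(1); b2 <- rnorm(1)
      if (bt == 0) next
      d <- mediate_decompose(bt, b1, b2)
      expect_identical(d$direct, bt - d$indirect)
      expect_identical(d$indirect, b1 * b2)
      expect_equal(d$direct + d$indirect, bt, tolerance = 1e-12)
      expect_equal(d$proportion * bt, d$indirect, tolerance = 1e-12)
      # pathological proportions are reported, never clamped
      if (sign(d$indirect) != sign(bt)) expect_false(d$congruent)
    }
  })
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(29, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q > 0 & q <= 1))
      # monotone non-decreasing in sorted-p order
      expect_true(!is.unsorted(q[order(p)]))
    }
  })
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("the smallest-p congruent mediator wins the screen", {
  # negative total effect; one positive (incongruent) and one negative mediator
  step1 <- tibble::tibble(mediator_id = c("dimethyl_sulfone", "hpr"),
                          beta = c(0.2, 0.2), pvalue = c(0.01, 0.01))
  step2 <- tibble::tibble(mediator_id = c("dimethyl_sulfone", "hpr"),
                          beta = c(log(1.30), log(0.76)),
                          se = c(0.12, 0.09), pvalue = c(0.029, 0.002))
  dec <- screen_mediators(step1, step2, beta_total = -0.507)
  expect_equal(dec$mediator_id[dec$selected], "hpr")
  expect_equal(dec$reason[dec$mediator_id == "hpr"], "best_p_congruent")
  expect_equal(dec$reason[dec$mediator_id == "dimethyl_sulfone"],
               "dropped_incongruent")
})

test_that("non-significant, unstable and uncontested cases are handled", {
  step1 <- tibble::tibble(mediator_id = c("m1", "m2"), beta = c(0.2, 0.2),
                          pvalue = c(0.01, 0.01))
  none <- tibble::tibble(mediator_id = c("m1", "m2"), beta = c(0.1, 0.1),
                         se = c(0.1, 0.1), pvalue = c(0.2, 0.4))
  dec <- screen_mediators(step1, none, beta_total = 0.4)
  expect_true(all(dec$reason == "dropped_nonsig"))
  expect_false(any(dec$selected))

  # m2's OR confidence bound rounds onto 1.00 -> unstable
  mixed <- tibble::tibble(mediator_id = c("m1", "m2"),
                          beta = c(-0.3, log(0.72)),
                          se = c(0.1, (log(1.0049) - log(0.72)) / 1.96),
                          pvalue = c(0.03, 0.049))
  dec2 <- screen_mediators(step1, mixed, beta_total = -0.4)
  expect_equal(dec2$reason[dec2$mediator_id == "m2"], "dropped_unstable_ci")
  expect_equal(dec2$mediator_id[dec2$selected], "m1")

  # a single congruent passer is selected regardless of p magnitude
  solo <- screen_mediators(step1[1, ], mixed[1, ] |>
                             dplyr::mutate(pvalue = 0.049),
                           beta_total = -0.4)
  expect_true(solo$selected)
  # selection invariant: selected implies both steps significant and congruent
  all_dec <- dplyr::bind_rows(dec, dec2, solo)
  sel <- all_dec[all_dec$selected, ]
  expect_true(all(sel$step1_p < 0.05 & sel$step2_p < 0.05 & sel$congruent))
})

test_that("an empty mediator panel yields an empty decision table", {
  empty <- screen_mediators(tibble::tibble(mediator_id = character(),
                                           beta = numeric(), pvalue = numeric()),
                            tibble::tibble(mediator_id = character(),
                                           beta = numeric(), se = numeric(),
                                           pvalue = numeric()),
                            beta_total = 0.3)
  expect_equal(nrow(empty), 0)
})
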