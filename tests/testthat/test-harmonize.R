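mk_rec <- function(snp, ea, oa, beta, trait, eaf = 0.3) {
  tibble::tibble(snp_id = snp, chrom = "1", pos = 100L, effect_allele = ea,
                 other_allele = oa, beta = beta, se = 0.05, pvalue = 0.001,
                 eaf = eaf, n = 10000L, trait_id = trait)
}

test_that("matching, swapped and palindromic alleles act as specified", {
  ex <- mk_rec("rs1", "A", "G", 0.2, "x")
  same <- harmonize(ex, mk_rec("rs1", "A", "G", 0.3, "y"))
  expect_equal(same$action, "kept_as_is")
  expect_equal(c(same$beta_exp, same$beta_out), c(0.2, 0.3))

  sw <- harmonize(ex, mk_rec("rs1", "G", "A", 0.3, "y", eaf = 0.3))
  expect_equal(sw$action, "flipped")
  expect_equal(sw$beta_out, -0.3)
  expect_equal(sw$eaf_out, 0.7)

  pal <- harmonize(mk_rec("rs1", "A", "T", 0.2, "x"),
                   mk_rec("rs1", "A", "T", 0.3, "y"))
  expect_equal(pal$action, "dropped_palindromic")

  strand <- harmonize(ex, mk_rec("rs1", "T", "C", 0.3, "y"))
  expect_equal(strand$action, "kept_as_is")
  expect_equal(strand$beta_out, 0.3)
})

test_that("every allele combination matches the hand-built truth table", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ea = bases, oa = bases, ea2 = bases, oa2 = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ea != combos$oa & combos$ea2 != combos$oa2, ]
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    got <- harmonize(mk_rec("rs1", cb$ea, cb$oa, 0.2, "x"),
                     mk_rec("rs1", cb$ea2, cb$oa2, 0.3, "y"))
    want <- oracle_harmonize_action(cb$ea, cb$oa, cb$ea2, cb$oa2)
    expect_equal(got$action, want,
                 label = paste(cb$ea, cb$oa, "vs", cb$ea2, cb$oa2))
    if (want == "flipped") expect_equal(got$beta_out, -0.3)
    if (want == "kept_as_is") expect_equal(got$beta_out, 0.3)
  }
})

test_that("the action tally covers the snp union and missing sides are counted", {
  ex <- dplyr::bind_rows(mk_rec("rs1", "A", "G", 0.2, "x"),
                         mk_rec("rs2", "C", "T", 0.1, "x"))
  out <- dplyr::bind_rows(mk_rec("rs2", "C", "T", 0.4, "y"),
                          mk_rec("rs3", "A", "C", 0.5, "y"))
  h <- harmonize(ex, out)
  tally <- harmonization_actions(h)
  expect_equal(sum(tally), 3)  # union of rs1, rs2, rs3
  expect_equal(tally[["dropped_missing"]], 2)
  expect_equal(tally[["kept_as_is"]], 1)
})

test_that("duplicate variant ids on one side are an error", {
  dup <- dplyr::bind_rows(mk_rec("rs1", "A", "G", 0.2, "x"),
                          mk_rec("rs1", "A", "G", 0.3, "x"))
  expect_error(harmonize(dup, mk_rec("rs1", "A", "G", 0.1, "y")), "duplicate")
})

test_that("harmonization is idempotent on kept pairs", {
  sim <- simulate_triple(sim_config(n_snps = 40, n_med_snps = 0,
                                    frac_palindromic = 0.2,
                                    frac_strand_flipped = 0.3, seed = 17))
  h1 <- harmonize(sim$exposure, sim$outcome)
  kept <- h1[h1$action %in% c("kept_as_is", "flipped"), ]
  # rebuild both sides on the harmonized orientation and run again
  as_records <- function(k, beta, se, p, eaf, trait) {
    tibble::tibble(snp_id = k$snp_id, chrom = "1", pos = 1L,
                   effect_allele = k$effect_allele, other_allele = k$other_allele,
                   beta = beta, se = se, pvalue = p, eaf = eaf, n = 1000L,
                   trait_id = trait)
  }
  h2 <- harmonize(as_records(kept, kept$beta_exp, kept$se_exp, kept$pvalue_exp,
                             kept$eaf_exp, "x"),
                  as_records(kept, kept$beta_out, kept$se_out, kept$pvalue_out,
                             kept$eaf_out, "y"))
  expect_true(all(h2$action == "kept_as_is"))
  expect_equal(h2$beta_out, kept$beta_out)
  expect_equal(h2$beta_exp, kept$beta_exp)
})

test_that("strand-flipped synthetic records are always recovered", {
  sim <- simulate_triple(sim_config(n_snps = 60, n_med_snps = 0,
                                    frac_palindromic = 0,
                                    frac_strand_flipped = 0.4, seed = 19))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(h$action %in% c("kept_as_is", "flipped")))
  flipped_ids <- sim$truth$strand_flipped_ids
  rec <- h[h$snp_id %in% flipped_ids, ]
  # strand complementing alone must not change the harmonized effect
  expect_equal(rec$beta_out,
               sim$outcome$beta[match(rec$snp_id, sim$outcome$snp_id)])
})
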