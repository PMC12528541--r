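# Programmatic fixtures shared across test files.

# A small harmonized-pairs tibble around a common causal slope.
fixture_pairs <- function(j = 8, slope = 0.4, noise = 0.02, seed = 11) {
  withr::with_seed(seed, {
    bx <- runif(j, 0.05, 0.3) * sample(c(-1, 1), j, replace = TRUE)
    seo <- runif(j, 0.01, 0.05)
    sex <- runif(j, 0.005, 0.02)
    by <- slope * bx + rnorm(j, 0, noise)
    tibble::tibble(snp_id = sprintf("rs%03d", seq_len(j)),
                   beta_exp = bx, se_exp = sex, beta_out = by, se_out = seo)
  })
}

# Random valid canonical summary-stat records for round-trip properties.
random_records <- function(n = 20, seed = 5, trait = "traitA") {
  withr::with_seed(seed, {
    pairs <- c("AC", "AG", "CT", "GT", "CA", "GA", "TC", "TG")
    pick <- sample(pairs, n, replace = TRUE)
    eaf <- runif(n, 0.01, 0.99)
    eaf[sample.int(n, max(1, n %/% 5))] <- NA
    tibble::tibble(
      snp_id = sprintf("rs%05d", sample.int(99999, n)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      effect_allele = substr(pick, 1, 1),
      other_allele = substr(pick, 2, 2),
      beta = rnorm(n, 0, 0.2),
      se = runif(n, 0.001, 0.1),
      pvalue = runif(n, 1e-12, 1),
      eaf = eaf,
      n = sample(1000:500000, n),
      trait_id = trait
    )
  })
}

# A three-taxon exposure panel plus combined outcome table: one taxon with a
# planted effect, two null. SNP ids are disambiguated per taxon so the
# combined outcome table stays uniquely keyed.
fixture_three_taxa <- function(seed = 21, theta = -0.5) {
  thetas <- c(taxonA = theta, taxonB = 0, taxonC = 0)
  sims <- lapply(seq_along(thetas), function(i) {
    sim <- simulate_triple(sim_config(
      n_snps = 25, n_med_snps = 0, theta_total = thetas[[i]],
      theta1 = 0, theta2 = 0, frac_palindromic = 0, frac_strand_flipped = 0,
      seed = seed + i))
    tag <- function(tb, trait) {
      tb$snp_id <- paste0(names(thetas)[i], "_", tb$snp_id)
      if (!is.null(trait)) tb$trait_id <- trait
      tb
    }
    list(exposure = tag(sim$exposure, names(thetas)[i]),
         outcome = tag(sim$outcome, "outcome"))
  })
  list(
    exposures = dplyr::bind_rows(lapply(sims, `[[`, "exposure")),
    outcome = dplyr::bind_rows(lapply(sims, `[[`, "outcome"))
  )
}
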