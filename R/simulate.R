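#' Configuration for the synthetic summary-statistics generator
#'
#' Describes one simulated exposure -> mediator -> outcome study. The
#' planted causal diagram follows the classical two-step mediation layout:
#' the exposure's total effect on the (binary) outcome is `theta_total`, of
#' which `theta1 * theta2` flows through the mediator (`theta1` exposure ->
#' mediator, `theta2` mediator -> outcome) and the rest is direct.
#'
#' Two blocks of independent variants are generated. The first (`n_snps`
#' variants) carries true exposure effects `gamma_j ~ N(0, gamma_sd^2)`;
#' these variants reach the mediator only through the exposure
#' (`theta1 * gamma_j`) and the outcome with total effect
#' `theta_total * gamma_j` plus, for a planted fraction, a horizontal
#' pleiotropy offset `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`. The
#' second block (`n_med_snps` variants) instruments the mediator directly
#' (`delta_j ~ N(0, delta_sd^2)`) and reaches the outcome only through it
#' (`theta2 * delta_j`), which is what makes the mediator -> outcome leg of
#' a two-step analysis identifiable from the generated tables.
#'
#' Default sample sizes mirror a microbiome-metabolite-meningioma design:
#' 18,340 exposure samples, 8,299 mediator samples, and 1,316 cases versus
#' 313,392 controls for the outcome, with non-overlapping samples by
#' construction. Default planted effects are `theta_total = -0.507`,
#' `theta1 = 0.199`, `theta2 = -0.274` (log-odds), i.e. a proportion
#' mediated of about 10.75%.
#'
#' @param n_snps Number of exposure-instrument variants.
#' @param n_med_snps Number of mediator-instrument variants.
#' @param n_exposure,n_mediator Continuous-trait GWAS sample sizes.
#' @param n_cases,n_controls Outcome case-control counts; the outcome
#'   standard errors use the effective size `4 / (1/n_cases + 1/n_controls)`.
#' @param theta_total,theta1,theta2 Planted total, exposure -> mediator and
#'   mediator -> outcome effects (additive / log-odds scale).
#' @param maf_range Interval within (0, 0.5] for minor-allele frequencies.
#' @param gamma_sd,delta_sd Spread of true per-variant effects on the
#'   exposure and (directly) on the mediator.
#' @param frac_pleiotropic Fraction of exposure-block variants given a
#'   horizontal-pleiotropy offset on the outcome.
#' @param pleiotropy_mean,pleiotropy_sd Offset distribution; a nonzero mean
#'   plants directional pleiotropy (an MR-Egger intercept signal).
#' @param frac_palindromic Fraction of variants given complementary (A/T or
#'   C/G) allele pairs.
#' @param frac_strand_flipped Fraction of outcome records written with
#'   strand-complemented alleles and unchanged beta; harmonization must
#'   recover them.
#' @param seed Integer seed; the whole triple is reproducible from it.
#' @return A list of class `sim_config`.
#' @seealso [simulate_triple()]
#' @export
sim_config <- function(n_snps = 30,
                       n_med_snps = 30,
                       n_exposure = 18340,
                       n_mediator = 8299,
                       n_cases = 1316,
                       n_controls = 313392,
                       theta_total = -0.507,
                       theta1 = 0.199,
                       theta2 = -0.274,
                       maf_range = c(0.1, 0.5),
                       gamma_sd = 0.1,
                       delta_sd = 0.12,
                       frac_pleiotropic = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       frac_palindromic = 0.15,
                       frac_strand_flipped = 0.02,
                       seed = 1L) {
  stopifnot(length(maf_range) == 2, !is.na(maf_range))
  if (n_snps < 1) abort("`n_snps` must be a positive integer")
  if (n_med_snps < 0) abort("`n_med_snps` must be a non-negative integer")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  for (f in c("frac_pleiotropic", "frac_palindromic", "frac_strand_flipped")) {
    v <- get(f)
    if (v < 0 || v >= 1) abort(paste0("`", f, "` must lie in [0, 1)"))
  }
  if (pleiotropy_sd < 0 || gamma_sd <= 0) abort("effect spreads must be positive")
  structure(
    list(n_snps = as.integer(n_snps), n_med_snps = as.integer(n_med_snps),
         n_exposure = as.integer(n_exposure), n_mediator = as.integer(n_mediator),
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         theta_total = theta_total, theta1 = theta1, theta2 = theta2,
         maf_range = maf_range, gamma_sd = gamma_sd, delta_sd = delta_sd,
         frac_pleiotropic = frac_pleiotropic, pleiotropy_mean = pleiotropy_mean,
         pleiotropy_sd = pleiotropy_sd, frac_palindromic = frac_palindromic,
         frac_strand_flipped = frac_strand_flipped, seed = as.integer(seed)),
    class = "sim_config"
  )
}

complement_base <- c(A = "T", T = "A", C = "G", G = "C")

#' Simulate an exposure / mediator / outcome summary-statistics triple
#'
#' Generates three GWAS summary-statistic tables with the planted causal
#' structure described in [sim_config()], plus the ground truth needed by
#' recovery tests. Variants are in linkage equilibrium; standard errors are
#' the exact closed forms `1 / sqrt(2 * maf * (1 - maf) * n)` (with the
#' case-control effective size for the outcome), and observed effects are
#' the true effects plus `N(0, se^2)` estimation noise. Two-sided normal
#' p-values. A configured share of variants is palindromic, and a share of
#' outcome records is emitted on the opposite strand (complemented alleles,
#' unchanged beta) to exercise harmonization.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_triple` with elements `exposure`, `mediator`,
#'   `outcome` (canonical summary-statistic tibbles accepted by every
#'   downstream function) and `truth`, a list holding the per-variant true
#'   effects (`gamma`, `delta`, `alpha`), the planted `theta_total`,
#'   `theta1`, `theta2`, and the planted outlier and palindromic variant ids.
#' @examples
#' sim <- simulate_triple(sim_config(n_snps = 10, n_med_snps = 0, seed = 7))
#' head(sim$exposure)
#' sim$truth$theta_total
#' @export
simulate_triple <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  m <- config$n_snps + config$n_med_snps
  withr::with_seed(config$seed, {
    snp_id <- sprintf("rs%06d", seq_len(m))
    chrom <- as.character(rep_len(1:22, m))
    pos <- as.integer(20e6 * (seq_len(m) %/% 22 + 1) + seq_len(m))
    maf <- runif(m, config$maf_range[1], config$maf_range[2])

    is_exp_block <- seq_len(m) <= config$n_snps
    gamma <- ifelse(is_exp_block, rnorm(m, 0, config$gamma_sd), 0)
    delta <- ifelse(is_exp_block, 0, rnorm(m, 0, config$delta_sd))

    n_outliers <- round(config$frac_pleiotropic * config$n_snps)
    outlier_ids <- sample(snp_id[is_exp_block], n_outliers)
    alpha <- numeric(m)
    if (n_outliers > 0) {
      alpha[match(outlier_ids, snp_id)] <-
        rnorm(n_outliers, config$pleiotropy_mean, config$pleiotropy_sd)
    }

    var_g <- 2 * maf * (1 - maf)
    n_eff <- 4 / (1 / config$n_cases + 1 / config$n_controls)
    se_x <- 1 / sqrt(var_g * config$n_exposure)
    se_m <- 1 / sqrt(var_g * config$n_mediator)
    se_y <- 1 / sqrt(var_g * n_eff)

    # pleiotropy offsets are expressed relative to the exposure-increasing
    # allele, so a nonzero mean is directional under the usual bx >= 0
    # orientation instead of cancelling across arbitrary allele codings
    alpha_oriented <- alpha * ifelse(gamma < 0, -1, 1)

    beta_x <- gamma + rnorm(m, 0, se_x)
    beta_m <- config$theta1 * gamma + delta + rnorm(m, 0, se_m)
    beta_y <- config$theta_total * gamma + config$theta2 * delta +
      alpha_oriented + rnorm(m, 0, se_y)

    # allele pairs: palindromic share gets complementary pairs
    n_pal <- round(config$frac_palindromic * m)
    pal_idx <- sort(sample.int(m, n_pal))
    ea <- character(m); oa <- character(m)
    pal_pair <- sample(c("AT", "CG"), m, replace = TRUE)
    ea[pal_idx] <- substr(pal_pair[pal_idx], 1, 1)
    oa[pal_idx] <- substr(pal_pair[pal_idx], 2, 2)
    rest <- setdiff(seq_len(m), pal_idx)
    nonpal <- c("AC", "AG", "CA", "CT", "GA", "GT", "TC", "TG")
    pair <- sample(nonpal, length(rest), replace = TRUE)
    ea[rest] <- substr(pair, 1, 1)
    oa[rest] <- substr(pair, 2, 2)
    swap <- runif(m) < 0.5
    tmp <- ea[pal_idx][swap[pal_idx]]
    ea[pal_idx][swap[pal_idx]] <- oa[pal_idx][swap[pal_idx]]
    oa[pal_idx][swap[pal_idx]] <- tmp

    make_table <- function(beta, se, n, trait_id, ea, oa) {
      tibble::tibble(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa,
        beta = beta, se = se,
        pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
        eaf = maf, n = as.integer(n), trait_id = trait_id
      )
    }
    exposure <- make_table(beta_x, se_x, config$n_exposure, "exposure", ea, oa)
    mediator <- make_table(beta_m, se_m, config$n_mediator, "mediator", ea, oa)

    n_flip <- round(config$frac_strand_flipped * m)
    flip_idx <- sort(sample.int(m, n_flip))
    ea_out <- ea; oa_out <- oa
    ea_out[flip_idx] <- unname(complement_base[ea[flip_idx]])
    oa_out[flip_idx] <- unname(complement_base[oa[flip_idx]])
    outcome <- make_table(beta_y, se_y, config$n_cases + config$n_controls,
                          "outcome", ea_out, oa_out)

    truth <- list(
      gamma = setNames(gamma, snp_id), delta = setNames(delta, snp_id),
      alpha = setNames(alpha, snp_id),
      theta_total = config$theta_total, theta1 = config$theta1,
      theta2 = config$theta2,
      outlier_ids = sort(outlier_ids),
      palindromic_ids = snp_id[pal_idx],
      strand_flipped_ids = snp_id[flip_idx],
      proportion = config$theta1 * config$theta2 / config$theta_total
    )
    structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                   truth = truth, config = config),
              class = "sim_triple")
  })
}

#' @export
print.sim_triple <- function(x, ...) {
  cat(sprintf("<sim_triple> %d variants (%d exposure-block, %d mediator-block)\n",
              nrow(x$exposure), x$config$n_snps, x$config$n_med_snps))
  cat(sprintf("  planted: theta_total = %.3f, theta1 = %.3f, theta2 = %.3f (proportion %.3f)\n",
              x$truth$theta_total, x$truth$theta1, x$truth$theta2, x$truth$proportion))
  cat(sprintf("  %d palindromic, %d strand-flipped, %d pleiotropic outliers\n",
              length(x$truth$palindromic_ids), length(x$truth$strand_flipped_ids),
              length(x$truth$outlier_ids)))
  invisible(x)
}
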