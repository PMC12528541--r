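#' Product-of-coefficients effect decomposition
#'
#' Splits a total exposure -> outcome effect into the part flowing through
#' a mediator and the rest: indirect effect `beta1 * beta2` (exposure ->
#' mediator times mediator -> outcome), direct effect
#' `beta_total - beta1 * beta2`, and proportion mediated
#' `beta1 * beta2 / beta_total`. The identities
#' `direct + indirect == beta_total` and
#' `proportion * beta_total == indirect` hold to full precision. The
#' proportion is reported as-is even when it exceeds 1 in magnitude or the
#' indirect and total effects disagree in sign (then `congruent` is
#' `FALSE`); pathological decompositions are surfaced, never clamped.
#'
#' @param beta_total Total effect (log-odds scale); must be nonzero.
#' @param beta1 Exposure -> mediator effect.
#' @param beta2 Mediator -> outcome effect.
#' @param exposure_id,mediator_id,outcome_id Optional labels.
#' @return One-row tibble: ids, `beta_total`, `beta1`, `beta2`, `indirect`,
#'   `direct`, `proportion` (fraction), `proportion_pct` (percent, rounded
#'   to two decimals, the form used in reports) and `congruent`.
#' @examples
#' mediate_decompose(-0.507, beta1 = 0.199, beta2 = -0.274)
#' @export
mediate_decompose <- function(beta_total, beta1, beta2,
                              exposure_id = NA_character_,
                              mediator_id = NA_character_,
                              outcome_id = NA_character_) {
  if (any(beta_total == 0)) abort("`beta_total` must be nonzero (proportion undefined)")
  indirect <- beta1 * beta2
  tibble::tibble(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    beta_total = beta_total, beta1 = beta1, beta2 = beta2,
    indirect = indirect, direct = beta_total - indirect,
    proportion = indirect / beta_total,
    proportion_pct = round(100 * indirect / beta_total, 2),
    congruent = sign(indirect) == sign(beta_total)
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: in sorted order
#' `q_(i) = min_{j >= i} m p_(j) / j`, mapped back to input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in (0, 1], same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-step mediator screening
#'
#' Applies the screening rule of a two-step mediation design: a mediator
#' passes step 1 if the exposure -> mediator estimate is significant at
#' `alpha`, passes step 2 if the mediator -> outcome estimate is
#' significant at `alpha`; among passers, those whose implied indirect
#' effect (`beta1 * beta2`) disagrees in sign with the total effect are
#' dropped as incongruent, those whose step-2 odds-ratio confidence bound
#' rounds onto 1.00 are dropped as unstable, and exactly one mediator — the
#' congruent stable passer with the smallest step-2 p-value — is selected.
#'
#' @param step1 Tibble of exposure -> mediator estimates with columns
#'   `mediator_id`, `beta`, `pvalue`.
#' @param step2 Tibble of mediator -> outcome estimates with columns
#'   `mediator_id`, `beta`, `se`, `pvalue`.
#' @param beta_total Total exposure -> outcome effect (or an `mr_estimate`).
#' @param alpha Significance level for both steps (default 0.05).
#' @param or_ci_tol Instability margin: a step-2 OR confidence bound within
#'   this distance of 1.0 after rounding to two decimals marks the
#'   mediator unstable (default 0.005, i.e. a bound printing as 1.00).
#' @return Tibble of screening decisions: `mediator_id`, `step1_p`,
#'   `step2_p`, `beta1`, `beta2`, `indirect`, `congruent`, `selected`,
#'   `reason` (one of `best_p_congruent`, `not_best_p`,
#'   `dropped_incongruent`, `dropped_unstable_ci`, `dropped_nonsig`).
#' @export
screen_mediators <- function(step1, step2, beta_total, alpha = 0.05,
                             or_ci_tol = 0.005) {
  if (inherits(beta_total, "mr_estimate")) beta_total <- beta_total$beta
  if (nrow(step1) == 0) {
    return(tibble::tibble(mediator_id = character(), step1_p = numeric(),
                          step2_p = numeric(), beta1 = numeric(),
                          beta2 = numeric(), indirect = numeric(),
                          congruent = logical(), selected = logical(),
                          reason = character()))
  }
  d <- step1 |>
    dplyr::select("mediator_id", beta1 = "beta", step1_p = "pvalue") |>
    dplyr::left_join(step2 |>
                       dplyr::select("mediator_id", beta2 = "beta",
                                     se2 = "se", step2_p = "pvalue"),
                     by = "mediator_id") |>
    dplyr::mutate(
      indirect = .data$beta1 * .data$beta2,
      congruent = sign(.data$indirect) == sign(beta_total),
      passes = !is.na(.data$step1_p) & .data$step1_p < alpha &
        !is.na(.data$step2_p) & .data$step2_p < alpha,
      unstable = .data$passes &
        (abs(round(exp(.data$beta2 - 1.96 * .data$se2), 2) - 1) < or_ci_tol |
           abs(round(exp(.data$beta2 + 1.96 * .data$se2), 2) - 1) < or_ci_tol),
      reason = dplyr::case_when(
        !passes ~ "dropped_nonsig",
        !congruent ~ "dropped_incongruent",
        unstable ~ "dropped_unstable_ci",
        .default = "candidate"
      )
    )
  cand <- which(d$reason == "candidate")
  selected_idx <- if (length(cand) > 0) {
    cand[order(d$step2_p[cand], d$mediator_id[cand])][1]
  } else integer(0)
  d$selected <- seq_len(nrow(d)) %in% selected_idx
  d$reason[d$reason == "candidate"] <- "not_best_p"
  d$reason[d$selected] <- "best_p_congruent"
  d |>
    dplyr::select("mediator_id", "step1_p", "step2_p", "beta1", "beta2",
                  "indirect", "congruent", "selected", "reason")
}
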