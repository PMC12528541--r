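#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' Joins the two record sets on `snp_id` and expresses the outcome effect
#' on the exposure's effect allele. The exposure orientation is canonical:
#' only outcome-side quantities are ever flipped. Per variant the action is
#' one of
#'
#' * `dropped_missing` — present on only one side;
#' * `dropped_palindromic` — the exposure alleles are complementary (A/T or
#'   C/G); such variants are excluded unconditionally, with no
#'   frequency-based rescue, because strand orientation is unresolvable;
#' * `kept_as_is` — outcome alleles match the exposure pair, directly or
#'   after complementing both (opposite-strand report);
#' * `flipped` — outcome alleles are the exposure pair swapped (directly or
#'   after complementing); the outcome beta is negated and its allele
#'   frequency replaced by 1 - eaf;
#' * `dropped_incompatible` — any other allele combination.
#'
#' @param exposure,outcome Canonical summary-statistic tibbles keyed by
#'   `snp_id` (duplicate ids within one side are an error).
#' @return A tibble with one row per variant in the union of the two snp-id
#'   sets: `snp_id`, exposure-orientation alleles, `beta_exp`, `se_exp`,
#'   `pvalue_exp`, `eaf_exp`, harmonized `beta_out`, `se_out`, `pvalue_out`,
#'   `eaf_out`, and `action`. The per-action tally is attached as attribute
#'   `action_tally` (it always sums to the union size). Estimators accept
#'   this tibble directly and use only the kept rows.
#' @seealso [harmonization_actions()]
#' @export
harmonize <- function(exposure, outcome) {
  if (anyDuplicated(exposure$snp_id)) abort("duplicate snp_id on exposure side")
  if (anyDuplicated(outcome$snp_id)) abort("duplicate snp_id on outcome side")
  exp_side <- exposure |>
    dplyr::select("snp_id",
                  ea_exp = "effect_allele", oa_exp = "other_allele",
                  beta_exp = "beta", se_exp = "se", pvalue_exp = "pvalue",
                  eaf_exp = "eaf")
  out_side <- outcome |>
    dplyr::select("snp_id",
                  ea_out = "effect_allele", oa_out = "other_allele",
                  beta_out = "beta", se_out = "se", pvalue_out = "pvalue",
                  eaf_out = "eaf")
  j <- dplyr::full_join(exp_side, out_side, by = "snp_id")

  comp <- function(x) unname(complement_base[x])
  missing_side <- is.na(j$ea_exp) | is.na(j$ea_out)
  palindromic <- !missing_side & j$oa_exp == comp(j$ea_exp)
  same <- j$ea_out == j$ea_exp & j$oa_out == j$oa_exp
  swapped <- j$ea_out == j$oa_exp & j$oa_out == j$ea_exp
  comp_same <- comp(j$ea_out) == j$ea_exp & comp(j$oa_out) == j$oa_exp
  comp_swapped <- comp(j$ea_out) == j$oa_exp & comp(j$oa_out) == j$ea_exp

  action <- dplyr::case_when(
    missing_side ~ "dropped_missing",
    palindromic ~ "dropped_palindromic",
    same | comp_same ~ "kept_as_is",
    swapped | comp_swapped ~ "flipped",
    .default = "dropped_incompatible"
  )

  flip <- action == "flipped"
  out <- tibble::tibble(
    snp_id = j$snp_id,
    effect_allele = j$ea_exp, other_allele = j$oa_exp,
    beta_exp = j$beta_exp, se_exp = j$se_exp,
    pvalue_exp = j$pvalue_exp, eaf_exp = j$eaf_exp,
    beta_out = ifelse(flip, -j$beta_out, j$beta_out),
    se_out = j$se_out, pvalue_out = j$pvalue_out,
    eaf_out = ifelse(flip, 1 - j$eaf_out, j$eaf_out),
    action = action
  )
  lv <- c("kept_as_is", "flipped", "dropped_palindromic",
          "dropped_incompatible", "dropped_missing")
  tally <- table(factor(action, levels = lv))
  attr(out, "action_tally") <- setNames(as.integer(tally), lv)
  out
}

#' Harmonization action tally
#'
#' @param x A tibble returned by [harmonize()].
#' @return Named integer vector of per-action counts.
#' @export
harmonization_actions <- function(x) {
  attr(x, "action_tally") %||% table(factor(x$action))
}

# Keep only analyzable pairs; accepts either a raw harmonize() result or a
# tibble already restricted to kept rows.
kept_pairs <- function(pairs) {
  if ("action" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, .data$action %in% c("kept_as_is", "flipped"))
  }
  pairs
}
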