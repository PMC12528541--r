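#' Pipeline configuration
#'
#' Thresholds and seeds governing a full bidirectional MR plus mediation
#' run. Defaults follow common two-sample MR practice for microbiome-scale
#' exposures: relaxed instrument threshold 1e-5 (strict genome-wide 5e-8
#' is kept for reference), reverse-direction threshold 5e-5, clumping to
#' r-squared < 0.001 within 10 Mb, F-statistic gate at 10, and 0.05
#' significance throughout.
#'
#' @param p_forward Instrument p-value threshold for forward and mediator
#'   scans.
#' @param p_strict Genome-wide threshold, kept in the report for reference.
#' @param p_reverse Instrument threshold when the outcome is the exposure.
#' @param alpha Significance level for screening and the suggestive tier.
#' @param r2_max,window_bp Clumping parameters.
#' @param f_min Minimum instrument-set F-statistic.
#' @param min_reverse_snps Reverse scans warn below this instrument count;
#'   thresholds are never auto-relaxed.
#' @param n_boot Weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param seed Base seed for every stochastic component.
#' @param run_presso,run_loo Toggle the heavier sensitivity diagnostics.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_forward = 1e-5, p_strict = 5e-8, p_reverse = 5e-5,
                      alpha = 0.05, r2_max = 0.001, window_bp = 1e7,
                      f_min = 10, min_reverse_snps = 20,
                      n_boot = 1000, n_sim = 1000, seed = 42,
                      run_presso = TRUE, run_loo = TRUE) {
  for (p in c(p_forward, p_strict, p_reverse, alpha)) {
    if (p <= 0 || p >= 1) abort("thresholds must lie in (0, 1)")
  }
  if (f_min <= 0) abort("`f_min` must be positive")
  structure(list(p_forward = p_forward, p_strict = p_strict,
                 p_reverse = p_reverse, alpha = alpha, r2_max = r2_max,
                 window_bp = window_bp, f_min = f_min,
                 min_reverse_snps = min_reverse_snps, n_boot = n_boot,
                 n_sim = n_sim, seed = as.integer(seed),
                 run_presso = run_presso, run_loo = run_loo),
            class = "mr_config")
}

# One exposure-vs-outcome analysis: select, clump, strength-filter,
# harmonize, estimate, diagnose. Returns NULL-estimates with a skip reason
# when no usable instrument survives.
scan_one <- function(exposure, outcome, p_threshold, config, ld = NULL,
                     sensitivity = TRUE) {
  iv <- select_instruments(exposure, p_threshold = p_threshold, ld = ld,
                           r2_max = config$r2_max,
                           window_bp = config$window_bp, f_min = config$f_min)
  if (iv$k == 0) {
    return(list(skip = "no_instruments", instruments = iv))
  }
  if (iv$weak) {
    return(list(skip = "weak_instruments", instruments = iv))
  }
  harm <- harmonize(iv$snps, outcome)
  pairs <- kept_pairs(harm)
  if (nrow(pairs) == 0) {
    return(list(skip = "no_harmonized_pairs", instruments = iv,
                harmonization = harmonization_actions(harm)))
  }
  est <- mr_all(pairs, n_boot = config$n_boot, seed = config$seed)
  sens <- if (sensitivity) {
    sensitivity_report(pairs, n_sim = config$n_sim, seed = config$seed,
                       run_presso = config$run_presso)
  } else NULL
  list(skip = NULL, instruments = iv, harmonization = harmonization_actions(harm),
       pairs = pairs, estimates = est, sensitivity = sens)
}

scan_many <- function(exposures, outcome, p_threshold, config, ld,
                      direction, sensitivity = TRUE) {
  stopifnot(is.data.frame(exposures), "trait_id" %in% names(exposures))
  traits <- unique(exposures$trait_id)
  fits <- purrr::map(traits, function(tr) {
    scan_one(dplyr::filter(exposures, .data$trait_id == tr), outcome,
             p_threshold, config, ld = ld, sensitivity = sensitivity)
  })
  names(fits) <- traits
  skipped <- purrr::imap_dfr(fits, function(f, tr) {
    if (is.null(f$skip)) NULL else tibble::tibble(trait_id = tr, reason = f$skip)
  })
  estimates <- purrr::imap_dfr(fits, function(f, tr) {
    if (is.null(f$skip)) dplyr::bind_cols(tibble::tibble(trait_id = tr),
                                          f$estimates) else NULL
  })
  if (nrow(estimates) > 0) {
    ivw <- estimates |> dplyr::filter(.data$method == "ivw")
    qv <- tibble::tibble(trait_id = ivw$trait_id, qvalue = bh_fdr(ivw$pvalue))
    estimates <- dplyr::left_join(estimates, qv, by = "trait_id")
  }
  structure(list(estimates = estimates, fits = fits, skipped = skipped,
                 direction = direction, config = config),
            class = "mr_scan")
}

#' Forward MR scan over exposures
#'
#' For every exposure trait: instrument selection at `p_forward`, clumping,
#' F-statistic gate, harmonization against the outcome, all applicable
#' estimators, and the sensitivity panel; IVW p-values across the exposure
#' family receive Benjamini-Hochberg q-values. Exposures with no surviving
#' instrument are recorded as skipped (reason `no_instruments`,
#' `weak_instruments` or `no_harmonized_pairs`), never fatal. Deterministic
#' given the config seed.
#'
#' @param exposures Long summary-statistics tibble covering one or more
#'   traits (distinguished by `trait_id`).
#' @param outcome Summary-statistics tibble for the outcome.
#' @param config An [mr_config()].
#' @param ld Optional [ld_table()].
#' @param sensitivity Logical; compute the sensitivity panel.
#' @return An object of class `mr_scan`: `estimates` (tidy rows per trait
#'   and method, with `qvalue` on every row of a trait), per-trait `fits`,
#'   and `skipped`. `tidy()` returns the estimate table; `glance()` one
#'   sensitivity row per trait.
#' @export
run_forward <- function(exposures, outcome, config = mr_config(), ld = NULL,
                        sensitivity = TRUE) {
  scan_many(exposures, outcome, config$p_forward, config, ld,
            direction = "forward", sensitivity = sensitivity)
}

#' Reverse MR scan (outcome as exposure)
#'
#' Treats the outcome trait as the exposure at the `p_reverse` instrument
#' threshold and analyzes each original exposure trait as an outcome, with
#' otherwise identical machinery. Emits a warning when fewer than
#' `min_reverse_snps` instruments survive; the threshold is never
#' auto-relaxed.
#'
#' @param outcome Summary statistics of the original outcome (now the
#'   exposure side).
#' @param exposures Long tibble of the original exposure traits (now
#'   outcomes).
#' @inheritParams run_forward
#' @return An `mr_scan` with `direction = "reverse"` and one estimate block
#'   per original exposure trait.
#' @export
run_reverse <- function(outcome, exposures, config = mr_config(), ld = NULL,
                        sensitivity = TRUE) {
  iv <- select_instruments(outcome, p_threshold = config$p_reverse, ld = ld,
                           r2_max = config$r2_max,
                           window_bp = config$window_bp, f_min = config$f_min)
  if (iv$k < config$min_reverse_snps) {
    warn(sprintf("reverse scan: only %d instrument(s) at p < %g (wanted >= %d); proceeding",
                 iv$k, config$p_reverse, config$min_reverse_snps))
  }
  traits <- unique(exposures$trait_id)
  fits <- purrr::map(traits, function(tr) {
    scan_one(outcome, dplyr::filter(exposures, .data$trait_id == tr),
             config$p_reverse, config, ld = ld, sensitivity = sensitivity)
  })
  names(fits) <- traits
  skipped <- purrr::imap_dfr(fits, function(f, tr) {
    if (is.null(f$skip)) NULL else tibble::tibble(trait_id = tr, reason = f$skip)
  })
  estimates <- purrr::imap_dfr(fits, function(f, tr) {
    if (is.null(f$skip)) dplyr::bind_cols(tibble::tibble(trait_id = tr),
                                          f$estimates) else NULL
  })
  structure(list(estimates = estimates, fits = fits, skipped = skipped,
                 direction = "reverse", config = config),
            class = "mr_scan")
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("<mr_scan> %s: %d trait(s) analyzed, %d skipped\n",
              x$direction, length(x$fits) - nrow(x$skipped), nrow(x$skipped)))
  if (nrow(x$estimates) > 0) print(x$estimates, n = 10)
  invisible(x)
}

#' @rdname tidy-mrmediate
#' @export
tidy.mr_scan <- function(x, ...) x$estimates

#' @rdname tidy-mrmediate
#' @export
glance.mr_scan <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, tr) {
    if (is.null(f$skip) && !is.null(f$sensitivity)) {
      dplyr::bind_cols(tibble::tibble(trait_id = tr), glance(f$sensitivity))
    } else NULL
  })
}

#' Two-step mediation over a mediator panel
#'
#' For each analyzed exposure of a forward scan (those with an IVW estimate
#' at uncorrected p < alpha — the suggestive tier, so this stage is flagged
#' exploratory): run exposure -> mediator MR for every mediator trait using
#' the exposure's instruments, mediator -> outcome MR using each mediator's
#' own instruments, screen with [screen_mediators()], and decompose the
#' forward (total) effect through the selected mediator with
#' [mediate_decompose()]. Exposures for which no mediator is selected are
#' reported without a decomposition.
#'
#' @param exposures,mediators,outcome Long summary-statistics tibbles.
#' @param forward The `mr_scan` from [run_forward()].
#' @inheritParams run_forward
#' @param exposure_ids Traits to mediate; defaults to the forward scan's
#'   suggestive IVW hits.
#' @return Object of class `mr_mediation`: `decisions` (screening rows per
#'   exposure x mediator), `results` (decomposition rows for selected
#'   mediators), `step2` (mediator -> outcome estimates), and
#'   `exploratory = TRUE`.
#' @export
run_mediation <- function(exposures, mediators, outcome, forward,
                          config = mr_config(), ld = NULL,
                          exposure_ids = NULL) {
  ivw <- forward$estimates |> dplyr::filter(.data$method == "ivw")
  if (is.null(exposure_ids)) {
    exposure_ids <- ivw$trait_id[ivw$pvalue < config$alpha]
  }
  med_traits <- unique(mediators$trait_id)

  # mediator -> outcome legs are shared across exposures; fit once
  step2 <- purrr::map_dfr(med_traits, function(m) {
    f <- scan_one(dplyr::filter(mediators, .data$trait_id == m), outcome,
                  config$p_forward, config, ld = ld, sensitivity = FALSE)
    if (is.null(f$skip)) {
      f$estimates |> dplyr::filter(.data$method == "ivw") |>
        dplyr::mutate(mediator_id = m, .before = 1)
    } else NULL
  })

  decisions <- list()
  results <- list()
  for (ex in exposure_ids) {
    exp_records <- dplyr::filter(exposures, .data$trait_id == ex)
    step1 <- purrr::map_dfr(med_traits, function(m) {
      f <- scan_one(exp_records, dplyr::filter(mediators, .data$trait_id == m),
                    config$p_forward, config, ld = ld, sensitivity = FALSE)
      if (is.null(f$skip)) {
        f$estimates |> dplyr::filter(.data$method == "ivw") |>
          dplyr::mutate(mediator_id = m, .before = 1)
      } else NULL
    })
    beta_total <- ivw$beta[ivw$trait_id == ex]
    if (nrow(step1) == 0 || nrow(step2) == 0 || length(beta_total) == 0) next
    dec <- screen_mediators(step1, step2, beta_total, alpha = config$alpha) |>
      dplyr::mutate(exposure_id = ex, .before = 1)
    decisions[[ex]] <- dec
    sel <- dec[dec$selected, ]
    if (nrow(sel) == 1) {
      results[[ex]] <- mediate_decompose(
        beta_total, sel$beta1, sel$beta2, exposure_id = ex,
        mediator_id = sel$mediator_id,
        outcome_id = outcome$trait_id[1]
      )
    }
  }
  structure(list(decisions = dplyr::bind_rows(decisions),
                 results = dplyr::bind_rows(results),
                 step2 = step2, exposure_ids = exposure_ids,
                 exploratory = TRUE, config = config),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("<mr_mediation> %d exposure(s) examined, %d decomposition(s)%s\n",
              length(x$exposure_ids), nrow(x$results),
              if (isTRUE(x$exploratory)) " [exploratory tier]" else ""))
  if (nrow(x$results) > 0) print(x$results)
  invisible(x)
}

#' @rdname tidy-mrmediate
#' @export
tidy.mr_mediation <- function(x, ...) x$results

#' Write an analysis report to delimited tables
#'
#' Writes the estimate table (and, when given, the sensitivity summary,
#' screening decisions and mediation table mirroring the usual
#' total/indirect/direct/proportion layout) as tab-separated files in
#' `dir`.
#'
#' @param forward An `mr_scan`.
#' @param dir Output directory (created if needed).
#' @param reverse,mediation Optional `mr_scan` / `mr_mediation` companions.
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(forward, dir, reverse = NULL, mediation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(forward), file.path(dir, "forward_estimates.tsv"))
  sens <- glance(forward)
  if (nrow(sens) > 0) readr::write_tsv(sens, file.path(dir, "forward_sensitivity.tsv"))
  if (nrow(forward$skipped) > 0) {
    readr::write_tsv(forward$skipped, file.path(dir, "forward_skipped.tsv"))
  }
  if (!is.null(reverse)) {
    readr::write_tsv(tidy(reverse), file.path(dir, "reverse_estimates.tsv"))
  }
  if (!is.null(mediation)) {
    readr::write_tsv(mediation$decisions, file.path(dir, "mediator_screen.tsv"))
    if (nrow(mediation$results) > 0) {
      mediation$results |>
        dplyr::select("exposure_id", "mediator_id", total = "beta_total",
                      indirect = "indirect", direct = "direct",
                      proportion_pct = "proportion_pct") |>
        readr::write_tsv(file.path(dir, "mediation_table.tsv"))
    }
  }
  invisible(dir)
}
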