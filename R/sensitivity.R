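#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-variant Wald ratios from
#' the fixed-effect IVW estimate, with ratio weights
#' `beta_exp^2 / se_out^2`; the p-value is chi-squared with J - 1 df.
#' Large Q flags instrument heterogeneity (possible pleiotropy).
#'
#' @inheritParams mr_estimators
#' @return Tibble with columns `q`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(pairs) {
  pairs <- check_pairs(pairs, 2, "Cochran's Q")
  bx <- pairs$beta_exp; by <- pairs$beta_out; seo <- pairs$se_out
  w <- bx^2 / seo^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  q_df <- length(bx) - 1L
  tibble::tibble(q = q, q_df = q_df,
                 q_pvalue = pchisq(q, q_df, lower.tail = FALSE))
}

#' Leave-one-out influence analysis
#'
#' Re-estimates IVW omitting each variant in turn; a single variant whose
#' omission moves the estimate far from the full-set value is influential.
#'
#' @inheritParams mr_estimators
#' @return Tibble with one row per omitted variant, in input order:
#'   `snp_id`, `n_snp`, `beta`, `se`, `pvalue`, `or`, `ci_low`, `ci_high`.
#' @export
mr_leave_one_out <- function(pairs) {
  pairs <- check_pairs(pairs, 2, "leave-one-out")
  ids <- if ("snp_id" %in% names(pairs)) pairs$snp_id else as.character(seq_len(nrow(pairs)))
  purrr::map2_dfr(seq_len(nrow(pairs)), ids, function(i, id) {
    dplyr::bind_cols(tibble::tibble(snp_id = id),
                     tidy(mr_ivw(pairs[-i, ])) |> dplyr::select(-"method"))
  })
}

# Leave-one-out IVW slopes from sufficient statistics; rows of bx/by may be
# a matrix of simulated replicates (replicates x J).
loo_slopes <- function(bx, by, w) {
  if (is.null(dim(bx))) {
    bx <- matrix(bx, nrow = 1)
    by <- matrix(by, nrow = 1)
  }
  wm <- matrix(w, nrow = nrow(bx), ncol = length(w), byrow = TRUE)
  sxy <- rowSums(bx * by * wm)
  sxx <- rowSums(bx^2 * wm)
  (sxy - bx * by * wm) / (sxx - bx^2 * wm)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based residual analysis for horizontal pleiotropy. The
#' observed residual sum of squares is
#' `RSS = sum_j (beta_out_j - b_(-j) * beta_exp_j)^2 / se_out_j^2`, where
#' `b_(-j)` is the IVW estimate excluding variant j. Its null distribution
#' comes from `n_sim` parametric replicates drawing
#' `beta_out_j* ~ N(b_(-j) beta_exp_j, se_out_j^2)` and
#' `beta_exp_j* ~ N(beta_exp_j, se_exp_j^2)`. Empirical p-values use the
#' add-one estimator, so the smallest attainable p is `1 / (n_sim + 1)`.
#' Per-variant outlier p-values compare each observed weighted squared
#' residual to its simulated distribution, Bonferroni-adjusted across the J
#' variants, declared at `outlier_alpha`. When outliers are found, the
#' corrected estimate is IVW without them and the distortion test compares
#' the resulting estimate shift to shifts under removal of equally many
#' variants at random (exhaustive over subsets when there are at most
#' 10,000 of them, otherwise `n_sim` random draws).
#'
#' @inheritParams mr_estimators
#' @param n_sim Number of parametric replicates (values below 100 warn).
#' @param outlier_alpha Significance level for outlier declaration after
#'   Bonferroni adjustment.
#' @param seed Integer seed; all simulation output is reproducible from it.
#' @return An object of class `mr_presso`: `global_p`, `outlier_tbl`
#'   (per-variant raw/adjusted p and flag), `outliers` (ids), `distortion_p`
#'   (`NA` when no outlier), `corrected` (IVW estimate without outliers, or
#'   `NULL`), `rss_obs`, `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05, seed = 42) {
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  if (n_sim < 100) warn("n_sim < 100 gives a very coarse empirical p-value")
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sex <- pairs$se_exp; seo <- pairs$se_out
  j <- length(bx)
  ids <- if ("snp_id" %in% names(pairs)) pairs$snp_id else as.character(seq_len(j))
  w <- 1 / seo^2

  b_loo <- drop(loo_slopes(bx, by, w))
  d_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(d_obs)

  sim <- withr::with_seed(seed, {
    bxs <- matrix(rnorm(n_sim * j, rep(bx, each = n_sim),
                        rep(sex, each = n_sim)), nrow = n_sim)
    bys <- matrix(rnorm(n_sim * j, rep(b_loo * bx, each = n_sim),
                        rep(seo, each = n_sim)), nrow = n_sim)
    b_loo_s <- loo_slopes(bxs, bys, w)
    d_sim <- sweep((bys - b_loo_s * bxs)^2, 2, w, `*`)
    list(d_sim = d_sim, rss = rowSums(d_sim))
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)

  p_raw <- (1 + colSums(sweep(sim$d_sim, 2, d_obs, `>=`))) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  is_outlier <- p_adj < outlier_alpha
  outlier_tbl <- tibble::tibble(snp_id = ids, p_raw = p_raw, p_adj = p_adj,
                                outlier = is_outlier)
  outliers <- ids[is_outlier]

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && sum(!is_outlier) >= 1) {
    full <- mr_ivw(pairs)
    corrected <- mr_ivw(pairs[!is_outlier, ])
    shift_obs <- corrected$beta - full$beta
    k <- length(outliers)
    shifts <- withr::with_seed(seed + 1L, {
      if (choose(j, k) <= 10000) {
        subsets <- combn(j, k, simplify = FALSE)
      } else {
        subsets <- replicate(n_sim, sample.int(j, k), simplify = FALSE)
      }
      vapply(subsets, function(idx) mr_ivw(pairs[-idx, ])$beta - full$beta,
             numeric(1))
    })
    distortion_p <- (1 + sum(abs(shifts) >= abs(shift_obs))) /
      (length(shifts) + 1)
  }
  structure(list(global_p = global_p, outlier_tbl = outlier_tbl,
                 outliers = outliers, distortion_p = distortion_p,
                 corrected = corrected, rss_obs = rss_obs,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global p = %.4g (%d sims); %d outlier(s)%s\n",
              x$global_p, x$n_sim, length(x$outliers),
              if (length(x$outliers) > 0)
                sprintf(" [%s]; distortion p = %.3g",
                        paste(x$outliers, collapse = ", "), x$distortion_p)
              else ""))
  invisible(x)
}

#' @rdname tidy-mrmediate
#' @export
tidy.mr_presso <- function(x, ...) x$outlier_tbl

#' @rdname tidy-mrmediate
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_p = x$global_p, n_outliers = length(x$outliers),
                 distortion_p = x$distortion_p,
                 corrected_beta = if (is.null(x$corrected)) NA_real_ else x$corrected$beta,
                 rss_obs = x$rss_obs, n_sim = x$n_sim)
}

#' Full sensitivity panel for one harmonized pair set
#'
#' Bundles Cochran's Q, the MR-Egger intercept pleiotropy test,
#' leave-one-out influence estimates and MR-PRESSO (the latter two only
#' when enough variants are available).
#'
#' @inheritParams mr_presso
#' @param run_presso Logical; skip the simulation-based test when `FALSE`.
#' @return Object of class `mr_sensitivity` with elements `q` (tibble),
#'   `egger_intercept` (`mr_estimate` or `NULL`), `loo` (tibble or `NULL`),
#'   `presso` (`mr_presso` or `NULL`).
#' @export
sensitivity_report <- function(pairs, n_sim = 1000, outlier_alpha = 0.05,
                               seed = 42, run_presso = TRUE) {
  pairs <- kept_pairs(pairs)
  j <- nrow(pairs)
  structure(
    list(
      q = if (j >= 2) cochran_q(pairs) else NULL,
      egger_intercept = if (j >= 3) mr_egger(pairs)$intercept else NULL,
      loo = if (j >= 2) mr_leave_one_out(pairs) else NULL,
      presso = if (run_presso && j >= 4)
        mr_presso(pairs, n_sim = n_sim, outlier_alpha = outlier_alpha,
                  seed = seed) else NULL,
      n_snp = j
    ),
    class = "mr_sensitivity"
  )
}

#' @rdname tidy-mrmediate
#' @export
glance.mr_sensitivity <- function(x, ...) {
  tibble::tibble(
    n_snp = x$n_snp,
    q = if (is.null(x$q)) NA_real_ else x$q$q,
    q_df = if (is.null(x$q)) NA_integer_ else x$q$q_df,
    q_pvalue = if (is.null(x$q)) NA_real_ else x$q$q_pvalue,
    egger_intercept = if (is.null(x$egger_intercept)) NA_real_ else x$egger_intercept$beta,
    egger_intercept_se = if (is.null(x$egger_intercept)) NA_real_ else x$egger_intercept$se,
    egger_intercept_p = if (is.null(x$egger_intercept)) NA_real_ else x$egger_intercept$pvalue,
    presso_global_p = if (is.null(x$presso)) NA_real_ else x$presso$global_p,
    presso_n_outliers = if (is.null(x$presso)) NA_integer_ else length(x$presso$outliers),
    presso_distortion_p = if (is.null(x$presso)) NA_real_ else x$presso$distortion_p
  )
}
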