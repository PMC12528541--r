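#' @rdname mr_estimators
#' @export
new_mr_estimate <- function(method, beta, se, pvalue, n_snp, df = NULL,
                            extra = list()) {
  crit <- if (is.null(df)) 1.96 else qt(0.975, df)
  structure(
    list(method = method, beta = beta, se = se, pvalue = pvalue,
         or_ = exp(beta), ci_low = exp(beta - crit * se),
         ci_high = exp(beta + crit * se), crit = crit, df = df,
         n_snp = as.integer(n_snp), extra = extra),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs): beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pvalue))
  invisible(x)
}

#' Tidiers for mrmediate result objects
#'
#' Broom-style [generics::tidy()] / [generics::glance()] methods returning
#' one-row-per-estimate tibbles.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-mrmediate
NULL

#' @rdname tidy-mrmediate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp, beta = x$beta,
                 se = x$se, pvalue = x$pvalue, or = x$or_,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @rdname tidy-mrmediate
#' @export
glance.mr_estimate <- function(x, ...) {
  out <- tidy(x)
  for (nm in names(x$extra)) {
    if (is.numeric(x$extra[[nm]]) && length(x$extra[[nm]]) == 1) {
      out[[nm]] <- x$extra[[nm]]
    }
  }
  out
}

check_pairs <- function(pairs, min_n, method) {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) < min_n) {
    abort(sprintf("%s needs at least %d harmonized pair(s), got %d",
                  method, min_n, nrow(pairs)))
  }
  if (any(pairs$beta_exp == 0)) abort("all exposure effects must be nonzero")
  if (any(pairs$se_out <= 0) || any(pairs$se_exp <= 0)) {
    abort("standard errors must be positive")
  }
  pairs
}

#' Two-sample Mendelian randomization estimators
#'
#' Causal-effect estimators operating on harmonized exposure/outcome pairs
#' (the output of [harmonize()]; rows with a dropped action are ignored).
#' All effects are on the additive (log-odds) scale; estimates also carry
#' the odds-ratio form `exp(beta)` with a 95% confidence interval.
#'
#' * `mr_wald_ratio()` — single-variant ratio `beta_out / beta_exp` with
#'   first-order standard error `se_out / |beta_exp|`.
#' * `mr_ivw()` — inverse-variance-weighted estimate, the weighted
#'   regression of outcome on exposure effects through the origin with
#'   weights `1 / se_out^2`. The primary standard error is multiplicative
#'   random-effects: the fixed-effect form inflated by
#'   `max(1, sqrt(Q / (J - 1)))`, which reduces to fixed-effect under
#'   homogeneity; the fixed-effect se, Q and the inflation factor are kept
#'   in `extra`.
#' * `mr_egger()` — weighted regression with a free intercept after
#'   orienting every pair to a non-negative exposure effect; the slope is
#'   the causal estimate and a nonzero intercept indicates directional
#'   horizontal pleiotropy. Standard errors use the weighted-least-squares
#'   covariance inflated by `max(1, sqrt(Q / (J - 2)))`; p-values and CIs
#'   use the t-distribution with J - 2 df.
#' * `mr_weighted_median()` — the ratio at the 50th percentile of the
#'   weight-ordered ratio distribution (linear interpolation across
#'   standardized cumulative weights), consistent when at least half the
#'   weight comes from valid instruments; its standard error is a
#'   parametric bootstrap, reproducible from `seed`.
#'
#' @param pairs Harmonized pairs tibble with columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (and optionally `action`).
#' @param n_boot Bootstrap draws for the weighted-median standard error.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `mr_estimate` (`mr_egger()` returns class
#'   `mr_egger_fit` holding the `slope` and `intercept` estimates); use
#'   [tidy()] for a tibble.
#' @examples
#' pairs <- tibble::tibble(beta_exp = c(0.1, 0.2, 0.15, 0.12),
#'                         se_exp = 0.01,
#'                         beta_out = c(0.05, 0.1, 0.075, 0.06),
#'                         se_out = 0.02)
#' tidy(mr_ivw(pairs))
#' @name mr_estimators
NULL

#' @rdname mr_estimators
#' @export
mr_wald_ratio <- function(pairs) {
  pairs <- check_pairs(pairs, 1, "wald ratio")
  if (nrow(pairs) != 1) abort("wald ratio is a single-variant estimator")
  beta <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  new_mr_estimate("wald", beta, se, 2 * pnorm(-abs(beta / se)), 1L)
}

#' @rdname mr_estimators
#' @export
mr_ivw <- function(pairs) {
  pairs <- check_pairs(pairs, 1, "IVW")
  bx <- pairs$beta_exp; by <- pairs$beta_out; seo <- pairs$se_out
  j <- length(bx)
  w <- bx^2 / seo^2
  beta <- sum(bx * by / seo^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (j >= 2) {
    q <- sum(w * (by / bx - beta)^2)
    inflation <- max(1, sqrt(q / (j - 1)))
  } else {
    q <- NA_real_
    inflation <- 1
  }
  se <- se_fixed * inflation
  new_mr_estimate("ivw", beta, se, 2 * pnorm(-abs(beta / se)), j,
                  extra = list(se_fixed = se_fixed, q = q,
                               inflation = inflation))
}

#' @rdname mr_estimators
#' @export
mr_egger <- function(pairs) {
  pairs <- check_pairs(pairs, 3, "MR-Egger")
  s <- sign(pairs$beta_exp)
  bx <- abs(pairs$beta_exp); by <- pairs$beta_out * s
  seo <- pairs$se_out
  j <- length(bx)
  x <- cbind(intercept = 1, slope = bx)
  w <- 1 / seo^2
  xtwx <- crossprod(x, x * w)
  coefs <- drop(solve(xtwx, crossprod(x, by * w)))
  resid <- by - drop(x %*% coefs)
  q <- sum(w * resid^2)
  inflation <- max(1, sqrt(q / (j - 2)))
  se <- sqrt(diag(solve(xtwx))) * inflation
  pv <- 2 * pt(-abs(coefs / se), df = j - 2)
  structure(
    list(
      slope = new_mr_estimate("egger_slope", coefs[["slope"]], se[["slope"]],
                              pv[["slope"]], j, df = j - 2,
                              extra = list(q = q, inflation = inflation)),
      intercept = new_mr_estimate("egger_intercept", coefs[["intercept"]],
                                  se[["intercept"]], pv[["intercept"]], j,
                                  df = j - 2),
      q = q, df = j - 2, n_snp = j
    ),
    class = "mr_egger_fit"
  )
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("<mr_egger_fit>\n  ")
  print(x$slope)
  cat("  ")
  print(x$intercept)
  invisible(x)
}

#' @rdname tidy-mrmediate
#' @export
tidy.mr_egger_fit <- function(x, ...) {
  dplyr::bind_rows(tidy(x$slope), tidy(x$intercept))
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' @rdname mr_estimators
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 42) {
  pairs <- check_pairs(pairs, 3, "weighted median")
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sex <- pairs$se_exp; seo <- pairs$se_out
  j <- length(bx)
  beta <- weighted_median_point(by / bx, bx^2 / seo^2)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- rnorm(j, bx, sex)
      bys <- rnorm(j, by, seo)
      weighted_median_point(bys / bxs, bxs^2 / seo^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_estimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)), j,
                  extra = list(n_boot = n_boot, seed = seed))
}

#' All applicable estimators for one harmonized pair set
#'
#' Runs the Wald ratio (single variant), IVW (always), and — with at least
#' three variants — MR-Egger and the weighted median, returning one tidy
#' row per method.
#'
#' @inheritParams mr_estimators
#' @return Tibble with one row per method.
#' @export
mr_all <- function(pairs, n_boot = 1000, seed = 42) {
  pairs <- kept_pairs(pairs)
  j <- nrow(pairs)
  out <- list()
  if (j == 1) out$wald <- tidy(mr_wald_ratio(pairs))
  if (j >= 1) out$ivw <- tidy(mr_ivw(pairs))
  if (j >= 3) {
    out$egger <- tidy(mr_egger(pairs))
    out$wm <- tidy(mr_weighted_median(pairs, n_boot = n_boot, seed = seed))
  }
  dplyr::bind_rows(out)
}
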