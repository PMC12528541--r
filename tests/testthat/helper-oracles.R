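# Independent brute-force oracles. These deliberately share no code with the
# package: normal equations are solved explicitly, the weighted median is
# found by root-finding on the forward cumulative-weight map, and BH is the
# literal step-up definition.

# Weighted least squares via explicit normal equations.
# Returns coefficients and the unscaled (unit-dispersion) covariance.
oracle_wls <- function(x, y, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  A <- t(X * w) %*% X
  b <- t(X * w) %*% y
  coefs <- solve(A, b)
  list(coef = unname(drop(coefs)), cov = unname(solve(A)),
       rss_w = sum(w * (y - drop(X %*% coefs))^2))
}

# IVW oracle: ratio-scale WLS through the origin plus both standard errors.
oracle_ivw <- function(bx, by, seo) {
  w <- 1 / seo^2
  fit <- oracle_wls(bx, by, w, intercept = FALSE)
  beta <- fit$coef
  se_fixed <- sqrt(fit$cov[1, 1])
  j <- length(bx)
  q <- sum((bx^2 / seo^2) * (by / bx - beta)^2)
  infl <- max(1, sqrt(q / (j - 1)))
  list(beta = beta, se_fixed = se_fixed, se_re = se_fixed * infl, q = q)
}

oracle_egger <- function(bx, by, seo) {
  s <- sign(bx)
  fit <- oracle_wls(abs(bx), by * s, 1 / seo^2, intercept = TRUE)
  j <- length(bx)
  infl <- max(1, sqrt(fit$rss_w / (j - 2)))
  list(intercept = fit$coef[1], slope = fit$coef[2],
       se_intercept = sqrt(fit$cov[1, 1]) * infl,
       se_slope = sqrt(fit$cov[2, 2]) * infl)
}

# Weighted-median oracle: root of s(r) - 0.5 where s() is the piecewise
# linear interpolant of standardized cumulative weights over sorted ratios.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  fun <- approxfun(r, s, ties = "ordered")
  uniroot(function(x) fun(x) - 0.5, range(r), tol = 1e-15)$root
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / seq(i, m))
  }
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Hand-built harmonization truth table, written as explicit set logic.
COMP <- c(A = "T", T = "A", C = "G", G = "C")
oracle_harmonize_action <- function(ea, oa, ea2, oa2) {
  if (oa == COMP[[ea]]) return("dropped_palindromic")
  if (ea2 == ea && oa2 == oa) return("kept_as_is")
  if (ea2 == oa && oa2 == ea) return("flipped")
  if (COMP[[ea2]] == ea && COMP[[oa2]] == oa) return("kept_as_is")
  if (COMP[[ea2]] == oa && COMP[[oa2]] == ea) return("flipped")
  "dropped_incompatible"
}
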