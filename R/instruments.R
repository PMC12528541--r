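#' Filter summary statistics to candidate instruments
#'
#' Keeps exactly the records with `pvalue < p_threshold`, sorted by
#' ascending p-value with ties broken by `snp_id` (lexicographic), which is
#' the order the greedy clumping step consumes.
#'
#' @param records Canonical summary-statistic tibble.
#' @param p_threshold Significance threshold in (0, 1). Conventional
#'   choices: 5e-8 (genome-wide), 1e-5 (relaxed, e.g. microbiome or
#'   metabolite exposures), 5e-5 (reverse analyses of a rare outcome).
#' @return Tibble of candidate records, possibly empty.
#' @export
select_candidates <- function(records, p_threshold = 1e-5) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("`p_threshold` must be in (0, 1)")
  records |>
    dplyr::filter(.data$pvalue < p_threshold) |>
    dplyr::arrange(.data$pvalue, .data$snp_id)
}

#' Read a pairwise linkage-disequilibrium table
#'
#' Three delimited columns: `snp_a`, `snp_b`, `r2`. The relation is treated
#' as symmetric and pairs not listed have r-squared 0 (the convention for a
#' pre-clumped or equilibrium panel).
#'
#' @param path Path to the delimited file (tab or comma; auto-detected by
#'   readr).
#' @return A tibble of class `ld_table`.
#' @export
read_ld_table <- function(path) {
  tb <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(tb)[1:3] <- c("snp_a", "snp_b", "r2")
  ld_table(tb)
}

#' Construct a linkage-disequilibrium table from a data frame
#'
#' @param x Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return A tibble of class `ld_table`.
#' @export
ld_table <- function(x = NULL) {
  if (is.null(x)) x <- tibble::tibble(snp_a = character(), snp_b = character(),
                                      r2 = numeric())
  x <- tibble::as_tibble(x)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(x)))
  if (any(x$r2 < 0 | x$r2 > 1)) abort("r2 values must lie in [0, 1]")
  structure(x, class = c("ld_table", class(tibble::tibble())))
}

ld_lookup <- function(ld, a, b) {
  if (is.null(ld) || nrow(ld) == 0) return(rep(0, length(a)))
  key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
  val <- c(ld$r2, ld$r2)
  r2 <- val[match(paste(a, b), key)]
  ifelse(is.na(r2), 0, r2)
}

#' Greedy clumping to an independent instrument set
#'
#' Standard p-value-ordered greedy pruning: repeatedly accept the best
#' remaining variant and discard every remaining variant on the same
#' chromosome within `window_bp` whose pairwise r-squared with it is at
#' least `r2_max`. Defaults reproduce the usual strict pruning (window
#' 10 Mb, r-squared < 0.001). Pairs absent from `ld` count as r-squared 0,
#' and variants with unknown coordinates are never considered co-located.
#'
#' @param candidates Candidate records sorted by ascending p-value (as from
#'   [select_candidates()]).
#' @param ld An [ld_table()] or `NULL` for full linkage equilibrium.
#' @param r2_max Independence threshold (discard at r-squared >= `r2_max`).
#' @param window_bp Clumping window in base pairs.
#' @return The retained candidate rows, in acceptance (p-value) order.
#' @export
clump_snps <- function(candidates, ld = NULL, r2_max = 0.001, window_bp = 1e7) {
  if (nrow(candidates) == 0) return(candidates)
  if (is.unsorted(candidates$pvalue)) {
    abort("`candidates` must be sorted by ascending p-value")
  }
  remaining <- candidates
  kept <- candidates[0, ]
  while (nrow(remaining) > 0) {
    best <- remaining[1, ]
    kept <- dplyr::bind_rows(kept, best)
    remaining <- remaining[-1, ]
    if (nrow(remaining) == 0) break
    same_chr <- !is.na(remaining$chrom) & !is.na(best$chrom) &
      remaining$chrom == best$chrom
    in_window <- same_chr & !is.na(remaining$pos) & !is.na(best$pos) &
      abs(remaining$pos - best$pos) <= window_bp
    r2 <- ld_lookup(ld, remaining$snp_id, rep(best$snp_id, nrow(remaining)))
    remaining <- remaining[!(in_window & r2 >= r2_max), ]
  }
  kept
}

#' Per-variant proportion of trait variance explained
#'
#' When the effect-allele frequency is available the primary form
#' `2 * eaf * (1 - eaf) * beta^2` is used (unit-variance trait); otherwise
#' the t-statistic fallback `t^2 / (t^2 + n - 2)` with `t = beta / se`,
#' which needs no frequency.
#'
#' @param records Canonical summary-statistic tibble.
#' @return Numeric vector of per-variant r-squared values.
#' @export
snp_r2 <- function(records) {
  t2 <- (records$beta / records$se)^2
  use_eaf <- !is.na(records$eaf)
  if (any(!use_eaf & records$n <= 2)) abort("t-statistic fallback needs n > 2")
  ifelse(use_eaf,
         2 * records$eaf * (1 - records$eaf) * records$beta^2,
         t2 / (t2 + records$n - 2))
}

#' Instrument-strength F-statistic
#'
#' `F = [R2 (n - k - 1)] / [k (1 - R2)]` for an instrument set explaining a
#' proportion `R2` of exposure variance with `k` variants in a sample of
#' size `n`. Values above 10 are the conventional threshold for adequate
#' strength (sets below it are flagged weak and excluded from analysis).
#'
#' @param r2 Proportion of variance explained, in [0, 1).
#' @param n Sample size, must exceed `k + 1`.
#' @param k Number of variants, at least 1.
#' @return The F-statistic.
#' @examples
#' f_statistic(0.01, 18340, 10)
#' @export
f_statistic <- function(r2, n, k) {
  if (any(k < 1)) abort("`k` must be at least 1")
  if (any(r2 < 0 | r2 >= 1)) abort("`r2` must lie in [0, 1)")
  if (any(n <= k + 1)) abort("`n` must exceed k + 1")
  (r2 * (n - k - 1)) / (k * (1 - r2))
}

#' Select an exposure's instrumental variables
#'
#' Full instrument-selection path for one trait: threshold filter, greedy
#' clumping to independence, summed variance explained, and the
#' F-statistic strength gate. Sets with F below `f_min` are flagged weak;
#' callers exclude them from analysis.
#'
#' @inheritParams select_candidates
#' @inheritParams clump_snps
#' @param f_min Minimum F-statistic for a usable set (default 10).
#' @return An object of class `instrument_set`: the retained records plus
#'   `trait_id`, `p_threshold`, `r2` (summed variance explained), `k`, `n`,
#'   `F` and the `weak` flag. `NULL`-like empty sets (no variant passes) are
#'   returned with `k = 0` and `F = NA`.
#' @export
select_instruments <- function(records, p_threshold = 1e-5, ld = NULL,
                               r2_max = 0.001, window_bp = 1e7, f_min = 10) {
  kept <- clump_snps(select_candidates(records, p_threshold), ld = ld,
                     r2_max = r2_max, window_bp = window_bp)
  trait <- if (nrow(records) > 0) records$trait_id[1] else NA_character_
  if (nrow(kept) == 0) {
    return(structure(list(trait_id = trait, snps = kept,
                          p_threshold = p_threshold, r2 = 0, k = 0L,
                          n = NA_integer_, F = NA_real_, weak = TRUE),
                     class = "instrument_set"))
  }
  r2 <- sum(snp_r2(kept))
  k <- nrow(kept)
  n <- as.integer(round(stats::median(kept$n)))
  f <- f_statistic(r2, n, k)
  structure(list(trait_id = trait, snps = kept, p_threshold = p_threshold,
                 r2 = r2, k = as.integer(k), n = n, F = f,
                 weak = f < f_min),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: k = %d, R2 = %.4g, F = %.2f%s (p < %g)\n",
              x$trait_id, x$k, x$r2, x$F, if (isTRUE(x$weak)) " [weak]" else "",
              x$p_threshold))
  invisible(x)
}

#' @rdname tidy-mrmediate
#' @export
tidy.instrument_set <- function(x, ...) {
  tibble::tibble(trait_id = x$trait_id, k = x$k, n = x$n, r2 = x$r2,
                 F = x$F, weak = x$weak, p_threshold = x$p_threshold)
}
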