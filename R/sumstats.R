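#' Describe the columns of a GWAS summary-statistics file
#'
#' A column map ties the canonical per-SNP fields used throughout the package
#' to the headers of a delimited source file. Canonical fields are `snp_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#' `eaf`, `n` and `trait_id`; all except `chrom`, `pos` and `eaf` must be
#' mapped. Coordinates are 1-based. Effects are on the additive scale
#' (log-odds for binary traits); set `effect_is_or = TRUE` when the source
#' stores odds ratios and they will be log-transformed at ingest (and
#' exponentiated again on write, so round trips are exact).
#'
#' @param snp_id,effect_allele,other_allele,beta,se,pvalue,n,trait_id Source
#'   column headers for the required canonical fields.
#' @param chrom,pos,eaf Source headers for the optional fields, or `NULL`
#'   when the file does not carry them.
#' @param delim Field delimiter, `"\t"` or `","`.
#' @param na Character vector of missing-value sentinels; the first element
#'   is also what [write_sumstats()] emits for missing values.
#' @param effect_is_or Logical; if `TRUE` the effect column holds odds ratios.
#'
#' @return An object of class `sumstats_colmap`.
#' @examples
#' cm <- sumstats_colmap(snp_id = "SNP", beta = "b", se = "se", pvalue = "p",
#'                       effect_allele = "A1", other_allele = "A2",
#'                       n = "N", trait_id = "trait")
#' @export
sumstats_colmap <- function(snp_id = "snp_id",
                            effect_allele = "effect_allele",
                            other_allele = "other_allele",
                            beta = "beta",
                            se = "se",
                            pvalue = "pvalue",
                            n = "n",
                            trait_id = "trait_id",
                            chrom = "chrom",
                            pos = "pos",
                            eaf = "eaf",
                            delim = "\t",
                            na = c("NA", ""),
                            effect_is_or = FALSE) {
  required <- list(snp_id = snp_id, effect_allele = effect_allele,
                   other_allele = other_allele, beta = beta, se = se,
                   pvalue = pvalue, n = n, trait_id = trait_id)
  bad <- names(required)[!vapply(required, function(x) is.character(x) && length(x) == 1L && !is.na(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Required canonical field(s) without a mapped source column: ",
                 paste(bad, collapse = ", ")))
  }
  optional <- list(chrom = chrom, pos = pos, eaf = eaf)
  structure(
    list(fields = c(required, optional[!vapply(optional, is.null, logical(1))]),
         delim = delim, na = na, effect_is_or = isTRUE(effect_is_or)),
    class = "sumstats_colmap"
  )
}

#' @export
print.sumstats_colmap <- function(x, ...) {
  cat("<sumstats_colmap>\n")
  for (f in names(x$fields)) cat(sprintf("  %-14s <- %s\n", f, x$fields[[f]]))
  cat(sprintf("  delim = %s; na = [%s]; effect_is_or = %s\n",
              deparse(x$delim), paste(x$na, collapse = ", "), x$effect_is_or))
  invisible(x)
}

canonical_fields <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "se", "pvalue", "eaf", "n", "trait_id")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-bearing delimited file, renames columns through the map,
#' and validates every row. Rows violating the record invariants (alleles
#' must be distinct single bases, `se > 0`, `pvalue` in (0, 1], `n > 0`,
#' `eaf` in (0, 1) when present) are dropped, and the dropped rows are
#' counted per reason in the `rejections` attribute — nothing is discarded
#' silently. p-values that underflow to zero (e.g. the string `1e-400`) are
#' clamped to the smallest positive normal double with a warning rather
#' than rejected.
#'
#' @param path Path to the file.
#' @param colmap A [sumstats_colmap()].
#' @return A tibble with the canonical columns, in file order, carrying
#'   attributes `rejections` (named integer vector, see
#'   [sumstats_rejections()]) and `n_input` (rows read). The accepted row
#'   count plus the rejection tally always equals `n_input`.
#' @seealso [write_sumstats()], [sumstats_rejections()]
#' @examples
#' path <- system.file("extdata", "synthetic_exposure.tsv",
#'                     package = "mrmediate")
#' head(read_sumstats(path))
#' @export
read_sumstats <- function(path, colmap = sumstats_colmap()) {
  if (!inherits(colmap, "sumstats_colmap")) abort("`colmap` must be a sumstats_colmap")
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = colmap$delim, na = colmap$na,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  src <- unlist(colmap$fields)
  missing_cols <- setdiff(unname(src), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Mapped column(s) absent from header: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(setNames(raw[unname(src)], names(src)))
  validate_sumstats(df, effect_is_or = colmap$effect_is_or)
}

# Row-wise validation of a character (or already-typed) canonical table.
# Returns the accepted tibble with a per-reason rejection tally attached.
validate_sumstats <- function(df, effect_is_or = FALSE) {
  n_input <- nrow(df)
  for (f in setdiff(canonical_fields, names(df))) df[[f]] <- NA_character_
  df <- df[canonical_fields]

  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  beta <- num(df$beta); se <- num(df$se); p <- num(df$pvalue)
  eaf <- num(df$eaf); n <- num(df$n); pos <- num(df$pos)
  ea <- toupper(as.character(df$effect_allele))
  oa <- toupper(as.character(df$other_allele))

  # p underflow: string present and parses to exactly 0
  underflow <- !is.na(p) & p == 0
  if (any(underflow)) {
    warn(sprintf("%d p-value(s) underflowed to 0; clamped to %.3e",
                 sum(underflow), .Machine$double.xmin))
    p[underflow] <- .Machine$double.xmin
  }

  reason <- rep(NA_character_, n_input)
  set_reason <- function(reason, cond, label) {
    ifelse(is.na(reason) & cond, label, reason)
  }
  req_missing <- is.na(df$snp_id) | is.na(df$trait_id) | is.na(ea) | is.na(oa) |
    is.na(as.character(df$beta)) | is.na(as.character(df$se)) |
    is.na(as.character(df$pvalue)) | is.na(as.character(df$n))
  reason <- set_reason(reason, req_missing, "missing_required")
  unparseable <- is.na(beta) | is.na(se) | is.na(p) | is.na(n) |
    (!is.na(as.character(df$eaf)) & is.na(eaf)) |
    (!is.na(as.character(df$pos)) & is.na(pos))
  reason <- set_reason(reason, unparseable, "unparseable_numeric")
  multi <- !(ea %in% c("A", "C", "G", "T")) | !(oa %in% c("A", "C", "G", "T"))
  reason <- set_reason(reason, multi, "multiallelic")
  reason <- set_reason(reason, ea == oa, "same_alleles")
  if (effect_is_or) reason <- set_reason(reason, beta <= 0, "nonpositive_or")
  reason <- set_reason(reason, se <= 0, "nonpositive_se")
  reason <- set_reason(reason, p < 0 | p > 1, "invalid_pvalue")
  reason <- set_reason(reason, n <= 0, "nonpositive_n")
  reason <- set_reason(reason, !is.na(eaf) & (eaf <= 0 | eaf >= 1), "invalid_eaf")
  reason <- set_reason(reason, !is.na(pos) & pos < 0, "invalid_pos")

  keep <- is.na(reason)
  out <- tibble::tibble(
    snp_id = as.character(df$snp_id)[keep],
    chrom = as.character(df$chrom)[keep],
    pos = as.integer(round(pos[keep])),
    effect_allele = ea[keep],
    other_allele = oa[keep],
    beta = if (effect_is_or) log(beta[keep]) else beta[keep],
    se = se[keep],
    pvalue = p[keep],
    eaf = eaf[keep],
    n = as.integer(round(n[keep])),
    trait_id = as.character(df$trait_id)[keep]
  )
  tally <- table(factor(reason[!keep]))
  attr(out, "rejections") <- setNames(as.integer(tally), names(tally))
  attr(out, "n_input") <- n_input
  out
}

#' Rejection tally of a summary-statistics read
#'
#' @param x A tibble returned by [read_sumstats()].
#' @return Named integer vector counting dropped rows per reason.
#' @export
sumstats_rejections <- function(x) {
  attr(x, "rejections") %||% setNames(integer(0), character(0))
}

#' Write GWAS summary statistics to delimited text
#'
#' Inverse of [read_sumstats()]: columns are renamed back through the map,
#' missing values become the map's first sentinel, and (when the map says the
#' source scale is odds ratios) effects are exponentiated so that a
#' read/write round trip reproduces the records field for field.
#'
#' @param records Tibble of canonical records (as from [read_sumstats()] or
#'   [simulate_triple()]).
#' @param path Output path.
#' @param colmap A [sumstats_colmap()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path, colmap = sumstats_colmap()) {
  if (!inherits(colmap, "sumstats_colmap")) abort("`colmap` must be a sumstats_colmap")
  out <- tibble::as_tibble(records)
  for (f in setdiff(canonical_fields, names(out))) out[[f]] <- NA
  out <- out[names(colmap$fields)]
  if (colmap$effect_is_or) out$beta <- exp(out$beta)
  names(out) <- unlist(colmap$fields)[names(colmap$fields)]
  readr::write_delim(out, path, delim = colmap$delim, na = colmap$na[1])
  invisible(path)
}
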