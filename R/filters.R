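#' Filter loci on minor allele frequency and missingness
#'
#' The reduced-representation (GBS-style) locus filter: a locus is kept iff
#' its minor allele frequency, computed on non-missing calls, is at least
#' `maf_min` AND its missing-genotype fraction is at most `miss_max`.
#' A locus with every call missing is attributed to the missingness rule
#' (never a division by zero). Loci are attributed to the first rule that
#' removes them, in the order missingness, then MAF.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param miss_max Maximum per-locus missing fraction (default 0.20).
#' @return A list: `gm` (filtered matrix) and `report` (a `filter_report`
#'   tibble: one row per rule with `rule`, `params`, `n_removed`, plus
#'   attributes `n_input`, `n_output`, and `multi_rule` — loci that violate
#'   more than one rule, for auditability).
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 0L, 0L, 0L, 1L), 5, 1))
#' filter_maf_missing(gm)$report
filter_maf_missing <- function(gm, maf_min = 0.01, miss_max = 0.20) {
  g <- gm$genotypes
  miss_frac <- colMeans(is.na(g))
  maf <- locus_maf(g)
  fail_miss <- miss_frac > miss_max
  fail_maf <- !fail_miss & (is.na(maf) | maf < maf_min)
  fail_maf_any <- is.na(maf) | maf < maf_min   # for multi-rule audit
  keep <- !fail_miss & !fail_maf
  report <- new_filter_report(
    rules = tibble::tibble(
      rule = c("missingness", "maf"),
      params = c(sprintf("miss_max=%g", miss_max),
                 sprintf("maf_min=%g", maf_min)),
      n_removed = c(sum(fail_miss), sum(fail_maf))
    ),
    n_input = ncol(g),
    n_output = sum(keep),
    multi_rule = locus_ids(gm)[fail_miss & fail_maf_any]
  )
  list(gm = subset_geno(gm, loci = keep), report = report)
}

#' Filter RNA-Seq-derived variants on quality, support, MAC and missingness
#'
#' Reproduces the variant-level thresholds typical of a bcftools + vcftools
#' transcriptome SNP workflow: variant base quality >= `min_qual` (phred),
#' alternate-allele read support (DP4 forward+reverse) >= `min_dp4`, minor
#' allele count on gene copies >= `mac` (vcftools `--mac` semantics), fraction
#' of samples with a call >= `max_missing` (vcftools `--max-missing`
#' semantics: 0.98 keeps a site when at least 98% of samples are genotyped),
#' and minor allele frequency >= `maf`. Rules whose QC fields are absent from
#' the locus table are skipped with a warning. Loci are attributed to the
#' first rule that removes them in the order quality, DP4, call rate, MAC,
#' MAF (order logged in the report).
#'
#' @param gm A [geno_matrix()] whose locus table carries `qual` and `dp4`.
#' @param min_qual,min_dp4,mac,max_missing,maf Thresholds (defaults 30, 10,
#'   4, 0.98, 0.01).
#' @return As [filter_maf_missing()]: list of filtered `gm` and `report`.
#' @export
filter_rna_variants <- function(gm, min_qual = 30, min_dp4 = 10, mac = 4,
                                max_missing = 0.98, maf = 0.01) {
  g <- gm$genotypes
  lt <- gm$loci
  L <- ncol(g)

  fail <- list()
  if ("qual" %in% names(lt) && !all(is.na(lt$qual))) {
    fail$quality <- !is.na(lt$qual) & lt$qual < min_qual
  } else {
    rlang::warn("filter_rna_variants: no 'qual' field; quality rule skipped")
    fail$quality <- rep(FALSE, L)
  }
  if ("dp4" %in% names(lt) && !all(is.na(lt$dp4))) {
    fail$dp4 <- !is.na(lt$dp4) & lt$dp4 < min_dp4
  } else {
    rlang::warn("filter_rna_variants: no 'dp4' field; DP4 rule skipped")
    fail$dp4 <- rep(FALSE, L)
  }
  called_frac <- colMeans(!is.na(g))
  fail$call_rate <- called_frac < max_missing
  alt_copies <- colSums(g, na.rm = TRUE)
  tot_copies <- 2 * colSums(!is.na(g))
  minor_count <- pmin(alt_copies, tot_copies - alt_copies)
  fail$mac <- minor_count < mac
  p <- locus_maf(g)
  fail$maf <- is.na(p) | p < maf

  order_rules <- c("quality", "dp4", "call_rate", "mac", "maf")
  fail_m <- do.call(cbind, fail[order_rules])
  first_fail <- apply(fail_m, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  n_removed <- vapply(seq_along(order_rules),
                      function(i) sum(first_fail == i, na.rm = TRUE),
                      integer(1))
  keep <- is.na(first_fail)
  params <- c(sprintf("min_qual=%g", min_qual), sprintf("min_dp4=%g", min_dp4),
              sprintf("max_missing=%g", max_missing), sprintf("mac=%g", mac),
              sprintf("maf=%g", maf))
  report <- new_filter_report(
    rules = tibble::tibble(rule = order_rules, params = params,
                           n_removed = n_removed),
    n_input = L,
    n_output = sum(keep),
    multi_rule = locus_ids(gm)[rowSums(fail_m) > 1]
  )
  list(gm = subset_geno(gm, loci = keep), report = report)
}

new_filter_report <- function(rules, n_input, n_output, multi_rule) {
  stopifnot(n_input == n_output + sum(rules$n_removed))
  structure(rules, n_input = n_input, n_output = n_output,
            multi_rule = multi_rule,
            class = c("filter_report", class(rules)))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d loci in, %d out (%d flagged by >1 rule)\n",
              attr(x, "n_input"), attr(x, "n_output"),
              length(attr(x, "multi_rule"))))
  NextMethod()
}

#' One-line summary of a filter report
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return A one-row tibble with input/output/removed locus counts.
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(
    n_input = attr(x, "n_input"),
    n_output = attr(x, "n_output"),
    n_removed = sum(x$n_removed),
    n_multi_rule = length(attr(x, "multi_rule"))
  )
}
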