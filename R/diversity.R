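# Per-population, per-locus sufficient statistics on non-missing calls:
# n (individuals called), x (alternate gene copies), het (heterozygote count).
# Each is a pops x loci matrix.
pop_locus_counts <- function(gm, pops) {
  pops <- align_pops(gm, pops)
  g <- gm$genotypes
  called <- !is.na(g)
  g0 <- g
  g0[!called] <- 0L
  n <- rowsum(called + 0L, pops)
  x <- rowsum(g0, pops)
  het <- rowsum((g == 1L & called) + 0L, pops)
  list(pops = levels(pops), n = n, x = x, het = het)
}

#' Observed heterozygosity per population and locus
#'
#' Ho at a locus is the fraction of heterozygous genotypes among non-missing
#' calls in that population. Loci with no calls in a population are skipped
#' (`NA`). The multilocus value reported by [diversity_report()] is the mean
#' over loci.
#'
#' @param gm A [geno_matrix()].
#' @param pops Population labels: a factor/character aligned with samples, or
#'   a sample-metadata data frame with `sample_id` and `locality`.
#' @return A tibble: `pop`, `locus_id`, `ho`.
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(1L, 1L, 0L, 2L), 4, 1))
#' observed_heterozygosity(gm, rep("A", 4))
observed_heterozygosity <- function(gm, pops) {
  cc <- pop_locus_counts(gm, pops)
  if (any(rowSums(cc$n) == 0)) rlang::abort("empty population")
  ho <- ifelse(cc$n > 0, cc$het / cc$n, NA_real_)
  per_locus_long(ho, cc$pops, locus_ids(gm), "ho")
}

#' Unbiased expected heterozygosity per population and locus
#'
#' Nei's unbiased gene diversity on `k` non-missing gene copies:
#' `He = k/(k-1) * (1 - p^2 - q^2)` with `p` the alternate-allele frequency
#' among non-missing calls. Loci with fewer than 2 gene copies in a
#' population are skipped (`NA`). Per locus this equals the mean pairwise
#' difference between gene copies, i.e. the per-locus nucleotide diversity
#' summed by [theta_pi()].
#'
#' @inheritParams observed_heterozygosity
#' @return A tibble: `pop`, `locus_id`, `he`.
#' @export
expected_heterozygosity <- function(gm, pops) {
  cc <- pop_locus_counts(gm, pops)
  if (any(rowSums(cc$n) == 0)) rlang::abort("empty population")
  k <- 2 * cc$n
  p <- ifelse(k > 0, cc$x / k, NA_real_)
  he <- ifelse(k >= 2, k / (k - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
  per_locus_long(he, cc$pops, locus_ids(gm), "he")
}

#' Nucleotide diversity over SNP loci per population
#'
#' Per locus, `pi_l = 2 x (k - x) / (k (k - 1))` with `x` alternate gene
#' copies among `k` non-missing copies — the mean pairwise difference between
#' gene copies at that locus. The reported theta-pi is the *sum* over loci
#' (the mean pairwise multilocus genotype difference); per-site normalization
#' is available with `per_site = TRUE`.
#'
#' @inheritParams observed_heterozygosity
#' @param per_site If `TRUE`, divide the sum by the number of contributing
#'   loci.
#' @return A tibble: `pop`, `theta_pi`, `n_loci_used`.
#' @export
theta_pi <- function(gm, pops, per_site = FALSE) {
  cc <- pop_locus_counts(gm, pops)
  k <- 2 * cc$n
  pi_l <- ifelse(k >= 2, 2 * cc$x * (k - cc$x) / (k * (k - 1)), NA_real_)
  used <- rowSums(!is.na(pi_l))
  tp <- rowSums(pi_l, na.rm = TRUE)
  if (per_site) tp <- ifelse(used > 0, tp / used, NA_real_)
  tibble::tibble(pop = cc$pops, theta_pi = unname(tp),
                 n_loci_used = unname(used))
}

#' Multilocus inbreeding coefficient FIS per population
#'
#' `FIS = 1 - sum(Ho_l) / sum(He_l)` over loci polymorphic within the
#' population (ratio of sums, the multilocus convention). Significance by
#' permutation: alleles are shuffled among individuals within the population
#' at each locus (destroying heterozygote deficit/excess while preserving
#' allele frequencies); the two-sided p-value is the fraction of permuted
#' `|FIS|` at least as large as observed, with the +1 correction.
#' `He` sums of zero give `FIS = NA`.
#'
#' @inheritParams observed_heterozygosity
#' @param n_perm Number of within-population allele permutations (default
#'   10,000); 0 skips the test.
#' @param seed Integer seed for the permutations.
#' @return A tibble: `pop`, `fis`, `p_value` (`NA` when `n_perm = 0` or FIS
#'   undefined).
#' @export
fis <- function(gm, pops, n_perm = 10000, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  cc <- pop_locus_counts(gm, pops_f)
  fis_from_counts <- function(n, x, het) {
    k <- 2 * n
    p <- ifelse(k > 0, x / k, NA_real_)
    he <- ifelse(k >= 2, k / (k - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
    ho <- ifelse(n > 0, het / n, NA_real_)
    poly <- !is.na(he) & he > 0
    if (!any(poly)) return(NA_real_)
    1 - sum(ho[poly]) / sum(he[poly])
  }
  obs <- vapply(seq_along(cc$pops), function(i) {
    fis_from_counts(cc$n[i, ], cc$x[i, ], cc$het[i, ])
  }, numeric(1))

  pv <- rep(NA_real_, length(cc$pops))
  if (n_perm > 0) {
    set.seed(seed)
    g <- gm$genotypes
    for (i in seq_along(cc$pops)) {
      if (is.na(obs[i])) next
      sub <- g[pops_f == cc$pops[i], , drop = FALSE]
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm <- apply(sub, 2, shuffle_alleles)
        n <- colSums(!is.na(perm))
        x <- colSums(perm, na.rm = TRUE)
        het <- colSums(perm == 1L, na.rm = TRUE)
        f <- fis_from_counts(n, x, het)
        if (!is.na(f) && abs(f) >= abs(obs[i])) exceed <- exceed + 1L
      }
      pv[i] <- (1 + exceed) / (n_perm + 1)
    }
  }
  tibble::tibble(pop = cc$pops, fis = obs, p_value = pv)
}

# Shuffle the gene copies of one locus among the called individuals of a
# population and re-pair them into genotypes.
shuffle_alleles <- function(geno) {
  called <- which(!is.na(geno))
  if (length(called) < 2) return(geno)
  copies <- c(rep(1L, sum(geno[called])),
              rep(0L, 2 * length(called) - sum(geno[called])))
  copies <- sample(copies)
  geno[called] <- copies[seq_along(called)] +
    copies[length(called) + seq_along(called)]
  geno
}

#' Compare observed and expected heterozygosity across loci
#'
#' Bartlett's test for equality of variances of the per-locus Ho and He
#' vectors, and a paired t-test for equality of their means. Per-locus values
#' are population-size-weighted means across populations when `pops` is
#' given, pooled across all samples otherwise.
#'
#' @inheritParams observed_heterozygosity
#' @return A one-row tibble: `bartlett_stat`, `bartlett_p`, `paired_t_stat`,
#'   `paired_t_p`, `n_loci`.
#' @export
compare_ho_he <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- rep("all", n_samples(gm))
  cc <- pop_locus_counts(gm, pops)
  k <- 2 * cc$n
  p <- ifelse(k > 0, cc$x / k, NA_real_)
  he_m <- ifelse(k >= 2, k / (k - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
  ho_m <- ifelse(cc$n > 0, cc$het / cc$n, NA_real_)
  w <- cc$n
  wsum <- colSums(w * !is.na(he_m))
  ho <- colSums(ho_m * w, na.rm = TRUE) / wsum
  he <- colSums(he_m * w, na.rm = TRUE) / wsum
  ok <- is.finite(ho) & is.finite(he)
  ho <- ho[ok]; he <- he[ok]
  if (length(ho) < 2) rlang::abort("compare_ho_he needs >= 2 loci")
  b <- if (stats::sd(ho) == 0 && stats::sd(he) == 0) {
    list(statistic = 0, p.value = 1)  # two degenerate equal-variance vectors
  } else {
    stats::bartlett.test(list(ho = ho, he = he))
  }
  tt <- if (stats::sd(ho - he) == 0) {
    list(statistic = if (all(ho == he)) 0 else Inf * sign(mean(ho - he)),
         p.value = if (all(ho == he)) 1 else 0)
  } else {
    stats::t.test(ho, he, paired = TRUE)
  }
  tibble::tibble(
    bartlett_stat = unname(b$statistic), bartlett_p = b$p.value,
    paired_t_stat = unname(tt$statistic), paired_t_p = tt$p.value,
    n_loci = length(ho)
  )
}

#' Per-population diversity table
#'
#' The standard diversity summary, one row per population: sample size,
#' nucleotide diversity over loci (theta-pi, summed), multilocus mean Ho and
#' unbiased He, and FIS with its permutation p-value.
#'
#' @inheritParams fis
#' @return A tibble: `pop`, `n`, `theta_pi`, `ho`, `he`, `fis`, `fis_p`.
#' @export
diversity_report <- function(gm, pops, n_perm = 10000, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  ho <- observed_heterozygosity(gm, pops_f) |>
    dplyr::summarise(ho = mean(.data$ho, na.rm = TRUE), .by = "pop")
  he <- expected_heterozygosity(gm, pops_f) |>
    dplyr::summarise(he = mean(.data$he, na.rm = TRUE), .by = "pop")
  tp <- theta_pi(gm, pops_f)
  fi <- fis(gm, pops_f, n_perm = n_perm, seed = seed)
  n_tbl <- tibble::tibble(pop = levels(pops_f),
                          n = as.integer(table(pops_f)))
  n_tbl |>
    dplyr::left_join(tp[, c("pop", "theta_pi")], by = "pop") |>
    dplyr::left_join(ho, by = "pop") |>
    dplyr::left_join(he, by = "pop") |>
    dplyr::left_join(fi |> dplyr::rename(fis_p = "p_value"), by = "pop")
}

per_locus_long <- function(m, pops, loci, value_name) {
  out <- tibble::tibble(
    pop = rep(pops, times = ncol(m)),
    locus_id = rep(loci, each = nrow(m)),
    value = as.numeric(m)
  )
  names(out)[3] <- value_name
  out
}
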