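#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions genotypic variance among regions, among localities within
#' regions, and within localities, from the squared Euclidean distances
#' between individual allele-count vectors (0/1/2 per locus). Missing calls
#' are pairwise-deleted and each pairwise distance rescaled by
#' `n_loci / n_loci_compared`. Variance components come from the standard
#' moment equations on the mean squares; Phi statistics are
#' `Phi_CT = s2_a / s2_total`, `Phi_SC = s2_b / (s2_b + s2_c)`,
#' `Phi_ST = (s2_a + s2_b) / s2_total`. Negative components are reported as
#' estimated and flagged. With fewer than two regions the design collapses
#' to two levels (among/within locality, `Phi_ST` only).
#'
#' Permutation p-values: `Phi_ST` permutes individuals across all
#' localities; `Phi_SC` permutes individuals among localities within their
#' region; `Phi_CT` permutes whole localities among regions.
#'
#' @inheritParams observed_heterozygosity
#' @param regions Region label per sample (or per locality via the metadata
#'   data frame in `pops`); `NULL` gives the 2-level design.
#' @param n_perm Number of permutations per statistic (default 1,000).
#' @param seed Integer seed.
#' @return An object of class `amova_result`: `components` tibble (`source`,
#'   `df`, `SS`, `MS`, `sigma2`, `pct`), `phi` tibble (`statistic`, `value`,
#'   `p_value`), `negative_components` flag.
#' @export
amova <- function(gm, pops, regions = NULL, n_perm = 1000, seed = 1L) {
  if (is.data.frame(pops) && is.null(regions) && "region" %in% names(pops)) {
    m <- match(sample_ids(gm), pops$sample_id)
    regions <- pops$region[m]
  }
  pops_f <- align_pops(gm, pops)
  singleton <- names(which(table(pops_f) < 2))
  if (length(singleton)) {
    rlang::warn(paste("amova: excluding singleton localities:",
                      paste(singleton, collapse = ", ")))
    keep <- !(pops_f %in% singleton)
    gm <- subset_geno(gm, samples = which(keep))
    if (!is.null(regions)) regions <- regions[keep]
    pops_f <- droplevels(pops_f[keep])
  }
  g <- gm$genotypes
  L <- ncol(g)
  # squared Euclidean distances with pairwise deletion, rescaled to L loci
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  g0 <- matrix(as.numeric(g0), nrow(g), ncol(g))
  sq <- g0^2
  cross <- tcrossprod(g0)
  sum_i <- tcrossprod(sq, obs + 0)        # sum over loci observed in both
  shared <- tcrossprod(obs + 0)
  d2 <- sum_i + t(sum_i) - 2 * cross
  d2 <- ifelse(shared > 0, d2 * L / shared, 0)
  diag(d2) <- 0

  three_level <- !is.null(regions) && length(unique(regions)) >= 2
  reg_f <- if (three_level) factor(regions) else NULL
  res <- amova_decompose(d2, pops_f, reg_f)

  set.seed(seed)
  phi_p <- rep(NA_real_, nrow(res$phi))
  if (n_perm > 0) {
    n <- nrow(d2)
    count <- stats::setNames(integer(nrow(res$phi)), res$phi$statistic)
    for (b in seq_len(n_perm)) {
      # Phi_ST: individuals across everything
      perm_all <- sample.int(n)
      r1 <- amova_decompose(d2[perm_all, perm_all], pops_f, reg_f)
      if (phi_ge(r1, res, "Phi_ST")) count["Phi_ST"] <- count["Phi_ST"] + 1L
      if (three_level) {
        # Phi_SC: individuals among localities within regions
        perm_wg <- seq_len(n)
        for (rg in levels(reg_f)) {
          idx <- which(reg_f == rg)
          perm_wg[idx] <- idx[sample.int(length(idx))]
        }
        r2 <- amova_decompose(d2[perm_wg, perm_wg], pops_f, reg_f)
        if (phi_ge(r2, res, "Phi_SC")) count["Phi_SC"] <- count["Phi_SC"] + 1L
        # Phi_CT: whole localities among regions
        loc_lv <- levels(pops_f)
        loc_reg <- reg_f[match(loc_lv, pops_f)]
        new_reg_by_loc <- sample(loc_reg)
        reg_perm <- new_reg_by_loc[match(pops_f, loc_lv)]
        r3 <- amova_decompose(d2, pops_f, factor(reg_perm))
        if (phi_ge(r3, res, "Phi_CT")) count["Phi_CT"] <- count["Phi_CT"] + 1L
      }
    }
    phi_p <- (1 + as.numeric(count)) / (n_perm + 1)
  }
  res$phi$p_value <- phi_p
  structure(list(components = res$components, phi = res$phi,
                 negative_components = any(res$components$sigma2 < 0),
                 n_perm = n_perm),
            class = "amova_result")
}

phi_ge <- function(perm, obs, stat) {
  a <- perm$phi$value[perm$phi$statistic == stat]
  b <- obs$phi$value[obs$phi$statistic == stat]
  is.finite(a) && is.finite(b) && a >= b
}

# Sum-of-squares decomposition from a squared-distance matrix. SS of a group
# of indices = sum of within-group squared distances / group size.
ss_of <- function(d2, idx) sum(d2[idx, idx]) / (2 * length(idx))

amova_decompose <- function(d2, pops_f, reg_f = NULL) {
  n <- nrow(d2)
  P <- nlevels(pops_f)
  ss_total <- ss_of(d2, seq_len(n))
  ss_wp <- sum(vapply(levels(pops_f),
                      function(p) ss_of(d2, which(pops_f == p)), numeric(1)))
  n_p <- as.numeric(table(pops_f))

  if (is.null(reg_f)) {
    df <- c(P - 1, n - P)
    ss <- c(ss_total - ss_wp, ss_wp)
    ms <- ss / df
    n0 <- (n - sum(n_p^2) / n) / (P - 1)
    s2c <- ms[2]
    s2b <- (ms[1] - s2c) / n0
    tot <- s2b + s2c
    components <- tibble::tibble(
      source = c("among_locality", "within_locality"),
      df = df, SS = ss, MS = ms,
      sigma2 = c(s2b, s2c),
      pct = 100 * c(s2b, s2c) / tot
    )
    phi <- tibble::tibble(statistic = "Phi_ST", value = s2b / tot)
    return(list(components = components, phi = phi))
  }

  R <- nlevels(reg_f)
  ss_wr <- sum(vapply(levels(reg_f),
                      function(r) ss_of(d2, which(reg_f == r)), numeric(1)))
  ss_ag <- ss_total - ss_wr
  ss_ap <- ss_wr - ss_wp
  df <- c(R - 1, P - R, n - P)
  ss <- c(ss_ag, ss_ap, ss_wp)
  ms <- ss / df

  n_g <- as.numeric(table(reg_f))
  # population sizes grouped by region
  reg_of_pop <- reg_f[match(levels(pops_f), pops_f)]
  sum_np2_over_ng <- sum(vapply(levels(reg_f), function(r) {
    sum(n_p[reg_of_pop == r]^2) / sum(n_p[reg_of_pop == r])
  }, numeric(1)))
  n1 <- (n - sum_np2_over_ng) / (P - R)
  n2 <- (sum_np2_over_ng - sum(n_p^2) / n) / (R - 1)
  n3 <- (n - sum(n_g^2) / n) / (R - 1)

  s2c <- ms[3]
  s2b <- (ms[2] - s2c) / n1
  s2a <- (ms[1] - s2c - n2 * s2b) / n3
  tot <- s2a + s2b + s2c
  components <- tibble::tibble(
    source = c("among_region", "among_locality_within_region",
               "within_locality"),
    df = df, SS = ss, MS = ms,
    sigma2 = c(s2a, s2b, s2c),
    pct = 100 * c(s2a, s2b, s2c) / tot
  )
  phi <- tibble::tibble(
    statistic = c("Phi_CT", "Phi_SC", "Phi_ST"),
    value = c(s2a / tot, s2b / (s2b + s2c), (s2a + s2b) / tot)
  )
  list(components = components, phi = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(as.data.frame(x$components), row.names = FALSE)
  print(as.data.frame(x$phi), row.names = FALSE)
  if (x$negative_components) {
    cat("note: negative variance component(s) reported as estimated\n")
  }
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$components

#' @export
glance.amova_result <- function(x, ...) {
  out <- tidyr::pivot_wider(x$phi, names_from = "statistic",
                            values_from = c("value", "p_value"))
  out$negative_components <- x$negative_components
  out
}
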