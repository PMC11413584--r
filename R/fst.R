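# Vectorized Weir & Cockerham (1984) variance components for every locus.
# pops: factor aligned with samples. Returns tibble with a, b, c, theta per
# locus; loci where fewer than 2 populations have calls, or where the mean
# sample size is <= 1, get NA components.
wc_components <- function(gm, pops) {
  cc <- pop_locus_counts(gm, pops)
  n <- cc$n                       # pops x loci individuals called
  x <- cc$x                       # alt gene copies
  het <- cc$het
  p <- ifelse(n > 0, x / (2 * n), 0)
  h <- ifelse(n > 0, het / n, 0)
  present <- n > 0

  r <- colSums(present)
  N <- colSums(n)
  nbar <- N / r
  ok <- r >= 2 & nbar > 1
  n_c <- (N - colSums(n^2) / N) / (r - 1)
  pbar <- colSums(n * p) / N
  s2 <- colSums(n * (p - rep(pbar, each = nrow(n)))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / N

  a <- nbar / n_c *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cmp <- hbar / 2

  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cmp[!ok] <- NA_real_
  tot <- a + b + cmp
  tibble::tibble(
    locus_id = locus_ids(gm),
    a = unname(a), b = unname(b), c = unname(cmp),
    theta = unname(ifelse(tot != 0, a / tot, NA_real_))
  )
}

#' Weir–Cockerham FST estimator theta
#'
#' Moment estimator of FST from the among-population (`a`), among-individual-
#' within-population (`b`) and within-individual (`c`) variance components of
#' Weir & Cockerham (1984), computed per locus with pairwise deletion of
#' missing calls. The multilocus estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)`; loci monomorphic overall contribute zeros to
#' both sums. An optional permutation test shuffles individuals across
#' populations and recomputes the multilocus theta.
#'
#' @inheritParams observed_heterozygosity
#' @param n_perm Number of label permutations for the global test (0 = none).
#' @param seed Integer seed.
#' @return An object of class `fst_result`: list with `per_locus` (tibble:
#'   `locus_id`, `a`, `b`, `c`, `theta`), `theta` (multilocus), `p_value`
#'   (or `NA`), `n_perm`.
#' @export
#' @examples
#' g <- matrix(c(0L, 0L, 2L, 2L), 4, 1)
#' wc_theta(geno_matrix(g), c("A", "A", "B", "B"))$theta
wc_theta <- function(gm, pops, n_perm = 0, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  per_locus <- wc_components(gm, pops_f)
  theta <- multilocus_theta(per_locus)
  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pops_f)
      t_b <- multilocus_theta(wc_components(gm, perm))
      if (!is.na(t_b) && t_b >= theta) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(per_locus = per_locus, theta = theta, p_value = p_value,
                 n_perm = n_perm),
            class = "fst_result")
}

multilocus_theta <- function(per_locus) {
  ok <- stats::complete.cases(per_locus[, c("a", "b", "c")])
  denom <- sum(per_locus$a[ok] + per_locus$b[ok] + per_locus$c[ok])
  if (denom == 0) return(NA_real_)
  sum(per_locus$a[ok]) / denom
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> multilocus theta = %.4f", x$theta))
  if (!is.na(x$p_value)) cat(sprintf(" (p = %.4g, %d perms)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(theta = x$theta, p_value = x$p_value, n_perm = x$n_perm,
                 n_loci = nrow(x$per_locus))
}

#' Pairwise FST between populations with permutation p-values
#'
#' [wc_theta()] applied to every population pair; the p-value for a pair is
#' the fraction of permutations (individual labels shuffled between the two
#' populations) with permuted theta at least the observed, +1-corrected.
#' Pairs where a population has fewer than 2 samples give `NA` with a
#' warning.
#'
#' @inheritParams wc_theta
#' @param n_perm Permutations per pair (default 10,000).
#' @return A tibble: `pop1`, `pop2`, `theta`, `p_value`; see [fst_matrix()]
#'   for the symmetric-matrix view.
#' @export
pairwise_fst <- function(gm, pops, n_perm = 10000, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  lv <- levels(pops_f)
  pairs <- utils::combn(lv, 2)
  set.seed(seed)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    sel <- pops_f %in% c(pa, pb)
    if (sum(pops_f == pa) < 2 || sum(pops_f == pb) < 2) {
      rlang::warn(sprintf("pairwise_fst: pair (%s, %s) has < 2 samples; NA", pa, pb))
      return(tibble::tibble(pop1 = pa, pop2 = pb,
                            theta = NA_real_, p_value = NA_real_))
    }
    sub <- subset_geno(gm, samples = which(sel))
    labs <- droplevels(pops_f[sel])
    obs <- multilocus_theta(wc_components(sub, labs))
    p <- NA_real_
    if (n_perm > 0) {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        t_b <- multilocus_theta(wc_components(sub, sample(labs)))
        if (!is.na(t_b) && t_b >= obs) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (n_perm + 1)
    }
    tibble::tibble(pop1 = pa, pop2 = pb, theta = obs, p_value = p)
  })
  dplyr::bind_rows(out)
}

#' @rdname pairwise_fst
#' @param tbl The tibble returned by `pairwise_fst()`.
#' @return For `fst_matrix()`, a symmetric matrix of theta with a zero
#'   diagonal.
#' @export
fst_matrix <- function(tbl) {
  lv <- sort(unique(c(tbl$pop1, tbl$pop2)))
  m <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(tbl))) {
    m[tbl$pop1[i], tbl$pop2[i]] <- m[tbl$pop2[i], tbl$pop1[i]] <- tbl$theta[i]
  }
  m
}
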