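#' Locality-level alternate-allele frequency matrix
#'
#' One row per locality, one column per locus: alternate gene copies over
#' non-missing gene copies. Cells with no calls are `NA` (downstream
#' ordinations mean-impute them with a log message).
#'
#' @inheritParams observed_heterozygosity
#' @return A localities x loci numeric matrix (dimnames set).
#' @export
locality_freqs <- function(gm, pops) {
  cc <- pop_locus_counts(gm, pops)
  if (any(rowSums(cc$n) == 0)) rlang::abort("empty locality")
  f <- ifelse(cc$n > 0, cc$x / (2 * cc$n), NA_real_)
  dimnames(f) <- list(cc$pops, locus_ids(gm))
  f
}

#' Principal-component contributions of SNPs
#'
#' Eigendecomposition of the covariance (default) of the centered columns of
#' a frequency matrix. The contribution of SNP `j` to axis `k` is
#' `100 * v_jk^2` with `v_k` the unit eigenvector, so contributions sum to
#' 100 per axis; axis variance percentages are `lambda_k / sum(lambda)`.
#' `NA` cells are mean-imputed (logged). With `scale = TRUE` constant
#' columns would divide by zero and are dropped (logged).
#'
#' @param freq Localities x loci frequency matrix (see [locality_freqs()]),
#'   or any observations x variables matrix.
#' @param center,scale Column centering/scaling (defaults `TRUE`/`FALSE`).
#' @return An object of class `ordination_contributions`: `eigenvalues`,
#'   `var_pct`, `contrib` (loci x axes, percent), `scores` (observations x
#'   axes), `method = "pca"`.
#' @export
pca_contributions <- function(freq, center = TRUE, scale = FALSE) {
  if (nrow(freq) < 2) rlang::abort("pca_contributions needs >= 2 observations")
  if (anyNA(freq)) {
    rlang::inform("pca_contributions: NA cells mean-imputed")
    freq <- impute_mean(freq)
  }
  if (scale) {
    const <- apply(freq, 2, stats::sd) == 0
    if (any(const)) {
      rlang::inform(sprintf(
        "pca_contributions: dropped %d constant column(s) under scaling",
        sum(const)))
      freq <- freq[, !const, drop = FALSE]
    }
  }
  pc <- stats::prcomp(freq, center = center, scale. = scale)
  eig <- pc$sdev^2
  pos <- eig > max(eig) * 1e-12
  eig <- eig[pos]
  v <- pc$rotation[, seq_along(eig), drop = FALSE]
  contrib <- 100 * v^2
  colnames(contrib) <- paste0("PC", seq_along(eig))
  scores <- pc$x[, seq_along(eig), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_along(eig))
  new_ordination(eigenvalues = eig, var_pct = 100 * eig / sum(pc$sdev^2),
                 contrib = contrib, scores = scores, method = "pca")
}

new_ordination <- function(eigenvalues, var_pct, contrib, scores, method,
                           ...) {
  structure(list(eigenvalues = eigenvalues, var_pct = var_pct,
                 contrib = contrib, scores = scores, method = method, ...),
            class = "ordination_contributions")
}

#' @export
print.ordination_contributions <- function(x, ...) {
  cat(sprintf("<ordination_contributions> %s: %d axes; leading var%%: %s\n",
              x$method, length(x$eigenvalues),
              paste(sprintf("%.1f", utils::head(x$var_pct, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ordination_contributions <- function(x, ...) {
  tibble::as_tibble(x$contrib, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "axis",
                        values_to = "contribution")
}

#' @export
glance.ordination_contributions <- function(x, ...) {
  tibble::tibble(method = x$method, n_axes = length(x$eigenvalues),
                 eigenvalue_1 = x$eigenvalues[1],
                 var_pct_1 = x$var_pct[1],
                 var_pct_2 = if (length(x$var_pct) > 1) x$var_pct[2] else NA_real_)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Step 1: PCA of the centered, mean-imputed genotype matrix, retaining
#' `n_pca` axes. Step 2: linear discriminant analysis of the retained PC
#' scores on the cluster labels, solved as the generalized eigenproblem
#' `B a = lambda W a` (between- vs pooled within-cluster covariance); each
#' discriminant eigenvalue is the between/within variance ratio along that
#' function. A singular within-cluster covariance gets a ridge (logged).
#' The SNP contribution to discriminant `f` is `100 * b_jf^2 / sum_j b_jf^2`
#' where `b_f` is the PCA-loading matrix times the discriminant vector.
#'
#' @inheritParams observed_heterozygosity
#' @param clusters Cluster label per sample (factor/character), e.g. the
#'   locality.
#' @param n_pca Number of PCs retained (see [optimize_a_score()]).
#' @return An `ordination_contributions` object with `method = "dapc"` and
#'   extra fields `n_pca`, `discriminant_eigenvalues` and `scores`
#'   (individual discriminant scores, columns `LD1`, `LD2`, ...).
#' @export
dapc_fit <- function(gm, clusters, n_pca) {
  cl <- factor(clusters)
  if (nlevels(cl) < 2) rlang::abort("dapc_fit needs >= 2 clusters")
  if (n_pca < 1) rlang::abort("n_pca must be >= 1")
  if (n_pca >= n_samples(gm)) rlang::abort("n_pca must be < number of samples")
  Y <- scale(impute_mean(gm$genotypes), center = TRUE, scale = FALSE)
  pc <- stats::prcomp(Y, center = FALSE)
  n_pca <- min(n_pca, sum(pc$sdev^2 > max(pc$sdev^2) * 1e-12))
  S <- pc$x[, seq_len(n_pca), drop = FALSE]
  P <- pc$rotation[, seq_len(n_pca), drop = FALSE]

  n <- nrow(S)
  k <- nlevels(cl)
  mu <- colMeans(S)
  W <- matrix(0, n_pca, n_pca)
  B <- matrix(0, n_pca, n_pca)
  for (g in levels(cl)) {
    Sg <- S[cl == g, , drop = FALSE]
    ng <- nrow(Sg)
    mg <- colMeans(Sg)
    if (ng > 1) W <- W + crossprod(scale(Sg, center = mg, scale = FALSE))
    B <- B + ng * tcrossprod(mg - mu)
  }
  W <- W / (n - k)
  B <- B / (k - 1)
  ridge <- 0
  if (rcond_sym(W) < 1e-10) {
    ridge <- 1e-8 * mean(diag(W))
    rlang::inform("dapc_fit: singular within-cluster covariance; ridge added")
  }
  M <- solve(W + diag(ridge, n_pca), B)
  ev <- eigen(M)
  n_df <- min(k - 1, n_pca)
  vals <- Re(ev$values)[seq_len(n_df)]
  A <- Re(ev$vectors)[, seq_len(n_df), drop = FALSE]
  # scale each discriminant vector so its eigenvalue is the raw
  # between/within variance ratio along the function
  lambda <- vapply(seq_len(n_df), function(f) {
    a <- A[, f]
    (a %*% B %*% a) / (a %*% W %*% a)
  }, numeric(1))
  ord <- order(lambda, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  lambda <- lambda[ord]

  b <- P %*% A                                   # loci x functions
  contrib <- 100 * sweep(b^2, 2, colSums(b^2), "/")
  colnames(contrib) <- paste0("LD", seq_len(n_df))
  rownames(contrib) <- locus_ids(gm)
  scores <- S %*% A
  colnames(scores) <- paste0("LD", seq_len(n_df))
  rownames(scores) <- sample_ids(gm)
  new_ordination(
    eigenvalues = lambda,
    var_pct = 100 * lambda / sum(lambda),
    contrib = contrib, scores = scores, method = "dapc",
    n_pca = n_pca, discriminant_eigenvalues = lambda, clusters = cl
  )
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Choose the number of retained PCs by the a-score
#'
#' For each candidate `n_pca`, fits the DAPC, reassigns each individual to
#' the cluster with the nearest centroid in discriminant space, and scores
#' `a = mean over clusters of (observed reassignment proportion - mean
#' reassignment proportion over n_sim random-label refits)`. Returns the
#' arg-max over the evaluated grid (ties give the smallest `n_pca`).
#'
#' @inheritParams dapc_fit
#' @param n_pca_grid Integer vector of candidate PC counts.
#' @param n_sim Label permutations per candidate (default 10).
#' @param seed Integer seed.
#' @return The optimal `n_pca` (integer) with attribute `a_score` (named
#'   vector over the grid).
#' @export
optimize_a_score <- function(gm, clusters, n_pca_grid, n_sim = 10, seed = 1L) {
  cl <- factor(clusters)
  set.seed(seed)
  score_of <- function(labels, n_pca) {
    fit <- dapc_fit(gm, labels, n_pca)
    reassign <- nearest_centroid(fit$scores, labels)
    tapply(reassign == labels, labels, mean)
  }
  a <- vapply(n_pca_grid, function(np) {
    obs <- score_of(cl, np)
    perm <- replicate(n_sim, {
      mean(score_of(sample(cl), np), na.rm = TRUE)
    })
    mean(obs, na.rm = TRUE) - mean(perm)
  }, numeric(1))
  names(a) <- n_pca_grid
  best <- as.integer(names(a)[which.max(a)])
  structure(best, a_score = a)
}

nearest_centroid <- function(scores, labels) {
  cent <- rowsum(scores, labels) / as.numeric(table(labels))
  d <- outer(rowSums(scores^2), rowSums(cent^2), "+") -
    2 * scores %*% t(cent)
  factor(rownames(cent)[max.col(-d)], levels = levels(labels))
}

#' Find genetic clusters by k-means + BIC on PC scores
#'
#' k-means (multiple restarts, fixed seed) on the retained PC scores for
#' `k = 1..k_max`; `BIC(k) = n log(W_k / n) + k log(n)` with `W_k` the total
#' within-cluster sum of squares. Returns the arg-min-BIC assignment and the
#' curve.
#'
#' @inheritParams dapc_fit
#' @param k_max Largest number of clusters tried (truncated at `n`).
#' @param n_pca PCs retained before clustering.
#' @param nstart k-means restarts (default 10).
#' @param seed Integer seed.
#' @return A list: `assignments` (factor), `k` (chosen), `bic` (tibble
#'   `k`, `bic`).
#' @export
find_clusters_bic <- function(gm, k_max, n_pca, nstart = 10, seed = 1L) {
  Y <- scale(impute_mean(gm$genotypes), center = TRUE, scale = FALSE)
  pc <- stats::prcomp(Y, center = FALSE)
  n_pca <- min(n_pca, ncol(pc$x))
  S <- pc$x[, seq_len(n_pca), drop = FALSE]
  n <- nrow(S)
  k_max <- min(k_max, n)
  set.seed(seed)
  fits <- purrr::map(seq_len(k_max), function(k) {
    if (k == 1) {
      list(cluster = rep(1L, n),
           wss = sum(scale(S, scale = FALSE)^2))
    } else {
      km <- stats::kmeans(S, centers = k, nstart = nstart)
      list(cluster = km$cluster, wss = km$tot.withinss)
    }
  })
  bic <- vapply(fits, function(f) n * log(f$wss / n) + 0, numeric(1)) +
    seq_len(k_max) * log(n)
  k_best <- which.min(bic)
  list(
    assignments = factor(fits[[k_best]]$cluster),
    k = k_best,
    bic = tibble::tibble(k = seq_len(k_max), bic = bic)
  )
}

#' Rank SNPs by descending contribution
#'
#' Stable descending order; ties are broken by locus id (lexicographic) so
#' the rank is deterministic.
#'
#' @param contrib Named numeric vector (names = locus ids) or one axis
#'   column of an `ordination_contributions` object's `contrib` matrix.
#' @return A tibble: `rank`, `locus_id`, `contribution`.
#' @export
rank_contributions <- function(contrib) {
  if (is.null(names(contrib))) names(contrib) <- seq_along(contrib)
  if (any(!is.finite(contrib))) rlang::abort("non-finite contribution")
  ord <- order(-contrib, names(contrib), method = "radix")
  tibble::tibble(
    rank = seq_along(contrib),
    locus_id = names(contrib)[ord],
    contribution = unname(contrib[ord])
  )
}

#' Cumulative contribution of the top-m SNPs
#'
#' @param contrib Numeric vector of contributions.
#' @param m Top depth.
#' @return Percent of the total contribution carried by the `m` largest
#'   values.
#' @export
cumulative_contribution <- function(contrib, m) {
  stopifnot(m <= length(contrib), m >= 0)
  if (m == 0) return(0)
  100 * sum(sort(contrib, decreasing = TRUE)[seq_len(m)]) / sum(contrib)
}

#' Iterative one-tailed Wilcoxon enrichment of kN SNPs in a contribution rank
#'
#' Walks the descending contribution rank: for each depth `m` from `start`
#' to `stop`, restricts to the top-`m` SNPs and tests whether the
#' within-top-`m` ranks of kN (non-synonymous) SNPs are smaller — nearer the
#' top — than those of the other SNPs (kS and oCDS), with a one-tailed
#' Wilcoxon rank-sum test. The exact null distribution is used when both
#' group sizes are at most 25 (ranks are distinct so there are never ties);
#' otherwise the normal approximation with continuity correction. Depths
#' where either group is empty are recorded with `p = NA`. No
#' multiple-testing correction is applied across depths — per-depth p-values
#' are reported, never a single series-level p.
#'
#' @param ranked_is_kn Logical vector in rank order (`TRUE` = kN SNP),
#'   typically `rank_contributions(...)$locus_id %in% kn_ids`.
#' @param start,stop First and last depth (defaults 10 and 200).
#' @param alpha Significance level annotated in the output (default 0.05).
#' @return A tibble of class `enrichment_series`: `m`, `n_kn`, `n_other`,
#'   `statistic` (Wilcoxon W for the kN group), `p_value`, `significant`.
#' @export
#' @examples
#' iterative_wilcoxon(c(TRUE, TRUE, TRUE, rep(FALSE, 7)), start = 10,
#'                    stop = 10)
iterative_wilcoxon <- function(ranked_is_kn, start = 10, stop = 200,
                               alpha = 0.05) {
  if (stop < start) rlang::abort("stop must be >= start")
  if (stop > length(ranked_is_kn)) {
    rlang::abort("stop exceeds the number of ranked SNPs")
  }
  rows <- purrr::map(start:stop, function(m) {
    lab <- ranked_is_kn[seq_len(m)]
    n1 <- sum(lab)
    n2 <- m - n1
    if (n1 == 0 || n2 == 0) {
      return(tibble::tibble(m = m, n_kn = n1, n_other = n2,
                            statistic = NA_real_, p_value = NA_real_))
    }
    r <- seq_len(m)
    wt <- stats::wilcox.test(r[lab], r[!lab], alternative = "less",
                             exact = (n1 <= 25 && n2 <= 25), correct = TRUE)
    tibble::tibble(m = m, n_kn = n1, n_other = n2,
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  class(out) <- c("enrichment_series", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Run the enrichment series on every axis of an ordination
#'
#' Convenience wrapper: ranks each axis of an `ordination_contributions`
#' object, labels kN SNPs, and runs [iterative_wilcoxon()] per axis.
#'
#' @param ord An `ordination_contributions` object.
#' @param kn_ids Locus ids classified as non-synonymous.
#' @param axes Which axes (default the first two).
#' @inheritParams iterative_wilcoxon
#' @return A tibble: the per-axis series row-bound with an `axis` column.
#' @export
enrichment_by_axis <- function(ord, kn_ids, axes = 1:2, start = 10,
                               stop = 200, alpha = 0.05) {
  axes <- axes[axes <= ncol(ord$contrib)]
  purrr::map(axes, function(k) {
    rk <- rank_contributions(ord$contrib[, k])
    stop_k <- min(stop, nrow(rk))
    if (stop_k < start) {
      rlang::inform(sprintf(
        "enrichment_by_axis: only %d ranked SNPs (< start = %d); axis skipped",
        nrow(rk), start))
      return(NULL)
    }
    ser <- iterative_wilcoxon(rk$locus_id %in% kn_ids, start = start,
                              stop = stop_k, alpha = alpha)
    dplyr::mutate(ser, axis = colnames(ord$contrib)[k], .before = 1)
  }) |> dplyr::bind_rows()
}
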