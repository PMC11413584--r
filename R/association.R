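#' Greedy collinearity pruning of environmental predictors
#'
#' Computes pairwise absolute Pearson correlations among predictors and,
#' while any pair exceeds `threshold`, drops the later-listed member of the
#' worst offending pair. Constant predictors (undefined correlation) are
#' dropped up front with a warning.
#'
#' @param env Tibble with a `locality` column plus numeric predictors.
#' @param threshold Absolute correlation above which a pair is collinear
#'   (default 0.8).
#' @return The pruned env tibble, with attribute `removed`: a tibble logging
#'   each removal (`dropped`, `kept`, `abs_r`).
#' @export
#' @examples
#' env <- tibble::tibble(locality = c("a", "b", "c"),
#'                       A = c(1, 2, 3), B = c(1, 2, 3.1), C = c(3, 1, 2))
#' names(prune_collinear(env))
prune_collinear <- function(env, threshold = 0.8) {
  preds <- setdiff(names(env), "locality")
  if (length(preds) < 2) rlang::abort("prune_collinear needs >= 2 predictors")
  if (nrow(env) < 3) rlang::abort("prune_collinear needs >= 3 localities")
  x <- as.matrix(env[, preds])
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    rlang::warn(paste("prune_collinear: dropping constant predictor(s):",
                      paste(preds[const], collapse = ", ")))
  }
  keep <- preds[!const]
  removed <- list()
  if (any(const)) {
    removed <- purrr::map(preds[const], function(p) {
      tibble::tibble(dropped = p, kept = NA_character_, abs_r = NA_real_)
    })
  }
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    w <- which(r == max(r), arr.ind = TRUE)[1, ]
    # drop the later-listed member of the worst pair
    pair <- sort(w)
    drop_name <- keep[pair[2]]
    removed[[length(removed) + 1]] <-
      tibble::tibble(dropped = drop_name, kept = keep[pair[1]],
                     abs_r = max(r))
    keep <- setdiff(keep, drop_name)
  }
  out <- env[, c("locality", keep)]
  attr(out, "removed") <- dplyr::bind_rows(removed)
  out
}

#' Redundancy-analysis outlier scan of genotypes on environment
#'
#' Constrained ordination of the centered (mean-imputed) genotype matrix on
#' the per-individual environmental predictors: the eigendecomposition of the
#' fitted values of the multivariate regression of genotypes on predictors.
#' Full-model and per-axis significance come from permutation of the rows of
#' the predictor matrix (pseudo-F for the full model; eigenvalue exceedance
#' per axis). A SNP is flagged when, on any constrained axis with permutation
#' p at most `axis_alpha`, its loading lies more than `sd_cutoff` standard
#' deviations from the mean loading of that axis.
#'
#' Individuals inherit their locality's predictor values: pass `env` with one
#' row per locality and `pops` mapping samples to localities.
#'
#' @inheritParams observed_heterozygosity
#' @param env Environment tibble (`locality` + numeric predictors).
#' @param n_perm Number of row permutations (default 1,000).
#' @param sd_cutoff Loading outlier cutoff in SD units (default 3).
#' @param axis_alpha Per-axis significance level used to select axes for the
#'   loading rule (default 0.01).
#' @param seed Integer seed.
#' @return An object of class `rda_result`: `eigenvalues`, `site_scores`,
#'   `loadings` (loci x axes), `full_model_p`, `axis_p`, `prop_variance`
#'   (genomic variance explained by the constrained space), `flagged`
#'   (character vector of locus ids), `flag_table` (tibble with per-axis
#'   outlier calls).
#' @export
rda_scan <- function(gm, pops, env, n_perm = 1000, sd_cutoff = 3,
                     axis_alpha = 0.01, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  X <- env_design(env, pops_f)
  if (ncol(X) >= nrow(unique(as.data.frame(X)))) {
    rlang::warn("rda_scan: predictors >= distinct localities; model is rank deficient")
  }
  Y <- scale(impute_mean(gm$genotypes), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr_x <- qr(Xc)
  q <- qr_x$rank
  Q <- qr.Q(qr_x)[, seq_len(q), drop = FALSE]

  B <- crossprod(Q, Y)                  # q x L; svd(B) = svd of fitted values
  sv <- svd(B)
  eig <- sv$d^2 / (n - 1)
  pos <- eig > max(eig) * 1e-12
  eig <- eig[pos]
  axes <- seq_along(eig)
  loadings <- sv$v[, axes, drop = FALSE]
  rownames(loadings) <- locus_ids(gm)
  colnames(loadings) <- paste0("RDA", axes)
  site_scores <- (Q %*% sv$u[, axes, drop = FALSE]) %*% diag(sv$d[axes],
                                                             length(axes))
  rownames(site_scores) <- sample_ids(gm)
  colnames(site_scores) <- paste0("RDA", axes)

  ss_tot <- sum(Y^2)
  ss_fit <- sum(B^2)
  resid_df <- n - q - 1
  f_obs <- (ss_fit / q) / ((ss_tot - ss_fit) / resid_df)

  set.seed(seed)
  exceed_f <- 0L
  exceed_axis <- integer(length(axes))
  for (b in seq_len(n_perm)) {
    Qp <- Q[sample.int(n), , drop = FALSE]
    Bp <- crossprod(Qp, Y)
    ssf <- sum(Bp^2)
    fp <- (ssf / q) / ((ss_tot - ssf) / resid_df)
    if (fp >= f_obs) exceed_f <- exceed_f + 1L
    dp <- svd(Bp, nu = 0, nv = 0)$d^2 / (n - 1)
    exceed_axis <- exceed_axis +
      (dp[seq_along(axes)] >= eig - 1e-15)
  }
  full_model_p <- (1 + exceed_f) / (n_perm + 1)
  axis_p <- (1 + exceed_axis) / (n_perm + 1)

  sig_axes <- which(axis_p <= axis_alpha)
  flag_table <- purrr::map(sig_axes, function(k) {
    ld <- loadings[, k]
    z <- (ld - mean(ld)) / stats::sd(ld)
    tibble::tibble(locus_id = names(z)[abs(z) > sd_cutoff],
                   axis = paste0("RDA", k),
                   loading = ld[abs(z) > sd_cutoff],
                   z = z[abs(z) > sd_cutoff])
  }) |> dplyr::bind_rows()
  if (!nrow(flag_table)) {
    flag_table <- tibble::tibble(locus_id = character(), axis = character(),
                                 loading = double(), z = double())
  }
  structure(list(
    eigenvalues = eig,
    site_scores = site_scores,
    loadings = loadings,
    full_model_p = full_model_p,
    axis_p = axis_p,
    prop_variance = ss_fit / ss_tot,
    flagged = unique(flag_table$locus_id),
    flag_table = flag_table,
    n_perm = n_perm
  ), class = "rda_result")
}

# Expand per-locality predictors to per-individual rows, in sample order.
env_design <- function(env, pops_f) {
  m <- match(as.character(pops_f), env$locality)
  if (anyNA(m)) {
    rlang::abort(paste("localities missing from env table:",
                       paste(unique(pops_f[is.na(m)]), collapse = ", ")))
  }
  as.matrix(env[m, setdiff(names(env), "locality")])
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "<rda_result> %d constrained axes, %.1f%% variance explained, full-model p = %.4g, %d flagged\n",
    length(x$eigenvalues), 100 * x$prop_variance, x$full_model_p,
    length(x$flagged)))
  invisible(x)
}

#' @export
tidy.rda_result <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "axis",
                        values_to = "loading") |>
    dplyr::mutate(flagged = .data$locus_id %in% x$flagged)
}

#' @export
glance.rda_result <- function(x, ...) {
  tibble::tibble(n_axes = length(x$eigenvalues),
                 prop_variance = x$prop_variance,
                 full_model_p = x$full_model_p,
                 n_flagged = length(x$flagged),
                 n_perm = x$n_perm)
}

#' Latent-factor association scan with genomic-inflation correction
#'
#' Per-predictor genotype–environment association absorbing population
#' structure with latent factors: the predictor is regressed out of the
#' centered, mean-imputed genotype matrix, the top-`K` left singular vectors
#' of the residual are taken as factors, and each SNP is tested in the linear
#' model `genotype ~ predictor + factors`. The per-SNP z-scores are rescaled
#' by the genomic inflation factor `lambda = median(z^2) / 0.454936` (the
#' median of a 1-df chi-square) and adjusted p-values are the upper tail of
#' `chi^2_1` at `z^2 / lambda`. A SNP is flagged when its adjusted p falls
#' below `alpha` for any predictor.
#'
#' @inheritParams rda_scan
#' @param K Number of latent factors (see [choose_k()]).
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @return An object of class `lfmm_result`: `z` (loci x predictors),
#'   `p_adj`, `lambda` (per predictor), `K`, `flagged`, `flag_table`.
#' @export
lfmm_scan <- function(gm, pops, env, K, alpha = 0.01, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  X <- env_design(env, pops_f)
  Y <- scale(impute_mean(gm$genotypes), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  if (K >= min(dim(Y))) rlang::abort("K must be < min(samples, loci)")
  set.seed(seed)
  preds <- colnames(X)
  z_mat <- matrix(NA_real_, ncol(Y), length(preds),
                  dimnames = list(locus_ids(gm), preds))
  lambda <- stats::setNames(numeric(length(preds)), preds)
  for (j in seq_along(preds)) {
    x <- as.numeric(scale(X[, j]))
    # one round: remove the predictor's signal, then estimate structure
    U <- NULL
    if (K > 0) {
      resid_Y <- Y - x %*% crossprod(x, Y) / sum(x^2)
      U <- svd(resid_Y, nu = K, nv = 0)$u
    }
    D <- cbind(1, x, U)
    qr_d <- qr(D)
    coefs <- qr.coef(qr_d, Y)
    res <- qr.resid(qr_d, Y)
    df <- n - ncol(D)
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qr_d))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    z <- coefs[2, ] / se
    z[!is.finite(z)] <- 0
    lambda[j] <- stats::median(z^2) / 0.454936
    z_mat[, j] <- z
  }
  p_adj <- matrix(
    stats::pchisq(sweep(z_mat^2, 2, lambda, "/"), df = 1,
                  lower.tail = FALSE),
    nrow = nrow(z_mat), dimnames = dimnames(z_mat)
  )
  flag_m <- p_adj < alpha
  flag_table <- tibble::as_tibble(p_adj, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "predictor",
                        values_to = "p_adj") |>
    dplyr::filter(.data$p_adj < alpha)
  structure(list(
    z = z_mat, p_adj = p_adj, lambda = lambda, K = K, alpha = alpha,
    flagged = rownames(flag_m)[rowSums(flag_m, na.rm = TRUE) > 0],
    flag_table = flag_table
  ), class = "lfmm_result")
}

#' @export
print.lfmm_result <- function(x, ...) {
  cat(sprintf(
    "<lfmm_result> K = %d, lambda in [%.2f, %.2f], %d flagged at alpha = %g\n",
    x$K, min(x$lambda), max(x$lambda), length(x$flagged), x$alpha))
  invisible(x)
}

#' @export
tidy.lfmm_result <- function(x, ...) {
  tibble::as_tibble(x$z, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "predictor",
                        values_to = "z") |>
    dplyr::left_join(
      tibble::as_tibble(x$p_adj, rownames = "locus_id") |>
        tidyr::pivot_longer(-"locus_id", names_to = "predictor",
                            values_to = "p_adj"),
      by = c("locus_id", "predictor")
    )
}

#' @export
glance.lfmm_result <- function(x, ...) {
  tibble::tibble(K = x$K, median_lambda = stats::median(x$lambda),
                 n_flagged = length(x$flagged), alpha = x$alpha)
}

#' Choose the number of latent factors by masked-entry cross-validation
#'
#' Masks a fraction of the entries of the centered, imputed genotype matrix
#' (replacing them with column means), computes the truncated SVD of the
#' masked matrix, and scores each candidate `K` by the reconstruction error
#' on the masked entries. Returns the arg-min `K`; deterministic under a
#' fixed seed.
#'
#' @param gm A [geno_matrix()].
#' @param k_max Largest candidate (`< min(samples, loci)`).
#' @param mask_frac Fraction of entries masked (default 0.10).
#' @param seed Integer seed.
#' @return The chosen `K` (integer, possibly 0) with attribute `cv_error`
#'   (named vector of errors for K = 0..k_max).
#' @export
choose_k <- function(gm, k_max, mask_frac = 0.10, seed = 1L) {
  Y <- impute_mean(gm$genotypes)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (k_max >= min(dim(Yc))) rlang::abort("k_max must be < min(samples, loci)")
  set.seed(seed)
  n_cells <- length(Yc)
  mask <- sample.int(n_cells, max(1, round(mask_frac * n_cells)))
  truth <- Yc[mask]
  Ym <- Yc
  Ym[mask] <- 0  # column mean of the centered matrix
  sv <- svd(Ym, nu = k_max, nv = k_max)
  errs <- numeric(k_max + 1)
  errs[1] <- mean(truth^2)  # K = 0: reconstruct by the column mean
  recon <- matrix(0, nrow(Ym), ncol(Ym))
  for (k in seq_len(k_max)) {
    recon <- recon + sv$d[k] * tcrossprod(sv$u[, k], sv$v[, k])
    errs[k + 1] <- mean((recon[mask] - truth)^2)
  }
  names(errs) <- 0:k_max
  k_best <- as.integer(names(errs)[which.min(errs)])
  structure(k_best, cv_error = errs)
}

#' Permutation FST-outlier scan
#'
#' A frequency-based outlier channel: per-locus Weir–Cockerham theta, with a
#' null distribution built by permuting individuals across populations (the
#' same permutations shared by all loci). The per-locus empirical p-value is
#' `(1 + #permuted theta >= observed) / (n_perm + 1)`; discoveries are the
#' Benjamini–Hochberg rejections at `fdr`.
#'
#' @inheritParams wc_theta
#' @param n_perm Number of label permutations (default 5,000).
#' @param fdr Benjamini–Hochberg false discovery rate (default 0.05).
#' @return An object of class `fst_scan_result`: `per_locus` tibble
#'   (`locus_id`, `theta`, `p_value`, `q_value`, `flagged`), `flagged` ids.
#' @export
fst_outlier_scan <- function(gm, pops, n_perm = 5000, fdr = 0.05, seed = 1L) {
  pops_f <- align_pops(gm, pops)
  if (nlevels(pops_f) < 2) rlang::abort("fst_outlier_scan needs >= 2 populations")
  obs <- wc_components(gm, pops_f)$theta
  obs[is.na(obs)] <- -Inf
  set.seed(seed)
  exceed <- integer(length(obs))
  for (b in seq_len(n_perm)) {
    th <- wc_components(gm, sample(pops_f))$theta
    th[is.na(th)] <- -Inf
    exceed <- exceed + (th >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  per_locus <- tibble::tibble(
    locus_id = locus_ids(gm),
    theta = ifelse(is.finite(obs), obs, NA_real_),
    p_value = p, q_value = q,
    flagged = q <= fdr
  )
  structure(list(per_locus = per_locus,
                 flagged = per_locus$locus_id[per_locus$flagged],
                 n_perm = n_perm, fdr = fdr),
            class = "fst_scan_result")
}

#' @export
print.fst_scan_result <- function(x, ...) {
  cat(sprintf("<fst_scan_result> %d of %d loci flagged at FDR %g (%d perms)\n",
              length(x$flagged), nrow(x$per_locus), x$fdr, x$n_perm))
  invisible(x)
}

#' @export
tidy.fst_scan_result <- function(x, ...) x$per_locus

#' Consensus partition of candidate loci across detection channels
#'
#' Given the per-method flagged locus sets, builds the candidate partition:
#' `consensus` (flagged by at least `min_methods` methods), `union` (flagged
#' by at least one) and `neutral` (flagged by none), plus the Venn counts of
#' every method combination.
#'
#' @param flagged Named list of character vectors of locus ids (one per
#'   method).
#' @param universe All locus ids under test.
#' @param min_methods Minimum number of agreeing methods for the consensus
#'   set (default 2).
#' @return A list of class `candidate_partition`: `per_method`, `consensus`,
#'   `union`, `neutral`, `venn` (tibble of method-combination counts),
#'   `min_methods`.
#' @export
#' @examples
#' consensus(list(a = c("l1", "l2"), b = c("l2", "l3"), c = c("l3", "l4")),
#'           paste0("l", 1:6))$consensus
consensus <- function(flagged, universe, min_methods = 2) {
  flagged <- purrr::map(flagged, intersect, universe)
  extra <- setdiff(unlist(flagged), universe)
  stopifnot(length(extra) == 0)
  counts <- rowSums(vapply(flagged, function(s) universe %in% s,
                           logical(length(universe))))
  cons <- universe[counts >= min_methods]
  uni <- universe[counts >= 1]
  neutral <- universe[counts == 0]
  membership <- vapply(flagged, function(s) universe %in% s,
                       logical(length(universe)))
  combo <- apply(membership, 1, function(z) {
    paste(names(flagged)[z], collapse = "+")
  })
  combo[combo == ""] <- "(none)"
  venn <- tibble::as_tibble(table(combo), .name_repair = ~c("methods", "n"))
  structure(list(per_method = flagged, consensus = cons, union = uni,
                 neutral = neutral, venn = venn, min_methods = min_methods),
            class = "candidate_partition")
}

#' @export
print.candidate_partition <- function(x, ...) {
  cat(sprintf(
    "<candidate_partition> consensus (>= %d methods): %d | union: %d | neutral: %d\n",
    x$min_methods, length(x$consensus), length(x$union), length(x$neutral)))
  invisible(x)
}

#' @export
tidy.candidate_partition <- function(x, ...) x$venn
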