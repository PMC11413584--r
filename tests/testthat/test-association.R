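make_assoc_fixture <- function(seed = 1, n_pops = 8, n_per_pop = 30,
                               n_loci = 1000, n_adaptive = 20, beta = 2,
                               F = 0.1, predictors = NULL) {
  p <- sim_params(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                  F = F, n_adaptive = n_adaptive, beta = beta,
                  missing_rate = 0.05, seed = seed)
  env <- if (is.null(predictors)) simulate_env(n_pops, seed = seed + 1) else
    simulate_env(n_pops, predictors, seed = seed + 1)
  sim <- simulate_genotypes(p, env)
  list(sim = sim, env = env, pops = sim$samples$locality)
}

test_that("collinearity pruning drops the later member of offending pairs", {
  env <- tibble::tibble(locality = letters[1:6],
                        A = c(1, 2, 3, 4, 5, 6))
  env$B <- env$A                      # r = 1 with A
  env$C <- c(3, 1, 4, 1, 5, 9)
  pruned <- prune_collinear(env)
  expect_equal(setdiff(names(pruned), "locality"), c("A", "C"))
  expect_equal(attr(pruned, "removed")$dropped, "B")

  # all below threshold: identity
  set.seed(2)
  env2 <- dplyr::bind_cols(tibble::tibble(locality = letters[1:20]),
                           tibble::as_tibble(matrix(rnorm(100), 20, 5,
                             dimnames = list(NULL, paste0("P", 1:5)))))
  expect_equal(names(prune_collinear(env2)), names(env2))
})

test_that("pruning a 14-predictor set with 4 planted duplicates retains 10", {
  set.seed(3)
  base <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(NULL, paste0("P", 1:10)))
  dup <- base[, 1:4] + matrix(rnorm(30 * 4, sd = 0.01), 30, 4)
  colnames(dup) <- paste0("D", 1:4)
  env <- dplyr::bind_cols(tibble::tibble(locality = paste0("l", 1:30)),
                          tibble::as_tibble(cbind(base, dup)))
  pruned <- prune_collinear(env)
  expect_equal(setdiff(names(pruned), "locality"), paste0("P", 1:10))
})

test_that("constant predictors are dropped with a warning", {
  env <- tibble::tibble(locality = letters[1:5], A = 1:5, B = rep(2, 5))
  expect_warning(pruned <- prune_collinear(env), "constant")
  expect_equal(setdiff(names(pruned), "locality"), "A")
})

test_that("rda_scan matches the explicit hat-matrix + PCA oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 24; L <- 60
    gm <- random_gm(n, L, miss = 0, seed = seed)
    env <- dplyr::bind_cols(
      tibble::tibble(locality = paste0("s", 1:n)),
      tibble::as_tibble(matrix(rnorm(n * 3), n, 3,
                               dimnames = list(NULL, c("a", "b", "c"))))
    )
    r <- rda_scan(gm, paste0("s", 1:n), env, n_perm = 19, seed = 1)
    # oracle: project Y on X explicitly, then eigendecompose
    Y <- scale(gm$genotypes, scale = FALSE)
    X <- scale(as.matrix(env[, -1]), scale = FALSE)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    fitted <- H %*% Y
    eig <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)
    expect_equal(r$eigenvalues, eig$values[seq_along(r$eigenvalues)],
                 tolerance = 1e-8)
    for (k in seq_along(r$eigenvalues)) {
      expect_equal(abs(sum(r$loadings[, k] * eig$vectors[, k])), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("rda_scan agrees with vegan's constrained ordination", {
  skip_if_not_installed("vegan")
  set.seed(6)
  n <- 30; L <- 40
  gm <- random_gm(n, L, miss = 0, seed = 7)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  env <- dplyr::bind_cols(tibble::tibble(locality = paste0("s", 1:n)),
                          tibble::as_tibble(X))
  r <- rda_scan(gm, paste0("s", 1:n), env, n_perm = 19, seed = 1)
  v <- vegan::rda(scale(gm$genotypes, scale = FALSE) ~ a + b + c,
                  data = as.data.frame(X))
  expect_equal(r$eigenvalues, unname(v$CCA$eig), tolerance = 1e-10)
  for (k in 1:3) {
    expect_equal(abs(stats::cor(r$loadings[, k], v$CCA$v[, k])), 1,
                 tolerance = 1e-10)
  }
})

test_that("rda flags are exactly the >3 SD loadings on significant axes", {
  fx <- make_assoc_fixture(seed = 31, n_loci = 300, n_adaptive = 10)
  suppressWarnings(
    r <- rda_scan(fx$sim$gm, fx$pops, fx$env, n_perm = 99, seed = 2)
  )
  sig <- which(r$axis_p <= 0.01)
  manual <- unique(unlist(lapply(sig, function(k) {
    ld <- r$loadings[, k]
    names(ld)[abs(ld - mean(ld)) > 3 * stats::sd(ld)]
  })))
  expect_setequal(r$flagged, manual)
})

test_that("rda full-model p is null-calibrated when env is shuffled", {
  # calibration requires the global null: no structure (F ~ 0) and no
  # genotype-environment association
  fx <- make_assoc_fixture(seed = 41, n_loci = 200, n_adaptive = 0,
                           n_per_pop = 15, F = 1e-6)
  hits <- vapply(1:5, function(s) {
    env_perm <- fx$env
    set.seed(400 + s)
    env_perm[, -1] <- env_perm[sample(nrow(env_perm)), -1]
    suppressWarnings(
      rda_scan(fx$sim$gm, fx$pops, env_perm, n_perm = 99,
               seed = s)$full_model_p
    )
  }, numeric(1))
  expect_gte(mean(hits > 0.05), 0.6)
})

test_that("lfmm with K = 0 reproduces per-locus OLS slopes", {
  fx <- make_assoc_fixture(seed = 51, n_loci = 40, n_per_pop = 10,
                           n_adaptive = 0, predictors = "pH")
  lf <- lfmm_scan(fx$sim$gm, fx$pops, fx$env, K = 0, seed = 1)
  Y <- impute_mean_for_test(fx$sim$gm$genotypes)
  x <- as.numeric(scale(fx$env$pH[match(fx$pops, fx$env$locality)]))
  for (j in sample(40, 8)) {
    fit <- stats::lm(Y[, j] ~ x)
    z_ols <- summary(fit)$coefficients["x", "t value"]
    expect_equal(unname(lf$z[j, "pH"]), unname(z_ols), tolerance = 1e-8)
  }
})

test_that("lambda follows the median-z identity and p-values stay in (0,1]", {
  fx <- make_assoc_fixture(seed = 61, n_loci = 500, n_adaptive = 0,
                           predictors = "pH")
  lf <- lfmm_scan(fx$sim$gm, fx$pops, fx$env, K = 2, seed = 1)
  expect_equal(unname(lf$lambda["pH"]),
               stats::median(lf$z[, "pH"]^2) / 0.454936, tolerance = 1e-12)
  expect_true(all(lf$p_adj > 0 & lf$p_adj <= 1))
  expect_true(all(lf$lambda > 0))
  # rescaled statistics are invariant to a common scaling of the z-scores:
  # chi^2 = z^2 / (median(z^2)/c) is unchanged when z -> 2z
  z <- lf$z[, "pH"]
  chi_1 <- z^2 / (stats::median(z^2) / 0.454936)
  z2 <- 2 * z
  chi_2 <- z2^2 / (stats::median(z2^2) / 0.454936)
  expect_equal(chi_1, chi_2, tolerance = 1e-12)
})

test_that("lfmm errors when K is too large", {
  gm <- random_gm(10, 20, seed = 1)
  env <- simulate_env(10, "pH", seed = 2)
  expect_error(lfmm_scan(gm, env$locality, env, K = 10), "K must be")
})

test_that("choose_k tracks the number of population axes", {
  p <- sim_params(n_pops = 4, n_per_pop = 30, n_loci = 400, F = 0.25,
                  n_adaptive = 0, missing_rate = 0, seed = 71)
  sim <- simulate_genotypes(p)
  k_struct <- as.integer(choose_k(sim$gm, k_max = 6, seed = 3))
  expect_true(k_struct %in% 2:4)

  p0 <- sim_params(n_pops = 4, n_per_pop = 30, n_loci = 400, F = 1e-6,
                   n_adaptive = 0, missing_rate = 0, seed = 72)
  sim0 <- simulate_genotypes(p0)
  k_pan <- as.integer(choose_k(sim0$gm, k_max = 6, seed = 3))
  expect_lte(k_pan, 1)

  expect_identical(choose_k(sim$gm, k_max = 6, seed = 3),
                   choose_k(sim$gm, k_max = 6, seed = 3))
})

test_that("fst outlier scan recovers strongly differentiated planted loci", {
  # background F = 0.02 with 10 loci at F = 0.5
  p_bg <- sim_params(n_pops = 4, n_per_pop = 30, n_loci = 490, F = 0.02,
                     n_adaptive = 0, missing_rate = 0, seed = 81)
  bg <- simulate_genotypes(p_bg)
  p_out <- sim_params(n_pops = 4, n_per_pop = 30, n_loci = 10, F = 0.5,
                      n_adaptive = 0, missing_rate = 0, seed = 82)
  out <- simulate_genotypes(p_out)
  colnames(out$gm$genotypes) <- paste0("out", 1:10)
  g <- cbind(bg$gm$genotypes, out$gm$genotypes)
  lt <- tibble::tibble(locus_id = colnames(g), ref = "A", alt = "G")
  gm <- geno_matrix(g, lt)
  scan <- fst_outlier_scan(gm, bg$samples$locality, n_perm = 999, seed = 5)
  expect_gte(sum(grepl("^out", scan$flagged)), 8)
  expect_true(all(scan$per_locus$p_value >= 1 / 1000 &
                    scan$per_locus$p_value <= 1))
})

test_that("fst outlier scan stays quiet under panmixia", {
  discoveries <- vapply(1:3, function(s) {
    p <- sim_params(n_pops = 4, n_per_pop = 25, n_loci = 300, F = 1e-6,
                    n_adaptive = 0, missing_rate = 0, seed = 90 + s)
    sim <- simulate_genotypes(p)
    length(fst_outlier_scan(sim$gm, sim$samples$locality, n_perm = 499,
                            seed = s)$flagged)
  }, numeric(1))
  expect_lte(sum(discoveries), 1)
})

test_that("consensus partitions follow the set algebra", {
  part <- consensus(list(a = c("l1", "l2"), b = c("l2", "l3"),
                         c = c("l3", "l4")), paste0("l", 1:6))
  expect_setequal(part$consensus, c("l2", "l3"))
  expect_setequal(part$union, c("l1", "l2", "l3", "l4"))
  expect_setequal(part$neutral, c("l5", "l6"))

  empty <- consensus(list(a = character(), b = character(), c = character()),
                     paste0("l", 1:4))
  expect_equal(length(empty$consensus), 0)
  expect_setequal(empty$neutral, paste0("l", 1:4))

  same <- consensus(list(a = c("l1", "l2"), b = c("l1", "l2"),
                         c = c("l1", "l2")), paste0("l", 1:4))
  expect_setequal(same$consensus, c("l1", "l2"))
  expect_setequal(same$consensus, same$union)
})

test_that("consensus is monotone and partition-consistent on random sets", {
  set.seed(12)
  universe <- paste0("l", 1:50)
  for (i in 1:20) {
    sets <- purrr::map(1:3, ~sample(universe, sample(0:20, 1)))
    names(sets) <- c("a", "b", "c")
    part <- consensus(sets, universe)
    expect_true(all(part$consensus %in% part$union))
    expect_setequal(c(part$union, part$neutral), universe)
    expect_equal(length(intersect(part$union, part$neutral)), 0)
    # enlarging a set never shrinks the union
    sets2 <- sets
    sets2$a <- union(sets2$a, sample(universe, 5))
    part2 <- consensus(sets2, universe)
    expect_true(all(part$union %in% part2$union))
    # a stricter consensus rule is a subset of a looser one
    part3 <- consensus(sets, universe, min_methods = 3)
    expect_true(all(part3$consensus %in% part$consensus))
  }
})
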