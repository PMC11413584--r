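test_that("locality frequencies match brute-force gene-copy counting", {
  g <- rbind(c(2L, 0L, NA), c(2L, 1L, 1L), c(0L, 2L, 0L), c(NA, 1L, 1L))
  gm <- geno_matrix(g)
  pops <- c("A", "A", "B", "B")
  f <- locality_freqs(gm, pops)
  expect_equal(unname(f["A", ]), c(1, 0.25, 0.5))
  expect_equal(unname(f["B", ]), c(0, 0.75, 0.25))
  # random fixtures against a loop oracle
  gm2 <- random_gm(10, 12, miss = 0.25, seed = 3)
  pops2 <- rep(c("A", "B"), each = 5)
  f2 <- locality_freqs(gm2, pops2)
  for (p in c("A", "B")) {
    for (j in 1:12) {
      geno <- gm2$genotypes[pops2 == p, j]
      geno <- geno[!is.na(geno)]
      exp_f <- if (length(geno)) sum(geno) / (2 * length(geno)) else NA_real_
      expect_equal(unname(f2[p, j]), exp_f)
    }
  }
})

test_that("PCA contributions are squared unit loadings summing to 100", {
  m <- cbind(v1 = c(1, 2, 3, 4), v2 = rep(5, 4))
  ord <- pca_contributions(m)
  expect_equal(unname(ord$contrib[, 1]), c(100, 0))
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 20), 8, 20)
    ord <- pca_contributions(m)
    expect_equal(unname(colSums(ord$contrib)),
                 rep(100, ncol(ord$contrib)), tolerance = 1e-6)
    # SVD oracle
    sv <- svd(scale(m, scale = FALSE))
    expect_equal(ord$eigenvalues, sv$d[seq_along(ord$eigenvalues)]^2 / 7,
                 tolerance = 1e-8)
    for (k in seq_along(ord$eigenvalues)) {
      expect_equal(unname(ord$contrib[, k]), 100 * sv$v[, k]^2,
                   tolerance = 1e-8)
    }
  }
})

test_that("DAPC separates clusters and attributes contributions correctly", {
  # labels carving a homogeneous pool: between-group variance is only the
  # sampling noise floor, far below any real separation
  set.seed(4)
  g <- matrix(sample(0:2, 200 * 30, replace = TRUE), 200, 30)
  gm <- geno_matrix(g)
  same <- dapc_fit(gm, rep(c("A", "B"), 100), n_pca = 3)

  # two clusters fully separated on one SNP
  g2 <- matrix(sample(0:1, 200 * 30, replace = TRUE), 200, 30)
  g2[, 1] <- rep(c(0L, 2L), each = 100)
  gm2 <- geno_matrix(g2)
  sep <- dapc_fit(gm2, rep(c("A", "B"), each = 100), n_pca = 10)
  expect_gt(sep$discriminant_eigenvalues[1], 10)
  expect_lt(same$discriminant_eigenvalues[1],
            sep$discriminant_eigenvalues[1] / 10)
  expect_gt(sep$contrib[1, 1], 75)
  expect_error(dapc_fit(gm2, rep("A", 200), n_pca = 5), ">= 2 clusters")
  expect_error(dapc_fit(gm2, rep(c("A", "B"), 100), n_pca = 300), "n_pca")
  expect_equal(unname(colSums(sep$contrib)),
               rep(100, ncol(sep$contrib)), tolerance = 1e-6)
})

test_that("a-score optimization rewards separable clusterings", {
  p <- sim_params(n_pops = 3, n_per_pop = 20, n_loci = 150, F = 0.4,
                  n_adaptive = 0, missing_rate = 0, seed = 15)
  sim <- simulate_genotypes(p)
  best <- optimize_a_score(sim$gm, sim$samples$locality,
                           n_pca_grid = c(2, 4, 6), n_sim = 5, seed = 6)
  a <- attr(best, "a_score")
  expect_gt(max(a), 0.4)   # near 1 - 1/3 for clean reassignment

  # random labels: no reassignment skill
  set.seed(7)
  rand_labels <- sample(sim$samples$locality)
  rand <- optimize_a_score(sim$gm, rand_labels, n_pca_grid = c(2, 4),
                           n_sim = 5, seed = 8)
  expect_lt(max(abs(attr(rand, "a_score"))), 0.15)

  expect_identical(
    optimize_a_score(sim$gm, sim$samples$locality, n_pca_grid = c(2, 4),
                     n_sim = 5, seed = 9),
    optimize_a_score(sim$gm, sim$samples$locality, n_pca_grid = c(2, 4),
                     n_sim = 5, seed = 9)
  )
})

test_that("BIC cluster search recovers blob counts", {
  p1 <- sim_params(n_pops = 1, n_per_pop = 60, n_loci = 100, F = 0.05,
                   n_adaptive = 0, missing_rate = 0, seed = 16)
  one <- simulate_genotypes(p1)
  res1 <- find_clusters_bic(one$gm, k_max = 6, n_pca = 40, seed = 10)
  expect_equal(res1$k, 1)
  expect_equal(nrow(res1$bic), 6)

  p3 <- sim_params(n_pops = 3, n_per_pop = 25, n_loci = 200, F = 0.5,
                   n_adaptive = 0, missing_rate = 0, seed = 17)
  three <- simulate_genotypes(p3)
  res3 <- find_clusters_bic(three$gm, k_max = 6, n_pca = 40, seed = 11)
  expect_equal(res3$k, 3)
})

test_that("contribution ranking is descending, stable and id-tiebroken", {
  r <- rank_contributions(c(L1 = 3, L2 = 1, L3 = 2))
  expect_equal(r$locus_id, c("L1", "L3", "L2"))
  ties <- rank_contributions(c(Lb = 1, La = 1, Lc = 1))
  expect_equal(ties$locus_id, c("La", "Lb", "Lc"))
  v <- c(a = 5, b = 2, c = 9, d = 2)
  expect_setequal(rank_contributions(v)$contribution, unname(v))
  expect_error(rank_contributions(c(a = 1, b = NA)), "non-finite")
})

test_that("cumulative contribution matches brute-force partial sums", {
  v <- c(5, 1, 3, 1)
  expect_equal(cumulative_contribution(v, 4), 100)
  expect_equal(cumulative_contribution(v, 0), 0)
  expect_equal(cumulative_contribution(v, 2), 100 * 8 / 10)
  set.seed(18)
  w <- runif(30)
  for (m in c(1, 10, 30)) {
    expect_equal(cumulative_contribution(w, m),
                 100 * sum(sort(w, decreasing = TRUE)[1:m]) / sum(w))
  }
})

test_that("the top-10 three-kN configuration gives the exact 1/120 p-value", {
  lab <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  ser <- iterative_wilcoxon(lab, start = 10, stop = 10)
  expect_equal(ser$p_value, 1 / 120, tolerance = 1e-12)
  expect_equal(ser$p_value, enum_wilcoxon_p(lab), tolerance = 1e-12)
})

test_that("the exact branch agrees with full enumeration on random configs", {
  set.seed(19)
  for (i in 1:30) {
    m <- sample(6:18, 1)
    n1 <- sample(1:min(8, m - 1), 1)
    lab <- sample(rep(c(TRUE, FALSE), c(n1, m - n1)))
    ours <- iterative_wilcoxon(lab, start = m, stop = m)$p_value
    expect_equal(ours, enum_wilcoxon_p(lab), tolerance = 1e-12,
                 info = paste("m =", m, "n1 =", n1))
  }
})

test_that("the one-tailed direction is kN-near-the-top", {
  lab <- c(rep(FALSE, 7), TRUE, TRUE, TRUE)   # kN at the bottom
  ser <- iterative_wilcoxon(lab, start = 10, stop = 10)
  expect_gte(ser$p_value, 0.5)
})

test_that("the series walks depths and records empty-group iterations as NA", {
  lab <- c(TRUE, rep(FALSE, 30))
  ser <- iterative_wilcoxon(lab, start = 10, stop = 31)
  expect_equal(ser$m, 10:31)
  expect_true(all(diff(ser$m) == 1))
  expect_true(all(!is.na(ser$p_value)))

  no_kn <- rep(FALSE, 31)
  ser0 <- iterative_wilcoxon(no_kn, start = 10, stop = 12)
  expect_true(all(is.na(ser0$p_value)))
  expect_error(iterative_wilcoxon(lab, start = 10, stop = 5), "stop")
  expect_error(iterative_wilcoxon(lab, start = 10, stop = 500), "exceeds")
})

test_that("plots build without evaluation errors", {
  lab <- sample(rep(c(TRUE, FALSE), c(5, 25)))
  ser <- iterative_wilcoxon(lab, start = 10, stop = 30)
  expect_s3_class(autoplot(ser), "ggplot")
  set.seed(20)
  ord <- pca_contributions(matrix(rnorm(40), 5, 8))
  expect_s3_class(autoplot(ord), "ggplot")
  expect_s3_class(plot_contributions(ord), "ggplot")
  p <- sim_params(n_pops = 2, n_per_pop = 10, n_loci = 30, seed = 21,
                  n_adaptive = 0)
  sim <- simulate_genotypes(p)
  cl <- find_clusters_bic(sim$gm, k_max = 3, n_pca = 3, seed = 12)
  expect_s3_class(plot_bic(cl), "ggplot")
})
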