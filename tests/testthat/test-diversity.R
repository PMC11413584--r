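test_that("observed heterozygosity counts heterozygote fractions", {
  gm <- geno_matrix(matrix(c(1L, 1L, 0L, 2L), 4, 1))
  expect_equal(observed_heterozygosity(gm, rep("A", 4))$ho, 0.5)
  gm2 <- geno_matrix(matrix(c(0L, 2L, 2L, 0L), 4, 1))
  expect_equal(observed_heterozygosity(gm2, rep("A", 4))$ho, 0)
})

test_that("unbiased He matches the closed form and per-locus theta-pi", {
  gm <- geno_matrix(matrix(c(0L, 2L), 2, 1))
  expect_equal(expected_heterozygosity(gm, c("x", "x"))$he, 4 / 3 * 0.5)
  # identity: per-locus He == per-locus pi (2x(k-x)/(k(k-1)))
  for (seed in 1:5) {
    gm <- random_gm(12, 30, miss = 0.2, seed = seed)
    pops <- rep(c("A", "B"), each = 6)
    he <- expected_heterozygosity(gm, pops)
    pi_pp <- purrr::map(c("A", "B"), function(p) {
      sub <- subset_geno(gm, samples = which(pops == p))
      vapply(seq_len(n_loci(sub)), function(j) {
        geno <- sub$genotypes[, j]
        k <- 2 * sum(!is.na(geno))
        x <- sum(geno, na.rm = TRUE)
        if (k < 2) return(NA_real_)
        2 * x * (k - x) / (k * (k - 1))
      }, numeric(1))
    })
    expect_equal(he$he[he$pop == "A"], pi_pp[[1]], tolerance = 1e-12)
    expect_equal(he$he[he$pop == "B"], pi_pp[[2]], tolerance = 1e-12)
  }
})

test_that("theta-pi is the pairwise-difference mean, summed over loci", {
  gm <- geno_matrix(matrix(c(0L, 2L), 2, 1))
  # enumeration: 4 gene copies -> C(4,2)=6 pairs, 4 differ
  expect_equal(theta_pi(gm, c("x", "x"))$theta_pi, 4 / 6)
  mono <- geno_matrix(matrix(c(2L, 2L), 2, 1))
  expect_equal(theta_pi(mono, c("x", "x"))$theta_pi, 0)
  # additivity over loci
  g69 <- matrix(rep(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L), 69), 10, 69)
  pi1 <- theta_pi(geno_matrix(g69[, 1, drop = FALSE]), rep("x", 10))$theta_pi
  expect_equal(theta_pi(geno_matrix(g69), rep("x", 10))$theta_pi, 69 * pi1)
})

test_that("FIS has the right sign, bounds and null behaviour", {
  all_het <- geno_matrix(matrix(1L, 4, 1))
  expect_lt(fis(all_het, rep("A", 4), n_perm = 0)$fis, 0)
  no_het <- geno_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  expect_equal(fis(no_het, rep("A", 4), n_perm = 0)$fis, 1)
  mono <- geno_matrix(matrix(0L, 4, 1))
  expect_true(is.na(fis(mono, rep("A", 4), n_perm = 0)$fis))

  p <- sim_params(n_pops = 1, n_per_pop = 400, n_loci = 300, F = 0.5,
                  n_adaptive = 0, missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(p)
  f <- fis(sim$gm, sim$samples$locality, n_perm = 0)
  expect_lt(abs(f$fis), 0.05)
})

test_that("FIS permutation p-value flags strong heterozygote deficit", {
  set.seed(4)
  g <- matrix(sample(c(0L, 2L), 40 * 30, replace = TRUE), 40, 30)
  f <- fis(geno_matrix(g), rep("A", 40), n_perm = 200, seed = 5)
  expect_equal(f$fis, 1)
  expect_lt(f$p_value, 0.05)
})

test_that("Weir-Cockerham components match the hand-evaluated fixed-pair case", {
  g <- matrix(c(0L, 0L, 2L, 2L), 4, 1)
  r <- wc_theta(geno_matrix(g), c("A", "A", "B", "B"))
  expect_equal(r$per_locus$a, 0.5)
  expect_equal(r$per_locus$b, 0)
  expect_equal(r$per_locus$c, 0)
  expect_equal(r$theta, 1)
})

test_that("wc_theta equals an independent WC84 transcription on random data", {
  for (seed in 1:30) {
    n <- sample(6:14, 1)
    gm <- random_gm(n, sample(3:8, 1), miss = 0.15, seed = 100 + seed)
    pops <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(pops)) < 2) next
    ours <- wc_theta(gm, pops)
    comp <- sapply(seq_len(n_loci(gm)), function(j) {
      naive_wc_locus(gm$genotypes[, j], pops)
    })
    expect_equal(ours$per_locus$a, unname(comp["a", ]), tolerance = 1e-12)
    expect_equal(ours$per_locus$b, unname(comp["b", ]), tolerance = 1e-12)
    expect_equal(ours$per_locus$c, unname(comp["c", ]), tolerance = 1e-12)
  }
})

test_that("theta is approximately zero for identical populations at HWE", {
  p <- sim_params(n_pops = 2, n_per_pop = 200, n_loci = 100, F = 1e-6,
                  n_adaptive = 0, missing_rate = 0, seed = 7)
  sim <- simulate_genotypes(p)
  expect_lt(abs(wc_theta(sim$gm, sim$samples$locality)$theta), 0.05)
})

test_that("statistics are invariant to sample and locus order", {
  gm <- random_gm(12, 20, miss = 0.1, seed = 8)
  pops <- rep(c("A", "B", "C"), each = 4)
  base <- wc_theta(gm, pops)$theta
  perm_s <- sample(12)
  perm_l <- sample(20)
  gm2 <- geno_matrix(gm$genotypes[perm_s, perm_l], gm$loci[perm_l, ])
  expect_equal(wc_theta(gm2, pops[perm_s])$theta, base, tolerance = 1e-12)
  d1 <- diversity_report(gm, pops, n_perm = 0)
  d2 <- diversity_report(gm2, pops[perm_s], n_perm = 0)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("pairwise FST is symmetric with unit theta for fixed differences", {
  g <- rbind(matrix(0L, 3, 4), matrix(2L, 3, 4), matrix(1L, 3, 4))
  pops <- rep(c("A", "B", "C"), each = 3)
  pw <- pairwise_fst(geno_matrix(g), pops, n_perm = 50, seed = 9)
  m <- fst_matrix(pw)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m["A", "B"], 1)
  expect_true(all(pw$p_value >= 1 / 51 & pw$p_value <= 1))
})

test_that("Ho-vs-He comparison behaves on degenerate and shifted inputs", {
  # genotypes [0, 1] give Ho = He = 0.5 exactly, at every locus
  g <- matrix(c(0L, 1L), 2, 6)
  res_same <- compare_ho_he(geno_matrix(g))
  expect_equal(res_same$paired_t_stat, 0)
  expect_equal(res_same$paired_t_p, 1)
  expect_equal(res_same$bartlett_p, 1)

  # complete heterozygote deficit: Ho = 0 < He at every polymorphic locus
  set.seed(10)
  g2 <- matrix(sample(c(0L, 2L), 30 * 50, replace = TRUE), 30, 50)
  res_def <- compare_ho_he(geno_matrix(g2))
  expect_lt(res_def$paired_t_stat, 0)
  expect_lt(res_def$paired_t_p, 1e-6)

  expect_error(compare_ho_he(geno_matrix(matrix(c(0L, 1L), 2, 1))),
               ">= 2 loci")
})

test_that("diversity_report assembles the per-population table", {
  p <- sim_params(n_pops = 3, n_per_pop = 15, n_loci = 60, F = 0.1,
                  n_adaptive = 0, missing_rate = 0.1, seed = 11)
  sim <- simulate_genotypes(p)
  tab <- diversity_report(sim$gm, sim$samples$locality, n_perm = 0)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$n == 15))
  expect_true(all(tab$ho >= 0 & tab$ho <= 1))
  expect_true(all(tab$he >= 0 & tab$he <= 1))
  expect_true(all(tab$theta_pi >= 0))
})
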