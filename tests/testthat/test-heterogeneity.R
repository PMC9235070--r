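test_that("cell z-scoring makes squared distance an exact function of Pearson rho", {
  set.seed(3)
  m <- toy_matrix(matrix(rnorm(10 * 6), 10), tumor = rep(c("a", "b"), 3))
  z <- zscore_cells(m)
  expect_equal(unname(colSums(z)), rep(0, 6), tolerance = 1e-12)
  C <- cor(m$values)
  for (i in 1:5) for (j in (i + 1):6) {
    d2 <- sum((z[, i] - z[, j])^2)
    expect_equal(d2, 2 - 2 * C[i, j], tolerance = 1e-9)
  }
  # identical cells: distance 0; anti-correlated cells: maximal distance
  dup <- toy_matrix(cbind(1:5, 1:5, 5:1), tumor = rep("t", 3))
  zd <- zscore_cells(dup)
  expect_equal(sum((zd[, 1] - zd[, 2])^2), 0, tolerance = 1e-12)
  expect_equal(sum((zd[, 1] - zd[, 3])^2), 4, tolerance = 1e-12)
  # constant cell is rejected by name
  cm <- toy_matrix(cbind(c(1, 1, 1), c(1, 2, 3)), tumor = rep("t", 2),
                   cells = c("flat", "ok"))
  expect_error(zscore_cells(cm), "flat")
})

test_that("silhouette values match a brute-force evaluation", {
  set.seed(11)
  # 6 cells / 2 tumors with hand-set coordinates
  v <- cbind(c(0, 0, 1), c(0.1, 0, 1.2), c(0, 0.2, 0.9),
             c(5, 1, 0), c(5.2, 1.1, 0), c(4.8, 0.9, 0.2))
  m <- toy_matrix(v, tumor = rep(c("A", "B"), each = 3))
  for (self in c(TRUE, FALSE)) {
    s <- silhouette_values(zscore_cells(m), m$tumor_of, include_self = self)
    expect_equal(unname(s),
                 unname(oracle_silhouette(m$values, m$tumor_of, self)),
                 tolerance = 1e-6)
  }
  # well-separated tight tumors: all s(i) near 1
  tight <- toy_matrix(cbind(c(0, 0, 1) + matrix(rnorm(9, 0, .01), 3),
                            c(9, 1, 0) + matrix(rnorm(9, 0, .01), 3)),
                      tumor = rep(c("A", "B"), each = 3))
  expect_true(all(silhouette_values(zscore_cells(tight), tight$tumor_of) > 0.8))
  # a cell sitting inside a foreign tumor gets a negative value
  stray <- toy_matrix(cbind(c(9.01, 1, 0), c(0, 0, 1), c(0.1, 0, 1.1),
                            c(9, 1, 0), c(9.1, 1.05, 0), c(8.9, 1, 0.05)),
                      tumor = c("A", "A", "A", "B", "B", "B"))
  s <- silhouette_values(zscore_cells(stray), stray$tumor_of)
  expect_lt(s[[1]], 0)
  expect_error(silhouette_values(zscore_cells(stray),
                                 setNames(rep("A", 6), names(stray$tumor_of))),
               "2 tumors")
})

test_that("NSV fractions count strictly negative silhouettes per tumor", {
  tumor <- setNames(rep(c("A", "B"), each = 10), paste0("c", 1:20))
  s <- setNames(rep(1, 20), paste0("c", 1:20))
  expect_equal(nsv_fractions(s, tumor)$avg_nsv, 0)
  s[c("c1", "c2")] <- -0.5   # 2 of 10 cells in tumor A
  nf <- nsv_fractions(s, tumor)
  expect_equal(unname(nf$per_tumor["A"]), 0.2)
  expect_equal(nf$avg_nsv, 0.1)
})

test_that("intra/inter correlation pools match all-pairs bookkeeping", {
  m3 <- toy_matrix(matrix(rnorm(12), 4), tumor = c("A", "A", "B"))
  cc <- intra_inter_correlations(m3)
  expect_equal(length(cc$intra), 1)
  expect_equal(length(cc$inter), 2)
  dup <- toy_matrix(cbind(1:4, 1:4, rnorm(4)), tumor = c("A", "A", "B"))
  expect_equal(max(intra_inter_correlations(dup)$intra), 1)
  set.seed(5)
  m <- toy_matrix(matrix(rnorm(8 * 20), 8),
                  tumor = rep(c("A", "B", "C", "D"), each = 5))
  cc <- intra_inter_correlations(m)
  expect_equal(length(cc$intra) + length(cc$inter), choose(20, 2))
  C <- cor(m$values)
  expect_equal(sort(c(cc$intra, cc$inter)), sort(C[upper.tri(C)]))
})

test_that("p_diff behaves at the extremes and is antisymmetric", {
  set.seed(7)
  same <- rnorm(500, 0, 0.2)
  expect_lt(abs(p_diff(same, same, n_samples = 2e4, seed = 1)), 0.03)
  hi <- rnorm(400, 0.9, 0.01); lo <- rnorm(400, 0.1, 0.01)
  expect_gt(p_diff(hi, lo, n_samples = 2e4, seed = 2), 0.97)
  a <- rnorm(400, 0.3, 0.1); b <- rnorm(400, 0.1, 0.15)
  expect_equal(p_diff(a, b, n_samples = 5e4, seed = 3),
               -p_diff(b, a, n_samples = 5e4, seed = 4), tolerance = 0.02)
  expect_error(p_diff(a, b, n_samples = 0), "positive")
  expect_error(p_diff(numeric(0), b), "nonempty")
})

test_that("p_diff matches the Gaussian closed form within Monte-Carlo error", {
  set.seed(21)
  eps <- 0.05
  x <- rnorm(5e4, 0.3, 0.1); y <- rnorm(5e4, 0, 0.1)
  est <- p_diff(x, y, epsilon = eps, n_samples = 2e4, seed = 9)
  truth <- gaussian_pdiff(0.3, 0.1, 0, 0.1, eps)
  se <- sqrt(0.5 / 2e4)  # conservative bound on the Monte-Carlo SE
  expect_lt(abs(est - truth), 3 * se)
})

test_that("entropy baseline follows Gaussian theory", {
  set.seed(13)
  n <- 400
  base_sd <- 0.3
  v1 <- matrix(rnorm(10 * n, sd = base_sd), 10)
  v2 <- matrix(rnorm(10 * n, sd = 2 * base_sd), 10)
  m <- toy_matrix(cbind(v1, v2), tumor = rep(c("A", "B"), each = n))
  ent <- entropy_per_tumor(m)
  # doubling sigma raises the 10-gene entropy by ~10 bits
  expect_equal(unname(ent["B"] - ent["A"]), 10, tolerance = 0.6)
  # single Gaussian gene: entropy ~ 0.5 log2(2 pi e sigma^2) within KDE bias
  single <- toy_matrix(rbind(rnorm(n, sd = base_sd), rnorm(n, sd = base_sd)),
                       tumor = rep("A", n))
  h_theory <- 0.5 * log2(2 * pi * exp(1) * base_sd^2)
  expect_equal(unname(entropy_per_tumor(single)["A"]) / 2, h_theory,
               tolerance = 0.15)
  # identical tumors give identical entropies
  m2 <- toy_matrix(cbind(v1, v1), tumor = rep(c("A", "B"), each = n))
  e2 <- entropy_per_tumor(m2)
  expect_equal(unname(e2["A"]), unname(e2["B"]))
})

test_that("heterogeneity report composes the individual statistics", {
  set.seed(17)
  m <- simulate_mixture(1, 0.1, seed = 31)
  rep_ <- heterogeneity_report(m, n_samples = 1e4, seed = 5, entropy = TRUE)
  z <- zscore_cells(m)
  nsv <- nsv_fractions(silhouette_values(z, m$tumor_of), m$tumor_of)
  expect_equal(rep_$avg_nsv, nsv$avg_nsv)
  expect_equal(rep_$nsv_per_tumor, nsv$per_tumor)
  cc <- intra_inter_correlations(m)
  expect_equal(rep_$p_diff, p_diff(cc$intra, cc$inter, n_samples = 1e4,
                                   seed = 5))
  expect_equal(rep_$entropy_per_tumor, entropy_per_tumor(m))
  expect_true(rep_$p_diff > 0.9)      # tight within-tumor populations
  expect_true(rep_$avg_nsv < 0.05)
  # shuffling tumor labels destroys the structure
  set.seed(41)
  shuf <- expression_matrix(m$values, tumor = sample(unname(m$tumor_of)))
  rep_s <- heterogeneity_report(shuf, n_samples = 1e4, seed = 6)
  expect_lt(abs(rep_s$p_diff), 0.1)
  # invariance to cell order and label renaming
  perm <- sample(colnames(m$values))
  m_perm <- subset_matrix(m, cells = perm)
  m_perm$tumor_of <- setNames(chartr("12345", "edcba", m_perm$tumor_of),
                              names(m_perm$tumor_of))
  rep_p <- heterogeneity_report(m_perm, n_samples = 1e4, seed = 5)
  expect_equal(rep_p$avg_nsv, rep_$avg_nsv)
  expect_equal(rep_p$p_diff, rep_$p_diff, tolerance = 0.02)
})
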