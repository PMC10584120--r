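test_that("z-score normalization centres and scales each measurement", {
  expect_equal(zscore_normalize(data.frame(v = c(1, 2, 3)))$v, c(-1, 0, 1))
  set.seed(1)
  x <- data.frame(a = rnorm(30, 5, 2), b = runif(30), lab = letters[1:30])
  z <- zscore_normalize(x)
  expect_lt(max(abs(colMeans(z[, 1:2]))), 1e-12)
  expect_equal(unname(apply(z[, 1:2], 2, sd)), c(1, 1))
  expect_equal(zscore_normalize(z)[, 1:2], z[, 1:2], tolerance = 1e-12)
  expect_identical(z$lab, x$lab)
  expect_error(zscore_normalize(data.frame(a = rep(2, 5))), "'a' is constant")
})

test_that("PERMANOVA partitions squared distances like its oracles", {
  set.seed(5)
  x <- matrix(rnorm(20 * 4), 20, 4)
  g <- rep(c("a", "b"), each = 10)
  x[g == "b", 1] <- x[g == "b", 1] + 1.2
  d <- euclidean_distance(x)
  pa <- permanova(d, g, n_perm = 199, seed = 3)
  # independent direct computation from the group-sum identity
  expect_equal(pa$pseudo_F[1], direct_pseudo_F(d, g))
  # single variable: pseudo-F equals the classical univariate F
  y <- x[, 1, drop = FALSE]
  pa1 <- permanova(euclidean_distance(y), g, n_perm = 99, seed = 1)
  Fcl <- summary(aov(y[, 1] ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(pa1$pseudo_F[1], Fcl)

  skip_if_not_installed("vegan")
  va <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(pa$pseudo_F[1], va$F[1])
  f2 <- rep(c("x", "y"), times = 10)
  pa2 <- permanova(d, list(A = g, B = f2), n_perm = 99, seed = 1)
  va2 <- vegan::adonis2(d ~ A * B, data = data.frame(A = g, B = f2),
                        permutations = 99, by = "terms")
  expect_equal(pa2$pseudo_F[1:3], va2$F[1:3])
  expect_equal(pa2$SS[1:3], va2$SumOfSqs[1:3])
})

test_that("permutation p-values match exhaustive enumeration on small instances", {
  set.seed(7)
  x <- matrix(rnorm(12), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  d <- euclidean_distance(x)
  # brute-force oracle over all 20 label assignments
  obs <- direct_pseudo_F(d, g)
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(w) {
    gg <- rep("b", 6); gg[w] <- "a"
    direct_pseudo_F(d, gg)
  })
  p_exact <- mean(stats >= obs - 1e-12)
  pe <- permanova(d, g, exhaustive = TRUE)
  expect_equal(pe$p[1], p_exact)

  # ANOSIM against the same enumeration
  r <- rank(as.vector(d))
  M <- 15
  pair <- combn(6, 2)
  anosim_R <- function(gg) {
    within <- gg[pair[1, ]] == gg[pair[2, ]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  obs_R <- anosim_R(g)
  stats_R <- apply(combos, 2, function(w) {
    gg <- rep("b", 6); gg[w] <- "a"
    anosim_R(gg)
  })
  ae <- anosim(d, g, exhaustive = TRUE)
  expect_equal(ae$statistic, obs_R)
  expect_equal(ae$p, mean(stats_R >= obs_R - 1e-12))

  # sampled p-values are reproducible under a seed and use the add-one rule
  ps <- permanova(d, g, n_perm = 99, seed = 5)$p[1]
  expect_identical(ps, permanova(d, g, n_perm = 99, seed = 5)$p[1])
  expect_true(ps >= 1 / 100 && ps <= 1)
})

test_that("PERMANOVA rejects degenerate inputs", {
  x <- matrix(1, 6, 2)
  expect_error(permanova(euclidean_distance(x), rep(c("a", "b"), each = 3),
                         n_perm = 19), "identical")
  set.seed(1)
  y <- matrix(rnorm(12), 6, 2)
  expect_error(permanova(euclidean_distance(y), c("a", rep("b", 5)),
                         n_perm = 19), ">= 2 samples")
})

test_that("ANOSIM attains its bounds and matches vegan", {
  # perfectly separated groups: R = 1
  x <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
             matrix(rnorm(10, 50, 0.01), 5, 2))
  g <- rep(c("a", "b"), each = 5)
  expect_equal(anosim(euclidean_distance(x), g, n_perm = 99, seed = 1)$statistic, 1)
  # random labels on null data: R near 0 on average
  set.seed(9)
  rs <- replicate(200, {
    z <- matrix(rnorm(16), 8, 2)
    anosim(euclidean_distance(z), sample(rep(c("a", "b"), each = 4)),
           n_perm = 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)

  skip_if_not_installed("vegan")
  set.seed(2)
  w <- matrix(rnorm(24), 12, 2)
  gw <- rep(c("a", "b"), each = 6)
  expect_equal(anosim(euclidean_distance(w), gw, n_perm = 49, seed = 1)$statistic,
               unname(vegan::anosim(euclidean_distance(w), gw,
                                    permutations = 49)$statistic))
})

test_that("PERMDISP measures dispersion, not location", {
  set.seed(5)
  x <- matrix(rnorm(10 * 3), 10, 3)
  # translated copies: identical within-group geometry, F = 0
  y <- rbind(x, sweep(x, 2, -7))
  g <- rep(c("a", "b"), each = 10)
  pd0 <- permdisp(euclidean_distance(y), g, n_perm = 99, seed = 1)
  expect_lt(pd0$statistic, 1e-12)
  expect_gt(pd0$p, 0.9)
  # one group scaled x10 about its centroid: strong signal
  x2 <- rbind(x, sweep(x, 2, colMeans(x)) * 10)
  pd1 <- permdisp(euclidean_distance(x2), g, n_perm = 199, seed = 1)
  expect_lt(pd1$p, 0.05)
  # statistic invariant to sample order
  perm <- sample(20)
  pd2 <- permdisp(as.dist(as.matrix(euclidean_distance(x2))[perm, perm]),
                  g[perm], n_perm = 19, seed = 1)
  expect_equal(pd2$statistic, pd1$statistic)

  skip_if_not_installed("vegan")
  bd <- vegan::betadisper(euclidean_distance(x2), g, type = "centroid")
  expect_equal(pd1$statistic, anova(bd)$`F value`[1])
  expect_error(permdisp(euclidean_distance(x), c("a", rep("b", 9)), 19),
               ">= 2 samples")
})

test_that("SIMPER decomposes squared Euclidean distance by variable", {
  # difference on exactly one variable: 100% contribution
  s1 <- simper(data.frame(v1 = c(1, 1, 2, 2), v2 = c(5, 5, 5, 5)),
               c("a", "a", "b", "b"))
  expect_equal(s1$contribution_pct, c(100, 0))
  # two variables with equal constant offsets: 50/50
  s2 <- simper(data.frame(v1 = c(0, 0, 1, 1), v2 = c(3, 3, 4, 4)),
               c("a", "a", "b", "b"))
  expect_equal(s2$contribution_pct, c(50, 50))
  # contributions always total 100
  set.seed(3)
  x <- data.frame(matrix(rnorm(60, 10), 10, 6))
  s3 <- simper(x, rep(c("a", "b"), each = 5))
  expect_equal(sum(s3$contribution_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(s3$contribution_pct) <= 1e-12))
  # identical group means at large n: near-uniform contributions
  set.seed(4)
  big <- data.frame(matrix(rnorm(4000 * 4, 20), ncol = 4))
  s4 <- simper(big, rep(c("a", "b"), each = 2000))
  expect_true(all(abs(s4$contribution_pct - 25) < 2))
  expect_error(simper(data.frame(v = rep(1, 4)), c("a", "a", "b", "b")),
               "identical")
  expect_error(simper(x, rep(c("a", "b", "c"), length.out = 10)),
               "two groups")
})

test_that("percent difference reproduces the reporting convention", {
  expect_equal(round(percent_difference(2.89, 2.73), 1), 5.5)
  expect_equal(round(percent_difference(1.68, 1.83), 1), -8.9)
  expect_equal(percent_difference(3, 3), 0)
  expect_error(percent_difference(0, 1), "nonzero")
})
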