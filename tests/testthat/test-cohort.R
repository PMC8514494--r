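# brute-force signed-rank oracle: enumerate every sign assignment
bruteWilcoxonP <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- signs %*% r
  w <- sum(r[d > 0])
  pLo <- mean(wAll <= w + 1e-9)
  pHi <- mean(wAll >= w - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

test_that("exact signed-rank p equals brute-force enumeration (n <= 12)", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n, 0.3)
    post[sample(n, 1)] <- pre[sample(n, 1)]   # allow zeros and ties
    if (all(post - pre == 0)) next
    res <- wilcoxonSignedRank(pre, post, mode = "exact")
    expect_equal(res$p, bruteWilcoxonP(pre, post), tolerance = 1e-12)
  }
  # ties in |d| handled via midranks in both routes
  pre <- c(0, 0, 0, 0, 0)
  post <- c(1, -1, 2, 2, 3)
  expect_equal(wilcoxonSignedRank(pre, post)$p, bruteWilcoxonP(pre, post))
})

test_that("13 uniformly increased pairs give the familiar 0.0002", {
  res <- wilcoxonSignedRank(rep(0, 13), seq_len(13))
  expect_equal(res$wPos, 13 * 14 / 2)
  expect_equal(res$wNeg, 0)
  expect_equal(res$p, 2 / 2^13)                # 0.000244, printed 0.0002
  expect_equal(wilcoxonSignedRank(c(0), c(1))$p, 1)
  expect_error(wilcoxonSignedRank(1:4, 1:4), "degenerate")
})

test_that("signed-rank matches the reference implementation without ties", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n, 0.2)
    ours <- wilcoxonSignedRank(pre, post, mode = "exact")
    ref <- wilcox.test(post, pre, paired = TRUE, exact = TRUE,
                       correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("paired t-test statistic, df and symmetry", {
  res <- pairedT(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3))
  expect_equal(res$df, 2)
  same <- pairedT(1:5, 1:5 + 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pairedT(x, y)$t, -pairedT(y, x)$t)
  expect_equal(pairedT(x, y)$p, pairedT(y, x)$p)
})

test_that("D'Agostino-Pearson p-values are uniform under the null and the
          test rejects heavy tails", {
  set.seed(41)
  ps <- replicate(400, dagostinoPearson(rnorm(100))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  power <- mean(replicate(200, dagostinoPearson(rt(200, df = 2))$p < 0.05))
  expect_gt(power, 0.9)
  expect_error(dagostinoPearson(rnorm(5)), "n >= 8")
  expect_error(dagostinoPearson(rep(1, 20)), "constant")
})

test_that("Lilliefors KS behaves as a normality test", {
  set.seed(42)
  ps <- replicate(200, lillieforsKS(rnorm(80))$p)
  expect_gt(mean(ps > 0.05), 0.85)
  power <- mean(replicate(200, lillieforsKS(rexp(80))$p < 0.05))
  expect_gt(power, 0.9)
  expect_error(lillieforsKS(rep(2, 10)), "constant")
})

test_that("the s0 = 0 volcano statistic is exactly the paired t statistic", {
  set.seed(5)
  pre <- matrix(rnorm(30 * 10), 30)
  post <- pre + matrix(rnorm(30 * 10, 0.2), 30)
  res <- s0Volcano(pre, post, volcanoConfig(s0 = 0, nPermutations = 64))
  tRef <- sapply(seq_len(30), function(i) pairedT(pre[i, ], post[i, ])$t)
  expect_equal(res$tS0, tRef, tolerance = 1e-12)
  expect_equal(res$negLog10P,
               -log10(sapply(seq_len(30),
                             function(i) pairedT(pre[i, ], post[i, ])$p)),
               tolerance = 1e-10)
})

test_that("identical pre and post yield no significant metabolites", {
  set.seed(6)
  pre <- matrix(rnorm(50 * 12), 50)
  res <- s0Volcano(pre, pre + 1e-15 * matrix(rnorm(50 * 12), 50),
                   volcanoConfig())
  expect_false(any(res$significant))
  expect_error(s0Volcano(pre, pre[, -1], volcanoConfig()), "dimensions")
})

test_that("a strong shifted metabolite is called significant", {
  set.seed(9)
  pre <- matrix(rnorm(40 * 20), 40)
  post <- pre + matrix(rnorm(40 * 20, 0, 0.3), 40)
  post[1, ] <- post[1, ] + 3
  res <- s0Volcano(pre, post, volcanoConfig(seed = 2))
  expect_true(res$significant[1])
  expect_lt(mean(res$significant[-1]), 0.1)
})

test_that("volcano permutation FDR is calibrated on a null cohort", {
  set.seed(77)
  falseHits <- replicate(15, {
    pre <- matrix(rnorm(100 * 12), 100)
    post <- pre + matrix(rnorm(100 * 12), 100)
    res <- s0Volcano(pre, post, volcanoConfig(nPermutations = 5000,
                                              seed = 3))
    any(res$significant)
  })
  # on a pure null any discovery is false; the rate of seeds with at
  # least one discovery stays near the target FDR
  expect_lte(mean(falseHits), 0.05 + 2 * sqrt(0.05 * 0.95 / 15))
})

test_that("shared-control bootstrap covers known shifts and is
          reproducible", {
  set.seed(11)
  control <- rnorm(47, 0, 0.5)
  groups <- list(null = control, shifted = control + 1)
  r1 <- sharedControlBootstrap(control, groups, nBoot = 2000, seed = 4)
  r2 <- sharedControlBootstrap(control, groups, nBoot = 2000, seed = 4)
  expect_identical(r1, r2)
  expect_equal(r1$meanDiff, c(0, 1))
  expect_true(r1$lower[1] <= 0 && r1$upper[1] >= 0)
  expect_true(r1$lower[2] <= 1 && r1$upper[2] >= 1)
  expect_gt(r1$lower[2], 0.5)
  cover <- replicate(100, {
    ci <- sharedControlBootstrap(rnorm(47, 0, 0.5),
                                 list(g = rnorm(47, 1, 0.5)),
                                 nBoot = 600, seed = sample.int(1e6, 1))
    ci$lower <= 1 && ci$upper >= 1
  })
  expect_gte(mean(cover), 0.85)
  expect_error(sharedControlBootstrap(numeric(0), list(g = 1:3)), "empty")
})

test_that("PCA matches an independent eigendecomposition and reconstructs
          the data", {
  set.seed(13)
  m <- matrix(rnorm(16), 4)
  res <- pcaAnalysis(m, standardScale = TRUE)
  xs <- scale(m)
  eig <- eigen(cov(xs))
  for (j in seq_len(3)) {
    expect_equal(abs(res$loadings[, j]), abs(eig$vectors[, j]),
                 tolerance = 1e-8)
  }
  expect_equal(res$explainedVariance,
               (eig$values / sum(eig$values))[seq_along(res$explainedVariance)],
               tolerance = 1e-8)
  # reconstruction with all components
  rec <- res$scores %*% t(res$loadings)
  expect_lt(max(abs(rec - xs)), 1e-10)
  # identical rows score identically; a line loads on one component
  m2 <- rbind(c(1, 2), c(1, 2), c(3, 4))
  res2 <- pcaAnalysis(m2, standardScale = FALSE)
  expect_equal(res2$scores[1, ], res2$scores[2, ])
  line <- cbind(1:3, 2 * (1:3))
  res3 <- pcaAnalysis(line, standardScale = FALSE)
  expect_equal(res3$explainedVariance[1], 1)
  expect_error(pcaAnalysis(cbind(1:4, rep(1, 4))), "constant column")
})

test_that("kinetic-constant correlations recover built-in structure", {
  expect_equal(unname(kCorrelationSummary(cbind(k2 = 1:5,
                                                k3 = 2 * (1:5)))[1, 2]), 1)
  expect_equal(unname(kCorrelationSummary(cbind(k2 = 1:5,
                                                k3 = -(1:5)))[1, 2]), -1)
  set.seed(19)
  n <- 40
  z <- rnorm(n)
  k3 <- 0.1 + 0.02 * z
  k4 <- 0.05 + 0.01 * (0.8 * z + sqrt(1 - 0.64) * rnorm(n))
  r <- kCorrelationSummary(cbind(k2 = rnorm(n, 0.08, 0.01), k3 = k3,
                                 k4 = k4))
  expect_lt(abs(r["k3", "k4"] - 0.8), 0.15)
})
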