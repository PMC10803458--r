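test_that("ICC(2,k) is exact for perfect agreement and bands correctly", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  res <- icc_2k(m)
  expect_equal(res$icc, 1)
  expect_identical(res$band, "excellent")
  expect_identical(icc_band(0.85), "excellent")
  expect_identical(icc_band(0.39999), "poor")
  expect_identical(icc_band(0.40), "fair")
  expect_identical(icc_band(0.60), "good")
  expect_identical(icc_band(0.75), "excellent")
  expect_error(icc_2k(matrix(3, 4, 2)), "zero total variance")
  expect_error(icc_2k(matrix(1:4, 1, 4)), "at least 2")
})

test_that("ICC(2,k) matches a two-way ANOVA mean-squares oracle", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(4:9, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, mean = 10), n, k)
    got <- icc_2k(m)
    # independent oracle: aov mean squares
    df <- data.frame(y = as.vector(m),
                     row = factor(rep(seq_len(n), k)),
                     col = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
    expect_equal(got$icc, oracle, tolerance = 1e-9)
  }
})

test_that("Pearson validity reports r, p and the published bands", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_validity(x, 2 * x + 3)
  expect_equal(res$r, 1)
  expect_identical(res$band, "very high")
  expect_equal(pearson_validity(x, -x)$r, -1)
  expect_identical(r_band(0.808), "high")
  expect_identical(r_band(0.299), "negligible")
  expect_identical(r_band(0.30), "low")
  expect_identical(r_band(0.50), "moderate")
  expect_identical(r_band(0.70), "high")
  expect_identical(r_band(0.90), "very high")
  expect_error(pearson_validity(rep(1, 5), x), "constant")
})

test_that("Welch t from summaries matches the formula and t.test", {
  same <- welch_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  # antisymmetry
  a <- welch_t_summary(7, 2, 12, 5, 3, 15)
  b <- welch_t_summary(5, 3, 15, 7, 2, 12)
  expect_equal(a$t, -b$t)
  expect_equal(a$df, b$df)
  expect_equal(a$p, b$p)
  # brute-force formula on random summaries
  set.seed(42)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 3)
    s2 <- runif(1, 0.5, 3); n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    got <- welch_t_summary(m1, s1, n1, m2, s2, n2)
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    expect_equal(got$t, (m1 - m2) / sqrt(v1 + v2), tolerance = 1e-12)
    expect_equal(got$df,
                 (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)),
                 tolerance = 1e-12)
  }
  # against stats::t.test on raw data (summaries computed from the sample)
  set.seed(1)
  x <- rnorm(30, 1); y <- rnorm(25, 0.2, 2)
  tt <- t.test(x, y, var.equal = FALSE)
  got <- welch_t_summary(mean(x), sd(x), 30, mean(y), sd(y), 25)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  expect_error(welch_t_summary(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("the Welch screen flags separated columns and not null ones", {
  set.seed(11)
  tab <- data.frame(null_col = rnorm(100),
                    sep_col = c(rnorm(50), rnorm(50, 5)),
                    group = rep(c("a", "b"), each = 50))
  res <- welch_screen(tab)
  expect_false(res$significant[res$parameter == "null_col"])
  expect_true(res$significant[res$parameter == "sep_col"])
  expect_error(welch_screen(data.frame(x = 1:3, group = c("a", "a", "b"))),
               "insufficient")
})

test_that("regenerated cohorts reproduce the reference Welch t values", {
  # mean over 5 seeded replicates to damp Monte Carlo noise on the
  # smaller t statistics
  printed <- reference_welch_tests()
  ts <- sapply(1:5, function(s) {
    tab <- synthetic_reference_cohort(seed = 100 + s)
    scr <- welch_screen(tab)
    scr$t[match(printed$parameter, scr$parameter)]
  })
  expect_true(all(abs(rowMeans(ts) - printed$t) <= 0.15 * abs(printed$t)))
})

test_that("k-means++ clustering is seeded, exact on blobs, and monotone", {
  # degenerate k = 1: centroid at the origin of standardized space
  tab <- data.frame(a = rnorm(20, 5), b = rnorm(20, -2))
  one <- kmeanspp_cluster(tab, k = 1, seed = 3)
  expect_equal(unname(one$centroids[1, ]), c(0, 0), tolerance = 1e-9)
  expect_true(all(one$assignments == 1))

  # three well-separated blobs: perfect recovery (ARI = 1)
  set.seed(5)
  blobs <- data.frame(
    x = c(rnorm(30), rnorm(30, 20), rnorm(30, 40)),
    y = c(rnorm(30), rnorm(30, -20), rnorm(30, 20))
  )
  truth <- rep(1:3, each = 30)
  res <- kmeanspp_cluster(blobs, k = 3, seed = 7)
  expect_equal(adjusted_rand_index(res$assignments, truth), 1)

  # determinism
  res2 <- kmeanspp_cluster(blobs, k = 3, seed = 7)
  expect_identical(res$assignments, res2$assignments)
  expect_identical(res$centroids, res2$centroids)

  # within-cluster sum of squares never increases across Lloyd iterations
  noisy <- data.frame(x = rnorm(200), y = rnorm(200), z = rnorm(200))
  for (seed in 1:5) {
    tr <- kmeanspp_cluster(noisy, k = 4, seed = seed)$wss_trace
    expect_true(all(diff(tr) <= 1e-9))
  }
  expect_error(kmeanspp_cluster(blobs, k = 200, seed = 1), "exceeds")
})

test_that("k-means++ agrees with stats::kmeans on an easy instance", {
  set.seed(9)
  blobs <- data.frame(x = c(rnorm(40), rnorm(40, 12)),
                      y = c(rnorm(40), rnorm(40, -12)))
  ours <- kmeanspp_cluster(blobs, k = 2, seed = 4)
  ref <- stats::kmeans(scale(as.matrix(blobs)), centers = 2, nstart = 5)
  expect_equal(adjusted_rand_index(ours$assignments, ref$cluster), 1)
})

test_that("clustering leaves the caller's RNG stream untouched", {
  set.seed(1234)
  r1 <- runif(1)
  set.seed(1234)
  invisible(kmeanspp_cluster(data.frame(a = 1:10, b = 11:20), k = 2,
                             seed = 99))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
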