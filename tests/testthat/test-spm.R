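# Nonparametric 1-D SPM: pointwise statistic and sign-flip permutation
# inference.

test_that("pointwise paired t matches hand arithmetic", {
  expect_equal(pointwise_paired_t(matrix(0, 5, 7)), rep(0, 7))
  expect_equal(pointwise_paired_t(cbind(c(1, 2, 3))), 2 / (1 / sqrt(3)),
               tolerance = 1e-12)
  d <- matrix(rnorm(30), 5)
  expect_equal(pointwise_paired_t(-d), -pointwise_paired_t(d),
               tolerance = 1e-12)
  # zero sd, nonzero mean: signed infinity sentinel
  expect_identical(pointwise_paired_t(cbind(c(2, 2, 2))), Inf)
  expect_error(pointwise_paired_t(matrix(1, 1, 3)), "2 subjects")
})

test_that("identical conditions give zero t and no clusters", {
  a <- matrix(rnorm(9 * 50), 9)
  r <- snpm_paired(a, a)
  expect_equal(r$t_stat, rep(0, 50))
  expect_identical(nrow(r$clusters), 0L)
})

test_that("a uniform shift at n = 9 attains the minimal exhaustive p", {
  set.seed(101)
  a <- matrix(rnorm(9 * 101, sd = 0.01), 9)
  b <- a + 1                               # constant shift, tiny noise
  r <- snpm_paired(a, b)
  expect_true(r$exhaustive)
  expect_identical(r$n_perm, 512L)
  expect_identical(nrow(r$clusters), 1L)
  expect_equal(r$clusters$start, 0)
  expect_equal(r$clusters$end, 100)
  expect_equal(r$clusters$p_value, 2 / 512, tolerance = 1e-12)
})

test_that("exhaustive inference is deterministic and order invariant", {
  set.seed(55)
  a <- matrix(rnorm(9 * 40), 9)
  b <- a + matrix(rnorm(9 * 40, 0.3, 0.5), 9)
  r1 <- snpm_paired(a, b)
  r2 <- snpm_paired(a, b)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(r1$clusters, r2$clusters)
  perm <- sample(9)
  r3 <- snpm_paired(a[perm, ], b[perm, ])
  expect_equal(r3$threshold, r1$threshold, tolerance = 1e-12)
  expect_equal(r3$t_stat, r1$t_stat, tolerance = 1e-12)
  expect_equal(r3$clusters, r1$clusters, tolerance = 1e-12)
})

test_that("swapping conditions negates t and preserves inference", {
  set.seed(66)
  a <- matrix(rnorm(8 * 30), 8)
  b <- a + matrix(rnorm(8 * 30, 0.4, 0.3), 8)
  r_ab <- snpm_paired(a, b)
  r_ba <- snpm_paired(b, a)
  expect_equal(r_ba$t_stat, -r_ab$t_stat, tolerance = 1e-12)
  expect_equal(r_ba$threshold, r_ab$threshold, tolerance = 1e-12)
  expect_equal(r_ba$clusters, r_ab$clusters, tolerance = 1e-12)
})

test_that("Monte-Carlo with a full budget reproduces exhaustive results", {
  set.seed(8)
  a <- matrix(rnorm(6 * 25), 6)
  b <- a + 0.8
  r_ex <- snpm_paired(a, b, exhaustive_max = 12)
  r_mc <- snpm_paired(a, b, exhaustive_max = 2, n_perm = 64, seed = 1)
  expect_true(r_mc$exhaustive)
  expect_identical(r_mc$threshold, r_ex$threshold)
  expect_identical(r_mc$clusters, r_ex$clusters)
})

test_that("Monte-Carlo mode is reproducible under a seed", {
  set.seed(12)
  a <- matrix(rnorm(15 * 30), 15)
  b <- a + matrix(rnorm(15 * 30, 0.2, 0.4), 15)
  r1 <- snpm_paired(a, b, exhaustive_max = 10, n_perm = 500, seed = 99)
  r2 <- snpm_paired(a, b, exhaustive_max = 10, n_perm = 500, seed = 99)
  expect_false(r1$exhaustive)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("an exactly constant difference yields the minimal attainable p", {
  # zero pointwise variance with nonzero mean: infinite-t sentinel; the
  # only permutations reproducing it are the identity and the full flip
  a <- matrix(1, 6, 10)
  b <- matrix(0, 6, 10)
  r <- snpm_paired(a, b)
  expect_identical(nrow(r$clusters), 1L)
  expect_equal(r$clusters$p_value, 2 / 64, tolerance = 1e-12)
  # at n = 5 the minimal attainable p (2/32) exceeds alpha: no cluster
  r5 <- snpm_paired(matrix(1, 5, 10), matrix(0, 5, 10))
  expect_identical(nrow(r5$clusters), 0L)
})

test_that("SPM results serialize to JSON", {
  set.seed(2)
  a <- matrix(rnorm(9 * 20), 9)
  r <- snpm_paired(a, a + 1)
  path <- tempfile(fileext = ".json")
  write_spm(r, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$threshold, r$threshold, tolerance = 1e-12)
  expect_equal(nrow(x$clusters), nrow(r$clusters))
})
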