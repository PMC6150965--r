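test_that("analysis of deviance equals hand-computed one-way ANOVA", {
  a <- anodev_oneway(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(a$deviance_explained, 150)
  expect_equal(a$statistic, 150)
  expect_identical(a$df_factor, 1L)
  expect_identical(a$df_residual, 4L)
  expect_equal(a$p_value, pf(150, 1, 4, lower.tail = FALSE))

  # agreement with a brute-force sum-of-squares oracle on random instances
  set.seed(501)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    n <- sample(3:9, k, replace = TRUE)
    g <- rep(letters[1:k], times = n)
    v <- rnorm(sum(n), mean = rep(runif(k, 0, 5), times = n))
    a <- anodev_oneway(v, g)
    o <- oracle_anova(v, g)
    expect_equal(a$deviance_explained, o$ss_between, tolerance = 1e-10)
    expect_equal(a$statistic, o$f, tolerance = 1e-10)
    expect_equal(a$p_value, o$p, tolerance = 1e-10)
    expect_identical(a$df_factor, o$df1)
    expect_identical(a$df_residual, o$df2)
  }
})

test_that("degenerate deviance cases are reported, not errors", {
  # identical within and between: no explained deviance, p = 1
  a <- anodev_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(a$deviance_explained, 0)
  expect_equal(a$p_value, 1)
  expect_false(a$degenerate)

  # zero residual deviance with a real group effect: p = 0, flagged
  b <- anodev_oneway(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_equal(b$p_value, 0)
  expect_true(b$degenerate)

  expect_error(anodev_oneway(1:5, rep("a", 5)), ">= 2 group")
})

test_that("level pooling matches the brute-force oracle on small data", {
  # well-separated third group: {g1, g2} pooled, {g3} apart
  set.seed(502)
  g <- rep(c("g1", "g2", "g3"), each = 10)
  v <- rnorm(30, mean = rep(c(0, 0, 100), each = 10), sd = 1)
  res <- pool_levels(v, g)
  expect_identical(canonical_partition(res$partition),
                   list(c("g1", "g2"), "g3"))
  expect_identical(unname(res$letters[c("g1", "g2", "g3")]),
                   c("b", "b", "a"))  # "a" = largest mean

  # randomized oracle suite over 2..5 levels
  set.seed(503)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    n <- sample(4:8, k, replace = TRUE)
    g <- rep(paste0("L", 1:k), times = n)
    mu <- runif(k, 0, 6)
    v <- rnorm(sum(n), mean = rep(mu, times = n), sd = runif(1, 0.3, 2))
    res <- pool_levels(v, g)
    expect_identical(canonical_partition(res$partition), oracle_pool(v, g))
  }
})

test_that("pooling extremes: alpha near 0 pools all, near 1 pools none", {
  set.seed(504)
  g <- rep(letters[1:4], each = 8)
  v <- rnorm(32, mean = rep(c(0, 2, 5, 9), each = 8))
  expect_length(pool_levels(v, g, alpha = 1e-12)$partition, 1L)
  expect_length(pool_levels(v, g, alpha = 1 - 1e-12)$partition, 4L)
})

test_that("letters are consistent with blocks and ordered by block mean", {
  set.seed(505)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    g <- rep(paste0("L", 1:k), each = 6)
    v <- rnorm(6 * k, mean = rep(runif(k, 0, 8), each = 6))
    res <- pool_levels(v, g)
    # same letter iff same block
    for (b in res$partition) {
      expect_length(unique(res$letters[b]), 1L)
      expect_false(any(res$letters[setdiff(names(res$letters), b)] %in%
                         res$letters[b[1]]))
    }
    # block means strictly descending across letters a, b, c ...
    expect_false(is.unsorted(rev(res$block_means)))
  }
})

test_that("zero-variance data collapse to a single flagged block", {
  res <- pool_levels(rep(3, 12), rep(c("a", "b", "c"), each = 4))
  expect_length(res$partition, 1L)
  expect_true(res$degenerate)
})

test_that("per-chromosome tests use both homologues and report df (k-1, N-k)", {
  d <- simulate_study(table1_params(), seed = 99)
  pc <- per_chromosome_tests(d)
  expect_identical(nrow(pc), 10L)
  expect_true(all(pc$df_factor == 4L))
  expect_true(all(pc$df_residual == 95L))  # 5 pops x 10 metaphases x 2 homologues

  # two identical populations: p = 1 everywhere
  one <- as.data.frame(simulate_measurements(table1_params()[["CI"]], seed = 1))
  two <- one; two$population_id <- "CI2"; two$colony_id <- "CI2"
  two$specimen_id <- sub("^CI", "CI2", two$specimen_id)
  dd <- measurement_dataset(rbind(one, two))
  pc2 <- per_chromosome_tests(dd)
  expect_true(all(pc2$p_value == 1))

  # Holm correction is monotone non-decreasing relative to raw p
  pc3 <- per_chromosome_tests(d, correction = "holm")
  expect_true(all(pc3$p_adjusted >= pc3$p_value - 1e-15))

  expect_error(per_chromosome_tests(
    simulate_measurements(table1_params()[["CI"]], seed = 1)), ">= 2 popul")
})

test_that("largest-vs-smallest chromosome contrast has high power at n = 20", {
  # rank-1 homologue lengths for the longest vs shortest karyotype
  # populations: means 6.29/6.06 vs 4.87/4.58, SDs ~0.8 vs ~0.6
  hits <- 0L
  for (s in 1:200) {
    set.seed(600 + s)
    v <- c(rnorm(10, 6.29, 0.82), rnorm(10, 6.06, 0.83),
           rnorm(10, 4.87, 0.60), rnorm(10, 4.58, 0.63))
    g <- rep(c("CI", "CC"), each = 20)
    if (anodev_oneway(v, g)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% of seeds
})
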