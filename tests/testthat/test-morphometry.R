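test_that("arm ratio is the long/short quotient with guarded domain", {
  expect_equal(arm_ratio(2, 2), 1)
  expect_equal(arm_ratio(3.4, 1), 3.4)
  expect_equal(arm_ratio(c(3, 5), c(2, 2)), c(1.5, 2.5))
  expect_error(arm_ratio(1, 0), "short arm")
  expect_error(arm_ratio(1, 2), ">= short arm")
})

test_that("morphology classes are a monotone, lower-inclusive step function", {
  expect_identical(classify_morphology(1), "M")
  # boundary semantics: a ratio exactly on a bound belongs to the higher class
  expect_identical(classify_morphology(c(1.6999, 1.7, 2.9999, 3.0, 6.9999, 7.0)),
                   c("M", "SM", "SM", "ST", "ST", "A"))
  expect_identical(classify_morphology(100), "A")
  expect_error(classify_morphology(0.9), ">= 1")

  # monotone over a sweep: class index never decreases as r grows
  r <- seq(1, 12, by = 0.01)
  cls <- classify_morphology(r)
  idx <- match(cls, c("M", "SM", "ST", "A"))
  expect_false(is.unsorted(idx))

  # arm ratio at the first bound classifies as SM via the same path
  expect_identical(classify_morphology(arm_ratio(1.7, 1.0)), "SM")
})

test_that("relative lengths are percentages that sum to 100", {
  expect_equal(relative_length(5, 100), 5)
  expect_equal(relative_length(6.29, 83.06), 6.29 * 100 / 83.06)
  # 2n equal chromosomes each get 100/2n
  expect_equal(relative_length(rep(2.5, 20)), rep(5, 20))
  expect_error(relative_length(1, 0), "> 0")

  # property: sums to 100 for random metaphases
  set.seed(401)
  for (i in 1:25) {
    tl <- runif(2 * sample(5:12, 1), 0.5, 8)
    expect_equal(sum(relative_length(tl)), 100, tolerance = 1e-9)
  }
})

test_that("asymmetry index spans [50, 100] with the metacentric floor", {
  allmeta <- data.frame(long_arm_um = c(2, 3), short_arm_um = c(2, 3))
  expect_equal(asymmetry_index(allmeta), 50)
  expect_equal(asymmetry_index(data.frame(long_arm_um = c(3, 2),
                                          short_arm_um = c(1, 2))), 62.5)
  # telocentric limit approaches 100
  near_telo <- data.frame(long_arm_um = rep(3, 4),
                          short_arm_um = rep(1e-6, 4))
  expect_gt(asymmetry_index(near_telo), 99.99)
  expect_error(asymmetry_index(data.frame()), "empty")

  # property: AI in [50, 100], and 50 only when all arms equal
  set.seed(402)
  for (i in 1:25) {
    s <- runif(10, 0.5, 3); l <- s * runif(10, 1, 6)
    ai <- asymmetry_index(data.frame(long_arm_um = l, short_arm_um = s))
    expect_true(ai >= 50 && ai <= 100)
    if (any(l > s)) expect_gt(ai, 50)
  }
})

test_that("karyotype length sums lengths for metaphases and summaries", {
  expect_equal(karyotype_length(4.0), 4.0)
  expect_equal(karyotype_length(data.frame(total_length_um = c(2, 3, 4))), 9)
  d <- tiny_dataset()
  s <- summarize_population(d, "P1")
  expect_equal(karyotype_length(s), attr(s, "karyotype_length_um"))
})

test_that("karyotype formula renders class counts and arm number", {
  kf <- karyotype_formula(rep("M", 20))
  expect_identical(kf$formula_string, "2K = 20M")
  expect_identical(kf$arm_number_2AN, 40L)
  expect_identical(kf$ploidy_2n, 20L)
  expect_identical(kf$haploid_n, 10L)

  expect_identical(karyotype_formula(rep("A", 2))$formula_string, "2K = 2A")
  expect_identical(karyotype_formula(rep("A", 2))$arm_number_2AN, 2L)

  kf2 <- karyotype_formula(c(rep("M", 10), rep("SM", 10)))
  expect_identical(kf2$formula_string, "2K = 10M + 10SM")
  expect_identical(kf2$arm_number_2AN, 40L)

  expect_error(karyotype_formula(rep("M", 3)), "even")
  expect_error(karyotype_formula(c("M", "Q")), "unknown")
})

test_that("population summary recovers means, SDs and morphology", {
  # single metaphase: means are the raw values, SD reported as 0 and flagged
  d1 <- measurement_dataset(data.frame(
    population_id = "P", specimen_id = "s",
    long_arm_um = c(3, 2.6), short_arm_um = c(2.8, 2.5)))
  s1 <- summarize_population(d1, "P")
  expect_equal(s1$mean_tl_um, c(5.8, 5.1))
  expect_equal(s1$sd_tl_um, c(0, 0))
  expect_false(attr(s1, "sd_defined"))

  # two identical metaphases: SD exactly 0 everywhere
  df <- data.frame(population_id = "P", specimen_id = rep(c("a", "b"), each = 2),
                   long_arm_um = rep(c(3, 2.6), 2),
                   short_arm_um = rep(c(2.8, 2.5), 2))
  s2 <- summarize_population(measurement_dataset(df), "P")
  expect_equal(s2$sd_tl_um, c(0, 0))
  expect_true(attr(s2, "sd_defined"))

  # parameter recovery at n = 10 from the packaged CI parameters.  Ranks
  # are re-assigned by descending TL after simulation, which biases the
  # extreme rank means (order statistics), so recovery is asserted where
  # it holds: the rank-1 mean and the karyotype length, each within 3 SE.
  p_ci <- table1_params()[["CI"]]
  s3 <- summarize_population(simulate_measurements(p_ci, seed = 2024), "CI")
  expect_lt(abs(s3$mean_tl_um[1] - 6.29),
            3 * p_ci$sd_tl_um[1] / sqrt(p_ci$n_metaphases))
  expect_lt(abs(attr(s3, "karyotype_length_um") - 83.06),
            3 * sqrt(sum(p_ci$sd_tl_um^2)) / sqrt(p_ci$n_metaphases))
  expect_true(all(s3$morphology == "M"))

  expect_error(summarize_population(tiny_dataset(), "nope"), "no metaphases")
})

test_that("karyotype CV and the one-SD validation rule", {
  expect_equal(karyotype_cv(c(5, 5, 5)), 0)
  expect_equal(karyotype_cv(c(80, 90, 100)), 10 / 90)
  expect_equal(karyotype_cv(c(80, 90, 100) * 7), 10 / 90)  # scale invariant
  expect_error(karyotype_cv(5), ">= 2")

  expect_true(cv_validation(c(0.1, 0.1, 0.1))$pass)
  v <- cv_validation(c(0.1, 0.1, 0.1, 0.5))
  expect_false(v$pass)
  expect_identical(v$flagged, 4L)

  # with two values |x - mean| = |x1 - x2|/2 < SD = |x1 - x2|/sqrt(2),
  # so any pair passes; verify by brute force
  set.seed(403)
  for (i in 1:50) expect_true(cv_validation(runif(2))$pass)
})
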