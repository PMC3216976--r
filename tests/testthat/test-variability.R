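test_that("probe variance is the unbiased pairwise-complete s2", {
  samples <- sprintf("s%d", 1:3)
  md <- meta_df(samples, rep("first", 3))
  b <- beta_mat(c(0, 0.5, 0.2, 1, 0.5, 0.3, NA, 0.5, 0.4), 3, 3,
                samples = samples)
  s2 <- probe_variance(b, md)
  expect_equal(unname(s2["p01", "first"]), 0.5)   # {0, 1}, n = 2
  expect_equal(unname(s2["p02", "first"]), 0)     # constant
  expect_equal(unname(s2["p03", "first"]), 0.01)  # {0.2, 0.3, 0.4}

  # fewer than two values: missing
  b2 <- beta_mat(c(0.1, NA, NA), 1, 3, samples = samples)
  expect_true(is.na(probe_variance(b2, md)[1, "first"]))
})

test_that("variability classes follow the two cutoffs", {
  cl <- classify_variability(c(0.001, 0.015, 0.05))
  expect_equal(cl$class, c("low", "intermediate", "high"))
  expect_equal(unname(cl$counts), c(1L, 1L, 1L))

  cl0 <- classify_variability(rep(0, 5))
  expect_true(all(cl0$class == "low"))

  expect_error(classify_variability(0.1, high_cut = 0.005, low_cut = 0.009))
})

test_that("chi-square on variable-probe counts matches Pearson's statistic", {
  # the published first-vs-third comparison reproduces to one decimal
  res <- compare_variable_counts(352, 106, 26162)
  expect_equal(round(res$chisq, 1), 133.3)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 0.001)

  # identical proportions give exactly zero
  expect_equal(compare_variable_counts(50, 50, 1000)$chisq, 0)

  # independent route: chisq.test without continuity correction
  ours <- compare_variable_counts(20, 5, 1000)
  ref <- chisq.test(matrix(c(20, 980, 5, 995), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # symmetric in the two counts
  expect_equal(compare_variable_counts(20, 5, 1000)$chisq,
               compare_variable_counts(5, 20, 1000)$chisq)

  expect_error(compare_variable_counts(1, 1, 0), "positive")
})

test_that("quadrant partition classifies first/third variance pairs", {
  s1 <- c(a = 0.03, b = 0.03, c = 0.01, d = 0.01)
  s3 <- c(a = 0.03, b = 0.01, c = 0.03, d = 0.01)
  q <- quadrant_partition(s1, s3)
  expect_equal(unname(q$counts), c(1L, 1L, 1L, 1L))
  expect_equal(q$sets$A, "a")
  expect_equal(q$sets$B, "b")
  expect_equal(q$sets$C, "c")

  # all below the cut
  q0 <- quadrant_partition(c(x = 0.001, y = 0.002), c(x = 0.001, y = 0.002))
  expect_equal(unname(q0$counts["neither"]), 2L)

  # missing variances go to neither with a warning
  expect_warning(qm <- quadrant_partition(c(a = NA, b = 0.05),
                                          c(a = 0.05, b = 0.05)), "missing")
  expect_equal(qm$sets$A, "b")
  expect_equal(qm$n_missing, 1L)
})

test_that("quadrant counts satisfy the bookkeeping identities", {
  set.seed(19)
  s1 <- setNames(rexp(500, 80), sprintf("p%03d", 1:500))
  s3 <- setNames(rexp(500, 60), names(s1))
  q <- quadrant_partition(s1, s3)
  expect_equal(unname(q$counts["A"] + q$counts["B"]), sum(s1 > 0.02))
  expect_equal(unname(q$counts["A"] + q$counts["C"]), sum(s3 > 0.02))
  expect_equal(sum(q$counts), 500L)
})

test_that("venn partition equals brute-force membership enumeration", {
  expect_equal(unname(venn_partition("a", "b", "c")),
               c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  s <- c("x", "y", "z")
  expect_equal(unname(venn_partition(s, s, s)),
               c(0L, 0L, 0L, 0L, 0L, 0L, 3L))

  set.seed(23)
  universe <- sprintf("p%02d", 1:50)
  for (i in 1:20) {
    A <- sample(universe, sample(0:30, 1))
    B <- sample(universe, sample(0:30, 1))
    C <- sample(universe, sample(0:30, 1))
    v <- venn_partition(A, B, C)
    brute <- table(factor(
      vapply(union(union(A, B), C), function(x) {
        paste0(as.integer(x %in% A), as.integer(x %in% B),
               as.integer(x %in% C))
      }, character(1)),
      levels = c("100", "010", "001", "110", "101", "011", "111")))
    expect_equal(unname(v), as.vector(unname(brute)))
    expect_equal(sum(v), length(union(union(A, B), C)))
  }
})

test_that("variance-by-level cross-tab matches hand enumeration", {
  samples <- sprintf("s%d", 1:4)
  md <- meta_df(samples, rep("first", 4))
  # 6 probes with known means and spreads
  b <- rbind(
    c(0.10, 0.10, 0.10, 0.10),   # low band, zero variance
    c(0.05, 0.15, 0.05, 0.15),   # low band, s2 ~ 0.0033 (low class)
    c(0.30, 0.50, 0.30, 0.50),   # intermediate band, s2 ~ 0.0133 (interm.)
    c(0.20, 0.60, 0.20, 0.60),   # intermediate band, s2 ~ 0.053 (high)
    c(0.70, 0.70, 0.70, 0.70),   # high band, zero variance
    c(0.65, 0.95, 0.65, 0.95))   # high band, s2 = 0.03 (high)
  dimnames(b) <- list(sprintf("p%d", 1:6), samples)
  s2 <- probe_variance(b, md)
  tab <- variance_by_level(b, md, s2)$first
  expect_equal(tab["low", "low"], 2L, ignore_attr = TRUE)
  expect_equal(tab["intermediate", "intermediate"], 1L, ignore_attr = TRUE)
  expect_equal(tab["intermediate", "high"], 1L, ignore_attr = TRUE)
  expect_equal(tab["high", "low"], 1L, ignore_attr = TRUE)
  expect_equal(tab["high", "high"], 1L, ignore_attr = TRUE)

  # marginals agree with classify_variability
  cl <- classify_variability(s2)
  expect_equal(unname(colSums(tab)), unname(cl$counts[, "first"]))
})

test_that("high-variance probes concentrate in the intermediate band", {
  ds <- generate_dataset(small_config(seed = 15, n_probes = 5000L,
                                      n_variable_third = 75L))
  b <- drop_sex_chromosomes(compute_beta(ds$signals), ds$annotation)
  s2 <- probe_variance(b, ds$metadata)
  tab <- variance_by_level(b, ds$metadata, s2)$third
  high_col <- tab[, "high"]
  expect_gt(high_col[["intermediate"]] / sum(high_col), 0.5)
})

test_that("null cohorts show no third-vs-first excess of variable probes", {
  reject <- 0L
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_probes = 2000L,
                             n_progressive = 0L, n_variable_third = 0L)
    ds <- generate_dataset(cfg)
    s2 <- probe_variance(ds$beta_observed, ds$metadata)
    k1 <- sum(s2[, "first"] > 0.02, na.rm = TRUE)
    k3 <- sum(s2[, "third"] > 0.02, na.rm = TRUE)
    if (k1 + k3 > 0 &&
        compare_variable_counts(k3, k1, nrow(s2))$p <= 0.01) {
      reject <- reject + 1L
    }
  }
  expect_lte(reject, 1L)
})
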