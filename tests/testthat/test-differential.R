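test_that("delta_beta is the later-minus-earlier group mean difference", {
  samples <- sprintf("s%d", 1:4)
  md <- meta_df(samples, c("first", "first", "third", "third"))
  b <- beta_mat(c(0.1, 0.1, 0.1, 0.1, 0.35, 0.35, 0.35, 0.35), 2, 4,
                samples = samples)
  d <- delta_beta(b, md, "first", "third")
  expect_equal(unname(d), c(0.25, 0.25))

  # identical groups: zero everywhere
  b2 <- beta_mat(rep(c(0.4, 0.6), 4), 2, 4, samples = samples)
  expect_equal(unname(delta_beta(b2, md, "first", "third")), c(0, 0))

  # a group entirely missing for a probe yields NA
  b3 <- b
  b3[1, c("s1", "s2")] <- NA
  expect_true(is.na(delta_beta(b3, md, "first", "third")[1]))

  expect_error(delta_beta(b, md, "first", "second"), "present")
})

test_that("per-probe t-test matches the closed-form pooled statistic", {
  samples <- sprintf("s%d", 1:4)
  md <- meta_df(samples, c("first", "first", "third", "third"))
  b <- beta_mat(c(0.1, 0.2, 0.6, 0.7), 1, 4, samples = samples)
  # hand computation: means 0.15 / 0.65, each variance 0.005,
  # pooled se = sqrt(0.005 * (1/2 + 1/2)) = sqrt(0.005), df = 2
  res <- probe_test(b, md, "first", "third")
  t_hand <- 0.5 / sqrt(0.005)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-t_hand, 2), tolerance = 1e-10)

  # agrees with stats::t.test as an independent route
  tt <- t.test(c(0.6, 0.7), c(0.1, 0.2), var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # identical groups: p = 1
  b2 <- beta_mat(rep(c(0.3, 0.5), 2), 1, 4, samples = samples)
  expect_equal(probe_test(b2, md, "first", "third")$p, 1)
})

test_that("null data give uniform p-values", {
  set.seed(31)
  samples <- sprintf("s%02d", 1:20)
  md <- meta_df(samples, rep(c("first", "third"), each = 10))
  b <- beta_mat(rbeta(1000 * 20, 4, 6), 1000, 20, samples = samples)
  p <- probe_test(b, md, "first", "third")$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment reproduces hand step-up results", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.04), 0.04)
  # NAs are excluded from m and propagated
  expect_equal(adjust_bh(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up on random short vectors", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    p <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)
    expect_equal(adjust_bh(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("differential classification applies both thresholds", {
  res <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    delta_beta = c(0.25, 0.21, -0.3, 0.05, 0.19, -0.2),
    adj_p = rep(0.01, 6))
  cl <- classify_differential(res, 0.2, 0.05)
  expect_equal(cl$n_hyper, 2L)   # 0.25, 0.21 (>= convention)
  expect_equal(cl$n_hypo, 2L)    # -0.3, -0.2
  expect_setequal(cl$hyper, c("p1", "p2"))
  expect_setequal(cl$hypo, c("p3", "p6"))
  expect_length(intersect(cl$hyper, cl$hypo), 0)

  # insignificant probes never classify
  res$adj_p <- 0.5
  cl2 <- classify_differential(res, 0.2, 0.05)
  expect_equal(cl2$n_hyper + cl2$n_hypo, 0L)

  # all-zero deltas classify nothing
  res$delta_beta <- 0; res$adj_p <- 0.001
  cl3 <- classify_differential(res)
  expect_equal(cl3$n_hyper + cl3$n_hypo, 0L)
})

test_that("swapping groups exchanges hyper and hypo sets", {
  ds <- generate_dataset(small_config(seed = 13))
  b <- ds$beta_observed
  md <- ds$metadata
  fwd <- classify_differential(
    differential_comparison(b, md, "first", "third"))
  rev <- classify_differential(
    differential_comparison(b, md, "third", "first"))
  expect_setequal(fwd$hyper, rev$hypo)
  expect_setequal(fwd$hypo, rev$hyper)
})

test_that("null cohorts yield essentially no differential calls", {
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_probes = 3000L,
                             n_progressive = 0L, n_variable_third = 0L)
    ds <- generate_dataset(cfg)
    res <- differential_comparison(ds$beta_observed, ds$metadata,
                                   "first", "third")
    cl <- classify_differential(res, 0.2, 0.05)
    expect_lte(cl$n_hyper + cl$n_hypo, 2L)
  }
})

test_that("fluctuating-pattern screen applies both rule parts", {
  m1 <- c(a = 0.1, b = 0.2, c = 0.3)
  m2 <- c(a = 0.2, b = 0.45, c = 0.3)
  m3 <- c(a = 0.3, b = 0.22, c = 0.3)
  # probe a is monotone: |first - third| = 0.2, not < 0.1
  expect_length(detect_fluctuating(m1["a"], m2["a"], m3["a"],
                                   threshold = 0.1), 0)
  # probe b spikes in second trimester at threshold 0.2
  expect_equal(detect_fluctuating(m1, m2, m3, threshold = 0.2), "b")
  # constant probes are never flagged
  const <- c(x = 0.4, y = 0.4)
  expect_length(detect_fluctuating(const, const, const), 0)
})

test_that("transition comparison recovers planted week effects", {
  set.seed(41)
  n <- 20
  samples <- sprintf("s%02d", 1:7)
  md <- meta_df(samples, "first", weeks = c(8L, 8L, 8L, 8L, 12L, 12L, 12L))
  base <- matrix(runif(n, 0.2, 0.5), n, 7)
  dimnames(base) <- list(sprintf("p%02d", 1:n), samples)
  b <- base + matrix(rnorm(n * 7, 0, 0.005), n, 7)
  w12 <- md$sample_id[md$gestational_week == 12]
  planted <- sprintf("p%02d", 1:5)
  b[planted, w12] <- b[planted, w12] + 0.3

  res <- transition_comparison(b, md)
  cl <- classify_differential(res, 0.2, 0.05)
  expect_setequal(cl$hyper, planted)
  expect_equal(cl$n_hypo, 0L)
  # positive delta means hypermethylated at the later week
  expect_true(all(res$delta_beta[res$probe_id %in% planted] > 0.25))

  # identical week groups: nothing called
  b0 <- base
  res0 <- transition_comparison(b0 + matrix(rnorm(n * 7, 0, 0.005), n, 7),
                                md)
  cl0 <- classify_differential(res0, 0.2, 0.05)
  expect_equal(cl0$n_hyper + cl0$n_hypo, 0L)

  # missing week labels are refused
  md_na <- md; md_na$gestational_week <- NA_integer_
  expect_error(transition_comparison(b, md_na), "week")
})
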