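test_that("identical config and seed give identical datasets", {
  d1 <- generate_dataset(small_config(seed = 9))
  d2 <- generate_dataset(small_config(seed = 9))
  expect_identical(d1$beta_observed, d2$beta_observed)
  expect_identical(d1$signals$A, d2$signals$A)
  expect_identical(d1$signals$detection_p, d2$signals$detection_p)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$truth_labels, d2$truth_labels)
  expect_identical(d1$expression, d2$expression)

  d3 <- generate_dataset(small_config(seed = 10))
  expect_false(identical(d1$beta_observed, d3$beta_observed))
})

test_that("noiseless limit reproduces the planted group means", {
  cfg <- small_config(seed = 2, noise_precision = 1e6,
                      detection_fail_rate = 0, batch_shift = 0,
                      n_variable_third = 0L)
  ds <- generate_dataset(cfg)
  grp <- ds$metadata$group[match(colnames(ds$beta_observed),
                                 ds$metadata$sample_id)]
  for (g in unique(grp)) {
    emp <- rowMeans(ds$beta_observed[, grp == g, drop = FALSE])
    expect_lt(max(abs(emp - ds$beta_truth[, grp == g][, 1])), 0.005)
  }
})

test_that("mixture and annotation fractions match the configuration", {
  ds <- generate_dataset(simulation_config(seed = 6))
  grp <- ds$metadata$group[match(colnames(ds$beta_observed),
                                 ds$metadata$sample_id)]
  first_means <- rowMeans(ds$beta_observed[, grp == "first", drop = FALSE])
  expect_equal(mean(first_means < 0.2), 0.63, tolerance = 0.02)
  expect_equal(mean(ds$annotation$cgi == "CGI"), 0.76, tolerance = 0.02)
  frac_sex <- mean(ds$annotation$chromosome %in% c("X", "Y"))
  expect_equal(frac_sex, 0.04, tolerance = 0.005)
})

test_that("truth labels are mutually exclusive and match the plan", {
  ds <- generate_dataset(small_config(seed = 8))
  expect_equal(sum(ds$truth_labels$label == "progressive"), 50L)
  expect_equal(sum(ds$truth_labels$label == "variable_third"), 30L)
  expect_true(all(ds$truth_labels$label %in%
                    c("progressive", "variable_third", "null")))
  # plants live on autosomes
  planted <- ds$truth_labels$probe_id[ds$truth_labels$label != "null"]
  chr <- ds$annotation$chromosome[match(planted, ds$annotation$probe_id)]
  expect_false(any(chr %in% c("X", "Y")))
})

test_that("plants exceeding band capacity are rejected", {
  expect_error(
    generate_dataset(simulation_config(seed = 1, n_probes = 200L,
                                       n_progressive = 190L,
                                       n_variable_third = 0L)),
    "capacity")
})

test_that("variance plants leave the group mean at its baseline", {
  cfg <- small_config(seed = 12, batch_shift = 0)
  ds <- generate_dataset(cfg)
  varb <- ds$truth_labels$probe_id[ds$truth_labels$label == "variable_third"]
  third <- ds$metadata$sample_id[ds$metadata$group == "third"]
  emp <- rowMeans(ds$beta_observed[varb, third])
  truth <- ds$beta_truth[varb, third[1]]
  # dispersal is symmetric: group means unbiased for the baseline
  expect_lt(max(abs(emp - truth)), 0.12)
  expect_lt(abs(mean(emp - truth)), 0.01)
})

test_that("expression coupling follows the linear model", {
  # zero slope, zero noise: constant expression
  ds <- generate_dataset(small_config(seed = 3))
  e0 <- generate_expression(ds, slope = 0, noise_sd = 0)
  expect_true(all(vapply(e0, function(m) diff(range(m)) == 0, logical(1))))
  expect_equal(unname(e0$first[1, 1]), 8)

  # slope -2, no noise: expression differences are -2x beta differences
  e2 <- generate_expression(ds, slope = -2, noise_sd = 0)
  ann <- ds$annotation
  first <- ds$metadata$sample_id[ds$metadata$group == "first"]
  gm <- rowMeans(ds$beta_truth[, first])
  gene_beta <- tapply(gm, ann$gene_symbol[match(names(gm), ann$probe_id)],
                      mean)
  g <- names(gene_beta)[1:2]
  expect_equal(e2$first[g[1], 1] - e2$first[g[2], 1],
               -2 * (gene_beta[[g[1]]] - gene_beta[[g[2]]]),
               tolerance = 1e-12)
})

test_that("epityper generator plants the three failure archetypes", {
  clean <- generate_epityper_table(10, 5, site_fail = 0, sample_fail = 0)
  expect_false(anyNA(clean$table))
  expect_length(clean$truth$rule1_samples, 0)

  # force one all-fail sample deterministically
  planted <- generate_epityper_table(10, 5, site_fail = 0, sample_fail = 0.3,
                                     seed = 21)
  af <- planted$truth$rule1_samples
  if (length(af)) {
    expect_true(all(is.na(planted$table[, af])))
  }
  # a high-fail site fails in 60% of surviving samples (> 40% rule)
  hf <- generate_epityper_table(20, 10, site_fail = 0.3, sample_fail = 0,
                                seed = 4)
  for (s in hf$truth$rule2_sites) {
    expect_gt(mean(is.na(hf$table[s, ])), 0.4)
  }
  # reproducibility
  expect_identical(generate_epityper_table(8, 6, 0.2, 0.2, seed = 5),
                   generate_epityper_table(8, 6, 0.2, 0.2, seed = 5))
})

test_that("written dataset files round-trip through the readers", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(simulation_config(seed = 2, n_probes = 300L,
                                           n_progressive = 10L,
                                           n_variable_third = 5L))
  write_dataset(ds, dir)
  beta <- read_beta_matrix(file.path(dir, "beta.tsv"))
  expect_equal(dim(beta), dim(ds$beta_observed))
  expect_equal(beta, ds$beta_observed, tolerance = 1e-6)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$group, ds$metadata$group)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$cgi, ds$annotation$cgi)
})
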