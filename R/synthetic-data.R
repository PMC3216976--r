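#' Simulation configuration for a synthetic gestational cohort
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 18/10/14 samples in first/second/third trimester, ~63% of probes with
#' beta < 0.2 and 13% above 0.6, 76% of probes in CpG islands, planted
#' progressive methylation gains of 0.15 per trimester step on
#' intermediate-band (mostly non-CGI) probes, and planted third-trimester
#' variance inflation (expected s2 = 0.03, mostly CGI probes). The
#' progressive increment is set so the planted first-to-third gain (0.3)
#' clears the delta-beta >= 0.2 calling threshold with high power at
#' these group sizes; an effect planted exactly at a threshold is
#' recovered only half the time by an unbiased estimator.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the config including the seed.
#' @param n_probes Total probe count (autosomal + sex-chromosome).
#' @param n_samples_per_group Named counts for first/second/third.
#' @param band_proportions Fractions of probes with baseline mean beta in
#'   the low (< 0.2), intermediate (0.2-0.6) and high (> 0.6) bands; must
#'   sum to 1.
#' @param cgi_fraction Fraction of probes annotated to CpG islands.
#' @param n_progressive Number of probes with a planted progressive gain.
#' @param progressive_delta Mean beta increment per trimester step for
#'   planted progressive probes (first -> third gain is twice this).
#' @param progressive_noncgi_fraction Fraction of progressive plants drawn
#'   from non-CGI probes.
#' @param n_variable_third Number of probes with planted third-trimester
#'   variance inflation.
#' @param variance_target Expected third-trimester sample variance of a
#'   variance plant. Implemented as a symmetric two-point dispersal of
#'   per-sample means (half the samples shifted up, half down) with the
#'   base Beta noise on top, so the group mean is unshifted and the
#'   planted s2 concentrates tightly around the target.
#' @param variable_cgi_fraction Fraction of variance plants drawn from
#'   CGI probes.
#' @param noise_precision Beta-distribution precision (a + b) of
#'   per-sample noise around the probe-group mean; variance is
#'   m(1-m)/(precision + 1).
#' @param batch_count Number of processing batches (balanced over groups).
#' @param batch_shift Total logit-scale offset spread across batches.
#' @param detection_fail_rate Probability a (probe, sample) cell has
#'   detection p >= 0.05.
#' @param expression_slope Coupling coefficient from gene-level beta to
#'   log-expression (negative: methylation represses).
#' @param expression_noise_sd SD of per-sample log-expression noise.
#' @param sexchrom_fraction Fraction of probes assigned to X/Y.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_probes = 20000L,
                              n_samples_per_group = c(first = 18L,
                                                      second = 10L,
                                                      third = 14L),
                              band_proportions = c(low = 0.63,
                                                   intermediate = 0.24,
                                                   high = 0.13),
                              cgi_fraction = 0.76,
                              n_progressive = 500L,
                              progressive_delta = 0.15,
                              progressive_noncgi_fraction = 0.8,
                              n_variable_third = 300L,
                              variance_target = 0.03,
                              variable_cgi_fraction = 0.9,
                              noise_precision = 100,
                              batch_count = 2L,
                              batch_shift = 0.05,
                              detection_fail_rate = 0.0003,
                              expression_slope = -2,
                              expression_noise_sd = 0.5,
                              sexchrom_fraction = 0.04) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              n_samples_per_group = n_samples_per_group,
              band_proportions = band_proportions,
              cgi_fraction = cgi_fraction,
              n_progressive = as.integer(n_progressive),
              progressive_delta = progressive_delta,
              progressive_noncgi_fraction = progressive_noncgi_fraction,
              n_variable_third = as.integer(n_variable_third),
              variance_target = variance_target,
              variable_cgi_fraction = variable_cgi_fraction,
              noise_precision = noise_precision,
              batch_count = as.integer(batch_count),
              batch_shift = batch_shift,
              detection_fail_rate = detection_fail_rate,
              expression_slope = expression_slope,
              expression_noise_sd = expression_noise_sd,
              sexchrom_fraction = sexchrom_fraction)
  stopifnot(abs(sum(cfg$band_proportions) - 1) < 1e-8,
            all(cfg$band_proportions >= 0),
            cfg$cgi_fraction >= 0, cfg$cgi_fraction <= 1,
            cfg$sexchrom_fraction >= 0, cfg$sexchrom_fraction < 1,
            cfg$detection_fail_rate >= 0, cfg$detection_fail_rate <= 1,
            cfg$n_progressive >= 0, cfg$n_variable_third >= 0,
            cfg$n_probes > 0,
            cfg$n_progressive + cfg$n_variable_third <= cfg$n_probes,
            cfg$noise_precision > 0, cfg$variance_target > 0,
            all(cfg$n_samples_per_group >= 0),
            setequal(names(cfg$n_samples_per_group),
                     c("first", "second", "third")))
  structure(cfg, class = "simulation_config")
}

group_levels <- c("first", "second", "third")

week_ranges <- list(first = 8:12, second = 17:24, third = 34:41)

#' Generate a synthetic gestational methylation cohort
#'
#' Draws per-probe baseline means from the three-band beta mixture,
#' plants progressive gains and third-trimester variance inflation,
#' simulates per-sample beta-values from a Beta(mean, precision) noise
#' model with logit-scale batch offsets, back-computes signal pairs so
#' that [compute_beta()] reproduces the drawn beta exactly, and couples
#' gene-level expression negatively to methylation.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `signals`
#'   ([signal_pair()]), `beta_observed`, `beta_truth` (noiseless
#'   probe-group means expanded to samples), `annotation`, `metadata`,
#'   `truth_labels` (probe_id + label in progressive/variable_third/null),
#'   and `expression` (per-group gene x sample matrices).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  P <- config$n_probes
  ns <- config$n_samples_per_group[group_levels]
  N <- sum(ns)

  probe_id <- sprintf("cg%06d", seq_len(P))
  sample_id <- unname(unlist(mapply(
    function(g, n) sprintf("%s_%02d", g, seq_len(n)),
    group_levels, ns, SIMPLIFY = FALSE)))
  group <- rep(group_levels, ns)
  week <- unname(unlist(mapply(function(g, n) {
    rep_len(week_ranges[[g]], n)
  }, group_levels, ns, SIMPLIFY = FALSE)))
  batch <- unname(unlist(lapply(ns, function(n) {
    rep_len(seq_len(config$batch_count), n)
  })))
  metadata <- data.frame(sample_id = sample_id, group = group,
                         gestational_week = as.integer(week),
                         batch = paste0("batch", batch),
                         stringsAsFactors = FALSE)

  # annotation: sex chromosomes, CGI flag, bands, genes
  n_sex <- round(config$sexchrom_fraction * P)
  chromosome <- c(sample(c("X", "Y"), n_sex, replace = TRUE, prob = c(0.85, 0.15)),
                  sample(as.character(1:22), P - n_sex, replace = TRUE))
  chromosome <- sample(chromosome)
  cgi <- ifelse(stats::runif(P) < config$cgi_fraction, "CGI", "non-CGI")
  band <- sample(c("low", "intermediate", "high"), P, replace = TRUE,
                 prob = config$band_proportions)
  annotation <- data.frame(probe_id = probe_id,
                           gene_symbol = sprintf("GENE%05d", seq_len(P)),
                           chromosome = chromosome,
                           cgi = cgi,
                           tss_distance = sample(-1500:500, P, replace = TRUE),
                           stringsAsFactors = FALSE)

  # plant selection: progressive from intermediate band (mostly non-CGI),
  # variance plants from intermediate band (mostly CGI), autosomes only
  autosomal <- !(chromosome %in% c("X", "Y"))
  inter <- which(band == "intermediate" & autosomal)
  pick_split <- function(pool_a, pool_b, n, frac_a, what) {
    na <- round(n * frac_a); nb <- n - na
    if (length(pool_a) < na || length(pool_b) < nb) {
      stop("planted ", what, " count exceeds intermediate-band capacity")
    }
    c(sample(pool_a, na), sample(pool_b, nb))
  }
  prog <- integer(0); varb <- integer(0)
  if (config$n_progressive > 0) {
    prog <- pick_split(intersect(inter, which(cgi == "non-CGI")),
                       intersect(inter, which(cgi == "CGI")),
                       config$n_progressive,
                       config$progressive_noncgi_fraction, "progressive")
  }
  remaining <- setdiff(inter, prog)
  if (config$n_variable_third > 0) {
    varb <- pick_split(intersect(remaining, which(cgi == "CGI")),
                       intersect(remaining, which(cgi == "non-CGI")),
                       config$n_variable_third,
                       config$variable_cgi_fraction, "variable_third")
  }
  label <- rep("null", P)
  label[prog] <- "progressive"
  label[varb] <- "variable_third"
  truth_labels <- data.frame(probe_id = probe_id, label = label,
                             stringsAsFactors = FALSE)

  # baseline means per band; progressive plants kept in 0.25-0.50 so the
  # +2*delta third-trimester mean stays inside (0, 1) comfortably
  m0 <- numeric(P)
  m0[band == "low"] <- stats::runif(sum(band == "low"), 0.02, 0.19)
  m0[band == "intermediate"] <- stats::runif(sum(band == "intermediate"),
                                             0.22, 0.58)
  m0[band == "high"] <- stats::runif(sum(band == "high"), 0.62, 0.95)
  m0[prog] <- stats::runif(length(prog), 0.25, 0.50)

  # per-group noiseless means
  step <- c(first = 0, second = 1, third = 2)
  group_means <- sapply(group_levels, function(g) {
    m <- m0
    m[prog] <- m0[prog] + config$progressive_delta * step[[g]]
    pmin(pmax(m, 0), 1)
  })

  beta_truth <- group_means[, group, drop = FALSE]
  dimnames(beta_truth) <- list(probe_id, sample_id)

  # per-sample beta from Beta(mean, precision); variance plants get a
  # symmetric two-point dispersal of third-trimester per-sample means
  # (+/- delta with delta^2 + noise variance = variance_target), which
  # leaves the group mean at its baseline and makes the realized s2
  # concentrate around the target
  mu <- beta_truth
  if (length(varb)) {
    third_cols <- which(group == "third")
    m3 <- group_means[varb, "third"]
    n3 <- length(third_cols)
    noise_var <- m3 * (1 - m3) / (config$noise_precision + 1)
    # balanced +/- split so the realized dispersal variance is fixed;
    # (n-1)/n factor makes E[s2] equal variance_target exactly
    delta <- sqrt(pmax(config$variance_target - noise_var, 0) *
                    (n3 - 1) / n3)
    signs <- t(replicate(length(varb),
                         sample(rep_len(c(-1, 1), n3))))
    shifted <- m3 + delta * signs
    mu[varb, third_cols] <- pmin(pmax(shifted, 0.02), 0.98)
  }
  phi <- config$noise_precision
  beta_obs <- matrix(stats::rbeta(P * N, shape1 = mu * phi,
                                  shape2 = (1 - mu) * phi), P, N)

  # logit-scale batch offsets, centered so they cancel across batches
  if (config$batch_count > 1 && config$batch_shift != 0) {
    offs <- seq(-0.5, 0.5, length.out = config$batch_count) *
      config$batch_shift
    eps <- 1e-6
    shift <- offs[batch]
    beta_obs <- stats::plogis(
      stats::qlogis(pmin(pmax(beta_obs, eps), 1 - eps)) +
        rep(shift, each = P))
  }
  dimnames(beta_obs) <- list(probe_id, sample_id)

  # detection p-values: rare failures at p >= 0.05
  fail <- matrix(stats::runif(P * N) < config$detection_fail_rate, P, N)
  detp <- matrix(stats::runif(P * N, 0, 0.049), P, N)
  detp[fail] <- stats::runif(sum(fail), 0.05, 1)
  dimnames(detp) <- list(probe_id, sample_id)

  # signals back-computed so the beta formula is an exact inverse
  S <- matrix(stats::rlnorm(P * N, meanlog = log(2000), sdlog = 0.25), P, N)
  signals <- signal_pair(A = S * (1 - beta_obs), B = S * beta_obs,
                         detection_p = detp)

  ds <- structure(list(signals = signals, beta_observed = beta_obs,
                       beta_truth = beta_truth, annotation = annotation,
                       metadata = metadata, truth_labels = truth_labels,
                       expression = NULL, config = config),
                  class = "synthetic_dataset")
  ds$expression <- generate_expression(ds, slope = config$expression_slope,
                                       noise_sd = config$expression_noise_sd)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$beta_observed), "probes x",
      ncol(x$beta_observed), "samples;",
      sum(x$truth_labels$label == "progressive"), "progressive and",
      sum(x$truth_labels$label == "variable_third"),
      "variance plants\n")
  invisible(x)
}

#' Generate gene-level expression coupled to methylation
#'
#' Per gestational group, log-expression of each gene is
#' `intercept + slope * gene_beta + noise`, where `gene_beta` is the mean
#' noiseless beta of the gene's probes in that group. A negative slope
#' (default) makes promoter methylation repressive.
#'
#' @param dataset A `synthetic_dataset`.
#' @param slope Coupling coefficient (log-expression units per beta unit).
#' @param noise_sd SD of per-sample Gaussian noise.
#' @param intercept Baseline log-expression.
#' @return Named list (first/second/third) of gene x sample matrices.
#' @export
generate_expression <- function(dataset, slope = -2, noise_sd = 0.5,
                                intercept = 8) {
  ann <- dataset$annotation
  md <- dataset$metadata
  out <- list()
  for (g in group_levels) {
    cols <- md$sample_id[md$group == g]
    if (!length(cols)) next
    gm <- rowMeans(dataset$beta_truth[, cols, drop = FALSE])
    gene_beta <- tapply(gm, ann$gene_symbol[match(names(gm), ann$probe_id)],
                        mean)
    nsamp <- length(cols)
    mu <- intercept + slope * as.numeric(gene_beta)
    expr <- matrix(mu, length(gene_beta), nsamp) +
      matrix(stats::rnorm(length(gene_beta) * nsamp, 0, noise_sd),
             length(gene_beta), nsamp)
    dimnames(expr) <- list(names(gene_beta), cols)
    out[[g]] <- expr
  }
  out
}

#' Generate an EpiTYPER-style validation table with planted failures
#'
#' Produces a CpG-unit x sample methylated-fraction table with `NA`
#' marking failed measurements, planting three failure archetypes matching
#' the three ordered cleaning rules: all-fail samples (rule 1), sites
#' failing in 60% of surviving samples (rule 2, > 40%), and low-coverage
#' samples failing in 80% of surviving sites (rule 3, > 70%).
#'
#' @param n_sites Number of CpG units (rows).
#' @param n_samples Number of samples (columns).
#' @param site_fail Probability a site is planted high-fail.
#' @param sample_fail Probability a sample is planted all-fail.
#' @param seed Integer seed.
#' @param lowcov_fail Probability a (non-all-fail) sample is planted
#'   low-coverage.
#' @return List with `table` (matrix with NAs) and `truth` (lists of the
#'   planted sample/site ids per rule).
#' @export
generate_epityper_table <- function(n_sites, n_samples, site_fail = 0,
                                    sample_fail = 0, seed = 1L,
                                    lowcov_fail = 0) {
  stopifnot(site_fail >= 0, site_fail <= 1, sample_fail >= 0,
            sample_fail <= 1, lowcov_fail >= 0, lowcov_fail <= 1)
  set.seed(seed)
  sites <- sprintf("unit_%02d", seq_len(n_sites))
  samples <- LETTERS[seq_len(n_samples)]
  tab <- matrix(round(stats::runif(n_sites * n_samples), 3),
                n_sites, n_samples, dimnames = list(sites, samples))

  allfail <- samples[stats::runif(n_samples) < sample_fail]
  tab[, allfail] <- NA_real_
  surv_samples <- setdiff(samples, allfail)

  highfail <- sites[stats::runif(n_sites) < site_fail]
  for (s in highfail) {
    k <- ceiling(0.6 * length(surv_samples))
    tab[s, sample(surv_samples, k)] <- NA_real_
  }
  surv_sites <- setdiff(sites, highfail)

  lowcov <- character(0)
  if (length(surv_samples) && length(surv_sites)) {
    lowcov <- surv_samples[stats::runif(length(surv_samples)) < lowcov_fail]
    for (s in lowcov) {
      k <- ceiling(0.8 * length(surv_sites))
      tab[sample(surv_sites, k), s] <- NA_real_
    }
  }
  list(table = tab,
       truth = list(rule1_samples = allfail, rule2_sites = highfail,
                    rule3_samples = lowcov))
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the beta matrix, detection p-values, annotation, metadata,
#' truth labels and per-group expression as TSV with fixed column order.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_id_matrix(dataset$beta_observed, file.path(dir, "beta.tsv"))
  write_id_matrix(dataset$signals$detection_p,
                  file.path(dir, "detection_p.tsv"))
  utils::write.table(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth_labels, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(dataset$expression)) {
    write_id_matrix(dataset$expression[[g]],
                    file.path(dir, paste0("expression_", g, ".tsv")),
                    id_name = "gene_symbol")
  }
  invisible(dir)
}
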