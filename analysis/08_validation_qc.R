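#!/usr/bin/env Rscript
# Locus-level validation workflow: generate an EpiTYPER-style table with
# planted failure archetypes, clean it with the three ordered rules
# (all-fail samples; sites failing > 40% of samples; samples failing
# > 70% of sites), and score cross-platform agreement (r2) between the
# array beta-values and noisy validation measurements on matched points.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/beta_analysable.tsv")

gen <- generate_epityper_table(n_sites = 12, n_samples = 9,
                               site_fail = 0.15, sample_fail = 0.1,
                               lowcov_fail = 0.1, seed = 2026L)
res <- clean_validation(gen$table)
message("validation table: ", nrow(gen$table), " CpG units x ",
        ncol(gen$table), " samples")
message("rule 1 (all-fail samples): ",
        paste(res$report$rule1_samples, collapse = ", "))
message("rule 2 (sites failing > 40%): ",
        paste(res$report$rule2_sites, collapse = ", "))
message("rule 3 (samples failing > 70%): ",
        paste(res$report$rule3_samples, collapse = ", "))
message("cleaned table: ", nrow(res$cleaned), " x ", ncol(res$cleaned))
write_id_matrix(res$cleaned, "results/validation_cleaned.tsv",
                id_name = "site_id")

# cross-platform agreement on 49 matched (probe, sample) points with
# measurement noise SD 0.1
set.seed(2026L)
probes <- sample(rownames(beta), 12)
samples <- sample(colnames(beta), 9)
arr <- beta[probes, samples]
pts <- sample(length(arr), 49)
arr_v <- rep(NA_real_, length(arr)); arr_v[pts] <- arr[pts]
val_v <- pmin(pmax(arr_v + rnorm(length(arr_v), 0, 0.1), 0), 1)
r2 <- cross_platform_r2(arr_v, val_v)
message("cross-platform r2 over ", r2$n, " matched points: ",
        round(r2$r2, 3))

jsonlite::write_json(
  list(removals = res$report, planted = gen$truth,
       cross_platform = r2),
  "results/validation_qc.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
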