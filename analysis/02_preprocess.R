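#!/usr/bin/env Rscript
# Quality control and batch adjustment: drop probes with any detection
# failure (p >= 0.05, probe-level exclusion so all samples share one
# analysable probe set), remove X/Y probes, and correct logit-scale
# batch offsets while protecting the trimester contrasts. Writes
# results/beta_analysable.tsv.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/cohort/beta.tsv")
detp <- read_beta_matrix("results/cohort/detection_p.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
md <- read_metadata("results/cohort/metadata.tsv")

n0 <- nrow(beta)
beta <- filter_detection(beta, detp, alpha = 0.05, policy = "drop_any")
message("detection filter: ", n0 - nrow(beta), " probes removed, ",
        nrow(beta), " retained")

n1 <- nrow(beta)
beta <- drop_sex_chromosomes(beta, ann)
message("sex-chromosome removal: ", n1 - nrow(beta), " probes removed, ",
        nrow(beta), " analysable autosomal probes")

beta <- correct_batch(beta, md)
message("batch correction applied across ",
        length(unique(md$batch)), " batches")

write_id_matrix(beta, "results/beta_analysable.tsv")
message("written to results/beta_analysable.tsv")
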