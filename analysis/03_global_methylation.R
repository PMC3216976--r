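#!/usr/bin/env Rscript
# Global promoter methylation over gestation: per-sample Methylation
# Index (mean beta over all analysable probes), pairwise trimester
# t-tests, and the beta-band composition (< 0.2 / 0.2-0.6 / > 0.6) per
# trimester.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/beta_analysable.tsv")
md <- read_metadata("results/cohort/metadata.tsv")

mi <- methylation_index(beta)
tests <- compare_mi(mi, md)
bands <- band_proportions(beta, md)

utils::write.table(
  data.frame(sample_id = names(mi), mi = mi, row.names = NULL),
  "results/methylation_index.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
jsonlite::write_json(
  list(per_group_mean = tapply(mi, md$group[match(names(mi),
                                                  md$sample_id)], mean),
       tests = tests, band_proportions = bands),
  "results/global_methylation.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)

grp <- md$group[match(names(mi), md$sample_id)]
for (g in c("first", "second", "third")) {
  message("mean MI ", g, " trimester: ", round(mean(mi[grp == g]), 4))
}
st <- tests[tests$group1 == "second" & tests$group2 == "third", ]
message("second vs third MI: t = ", round(st$t, 2), ", p = ",
        signif(st$p, 3))
message("low-band (beta < 0.2) fraction per trimester: ",
        paste(round(bands[, "low"], 3), collapse = " / "))
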