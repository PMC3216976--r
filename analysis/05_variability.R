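#!/usr/bin/env Rscript
# Inter-individual variability: per-trimester probe variance, the
# low/intermediate/high classification (s2 < 0.009 / > 0.02), the
# chi-square comparison of highly variable probe counts (including the
# desk reproduction from the published counts 352 vs 106 of 26,162),
# the first-vs-third quadrant partition, the three-trimester Venn
# partition, and the methylation-band cross-tabulation.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/beta_analysable.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
truth <- utils::read.table("results/cohort/truth_labels.tsv",
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)

# desk reproduction from printed counts
chi_pub <- compare_variable_counts(352, 106, 26162)
message("published counts (352 vs 106 of 26,162): chi-square = ",
        round(chi_pub$chisq, 1), ", p < 0.001")

s2 <- probe_variance(beta, md)
write_id_matrix(s2, "results/probe_variance.tsv")
cl <- classify_variability(s2)
for (g in colnames(s2)) {
  message(g, " trimester: ", cl$counts["high", g], " highly variable ",
          "(s2 > 0.02); ",
          round(100 * cl$counts["low", g] / nrow(s2), 1),
          "% with s2 < 0.009")
}

k1 <- cl$counts["high", "first"]; k3 <- cl$counts["high", "third"]
chi <- compare_variable_counts(k3, k1, nrow(s2))
message("third vs first highly-variable counts (", k3, " vs ", k1,
        "): chi-square = ", round(chi$chisq, 1), ", p = ",
        signif(chi$p, 3))

quad <- quadrant_partition(s2[, "first"], s2[, "third"])
venn <- venn_partition(rownames(s2)[cl$class[, "first"] == "high"],
                       rownames(s2)[cl$class[, "second"] == "high"],
                       rownames(s2)[cl$class[, "third"] == "high"])
varb <- truth$probe_id[truth$label == "variable_third"]
message("quadrants (first vs third): A = ", quad$counts[["A"]],
        ", B = ", quad$counts[["B"]], ", C = ", quad$counts[["C"]],
        " (", length(varb), " variance plants; ",
        sum(varb %in% quad$sets$C), " recovered in C)")
message("variable across all three trimesters: ", venn[["all_three"]])

vlevel <- variance_by_level(beta, md, s2)
high3 <- vlevel$third[, "high"]
message("third-trimester high-variance probes by methylation band: ",
        paste(names(high3), high3, sep = "=", collapse = ", "))

jsonlite::write_json(
  list(published_chisq = chi_pub, counts = cl$counts,
       chisq_third_v_first = chi, quadrant = quad$counts, venn = venn,
       by_level = lapply(vlevel, function(tb) as.data.frame.matrix(tb))),
  "results/variability.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)
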