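#!/usr/bin/env Rscript
# Genomic context: CpG-island enrichment of the differential and
# variable probe sets against the array background, and the Spearman
# association between |TSS distance| and each statistic.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/beta_analysable.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
res13 <- utils::read.table("results/differential_first_v_third.tsv",
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
s2 <- read_beta_matrix("results/probe_variance.tsv")

bg <- background_proportions(ann, rownames(beta))
message("array background: ", round(bg[["cgi"]], 3), " CGI / ",
        round(bg[["noncgi"]], 3), " non-CGI")

cl13 <- classify_differential(res13, 0.2, 0.05)
quad <- quadrant_partition(s2[, "first"], s2[, "third"])
subsets <- list(differential_hyper = cl13$hyper,
                differential_hypo = cl13$hypo,
                quadrant_A = quad$sets$A, quadrant_B = quad$sets$B,
                quadrant_C = quad$sets$C)
enrich <- list()
for (nm in names(subsets)) {
  sub <- subsets[[nm]]
  if (length(sub) < 2) { message(nm, ": too few probes, skipped"); next }
  e <- cgi_enrichment(sub, ann, bg)
  enrich[[nm]] <- e
  message(nm, " (n = ", e$size, "): ", e$direction,
          ", chi-square = ", round(e$chisq, 1), ", p = ", signif(e$p, 3),
          if (e$low_count) " [low expected count]" else "")
}

# TSS-distance association with |delta-beta| and third-trimester s2
tss_diff <- tss_distance_association(
  res13$probe_id, ann,
  setNames(abs(res13$delta_beta), res13$probe_id), seed = 2026L)
tss_var <- tss_distance_association(
  rownames(s2), ann, setNames(s2[, "third"], rownames(s2)), seed = 2026L)
message("TSS distance vs |delta-beta|: rho = ", round(tss_diff$rho, 3),
        ", permutation p = ", signif(tss_diff$p, 3))
message("TSS distance vs third-trimester s2: rho = ",
        round(tss_var$rho, 3), ", permutation p = ", signif(tss_var$p, 3))

jsonlite::write_json(
  list(background = bg, enrichment = enrich,
       tss_association = list(delta_beta = tss_diff,
                              variance_third = tss_var)),
  "results/context.json", auto_unbox = TRUE, digits = NA, pretty = TRUE,
  force = TRUE)
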