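#!/usr/bin/env Rscript
# Methylation-expression integration: link probes to gene-level
# expression by gene symbol, quartile probes by methylation level,
# summarise expression per quartile (the negative-coupling trend), and
# screen for genes with concordant methylation-up / expression-down
# changes between first and third trimester.

suppressPackageStartupMessages(library(gestmeth))

beta <- read_beta_matrix("results/beta_analysable.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
res13 <- utils::read.table("results/differential_first_v_third.tsv",
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
expr <- list(
  first = read_beta_matrix("results/cohort/expression_first.tsv"),
  second = read_beta_matrix("results/cohort/expression_second.tsv"),
  third = read_beta_matrix("results/cohort/expression_third.tsv"))

gm <- group_mean_beta(beta, md)
quartile_summaries <- list()
for (g in names(expr)) {
  linked <- merge_by_gene(
    data.frame(probe_id = rownames(beta), beta = gm[, g],
               stringsAsFactors = FALSE),
    ann, rowMeans(expr[[g]]))
  qq <- quartile_by_methylation(setNames(gm[, g], rownames(beta)))
  summ <- expression_by_quartile(linked, qq)
  quartile_summaries[[g]] <- summ
  message(g, " trimester quartile medians (low to high methylation): ",
          paste(round(summ$median, 2), collapse = " > "))
}

lfc <- expression_logfc(expr$first, expr$third)
conc <- delta_vs_logfc(res13, ann, lfc, delta_cut = 0.2, lfc_cut = 1.0)
utils::write.table(conc$scatter, "results/delta_vs_logfc.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(length(conc$concordant), " genes with concordant methylation ",
        "and expression change (|delta-beta| >= 0.2, |logFC| >= 1)")

jsonlite::write_json(
  list(quartile_summaries = quartile_summaries,
       n_concordant = length(conc$concordant),
       concordant_genes = conc$concordant),
  "results/expression_link.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
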