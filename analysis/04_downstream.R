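#!/usr/bin/env Rscript
# Downstream analyses of the called RS genes: pairwise correlation with
# strength categories, hierarchical clustering of patients on the Type II
# panel with per-cluster radiotherapy survival comparison, and the
# extreme-survivor expression contrast.

library(radsens)

dir.create("results/downstream", recursive = TRUE, showWarnings = FALSE)

expr <- read_expression("results/prep/expression_eligible.tsv")
clin <- read_clinical("results/prep/clinical_eligible.tsv",
                      schema = list(
                        cov_continuous("age"),
                        cov_categorical("age_group", levels = c("<60", ">=60")),
                        cov_categorical("chemotherapy", levels = c("No", "Yes")),
                        cov_categorical("stage", levels = c("I/II", "III/IV"))))
cohort <- cohort_dataset(expr, clin)
calls <- read_rs_table("results/discover/rs_calls.tsv")

type1 <- calls$gene[calls$is_rs & calls$rs_type == "I"]
type2 <- calls$gene[calls$is_rs & calls$rs_type == "II"]
message(sprintf("panels: %d Type I, %d Type II genes", length(type1), length(type2)))

## correlation structure of the Type II panel
if (length(type2) >= 2) {
  cc <- rs_correlation(cohort, type2)
  write.table(data.frame(gene = rownames(cc$r), round(cc$r, 4)),
              "results/downstream/type2_correlation.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  off <- cc$category[upper.tri(cc$category)]
  message(sprintf("Type II pairwise correlations: %d strong, %d moderate, %d weak",
                  sum(off == "strong"), sum(off == "moderate"), sum(off == "weak")))
}

## cluster patients on the Type II panel and compare RT benefit per cluster
if (length(type2) >= 2) {
  clres <- cluster_patients(cohort, type2, k = 2)
  surv <- compare_cluster_survival(cohort, clres)
  labels <- data.frame(sample_id = names(clres$labels), cluster = clres$labels)
  write.table(labels, "results/downstream/cluster_labels.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(surv$per_cluster, "results/downstream/cluster_survival.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(surv$per_cluster)
  message(if (!is.na(surv$rs_cluster))
            sprintf("radio-sensitive cluster: %d (RT benefit significant there only)",
                    surv$rs_cluster)
          else "no single cluster captures the radiotherapy benefit")
}

## extreme-survivor contrast among irradiated patients
genes <- c(type1, type2)
if (length(genes)) {
  contrast <- extreme_survivor_contrast(cohort, genes, rt_status = 1,
                                        long_cut = 2000, short_cut = 1000)
  write.table(contrast, "results/downstream/extreme_survivor_wilcoxon.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("extreme-survivor contrast (alive n=%d, dead n=%d): %d/%d genes p < 0.05",
                  attr(contrast, "n_alive"), attr(contrast, "n_dead"),
                  sum(contrast$p < 0.05), nrow(contrast)))
}
message("wrote results/downstream/")
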