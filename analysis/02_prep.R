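#!/usr/bin/env Rscript
# Eligibility preparation: read the simulated files back through the text
# parsers, apply the tumor-sample filter (a pass-through with a warning for
# non-TCGA ids), drop records with missing survival/radiotherapy or survival
# under 5 days, and run the cohort-level radiotherapy-protective screen.
# Writes the eligibility report and the filtered cohort.

library(radsens)

dir.create("results/prep", recursive = TRUE, showWarnings = FALSE)

expr <- read_expression("results/sim/expression.tsv")
clin <- read_clinical("results/sim/clinical.tsv",
                      schema = list(
                        cov_continuous("age"),
                        cov_categorical("age_group", levels = c("<60", ">=60")),
                        cov_categorical("chemotherapy", levels = c("No", "Yes")),
                        cov_categorical("stage", levels = c("I/II", "III/IV"))))

expr <- withCallingHandlers(
  filter_tumor_samples(expr),
  warning = function(w) { message("note: ", conditionMessage(w))
                          invokeRestart("muffleWarning") })

cohort <- apply_eligibility(expr, clin, rs_config())
print(cohort)

report <- data.frame(rule = names(cohort$eligibility_log),
                     removed = as.integer(cohort$eligibility_log))
report <- rbind(report, data.frame(rule = "eligible", removed = nrow(cohort$clinical)))
write.table(report, "results/prep/eligibility_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

screen <- screen_rt_protective(cohort, rs_config())
message(sprintf("radiotherapy screen: HR = %.3f, p = %.3g -> %s",
                screen$hr, screen$p, ifelse(screen$keep, "keep", "drop")))
write.table(data.frame(hr = screen$hr, p = screen$p, keep = screen$keep),
            "results/prep/rt_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

write_expression(cohort$expression, "results/prep/expression_eligible.tsv")
write_clinical(cohort$clinical, "results/prep/clinical_eligible.tsv")
message("wrote results/prep/")
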