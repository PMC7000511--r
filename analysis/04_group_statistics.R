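#!/usr/bin/env Rscript

# Step 4: group-level statistics on behavior and on fitted parameters.
#
# Mirrors the study's inferential structure:
#  - mixed repeated-measures ANOVA (condition within, age group between) on
#    error rates and correct-trial mean RTs,
#  - the planned proactive-interference (PI) contrast: recent minus
#    non-recent negative, and its interaction with age,
#  - the same ANOVA + contrast on the winning model's drift rates,
#  - pooled-variance t-tests on boundary separation and nondecision time.
#
# Reads behavior.csv and scratch/fits.rds, writes the statistics tables.

library(piddm)
library(dplyr)

outdir <- "results/analysis"
data <- read_behavior(file.path(outdir, "behavior.csv"))
fits <- readRDS(file.path("scratch", "fits.rds"))

beh <- summarize_behavior(data)
rt_long <- transmute(beh, participant_id, group, condition,
                     value = mean_rt_correct_s)
err_long <- transmute(beh, participant_id, group, condition,
                      value = error_rate_pct)

cat("== behavior: correct-trial RTs ==\n")
print(mixed_anova(rt_long))
print(planned_pi_contrast(rt_long))
cat("== behavior: error rates ==\n")
print(mixed_anova(err_long))
print(planned_pi_contrast(err_long))

win_model <- ranking_table(select_best(fits))$model_id[1]
wf <- filter(fits, model_id == win_model)
drift_long <- bind_rows(lapply(seq_len(nrow(wf)), function(i) {
  p <- wf$fit[[i]]$params
  tibble::tibble(participant_id = wf$participant_id[i], group = wf$group[i],
                 condition = p$conditions, value = unname(p$v))
}))
cat("== winning model (", win_model, "): drift rates ==\n")
print(mixed_anova(drift_long))
print(planned_pi_contrast(drift_long))

a_vals <- vapply(wf$fit, function(f) f$params$a[[1]], 0)
t_vals <- vapply(wf$fit, function(f) f$params$ter[[1]], 0)
cat("== boundary separation and nondecision time by age ==\n")
print(independent_t(a_vals, wf$group))
print(independent_t(t_vals, wf$group))

utils::write.csv(mixed_anova(rt_long), file.path(outdir, "anova_rt.csv"),
                 row.names = FALSE)
utils::write.csv(mixed_anova(err_long), file.path(outdir, "anova_err.csv"),
                 row.names = FALSE)
utils::write.csv(mixed_anova(drift_long),
                 file.path(outdir, "anova_drift.csv"), row.names = FALSE)
utils::write.csv(planned_pi_contrast(drift_long),
                 file.path(outdir, "pi_drift.csv"), row.names = FALSE)
utils::write.csv(independent_t(a_vals, wf$group),
                 file.path(outdir, "t_boundary.csv"), row.names = FALSE)
utils::write.csv(independent_t(t_vals, wf$group),
                 file.path(outdir, "t_ter.csv"), row.names = FALSE)
cat("wrote statistics tables under", outdir, "\n")
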