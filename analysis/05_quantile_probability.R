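#!/usr/bin/env Rscript

# Step 5: quantile-probability fit diagnostics.
#
# Per age group and condition, the observed response proportions and five RT
# quantiles (10/30/50/70/90%) for correct and error responses are plotted
# against the winning model's predictions (predicted per participant from
# the fitted parameters, then averaged). Crosses = observed, circles =
# predicted; a well-fitting model places its circles on the crosses.
#
# Reads behavior.csv and scratch/fits.rds, writes qpp.csv and qpp.png.

library(piddm)
library(dplyr)

outdir <- "results/analysis"
data <- read_behavior(file.path(outdir, "behavior.csv"))
fits <- readRDS(file.path("scratch", "fits.rds"))

win_model <- ranking_table(select_best(fits))$model_id[1]
obs <- data |>
  group_by(group) |>
  group_modify(~ observed_quantiles(.x)) |>
  ungroup() |>
  rename(panel = group)
pred <- predicted_quantiles_cohort(filter(fits, model_id == win_model)) |>
  rename(panel = group)

utils::write.csv(obs, file.path(outdir, "qpp_observed.csv"),
                 row.names = FALSE)
utils::write.csv(pred, file.path(outdir, "qpp_predicted.csv"),
                 row.names = FALSE)
qpp_figure(obs, pred, file = file.path(outdir, "qpp.png"))
cat("wrote", file.path(outdir, "qpp.png"), "\n")

# quick text summary of fit quality: median absolute gap between observed
# and predicted correct-response medians per condition x group
cmp <- inner_join(
  obs |> filter(response == "correct") |> select(panel, condition, q50),
  pred |> filter(response == "correct") |> select(panel, condition, q50),
  by = c("panel", "condition"), suffix = c("_obs", "_pred"))
cmp$gap_ms <- 1000 * abs(cmp$q50_obs - cmp$q50_pred)
print(cmp)
cat(sprintf("median |observed - predicted| correct median RT: %.0f ms\n",
            stats::median(cmp$gap_ms)))
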