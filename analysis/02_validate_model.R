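#!/usr/bin/env Rscript
# Stage 2 — external-validation statistics against the prediction model.
#
# Reads the cohort written by 01_simulate_cohort.R back through the CSV
# contract (exercising ingestion, exclusion flow and time normalization),
# predicts each case's concentration table on the 5-minute grid,
# time-matches the measurements, and computes: mean prediction error with
# 95% t interval, bias regressions on weight / creatinine / duration,
# the calibration table, treatment-period summaries, and the
# aberrant-value / toxicity review.

suppressPackageStartupMessages(library(mgpk))

coh <- read_cohort("results/cohort/dosing.csv",
                   "results/cohort/observations.csv",
                   "results/cohort/covariates.csv")
stopifnot(nrow(coh$rejected) == 0)

pairs <- validate_predictions(coh)
write.csv(pairs, "results/pairs.csv", row.names = FALSE)

mpe <- mean_prediction_error(pairs)
mpe_cl <- mean_prediction_error(pairs, cluster = TRUE)
cat(sprintf("Mean prediction error: %.3f mmol/L (95%% CI %.3f to %.3f, %d pairs)\n",
            mpe$mean, mpe$ci[1], mpe$ci[2], mpe$n))
cat(sprintf("  case-clustered CI:   %.3f to %.3f (%d cases)\n",
            mpe_cl$ci[1], mpe_cl$ci[2], mpe_cl$n))

for (cv in c("weight", "creatinine", "duration")) {
  b <- bias_regression(pairs, cv)
  cat(sprintf("Bias vs %-10s slope %+.5f mmol/L per unit (p = %.2f)\n",
              cv, b$slope, b$p))
}

calib <- calibration_table(pairs)
write.csv(calib, "results/calibration.csv", row.names = FALSE)
cal_fit <- lm(mean_measured ~ midpoint, data = calib, weights = calib$n)
cat(sprintf("Calibration slope (measured vs predicted): %.3f\n",
            coef(cal_fit)[2]))

ps <- period_summary(coh, pairs)
write.csv(ps$summary, "results/period_summary.csv", row.names = FALSE)
cat("Per-period maintenance rate and measured concentration:\n")
print(ps$summary, row.names = FALSE, digits = 3)
if (!is.null(ps$comparisons)) print(ps$comparisons, row.names = FALSE, digits = 3)

tox <- screen_toxicity(coh, threshold = 3.5)
write.csv(tox, "results/toxicity_review.csv", row.names = FALSE)
cat(sprintf("Measurements > 3.5 mmol/L under review: %d (%d resolved by resample)\n",
            nrow(tox), sum(tox$resolved_by_resample)))
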