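#!/usr/bin/env Rscript
# Stage 4: the ordinal confidence model and its transfer to the main task.
#
# Per subject, fits the cumulative-logit regression of 6-level confidence on
# z-scored difficulty, accuracy, log RT and the difficulty x accuracy
# interaction (metacognition session), compares the default grid of
# candidate regressor sets by summed deviance, takes the full model's
# coefficients to the group level, and transfers each subject's fit to their
# main session to obtain predicted trial-wise confidence.

suppressPackageStartupMessages(library(spemeta))

trials <- read_trials("results/trials.csv")
meta <- exclude_trials(trials[trials$session == "metacog", ])$kept
main <- exclude_trials(trials[trials$session == "main", ])$kept

fits <- list()
main_out <- list()
for (s in unique(meta$subject)) {
  tr <- meta[meta$subject == s, ]
  f <- suppressWarnings(build_features(tr))
  fit <- fit_ordinal(f, tr$confidence)
  fits[[as.character(s)]] <- fit
  mt <- main[main$subject == s, ]
  fm <- suppressWarnings(build_features(mt))[, names(fit$betas), drop = FALSE]
  mt$predicted_confidence <- predict_confidence(fit, fm)
  main_out[[as.character(s)]] <- mt
}
main_pred <- do.call(rbind, main_out)
write_trials(main_pred, "results/main_with_predicted_confidence.csv")

group <- group_coefficient_tests(fits)
write.csv(group, "results/ordinal_group_tests.csv", row.names = FALSE)
cat("Group-level ordinal coefficients (one-sample t vs 0):\n")
print(group, row.names = FALSE, digits = 3)

cmp <- compare_models(meta)
write.csv(cmp, "results/confidence_model_comparison.csv", row.names = FALSE)
cat("\nCandidate-model comparison (summed deviance, ascending):\n")
print(cmp, row.names = FALSE, digits = 6)
cat(sprintf("\nBest model: %s.\n", cmp$model[cmp$rank == 1]))
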