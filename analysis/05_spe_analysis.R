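#!/usr/bin/env Rscript
# Stage 5: global self-performance estimates from end-of-block task choices.
#
# Labels main-task trials by their block's choice, summarizes blocks per
# task, and runs the choice analyses: easy-task choice frequency (SPE
# sensitivity) and its split by the between-task performance difference
# (with the one-sample t and JZS Bayes factor in equal-performance blocks),
# the difficulty/accuracy task-choice logistic, the deviance comparison of
# the predicted-confidence vs accuracy vs RT choice models, and the
# higher- vs lower-SPE comparison of predicted local confidence.

suppressPackageStartupMessages(library(spemeta))

main <- read_trials("results/main_with_predicted_confidence.csv")
blocks <- read.csv("results/blocks.csv", stringsAsFactors = FALSE)

main <- label_trials(main, blocks)
bs <- block_summaries(main, blocks)
write.csv(bs, "results/block_summaries.csv", row.names = FALSE)

freq <- choice_frequencies(bs)
cat(sprintf("Easy-task choice frequency (SPE sensitivity): %.1f%%.\n",
            100 * freq$easy_choice_freq))
cat(sprintf("Best-performed-task choice frequency: %.1f%% (%d tied blocks excluded).\n",
            100 * freq$best_performed_choice_freq, freq$n_acc_ties))
cat(sprintf("Split by performance class: positive %.2f, null %.2f, negative %.2f.\n",
            freq$split_freq["positive"], freq$split_freq["null"],
            freq$split_freq["negative"]))
nt <- freq$tests$null_vs_half
cat(sprintf("Equal-performance blocks vs 0.5: t(%d) = %.2f, p = %.3f, BF10 = %.3f.\n",
            nt$df, nt$t, nt$p, nt$bf10))
pn <- freq$tests$positive_vs_negative
cat(sprintf("Positive vs negative class (paired, n = %d): t = %.2f, p = %.4f.\n",
            pn$n, pn$t, pn$p))

tcl <- task_choice_logistic(bs)
cat("\nTask-choice logistic (group t on per-subject betas):\n")
print(tcl$group, row.names = FALSE, digits = 3)

cmp <- compare_choice_models(bs)
write.csv(cmp, "results/choice_model_deviance.csv", row.names = FALSE)
cat("\nChoice-model summed deviances (ascending):\n")
print(cmp, row.names = FALSE, digits = 6)

pc <- aggregate(predicted_confidence ~ subject + spe_label, main, mean)
wide <- reshape(pc, idvar = "subject", timevar = "spe_label",
                direction = "wide")
tt <- t.test(wide$predicted_confidence.higher_SPE,
             wide$predicted_confidence.lower_SPE, paired = TRUE)
cat(sprintf("\nPredicted confidence, higher vs lower SPE trials: %.3f vs %.3f (t(%d) = %.2f, p = %.2g).\n",
            mean(wide$predicted_confidence.higher_SPE),
            mean(wide$predicted_confidence.lower_SPE),
            round(tt$parameter), tt$statistic, tt$p.value))

report <- list(
  spe_sensitivity = freq$easy_choice_freq,
  best_performed_choice_freq = freq$best_performed_choice_freq,
  split_freq = as.list(freq$split_freq),
  tests = freq$tests,
  task_choice_logistic = tcl$group,
  choice_model_deviance = cmp,
  predicted_confidence_by_spe = list(
    higher = mean(wide$predicted_confidence.higher_SPE),
    lower = mean(wide$predicted_confidence.lower_SPE),
    t = unname(tt$statistic), p = tt$p.value))
jsonlite::write_json(report, "results/spe_report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, force = TRUE)
cat("\nWrote results/spe_report.json.\n")
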