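#!/usr/bin/env Rscript
# Stage 3: metacognition-session analyses.
#
# Applies the missed/RT-outlier exclusions, then per subject: type-1 d',
# maximum likelihood meta-d' and M-ratio per difficulty condition, AUROC2
# per condition (both averaged across conditions), and the 2x2
# Accuracy x Difficulty ANOVA on confidence.

suppressPackageStartupMessages(library(spemeta))

trials <- read_trials("results/trials.csv")
meta <- trials[trials$session == "metacog", ]
ex <- exclude_trials(meta)
cat(sprintf("Exclusions: %.1f%% of metacognition trials (missed + RT outliers).\n",
            100 * mean(ex$report$frac_excluded)))

rows <- lapply(split(ex$kept, ex$kept$subject), function(tr) {
  m <- per_condition_metrics(tr)
  an <- anova_2x2(tr)
  data.frame(subject = tr$subject[1],
             d_easy = m$easy$metad$d_prime, d_hard = m$hard$metad$d_prime,
             meta_d_easy = m$easy$metad$meta_d,
             meta_d_hard = m$hard$metad$meta_d,
             m_ratio_avg = m$m_ratio_avg, auroc2_avg = m$auroc2_avg,
             F_accuracy = an$F[1], p_accuracy = an$p[1],
             F_difficulty = an$F[2], p_difficulty = an$p[2],
             F_interaction = an$F[3], p_interaction = an$p[3])
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/metacog_metrics.csv", row.names = FALSE)

cat(sprintf("Group means: d' (easy/hard) = %.2f/%.2f, M-ratio = %.2f, AUROC2 = %.2f.\n",
            mean(tab$d_easy), mean(tab$d_hard),
            mean(tab$m_ratio_avg), mean(tab$auroc2_avg)))
cat(sprintf("Accuracy main effect on confidence significant in %d/%d subjects (p < .05).\n",
            sum(tab$p_accuracy < 0.05), nrow(tab)))
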