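test_that("exclusions drop missed trials and 3-SD log-RT outliers in one pass", {
  rt <- c(rep(700, 100), 7000)
  tr <- data.frame(subject = 1, response = "right", rt_ms = rt)
  # hand z-score: with one 10x RT among 100 identical, only it exceeds 3 SD
  lrt <- log(rt)
  z <- (lrt - mean(lrt)) / sd(lrt)
  expect_true(sum(abs(z) > 3) == 1)
  out <- exclude_trials(tr)
  expect_equal(nrow(out$kept), 100L)
  expect_equal(out$report$n_outlier, 1L)
  expect_equal(out$report$frac_excluded, 1 / 101)

  # identity when nothing is excludable
  tr2 <- data.frame(subject = 1, response = "right",
                    rt_ms = seq(600, 800, length.out = 50))
  out2 <- exclude_trials(tr2)
  expect_identical(out2$kept, tr2)

  # all trials missed
  tr3 <- data.frame(subject = 1, response = "none", rt_ms = NA_real_)
  expect_warning(out3 <- exclude_trials(tr3), "all trials excluded")
  expect_equal(nrow(out3$kept), 0L)
  expect_equal(out3$report$n_missed, 1L)
})

test_that("SPE labels follow the block choice and flip under choice reversal", {
  trials <- data.frame(subject = 1, block = rep(1:4, each = 12),
                       trial = rep(1:12, 4),
                       task = rep(rep(c("A", "B"), each = 6), 4))
  blocks <- data.frame(subject = 1, block = 1:4,
                       chosen_task = c("A", "B", "A", "B"))
  lab <- label_trials(trials, blocks)
  b1 <- lab[lab$block == 1, ]
  expect_true(all(b1$spe_label[b1$task == "A"] == "higher_SPE"))
  expect_true(all(b1$spe_label[b1$task == "B"] == "lower_SPE"))
  counts <- table(lab$block, lab$spe_label)
  expect_true(all(counts == 6L))

  flipped <- blocks
  flipped$chosen_task <- ifelse(blocks$chosen_task == "A", "B", "A")
  lab2 <- label_trials(trials, flipped)
  expect_true(all(lab2$spe_label != lab$spe_label))

  blocks$chosen_task[2] <- NA
  expect_error(label_trials(trials, blocks), "without a recorded choice")
})

test_that("choice frequencies match hand counts on a small fixture", {
  set.seed(81)
  # 6 blocks, known composition: easy chosen in 4/6; one accuracy tie
  bs <- make_block_summaries(subject = 1, lp = rep(0, 6),
                             delta_diff = c(8, 8, -8, -8, 8, 8),
                             acc_diff = c(0.3, 0.3, -0.3, 0.2, 0, -0.2))
  bs$chosen_task <- c("A", "A", "B", "A", "A", "B")
  bs$easy_chosen <- bs$chosen_task == bs$easy_task
  bs$chose_first <- bs$chosen_task == bs$first_task
  freq <- choice_frequencies(bs)
  expect_equal(freq$easy_choice_freq, mean(bs$easy_chosen))
  expect_equal(freq$n_acc_ties, 1L)
  hand_best <- mean((bs$chosen_task == bs$easy_task) ==
                      (bs$acc_diff > 0), na.rm = TRUE)
  manual <- ifelse(bs$acc_diff == 0, NA,
                   (bs$chosen_task == bs$easy_task) == (bs$acc_diff > 0))
  expect_equal(freq$best_performed_choice_freq, mean(manual, na.rm = TRUE))
  expect_equal(spe_sensitivity(bs), freq$easy_choice_freq)
})

test_that("random choices give chance-level frequencies, greedy choices extreme ones", {
  # uniform random choices
  set.seed(82)
  bs <- make_block_summaries(subject = 1, lp = rep(0, 1000),
                             delta_diff = sample(c(-8, 8), 1000, TRUE),
                             acc_diff = rnorm(1000, 0, 0.2))
  expect_lt(abs(spe_sensitivity(bs) - 0.5), 3 * sqrt(0.25 / 1000))

  # near-zero temperature with well separated difficulties
  p <- observer_params(sigma_p = 10, miss_rate = 0, tau = 0.05)
  res <- simulate_main_session(p, design_params(n_blocks = 400L), 18, 4,
                               seed = 83)
  ex <- exclude_trials(res$trials)
  bs2 <- block_summaries(ex$kept, res$blocks)
  expect_gt(spe_sensitivity(bs2), 0.9)
})

test_that("SPE sensitivity decreases monotonically in choice temperature", {
  sens <- vapply(c(0.1, 0.5, 2, 10), function(tau) {
    p <- observer_params(sigma_p = 10, miss_rate = 0, tau = tau)
    res <- simulate_main_session(p, design_params(n_blocks = 1000L), 14, 6,
                                 seed = 84)
    mean(res$blocks$chosen_task == res$blocks$easy_task)
  }, 0)
  expect_true(all(diff(sens) < 0))
})

test_that("the task-choice logistic recovers a known generating rule", {
  set.seed(85)
  n <- 1e4
  acc_diff <- rnorm(n, 0, 0.25)
  delta_diff <- sample(c(-8, 8), n, TRUE)
  # choices depend only on the z-scored accuracy difference, beta = 1
  lp <- 1.0 * (acc_diff - mean(acc_diff)) / sd(acc_diff)
  bs <- make_block_summaries(subject = 1, lp = lp,
                             delta_diff = delta_diff, acc_diff = acc_diff)
  fit <- task_choice_logistic(bs)
  ps <- fit$per_subject
  # asymptotic SE ~ 2/sqrt(n) for a logistic slope at beta = 1
  expect_lt(abs(ps$b_accuracy - 1), 0.1)
  expect_lt(abs(ps$b_difficulty), 0.1)
  expect_false(ps$separated)

  # deterministic difficulty-driven choices: flagged separation, right sign
  bs2 <- make_block_summaries(subject = 1, lp = rep(0, 200),
                              delta_diff = sample(c(-8, 8), 200, TRUE),
                              acc_diff = rnorm(200, 0, 0.2))
  bs2$chose_first <- ifelse(bs2$first_task == bs2$easy_task, TRUE, FALSE)
  bs2$chosen_task <- ifelse(bs2$chose_first, bs2$first_task,
                            ifelse(bs2$first_task == "A", "B", "A"))
  fit2 <- task_choice_logistic(bs2)
  expect_true(fit2$per_subject$separated)
  expect_gt(fit2$per_subject$b_difficulty, 0)

  expect_error(task_choice_logistic(bs2[1:5, ]), "fewer than")
})

test_that("null choice data give uniform p-values across replicates", {
  set.seed(86)
  pvals <- vapply(seq_len(200), function(i) {
    bs <- make_block_summaries(subject = 1, lp = rep(0, 64),
                               delta_diff = sample(c(-8, 8), 64, TRUE),
                               acc_diff = rnorm(64, 0, 0.25))
    fit <- suppressWarnings(task_choice_logistic(bs))
    s <- fit$per_subject
    2 * pnorm(-abs(s$b_accuracy / (2 / sqrt(64))))
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("choice-model deviances match the brute-force likelihood and null identity", {
  set.seed(87)
  conf_diff <- rnorm(300, 0, 0.8)
  bs <- make_block_summaries(subject = 1, lp = 1.2 * conf_diff,
                             delta_diff = sample(c(-8, 8), 300, TRUE),
                             acc_diff = rnorm(300, 0, 0.2),
                             conf_diff = conf_diff)
  dev <- choice_model_deviance(bs, "predicted_confidence")
  # brute force: -2 sum log p under the fitted coefficients
  first_is_a <- bs$first_task == "A"
  x <- ifelse(first_is_a, bs$conf_A - bs$conf_B, bs$conf_B - bs$conf_A)
  y <- as.integer(bs$chose_first)
  g <- glm(y ~ x, family = binomial())
  p_hat <- fitted(g)
  expect_equal(dev$sum_deviance, -2 * sum(log(ifelse(y == 1, p_hat, 1 - p_hat))),
               tolerance = 1e-6)

  # constant predictor degenerates to the intercept-only binomial deviance
  bs0 <- transform(bs, conf_A = 3.5, conf_B = 3.5)
  dev0 <- choice_model_deviance(bs0, "predicted_confidence")
  expect_equal(dev0$sum_deviance,
               glm(y ~ 1, family = binomial())$deviance, tolerance = 1e-6)

  bs_na <- transform(bs, conf_A = NA_real_, conf_B = NA_real_)
  expect_error(choice_model_deviance(bs_na, "predicted_confidence"),
               "transfer")
})

test_that("confidence-driven choices favor the confidence model's deviance", {
  set.seed(88)
  wins <- vapply(seq_len(50), function(i) {
    n <- 128
    conf_diff <- rnorm(n, 0, 0.8)
    # accuracy and RT are noisy correlates of the confidence signal
    acc_diff <- 0.2 * conf_diff + rnorm(n, 0, 0.25)
    logrt_diff <- -0.05 * conf_diff + rnorm(n, 0, 0.08)
    bs <- make_block_summaries(subject = 1, lp = 1.5 * conf_diff,
                               delta_diff = sample(c(-8, 8), n, TRUE),
                               acc_diff = acc_diff, conf_diff = conf_diff,
                               logrt_diff = logrt_diff)
    cmp <- compare_choice_models(bs)
    cmp$model[cmp$rank == 1] == "predicted_confidence"
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("frequencies and deviances are invariant to trial order within blocks", {
  p <- observer_params(sigma_p = 10, miss_rate = 0)
  res <- simulate_main_session(p, design_params(n_blocks = 40L), 14, 6,
                               seed = 89)
  tr <- res$trials
  tr$predicted_confidence <- 3 + tr$accuracy * 0.5
  bs1 <- block_summaries(tr, res$blocks)
  set.seed(90)
  shuffled <- tr[sample(nrow(tr)), ]
  bs2 <- block_summaries(shuffled, res$blocks)
  expect_equal(spe_sensitivity(bs2), spe_sensitivity(bs1))
  expect_equal(choice_model_deviance(bs2, "accuracy")$sum_deviance,
               choice_model_deviance(bs1, "accuracy")$sum_deviance)
})

test_that("the JZS Bayes factor matches quadrature and behaves monotonically", {
  # no effect: evidence for the null
  expect_lt(jzs_bayes_factor(0, 40), 1)
  # monotone in |t| at fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5), jzs_bayes_factor, 0, n = 30)
  expect_true(all(diff(bfs) > 0))
  # fine-grid quadrature oracle within 1%
  for (t_stat in c(0, 1, 2.5, 5))
    for (n in c(20, 40))
      expect_lt(abs(jzs_bayes_factor(t_stat, n) /
                      jzs_bf_quadrature(t_stat, n) - 1), 0.01)
  expect_error(jzs_bayes_factor(1, 1), "n")
})

test_that("the equal-performance Bayes factor reproduces the reported analysis scale", {
  # a t of 2.003 with 39 subjects is equivocal evidence (BF ~ 1)
  bf <- jzs_bayes_factor(2.003, 39)
  expect_equal(bf, 1.042, tolerance = 0.005)
})
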