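test_that("feature building z-scores within scope and drops constants", {
  set.seed(61)
  n <- 24
  tr <- data.frame(delta = sample(c(6, 14), n, replace = TRUE),
                   accuracy = rbinom(n, 1, 0.7),
                   rt_ms = exp(rnorm(n, 6.7, 0.3)),
                   response = "right")
  f <- build_features(tr)
  for (cn in c("difficulty", "accuracy", "log_rt")) {
    expect_lt(abs(mean(f[[cn]])), 1e-10)
    expect_lt(abs(sd(f[[cn]]) - 1), 1e-10)
  }
  # hand-computed z-scores
  expect_equal(f$difficulty,
               (tr$delta - mean(tr$delta)) / sd(tr$delta))
  expect_equal(f$log_rt,
               (log(tr$rt_ms) - mean(log(tr$rt_ms))) / sd(log(tr$rt_ms)))
  expect_equal(f$diff_x_acc, f$difficulty * f$accuracy)

  # all-correct subset: accuracy and the interaction disappear
  tr2 <- transform(tr, accuracy = 1L)
  expect_warning(f2 <- build_features(tr2), "accuracy")
  expect_false("accuracy" %in% names(f2))
  expect_false("diff_x_acc" %in% names(f2))

  expect_error(build_features(tr[1:10, ]), "20")
})

test_that("the ordinal fit recovers proportional-odds parameters", {
  set.seed(62)
  n <- 1e4
  x <- data.frame(difficulty = rnorm(n), accuracy = rnorm(n),
                  log_rt = rnorm(n))
  x$diff_x_acc <- x$difficulty * x$accuracy
  beta <- c(0.8, 0.5, -0.4, -0.05)
  zeta <- c(-2, -1, 0, 1, 2)
  y <- draw_proportional_odds(x, beta, zeta)
  fit <- fit_ordinal(x, y)
  expect_true(fit$converged)
  expect_true(all(diff(fit$cutpoints) > 0))

  # standard errors from the observed information of the fitted likelihood
  cdf <- plogis
  nll <- function(par) {
    zet <- cumsum(c(par[1], exp(par[2:5])))
    b <- par[6:9]
    eta <- drop(as.matrix(x) %*% b)
    up <- c(zet, Inf)[y] - eta
    lo <- c(-Inf, zet)[y] - eta
    -sum(log(pmax(cdf(up) - cdf(lo), 1e-12)))
  }
  par_hat <- c(fit$cutpoints[1], log(diff(fit$cutpoints)), fit$betas)
  h <- optimHess(par_hat, nll)
  se_beta <- sqrt(diag(solve(h)))[6:9]
  expect_true(all(abs(fit$betas - beta) < 3 * se_beta))
})

test_that("intercept-only cutpoints reproduce the marginal rating frequencies", {
  set.seed(63)
  y <- sample(1:6, 500, replace = TRUE, prob = c(0.05, 0.1, 0.2, 0.3, 0.25, 0.1))
  fit <- fit_ordinal(data.frame(), y)
  emp_cum <- cumsum(prop.table(table(factor(y, levels = 1:6))))[1:5]
  expect_equal(plogis(fit$cutpoints), unname(emp_cum), tolerance = 1e-5)
  # and the baseline prediction is the empirical expected rating
  pred <- predict_confidence(fit, data.frame())
  expect_equal(pred[1], mean(y), tolerance = 1e-5)
})

test_that("reported deviance equals the brute-force likelihood", {
  set.seed(64)
  n <- 400
  x <- data.frame(difficulty = rnorm(n), accuracy = rnorm(n))
  y <- draw_proportional_odds(x, c(0.7, 0.4), c(-1.5, -0.5, 0.3, 1.1, 2))
  fit <- fit_ordinal(x, y)
  expect_equal(fit$deviance, ordinal_deviance_brute(fit, x, y),
               tolerance = 1e-6)
  expect_gte(fit$deviance, 0)
})

test_that("the ordinal fit agrees with an independent proportional-odds implementation", {
  skip_if_not_installed("MASS")
  set.seed(65)
  n <- 2000
  x <- data.frame(difficulty = rnorm(n), accuracy = rnorm(n),
                  log_rt = rnorm(n))
  y <- draw_proportional_odds(x, c(0.6, 0.5, -0.3), c(-1.5, -0.5, 0.3, 1.1, 2))
  fit <- fit_ordinal(x, y)
  pol <- MASS::polr(factor(y, levels = 1:6) ~ difficulty + accuracy + log_rt,
                    data = cbind(x, y = y), method = "logistic")
  expect_equal(unname(fit$betas), unname(coef(pol)), tolerance = 1e-3)
  expect_equal(unname(fit$cutpoints), unname(pol$zeta), tolerance = 1e-3)
  expect_equal(fit$deviance, pol$deviance, tolerance = 1e-6)
})

test_that("degenerate rating patterns are handled, separation is flagged", {
  set.seed(66)
  n <- 300
  x <- data.frame(difficulty = rnorm(n))
  # only three observed categories -> collapsed fit, still valid
  y3 <- draw_proportional_odds(x, 0.5, c(-0.5, 0.5)) + 1  # values 2..4
  fit3 <- fit_ordinal(x, y3)
  expect_true(fit3$collapsed)
  expect_equal(fit3$levels, 2:4)
  expect_true(all(predict_confidence(fit3, x) >= 2 &
                    predict_confidence(fit3, x) <= 4))
  # complete separation: rating is a step function of x
  ys <- ifelse(x$difficulty > 0, 6, 1)
  fit_sep <- fit_ordinal(x, ys)
  expect_false(fit_sep$converged)
  expect_true(is.finite(fit_sep$betas[["difficulty"]]))
  expect_error(fit_ordinal(x, rep(3, n)), "distinct")
})

test_that("model comparison respects deviance nesting and detects the generator", {
  set.seed(67)
  n <- 400
  mk_subject <- function(sid) {
    tr <- data.frame(subject = sid,
                     delta = sample(c(6, 14), n, replace = TRUE),
                     accuracy = rbinom(n, 1, 0.75),
                     rt_ms = exp(rnorm(n, 6.7, 0.3)),
                     response = "right")
    f <- build_features(tr)
    tr$confidence <- draw_proportional_odds(
      f, c(0.6, 0.7, -0.3, -0.05)[seq_len(ncol(f))],
      c(-1.5, -0.5, 0.3, 1.1, 2))
    tr
  }
  trials <- rbind(mk_subject(1), mk_subject(2))
  sets <- c(default_candidate_sets(), list(intercept = character(0)))
  cmp <- compare_models(trials, sets)
  dev <- attr(cmp, "per_subject")
  # nesting: every superset fits at least as well, per subject
  nested <- list(c("acc", "acc_rt"), c("rt", "acc_rt"), c("diff", "acc_diff"),
                 c("acc_rt", "acc_rt_diff"), c("acc_rt_diff", "full"),
                 c("intercept", "acc"), c("intercept", "rt"),
                 c("intercept", "diff"))
  for (pair in nested)
    expect_true(all(dev[, pair[2]] <= dev[, pair[1]] + 1e-6))
  # the empty set is the worst of all
  expect_true(all(cmp$sum_deviance <= cmp$sum_deviance[cmp$model == "intercept"] + 1e-6))
})

test_that("an accuracy-only generator ranks the accuracy model above the RT model", {
  set.seed(68)
  wins <- vapply(seq_len(50), function(i) {
    n <- 300
    tr <- data.frame(subject = 1,
                     delta = sample(c(6, 14), n, replace = TRUE),
                     accuracy = rbinom(n, 1, 0.75),
                     rt_ms = exp(rnorm(n, 6.7, 0.3)),
                     response = "right")
    f <- build_features(tr)
    tr$confidence <- draw_proportional_odds(
      f[, "accuracy", drop = FALSE], 0.9, c(-1.5, -0.5, 0.3, 1.1, 2))
    cmp <- compare_models(tr, list(acc = "accuracy", rt = "log_rt"))
    cmp$sum_deviance[cmp$model == "acc"] <
      cmp$sum_deviance[cmp$model == "rt"]
  }, TRUE)
  expect_gt(mean(wins), 0.9)
})

test_that("predicted confidence transfers to the main session", {
  # bounds are structural
  set.seed(69)
  x <- data.frame(difficulty = rnorm(30), accuracy = rnorm(30))
  y <- draw_proportional_odds(x, c(0.8, 0.4), c(-1.5, -0.5, 0.3, 1.1, 2))
  fit <- fit_ordinal(x, y)
  wild <- data.frame(difficulty = c(-50, 0, 50), accuracy = c(50, 0, -50))
  pred <- predict_confidence(fit, wild)
  expect_true(all(pred >= 1 & pred <= 6))
  expect_error(predict_confidence(fit, data.frame(difficulty = 0)),
               "mismatch")

  # generative transfer: predictions track the simulator's latent confidence
  cors <- vapply(seq_len(20), function(i) {
    p <- observer_params(sigma_p = 10 + i %% 5, sigma_m = 0.4, miss_rate = 0)
    d <- design_params()
    meta <- simulate_metacog_session(p, d, 14, 6, seed = 800 + i)
    ofit <- fit_ordinal(suppressWarnings(build_features(meta)),
                        meta$confidence)
    main <- simulate_main_session(p, d, 14, 6, seed = 900 + i)$trials
    main <- main[main$response != "none", ]
    fmain <- suppressWarnings(build_features(main))[, names(ofit$betas)]
    cor(predict_confidence(ofit, fmain), main$rating)
  }, 0)
  expect_gt(median(cors), 0.5)
})

test_that("transfer reproduces the correct/easy confidence ordering and predicts choices", {
  higher_correct <- logical(100)
  higher_easy <- logical(100)
  conf_beta_pos <- logical(100)
  for (i in seq_len(100)) {
    p <- observer_params(sigma_p = 9 + (i %% 7), sigma_m = 0.3, miss_rate = 0,
                         tau = 1)
    d <- design_params()
    meta <- simulate_metacog_session(p, d, 14, 6, seed = 2000 + i)
    ofit <- fit_ordinal(suppressWarnings(build_features(meta)),
                        meta$confidence)
    sim <- simulate_main_session(p, d, 14, 6, seed = 3000 + i)
    main <- sim$trials[sim$trials$response != "none", ]
    fmain <- suppressWarnings(build_features(main))[, names(ofit$betas)]
    main$predicted_confidence <- predict_confidence(ofit, fmain)
    higher_correct[i] <-
      mean(main$predicted_confidence[main$accuracy == 1]) >
      mean(main$predicted_confidence[main$accuracy == 0])
    higher_easy[i] <-
      mean(main$predicted_confidence[main$delta == 14]) >
      mean(main$predicted_confidence[main$delta == 6])
    bs <- block_summaries(main, sim$blocks)
    dev <- choice_model_deviance(bs, "predicted_confidence")
    conf_beta_pos[i] <- dev$per_subject$beta > 0
  }
  expect_gte(mean(higher_correct), 0.95)
  expect_gte(mean(higher_easy), 0.95)
  expect_gte(mean(conf_beta_pos), 0.95)
})

test_that("group-level coefficient tests behave like one-sample t tests", {
  mk_fit <- function(betas) {
    structure(list(betas = betas, cutpoints = c(-1, 0, 1, 2, 3),
                   deviance = 0, levels = 1:6, link = "logit"),
              class = "ordinal_fit")
  }
  zero <- lapply(1:5, function(i) mk_fit(c(difficulty = 0, accuracy = 0)))
  gt <- group_coefficient_tests(zero)
  expect_true(all(gt$t == 0))

  set.seed(70)
  reject <- vapply(seq_len(100), function(i) {
    b <- rnorm(30, 0.5, 0.1)
    fits <- lapply(b, function(x) mk_fit(c(difficulty = x)))
    group_coefficient_tests(fits)$p < 0.001
  }, TRUE)
  expect_gt(mean(reject), 0.95)

  set.seed(71)
  fits <- lapply(rnorm(10, 0.3, 0.2), function(x) mk_fit(c(accuracy = x)))
  flipped <- lapply(fits, function(f) mk_fit(-f$betas))
  expect_equal(group_coefficient_tests(flipped)$t,
               -group_coefficient_tests(fits)$t)
  expect_error(group_coefficient_tests(fits[1:2]), "3 subjects")
})
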