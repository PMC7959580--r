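## Global self-performance estimate (SPE) analyses: trial exclusions,
## a-posteriori SPE labelling, end-of-block choice frequencies, task-choice
## logistic regressions and deviance-based comparison of choice models.

#' Exclude missed and RT-outlier trials
#'
#' Drops trials with no response, then trials whose log RT lies more than 3
#' SDs from the subject's mean log RT (mean/SD computed once on the responded
#' set, no re-iteration after removal).
#'
#' @param trials Tidy trial data.frame with `subject`, `response`, `rt_ms`.
#' @param z_cut Outlier cut in SD units (default 3).
#' @return List with `kept` (filtered trials) and `report` (per subject:
#'   `n_total`, `n_missed`, `n_outlier`, `frac_excluded`).
#' @export
exclude_trials <- function(trials, z_cut = 3) {
  keep <- logical(nrow(trials))
  reports <- list()
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s)
    responded <- trials$response[idx] != "none"
    lrt <- log(trials$rt_ms[idx])
    mu <- mean(lrt[responded])
    sd_ <- stats::sd(lrt[responded])
    z <- if (is.na(sd_) || sd_ == 0) rep(0, length(idx)) else (lrt - mu) / sd_
    ok <- responded & abs(z) <= z_cut
    ok[is.na(ok)] <- FALSE
    keep[idx] <- ok
    reports[[length(reports) + 1L]] <- data.frame(
      subject = s, n_total = length(idx), n_missed = sum(!responded),
      n_outlier = sum(responded & !ok),
      frac_excluded = 1 - sum(ok) / length(idx))
  }
  if (all(!keep))
    warning("all trials excluded", call. = FALSE)
  list(kept = trials[keep, , drop = FALSE],
       report = do.call(rbind, reports))
}

#' Label trials by their block's end-of-block choice
#'
#' Tags each main-session trial `higher_SPE` if it belongs to the task chosen
#' at the end of its block, `lower_SPE` otherwise.
#'
#' @param trials Main-session trials with `subject`, `block`, `task`.
#' @param blocks Block table with `subject`, `block`, `chosen_task`.
#' @return `trials` with an added `spe_label` column.
#' @export
label_trials <- function(trials, blocks) {
  if (anyNA(blocks$chosen_task))
    stop_param("block(s) without a recorded choice: ",
               paste(blocks$block[is.na(blocks$chosen_task)], collapse = ", "))
  key_t <- paste(trials$subject, trials$block)
  key_b <- paste(blocks$subject, blocks$block)
  mi <- match(key_t, key_b)
  if (anyNA(mi))
    stop_param("trial block(s) missing from block table: ",
               paste(unique(key_t[is.na(mi)]), collapse = "; "))
  chosen <- blocks$chosen_task[mi]
  trials$spe_label <- ifelse(trials$task == chosen, "higher_SPE", "lower_SPE")
  trials
}

#' Summarize main-session blocks per task
#'
#' Collapses (post-exclusion) main-session trials to one row per block with
#' per-task accuracy, mean log RT, mean predicted confidence (if a
#' `predicted_confidence` column is present) and valid-trial counts, plus the
#' derived quantities used by the choice analyses: the easy task, the
#' accuracy difference (easy - difficult), the performance class (sign of
#' that difference; exact ties are "null") and indicator columns for the
#' chosen task.
#'
#' @param trials Post-exclusion main-session trials.
#' @param blocks Block table from [simulate_main_session()] (or equivalent):
#'   `subject`, `block`, `easy_task`, `first_task`, `delta_A`, `delta_B`,
#'   `chosen_task`.
#' @return Data.frame, one row per block.
#' @export
block_summaries <- function(trials, blocks) {
  has_pc <- "predicted_confidence" %in% names(trials)
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    tr <- trials[trials$subject == b$subject & trials$block == b$block, ]
    stat <- function(tk) {
      tt <- tr[tr$task == tk, ]
      data.frame(acc = mean(tt$accuracy), logrt = mean(log(tt$rt_ms)),
                 conf = if (has_pc) mean(tt$predicted_confidence) else NA_real_,
                 n = nrow(tt))
    }
    a <- stat("A"); bb <- stat("B")
    easy_is_a <- b$easy_task == "A"
    acc_easy <- if (easy_is_a) a$acc else bb$acc
    acc_hard <- if (easy_is_a) bb$acc else a$acc
    acc_diff <- acc_easy - acc_hard
    data.frame(subject = b$subject, block = b$block,
               easy_task = b$easy_task, first_task = b$first_task,
               chosen_task = b$chosen_task,
               delta_A = b$delta_A, delta_B = b$delta_B,
               acc_A = a$acc, acc_B = bb$acc,
               logrt_A = a$logrt, logrt_B = bb$logrt,
               conf_A = a$conf, conf_B = bb$conf,
               n_A = a$n, n_B = bb$n,
               acc_diff = acc_diff,
               perf_class = if (is.na(acc_diff)) NA_character_
                            else if (acc_diff > 0) "positive"
                            else if (acc_diff < 0) "negative" else "null",
               easy_chosen = b$chosen_task == b$easy_task,
               chose_first = b$chosen_task == b$first_task,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-of-block choice frequencies and their group tests
#'
#' Computes the frequency of choosing the easier task (the SPE sensitivity),
#' the frequency of choosing the better-performed task (blocks with exactly
#' tied accuracies are excluded from this denominator and counted), and the
#' easy-choice frequency split by performance class (positive / null /
#' negative accuracy difference). Group tests: a one-sample t (plus JZS
#' Bayes factor) of the per-subject null-class frequency against 0.5, and
#' paired t tests of per-subject frequencies between classes (subjects
#' missing a class are excluded from that test, with the n reported).
#'
#' @param bs Block summaries from [block_summaries()].
#' @return List of class `spe_behavior` with `easy_choice_freq`,
#'   `best_performed_choice_freq`, `n_acc_ties`, `split_freq`,
#'   `per_subject`, and `tests`.
#' @export
choice_frequencies <- function(bs) {
  if (nrow(bs) < 1L) stop_param("need >= 1 block")
  best_chosen <- ifelse(bs$acc_diff == 0, NA,
                        (bs$chosen_task == bs$easy_task) == (bs$acc_diff > 0))
  subj_freq <- function(sel) {
    d <- bs[sel, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    stats::aggregate(easy_chosen ~ subject, data = d, FUN = mean)
  }
  per_subject <- list(
    overall = subj_freq(rep(TRUE, nrow(bs))),
    positive = subj_freq(bs$perf_class == "positive"),
    null = subj_freq(bs$perf_class == "null"),
    negative = subj_freq(bs$perf_class == "negative"))

  paired_t <- function(a, b) {
    m <- merge(a, b, by = "subject")
    if (nrow(m) < 2L)
      return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = nrow(m)))
    tt <- stats::t.test(m$easy_chosen.x, m$easy_chosen.y, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n = nrow(m))
  }
  null_vs_half <- if (!is.null(per_subject$null) &&
                      nrow(per_subject$null) >= 2L) {
    x <- per_subject$null$easy_chosen
    if (stats::sd(x) == 0) {
      list(t = if (mean(x) == 0.5) 0 else Inf * sign(mean(x) - 0.5),
           df = length(x) - 1L, p = NA_real_, n = length(x), bf10 = NA_real_)
    } else {
      tt <- stats::t.test(x, mu = 0.5)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, n = length(x),
           bf10 = jzs_bayes_factor(unname(tt$statistic), length(x)))
    }
  } else list(t = NA_real_, df = NA_real_, p = NA_real_, n = 0L,
              bf10 = NA_real_)

  structure(list(
    easy_choice_freq = mean(bs$easy_chosen),
    best_performed_choice_freq = mean(best_chosen, na.rm = TRUE),
    n_acc_ties = sum(bs$acc_diff == 0, na.rm = TRUE),
    split_freq = vapply(c("positive", "null", "negative"), function(cl) {
      sel <- bs$perf_class == cl
      if (any(sel)) mean(bs$easy_chosen[sel]) else NA_real_
    }, 0),
    per_subject = per_subject,
    tests = list(null_vs_half = null_vs_half,
                 positive_vs_negative = paired_t(per_subject$positive,
                                                 per_subject$negative),
                 positive_vs_null = paired_t(per_subject$positive,
                                             per_subject$null))),
    class = "spe_behavior")
}

#' SPE sensitivity
#'
#' Frequency of choosing the objectively easier task at the end of blocks —
#' the behavioral covariate of global SPE accuracy.
#'
#' @param bs Block summaries from [block_summaries()].
#' @return Value in \[0, 1\].
#' @export
spe_sensitivity <- function(bs) {
  if (nrow(bs) < 1L) stop_param("need >= 1 block")
  mean(bs$easy_chosen)
}

## Logistic fit with a ridge fallback on separation; returns coefficients,
## deviance, and a separation flag. y in {0,1}, x a model matrix sans
## intercept.
logistic_fit <- function(y, x) {
  df <- data.frame(y = y, x)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  separated <- warned && any(abs(co[-1]) > 15, na.rm = TRUE)
  if (separated || anyNA(co)) {
    xm <- cbind(1, as.matrix(x))
    nll <- function(b) {
      eta <- drop(xm %*% b)
      -sum(y * eta - log1p(exp(eta))) + 1e-4 * sum(b[-1]^2)
    }
    op <- stats::optim(rep(0, ncol(xm)), nll, method = "BFGS",
                       control = list(maxit = 1000))
    co <- op$par
    names(co) <- c("(Intercept)", colnames(x))
    eta <- drop(xm %*% co)
    dev <- -2 * sum(y * eta - log1p(exp(eta)))
    return(list(coef = co, deviance = dev, separated = TRUE))
  }
  list(coef = co, deviance = stats::deviance(fit), separated = FALSE)
}

#' Per-subject logistic regression of task choice on difficulty and accuracy
#'
#' Outcome: choice of the first-cued task in each block. Predictors:
#' between-task differences (first minus second cued task) in difficulty
#' (square difference) and realized accuracy, each z-scored across blocks
#' within subject, plus their product. Coefficients are tested at the group
#' level with one-sample t tests.
#'
#' @param bs Block summaries from [block_summaries()].
#' @param min_blocks Minimum blocks per subject (default 10).
#' @return List of class `choice_model_fit` with `per_subject` (coefficients,
#'   deviance, separation flag) and `group` (t tests per coefficient).
#' @export
task_choice_logistic <- function(bs, min_blocks = 10L) {
  per <- lapply(split(bs, bs$subject), function(d) {
    if (nrow(d) < min_blocks)
      stop_param("subject ", d$subject[1], ": fewer than ", min_blocks,
                 " blocks")
    first_is_a <- d$first_task == "A"
    ddiff <- ifelse(first_is_a, d$delta_A - d$delta_B, d$delta_B - d$delta_A)
    adiff <- ifelse(first_is_a, d$acc_A - d$acc_B, d$acc_B - d$acc_A)
    zd <- zscore_or_null(ddiff) %||% rep(0, nrow(d))
    za <- zscore_or_null(adiff) %||% rep(0, nrow(d))
    x <- data.frame(difficulty = zd, accuracy = za, interaction = zd * za)
    fit <- logistic_fit(as.integer(d$chose_first), x)
    data.frame(subject = d$subject[1],
               b_difficulty = fit$coef[["difficulty"]],
               b_accuracy = fit$coef[["accuracy"]],
               b_interaction = fit$coef[["interaction"]],
               deviance = fit$deviance, separated = fit$separated)
  })
  per <- do.call(rbind, per)
  group <- do.call(rbind, lapply(
    c("b_difficulty", "b_accuracy", "b_interaction"), function(cn) {
      b <- per[[cn]]
      if (length(b) < 2L || stats::sd(b) == 0)
        return(data.frame(coef = cn, mean = mean(b), t = NA_real_,
                          df = NA_real_, p = NA_real_))
      tt <- stats::t.test(b)
      data.frame(coef = cn, mean = mean(b), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }))
  structure(list(per_subject = per, group = group),
            class = "choice_model_fit")
}

#' Deviance of a single-predictor choice model
#'
#' Per subject, a logistic regression of the end-of-block choice (first-cued
#' task chosen) on the between-task difference (first minus second) in one
#' predictor: mean predicted confidence, realized accuracy, or mean log RT.
#' Deviances (-2 logL) are summed across subjects.
#'
#' @param bs Block summaries (with `conf_A`/`conf_B` populated when
#'   `predictor = "predicted_confidence"`).
#' @param predictor One of `"predicted_confidence"`, `"accuracy"`,
#'   `"log_rt"`.
#' @return List with `predictor`, `per_subject` (subject, beta, deviance,
#'   separated), `sum_deviance`.
#' @export
choice_model_deviance <- function(bs,
                                  predictor = c("predicted_confidence",
                                                "accuracy", "log_rt")) {
  predictor <- match.arg(predictor)
  cols <- switch(predictor,
                 predicted_confidence = c("conf_A", "conf_B"),
                 accuracy = c("acc_A", "acc_B"),
                 log_rt = c("logrt_A", "logrt_B"))
  if (predictor == "predicted_confidence" && all(is.na(bs$conf_A)))
    stop_param("no predicted confidence in the block summaries; run the ",
               "transfer step first")
  per <- lapply(split(bs, bs$subject), function(d) {
    first_is_a <- d$first_task == "A"
    xdiff <- ifelse(first_is_a, d[[cols[1]]] - d[[cols[2]]],
                    d[[cols[2]]] - d[[cols[1]]])
    fit <- logistic_fit(as.integer(d$chose_first),
                        data.frame(x = xdiff))
    data.frame(subject = d$subject[1], beta = fit$coef[["x"]],
               deviance = fit$deviance, separated = fit$separated)
  })
  per <- do.call(rbind, per)
  list(predictor = predictor, per_subject = per,
       sum_deviance = sum(per$deviance))
}

#' Compare the confidence, accuracy and RT choice models by summed deviance
#'
#' @param bs Block summaries with predicted confidence populated.
#' @return Data.frame ranked ascending by summed deviance.
#' @export
compare_choice_models <- function(bs) {
  fits <- lapply(c("predicted_confidence", "accuracy", "log_rt"),
                 function(p) choice_model_deviance(bs, p))
  out <- data.frame(model = vapply(fits, `[[`, "", "predictor"),
                    sum_deviance = vapply(fits, `[[`, 0, "sum_deviance"))
  out$rank <- rank(out$sum_deviance, ties.method = "min")
  out[order(out$rank), ]
}
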