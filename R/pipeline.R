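## End-to-end cohort pipeline: simulate -> calibrate -> main/metacog at the
## extracted levels -> exclusions -> metacognitive metrics -> confidence
## model and transfer -> SPE analyses.

#' Simulate one subject's three sessions
#'
#' Runs the closed loop for a single observer: a calibration session, a
#' psychometric fit, extraction of the 70%/85% levels, then the main
#' (blocked, with end-of-block choices) and metacognition (confidence-rating)
#' sessions at those levels. Session seeds are derived from `seed` by fixed
#' offsets.
#'
#' @param params An [observer_params()] object.
#' @param design A [design_params()] object.
#' @param subject Subject identifier.
#' @param seed Integer seed for this subject.
#' @param fix_lapse Passed to [fit_psychometric()].
#' @return List: `trials` (all sessions, row-bound), `blocks`, `psych_fit`,
#'   `levels`, `params`, `seed`.
#' @export
simulate_subject <- function(params = observer_params(),
                             design = design_params(),
                             subject = 1L, seed = 1L, fix_lapse = TRUE) {
  calib <- simulate_calibration_session(params, design, subject, seed = seed)
  fit <- fit_psychometric(calib, fix_lapse = fix_lapse)
  lev <- extract_difficulty_levels(fit, design$target_accuracies)
  main <- simulate_main_session(params, design, lev$easy_delta,
                                lev$hard_delta, subject, seed = seed + 1L)
  meta <- simulate_metacog_session(params, design, lev$easy_delta,
                                   lev$hard_delta, subject, seed = seed + 2L)
  list(trials = rbind(calib, main$trials, meta),
       blocks = main$blocks, psych_fit = fit, levels = lev,
       params = params, seed = seed)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Draws a cohort of observers from the configured parameter ranges,
#' simulates all three sessions per subject, applies the missed/RT-outlier
#' exclusions, fits the metacognitive metrics (per-condition meta-d' and
#' AUROC2) and the full ordinal confidence model per subject, transfers the
#' confidence model to the main session, and runs the block-level SPE
#' analyses (choice frequencies with group tests, the difficulty/accuracy
#' task-choice logistic, and the confidence/accuracy/RT choice-model
#' deviance comparison). Fully reproducible given the configuration.
#'
#' @param config A [study_config()] object.
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `blocks.csv`, `config.txt`, `sidecar.json` and `report.json`.
#' @return List of class `spe_report`; see the `report` element names.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL) {
  design <- config$design
  set.seed(config$seed)
  runif_range <- function(r) stats::runif(config$n_subjects, r[1], r[2])
  sigma_p <- runif_range(config$sigma_p_range)
  sigma_m <- runif_range(config$sigma_m_range)
  tau <- runif_range(config$tau_range)
  subj_seed <- config$seed + 7919L * seq_len(config$n_subjects)

  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    params <- observer_params(sigma_p = sigma_p[i], sigma_m = sigma_m[i],
                              tau = tau[i], lapse = config$lapse,
                              miss_rate = config$miss_rate)
    subjects[[i]] <- simulate_subject(params, design, subject = i,
                                      seed = subj_seed[i],
                                      fix_lapse = config$fix_lapse)
  }
  trials <- do.call(rbind, lapply(subjects, `[[`, "trials"))
  blocks <- do.call(rbind, lapply(subjects, `[[`, "blocks"))

  main_ex <- exclude_trials(trials[trials$session == "main", ])
  meta_ex <- exclude_trials(trials[trials$session == "metacog", ])

  per_subject <- vector("list", config$n_subjects)
  ordinal_fits <- vector("list", config$n_subjects)
  main_kept_list <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    s <- subjects[[i]]
    meta_tr <- meta_ex$kept[meta_ex$kept$subject == i, ]
    main_tr <- main_ex$kept[main_ex$kept$subject == i, ]
    metrics <- if (config$run_metad) per_condition_metrics(meta_tr) else NULL
    an <- anova_2x2(meta_tr)
    feats_meta <- suppressWarnings(build_features(meta_tr))
    ofit <- fit_ordinal(feats_meta, meta_tr$confidence, link = config$link)
    feats_main <- suppressWarnings(build_features(main_tr))
    feats_main <- feats_main[, names(ofit$betas), drop = FALSE]
    main_tr$predicted_confidence <- predict_confidence(ofit, feats_main)
    ordinal_fits[[i]] <- ofit
    main_kept_list[[i]] <- main_tr
    per_subject[[i]] <- list(
      subject = i,
      sigma_f = s$psych_fit$sigma_f,
      easy_delta = s$levels$easy_delta, hard_delta = s$levels$hard_delta,
      m_ratio_avg = if (is.null(metrics)) NA else metrics$m_ratio_avg,
      auroc2_avg = if (is.null(metrics)) NA else metrics$auroc2_avg,
      anova = an,
      ordinal = list(betas = as.list(ofit$betas),
                     deviance = ofit$deviance,
                     converged = ofit$converged))
  }
  main_kept <- do.call(rbind, main_kept_list)
  main_kept <- label_trials(main_kept, blocks)
  bs <- block_summaries(main_kept, blocks)

  freq <- choice_frequencies(bs)
  tcl <- task_choice_logistic(bs)
  dev_cmp <- compare_choice_models(bs)
  coef_tests <- if (config$n_subjects >= 3L) {
    group_coefficient_tests(ordinal_fits)
  } else {
    list(note = "group coefficient tests need >= 3 subjects")
  }

  ## Mean predicted confidence on higher- vs lower-SPE trials (per subject),
  ## the Fig-style local-global link
  pc <- stats::aggregate(predicted_confidence ~ subject + spe_label,
                         data = main_kept, FUN = mean)
  wide <- stats::reshape(pc, idvar = "subject", timevar = "spe_label",
                         direction = "wide")
  names(wide) <- sub("predicted_confidence\\.", "", names(wide))
  spe_conf_test <- if (nrow(wide) >= 2L &&
                       all(c("higher_SPE", "lower_SPE") %in% names(wide))) {
    tt <- stats::t.test(wide$higher_SPE, wide$lower_SPE, paired = TRUE)
    list(mean_higher = mean(wide$higher_SPE),
         mean_lower = mean(wide$lower_SPE),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  } else list(mean_higher = mean(wide$higher_SPE %||% NA_real_),
              mean_lower = mean(wide$lower_SPE %||% NA_real_),
              t = NA_real_, df = NA_real_, p = NA_real_,
              note = "group test needs >= 2 subjects")

  report <- list(
    n_subjects = config$n_subjects,
    seed = config$seed,
    exclusions = list(main = main_ex$report, metacog = meta_ex$report),
    accuracy = NULL,  # filled below from the block summaries
    choice_frequencies = list(
      easy_choice_freq = freq$easy_choice_freq,
      best_performed_choice_freq = freq$best_performed_choice_freq,
      split_freq = as.list(freq$split_freq),
      per_subject = freq$per_subject,
      tests = freq$tests),
    task_choice_logistic = list(per_subject = tcl$per_subject,
                                group = tcl$group),
    choice_model_deviance = dev_cmp,
    ordinal_group_tests = coef_tests,
    predicted_confidence_by_spe = spe_conf_test,
    per_subject = per_subject)
  acc_easy <- ifelse(bs$easy_task == "A", bs$acc_A, bs$acc_B)
  acc_hard <- ifelse(bs$easy_task == "A", bs$acc_B, bs$acc_A)
  report$accuracy <- list(easy = mean(acc_easy, na.rm = TRUE),
                          hard = mean(acc_hard, na.rm = TRUE))

  out <- structure(list(report = report, trials = trials, blocks = blocks,
                        block_summaries = bs, main_kept = main_kept,
                        ordinal_fits = ordinal_fits, config = config),
                   class = "spe_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(blocks, file.path(out_dir, "blocks.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.txt"))
    write_sidecar(lapply(subjects, `[[`, "params"), design, config$seed,
                  file.path(out_dir, "sidecar.json"))
    rep_out <- report
    rep_out$config_hash <- config_hash(config)
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  out
}

#' Stable hash of a study configuration
#'
#' A dependency-free polynomial checksum over the flat key=value rendering,
#' used to stamp pipeline artifacts with the configuration that produced
#' them.
#'
#' @param config A [study_config()] object.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(config, tmp)
  bytes <- utf8ToInt(paste(readLines(tmp), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}

#' @export
print.spe_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Synthetic SPE cohort: %d subjects (seed %d)\n",
              r$n_subjects, r$seed))
  cat(sprintf("  accuracy: easy %.3f, hard %.3f\n",
              r$accuracy$easy, r$accuracy$hard))
  cat(sprintf("  easy-task choice frequency: %.3f\n",
              r$choice_frequencies$easy_choice_freq))
  cat(sprintf("  predicted confidence higher/lower SPE: %.3f / %.3f\n",
              r$predicted_confidence_by_spe$mean_higher,
              r$predicted_confidence_by_spe$mean_lower))
  cat("  choice-model deviances:\n")
  print(r$choice_model_deviance, row.names = FALSE)
  invisible(x)
}
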