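## Data contracts: the tidy trial-table CSV shared by synthetic and deposited
## data, its JSON sidecar, and the flat key=value study configuration.

TRIAL_COLUMNS <- c("subject", "session", "block", "trial", "task", "delta",
                   "side", "response", "accuracy", "rt_ms", "confidence",
                   "chosen_task")

#' Write the tidy trial table
#'
#' Writes the public columns of a trial table (header
#' `subject,session,block,trial,task,delta,side,response,accuracy,rt_ms,confidence,chosen_task`)
#' as CSV. Numeric columns are rendered with 17 significant digits so the
#' table round-trips losslessly through [read_trials()]. Generative internals
#' (`rating`, `evidence`, `meta_evidence`) are never written.
#'
#' @param trials Trial data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop_param("trial table lacks column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(trials),
                   c(TRIAL_COLUMNS, "rating", "evidence", "meta_evidence",
                     "spe_label", "predicted_confidence"))
  out <- trials[, c(TRIAL_COLUMNS,
                    intersect(c("predicted_confidence", "spe_label"),
                              names(trials)),
                    extra)]
  for (cn in names(out))
    if (is.double(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), NA,
                          sprintf("%.17g", out[[cn]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a tidy trial table
#'
#' Schema validation: required columns present, `session` in
#' calibration/main/metacog, `side`/`response` in their domains, `accuracy`
#' in 0/1, `rt_ms` positive on responded trials, `confidence` in 1..6 or
#' empty, and no duplicate (subject, session, block, trial) key. The first
#' violation is reported with its row number. Extra columns are preserved
#' with a warning. Row order is preserved.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing))
    stop_param("missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(tr),
                   c(TRIAL_COLUMNS, "predicted_confidence", "spe_label"))
  if (length(extra))
    warning("extra column(s) preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  fail <- function(what, rows)
    stop_param(what, " (first at file row ", rows[1] + 1L, ")")
  chk <- function(bad, what) if (any(bad)) fail(what, which(bad))
  chk(!tr$session %in% c("calibration", "main", "metacog"),
      "invalid `session` value")
  chk(!tr$side %in% c("left", "right"), "invalid `side` value")
  chk(!tr$response %in% c("left", "right", "none"),
      "invalid `response` value")
  chk(!tr$accuracy %in% c(0L, 1L), "`accuracy` must be 0 or 1")
  chk(!is.na(tr$delta) & tr$delta <= 0, "`delta` must be positive")
  chk(tr$response != "none" & (is.na(tr$rt_ms) | tr$rt_ms <= 0),
      "`rt_ms` must be positive on responded trials")
  chk(!is.na(tr$confidence) & !tr$confidence %in% 1:6,
      "`confidence` must lie in 1..6")
  key <- paste(tr$subject, tr$session, tr$block, tr$trial)
  chk(duplicated(key), "duplicate (subject, session, block, trial) key")
  tr
}

#' Write the JSON sidecar recording how a dataset was generated
#'
#' @param params,design Generating [observer_params()] / [design_params()]
#'   (or a list of per-subject `observer_params`).
#' @param seed Master seed.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(params, design, seed, path) {
  jsonlite::write_json(list(params = unclass_deep(params),
                            design = unclass(design), seed = seed),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Study configuration
#'
#' The full specification of a synthetic cohort run: the master seed, the
#' design, per-subject observer-parameter ranges (subjects are drawn
#' uniformly within each range), and analysis switches.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param design A [design_params()] object.
#' @param sigma_p_range,sigma_m_range,tau_range Uniform ranges for the
#'   between-subject parameter draws.
#' @param lapse,miss_rate Shared observer parameters.
#' @param link Ordinal link function.
#' @param fix_lapse Fix the psychometric lapse at 0.
#' @param run_metad Compute per-condition meta-d' fits in the pipeline.
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_subjects = 40L,
                         design = design_params(),
                         sigma_p_range = c(9, 16),
                         sigma_m_range = c(0.2, 0.8),
                         tau_range = c(0.6, 1.4),
                         lapse = 0, miss_rate = 0.02,
                         link = "logit", fix_lapse = TRUE,
                         run_metad = TRUE) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 design = design, sigma_p_range = sigma_p_range,
                 sigma_m_range = sigma_m_range, tau_range = tau_range,
                 lapse = lapse, miss_rate = miss_rate, link = link,
                 fix_lapse = fix_lapse, run_metad = run_metad),
            class = "study_config")
}

#' Write a study configuration as flat key=value text
#' @param config A [study_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(config[setdiff(names(config), "design")], unclass(config$design))
  fmt <- function(v) {
    if (is.double(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(v, collapse = ",")
  }
  writeLines(paste0(names(flat), "=", vapply(flat, fmt, "")), path)
  invisible(path)
}

#' Read a study configuration written by [write_config()]
#' @param path Path to the key=value file.
#' @return A [study_config()] object (bit-exact round trip).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(p)
    strsplit(p[2], ",", fixed = TRUE)[[1]]), vapply(kv, `[[`, "", 1))
  num <- function(x) as.numeric(x)
  int <- function(x) as.integer(x)
  lgl <- function(x) as.logical(x)
  design <- design_params(
    n_blocks = int(vals$n_blocks),
    trials_per_block = int(vals$trials_per_block),
    trials_per_task = int(vals$trials_per_task),
    max_run = int(vals$max_run),
    calib_levels = num(vals$calib_levels),
    n_calib_trials = int(vals$n_calib_trials),
    n_metacog_trials = int(vals$n_metacog_trials),
    target_accuracies = num(vals$target_accuracies),
    n_rating_levels = int(vals$n_rating_levels),
    deadline_ms = num(vals$deadline_ms),
    grid_cells = int(vals$grid_cells),
    reference_squares = int(vals$reference_squares))
  study_config(seed = int(vals$seed), n_subjects = int(vals$n_subjects),
               design = design,
               sigma_p_range = num(vals$sigma_p_range),
               sigma_m_range = num(vals$sigma_m_range),
               tau_range = num(vals$tau_range),
               lapse = num(vals$lapse), miss_rate = num(vals$miss_rate),
               link = vals$link, fix_lapse = lgl(vals$fix_lapse),
               run_metad = lgl(vals$run_metad))
}
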