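## Synthetic SDT observer and session generators.
##
## The generative model: on a trial with square difference `delta` and correct
## side `side`, the observer draws decision evidence
##   e ~ Normal(s * delta / sigma_p, 1),   s = +1 (right), -1 (left),
## responds with the sign of e (random guess with probability `lapse`, no
## response with probability `miss_rate`), forms metacognitive evidence
##   m = |e| + Normal(0, sigma_m),
## and maps m through 5 fixed criteria to a 1-6 confidence rating. Log RT is
## linear in |e| with Gaussian noise. End-of-block task choices are softmax on
## the within-block mean rating difference with temperature `tau`.

#' Parameters of the generative SDT observer
#'
#' Bundles the parameters of the simulated metacognitive observer used by all
#' session generators.
#'
#' @param sigma_p Perceptual noise in square-difference units (> 0). Accuracy
#'   at square difference `delta` is `Phi(delta / sigma_p)` (lapse-free).
#' @param lapse Probability of a stimulus-independent random guess, in
#'   \[0, 0.1\].
#' @param sigma_m Metacognitive noise (>= 0): SD of additive Gaussian noise on
#'   the confidence evidence `|e|`. 0 gives an SDT-ideal rater (M-ratio 1).
#' @param criteria Five strictly increasing nonnegative thresholds on the
#'   metacognitive evidence axis mapping to ratings 1-6.
#' @param rt_intercept,rt_slope,rt_sd Log-RT model: `log RT = rt_intercept -
#'   rt_slope * |e| + Normal(0, rt_sd)`, RT in ms.
#' @param miss_rate Probability of no response within the deadline, in
#'   \[0, 0.05\].
#' @param tau Task-choice softmax temperature (> 0) on the ratings scale.
#' @return An object of class `observer_params` (a named list).
#' @export
observer_params <- function(sigma_p = 12, lapse = 0, sigma_m = 0.4,
                            criteria = c(0.5, 1.0, 1.5, 2.0, 2.5),
                            rt_intercept = 6.85, rt_slope = 0.12, rt_sd = 0.15,
                            miss_rate = 0.02, tau = 1) {
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || sigma_p <= 0)
    stop_param("`sigma_p` must be a single positive number")
  if (lapse < 0 || lapse > 0.1)
    stop_param("`lapse` must lie in [0, 0.1]")
  if (sigma_m < 0)
    stop_param("`sigma_m` must be >= 0")
  if (length(criteria) != 5L || any(diff(criteria) <= 0) || any(criteria < 0))
    stop_param("`criteria` must be 5 strictly increasing nonnegative thresholds")
  if (rt_sd < 0)
    stop_param("`rt_sd` must be >= 0")
  if (miss_rate < 0 || miss_rate > 0.05)
    stop_param("`miss_rate` must lie in [0, 0.05]")
  if (tau <= 0)
    stop_param("`tau` must be > 0")
  structure(list(sigma_p = sigma_p, lapse = lapse, sigma_m = sigma_m,
                 criteria = criteria, rt_intercept = rt_intercept,
                 rt_slope = rt_slope, rt_sd = rt_sd,
                 miss_rate = miss_rate, tau = tau),
            class = "observer_params")
}

#' Parameters of the experimental design
#'
#' Defaults mirror the study paradigm: a 200-trial calibration session over 10
#' square-difference levels, 32 main-task blocks of 12 trials (6 per task, no
#' more than 3 consecutive trials of the same task), a 200-trial
#' confidence-rating session at two difficulty levels targeting 70% and 85%
#' accuracy, 6 rating categories and a 1500-ms response deadline. Stimuli are
#' 400-cell grids: the reference box holds 200 squares, the comparison
#' 200 + delta.
#'
#' @param n_blocks Number of main-task blocks.
#' @param trials_per_block Trials per block (must equal `2 * trials_per_task`).
#' @param trials_per_task Trials of each task per block.
#' @param max_run Maximum allowed run of same-task trials within a block.
#' @param calib_levels Square-difference levels of the calibration session
#'   (positive integers).
#' @param n_calib_trials Calibration trials (divisible by the number of levels).
#' @param n_metacog_trials Metacognition-session trials (even).
#' @param target_accuracies Accuracy targets for difficulty extraction,
#'   strictly inside (0.5, 1).
#' @param n_rating_levels Number of confidence categories.
#' @param deadline_ms Response deadline in ms.
#' @param grid_cells,reference_squares Stimulus grid capacity and reference
#'   square count per box.
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_blocks = 32L, trials_per_block = 12L,
                          trials_per_task = 6L, max_run = 3L,
                          calib_levels = c(2, 5, 7, 9, 10, 12, 14, 18, 34, 70),
                          n_calib_trials = 200L, n_metacog_trials = 200L,
                          target_accuracies = c(0.70, 0.85),
                          n_rating_levels = 6L, deadline_ms = 1500,
                          grid_cells = 400L, reference_squares = 200L) {
  if (trials_per_block != 2L * trials_per_task)
    stop_param("`trials_per_block` must equal 2 * `trials_per_task`")
  if (any(target_accuracies <= 0.5) || any(target_accuracies >= 1))
    stop_param("`target_accuracies` must lie strictly within (0.5, 1)")
  if (any(calib_levels <= 0) || any(calib_levels != round(calib_levels)))
    stop_param("`calib_levels` must be positive integers")
  if (max_run < 1L)
    stop_param("`max_run` must be >= 1 (design unsatisfiable otherwise)")
  if (reference_squares + max(calib_levels) > grid_cells)
    stop_param("largest comparison count exceeds grid capacity")
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 trials_per_task = as.integer(trials_per_task),
                 max_run = as.integer(max_run),
                 calib_levels = as.integer(calib_levels),
                 n_calib_trials = as.integer(n_calib_trials),
                 n_metacog_trials = as.integer(n_metacog_trials),
                 target_accuracies = sort(target_accuracies),
                 n_rating_levels = as.integer(n_rating_levels),
                 deadline_ms = deadline_ms,
                 grid_cells = as.integer(grid_cells),
                 reference_squares = as.integer(reference_squares)),
            class = "design_params")
}

#' Numeric stimulus specification for a square difference
#'
#' @param delta Positive square difference.
#' @param design A [design_params()] object.
#' @return List with `reference`, `comparison` and `grid_cells` counts.
#' @export
stimulus_spec <- function(delta, design = design_params()) {
  if (any(delta <= 0)) stop_param("`delta` must be positive")
  comparison <- design$reference_squares + delta
  if (any(comparison > design$grid_cells))
    stop_param("comparison count exceeds grid capacity")
  list(reference = design$reference_squares, comparison = comparison,
       grid_cells = design$grid_cells)
}

#' Simulate perceptual decisions of the SDT observer
#'
#' Vectorized over trials. Uses the current R random number stream; call
#' `set.seed()` (or pass `seed` to the session generators) for
#' reproducibility.
#'
#' @param delta Vector of positive square differences.
#' @param side Vector of correct sides, `"left"` or `"right"`.
#' @param params An [observer_params()] object.
#' @param design A [design_params()] object (for the response deadline).
#' @return A data.frame with one row per trial: `delta`, `side`, `response`
#'   (`"left"`, `"right"` or `"none"`), `accuracy` (0/1), `rt_ms`, `rating`
#'   (1-6, NA when missed), and the generative internals `evidence` and
#'   `meta_evidence` (retained for ground-truth recovery only; never written
#'   to disk).
#' @export
simulate_trials <- function(delta, side, params = observer_params(),
                            design = design_params()) {
  if (any(delta <= 0)) stop_param("`delta` must be positive")
  if (!all(side %in% c("left", "right")))
    stop_param("`side` must be 'left' or 'right'")
  n <- length(delta)
  side <- rep_len(side, n)
  s <- ifelse(side == "right", 1, -1)
  e <- stats::rnorm(n, mean = s * delta / params$sigma_p, sd = 1)
  response <- ifelse(e > 0, "right", "left")
  lapsed <- stats::runif(n) < params$lapse
  if (any(lapsed))
    response[lapsed] <- sample(c("left", "right"), sum(lapsed), replace = TRUE)
  m <- abs(e) + stats::rnorm(n, 0, params$sigma_m)
  rating <- 1L + findInterval(m, params$criteria)
  log_rt <- params$rt_intercept - params$rt_slope * abs(e) +
    stats::rnorm(n, 0, params$rt_sd)
  rt_ms <- pmin(design$deadline_ms, pmax(200, exp(log_rt)))
  missed <- stats::runif(n) < params$miss_rate
  response[missed] <- "none"
  rt_ms[missed] <- NA_real_
  rating[missed] <- NA_integer_
  accuracy <- as.integer(response == side)
  data.frame(delta = delta, side = side, response = response,
             accuracy = accuracy, rt_ms = rt_ms, rating = rating,
             evidence = e, meta_evidence = m,
             stringsAsFactors = FALSE)
}

#' Pseudorandom within-block task sequence
#'
#' Draws a sequence of task labels with exactly `trials_per_task` trials of
#' each task and no run of the same task longer than `max_run`, by rejection
#' sampling of balanced shuffles (retry cap 10^4).
#'
#' @param design A [design_params()] object.
#' @return Character vector of length `trials_per_block` over `c("A", "B")`.
#' @export
generate_block_sequence <- function(design = design_params()) {
  labels <- rep(c("A", "B"), each = design$trials_per_task)
  for (i in seq_len(10000L)) {
    s <- sample(labels)
    if (max_run_length(s) <= design$max_run) return(s)
  }
  stop_param("could not generate a task sequence satisfying max_run = ",
             design$max_run, " within 10^4 attempts")
}

#' Simulate the calibration session
#'
#' 200 trials (by default) equally distributed across the design's
#' square-difference levels, sides balanced within level, trial order
#' randomized, no confidence ratings collected.
#'
#' @param params,design Observer and design parameters.
#' @param subject Subject identifier.
#' @param seed Optional integer seed.
#' @return Trial data.frame in the tidy schema (see [write_trials()]) plus
#'   generative internals.
#' @export
simulate_calibration_session <- function(params = observer_params(),
                                         design = design_params(),
                                         subject = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nlev <- length(design$calib_levels)
  if (design$n_calib_trials %% nlev != 0L)
    stop_param("`n_calib_trials` must be divisible by the number of levels")
  per <- design$n_calib_trials %/% nlev
  delta <- rep(design$calib_levels, each = per)
  side <- unlist(lapply(seq_len(nlev), function(i) balanced_sides(per)))
  ord <- sample(length(delta))
  tr <- simulate_trials(delta[ord], side[ord], params, design)
  data.frame(subject = subject, session = "calibration", block = 0L,
             trial = seq_len(nrow(tr)), task = NA_character_,
             tr[, c("delta", "side", "response", "accuracy", "rt_ms")],
             confidence = NA_integer_, chosen_task = NA_character_,
             rating = tr$rating, evidence = tr$evidence,
             meta_evidence = tr$meta_evidence,
             stringsAsFactors = FALSE)
}

#' Simulate the main (blocked, two-task) session
#'
#' Each block assigns the easy and difficult square-difference levels to the
#' two tasks at random, interleaves them pseudorandomly (max run constraint),
#' and ends with a task choice sampled as
#' `P(choose A) = logistic((mean_rating_A - mean_rating_B) / tau)` over the
#' block's simulated ratings-scale confidence. No confidence is reported
#' (`confidence` is NA); the latent `rating` column carries the ground truth.
#'
#' @param params,design Observer and design parameters.
#' @param easy_delta,hard_delta Square differences with
#'   `easy_delta > hard_delta > 0`.
#' @param subject Subject identifier.
#' @param seed Optional integer seed.
#' @return List with `trials` (tidy trial data.frame) and `blocks` (one row
#'   per block: `subject`, `block`, `easy_task`, `first_task`, `delta_A`,
#'   `delta_B`, `chosen_task`).
#' @export
simulate_main_session <- function(params = observer_params(),
                                  design = design_params(),
                                  easy_delta, hard_delta,
                                  subject = 1L, seed = NULL) {
  check_levels(easy_delta, hard_delta)
  if (!is.null(seed)) set.seed(seed)
  trial_list <- vector("list", design$n_blocks)
  block_list <- vector("list", design$n_blocks)
  for (b in seq_len(design$n_blocks)) {
    easy_task <- sample(c("A", "B"), 1L)
    task_seq <- generate_block_sequence(design)
    delta_b <- ifelse(task_seq == easy_task, easy_delta, hard_delta)
    side_b <- character(length(task_seq))
    for (tk in c("A", "B")) {
      idx <- which(task_seq == tk)
      side_b[idx] <- balanced_sides(length(idx))
    }
    tr <- simulate_trials(delta_b, side_b, params, design)
    mean_conf <- function(tk) {
      r <- tr$rating[task_seq == tk & tr$response != "none"]
      if (length(r) == 0L) NA_real_ else mean(r)
    }
    m_a <- mean_conf("A")
    m_b <- mean_conf("B")
    p_a <- if (is.na(m_a) || is.na(m_b)) 0.5 else
      stats::plogis((m_a - m_b) / params$tau)
    chosen <- if (stats::runif(1) < p_a) "A" else "B"
    trial_list[[b]] <- data.frame(
      subject = subject, session = "main", block = b,
      trial = seq_along(task_seq), task = task_seq,
      tr[, c("delta", "side", "response", "accuracy", "rt_ms")],
      confidence = NA_integer_, chosen_task = chosen,
      rating = tr$rating, evidence = tr$evidence,
      meta_evidence = tr$meta_evidence, stringsAsFactors = FALSE)
    block_list[[b]] <- data.frame(
      subject = subject, block = b, easy_task = easy_task,
      first_task = task_seq[1L],
      delta_A = if (easy_task == "A") easy_delta else hard_delta,
      delta_B = if (easy_task == "B") easy_delta else hard_delta,
      chosen_task = chosen, stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, trial_list),
       blocks = do.call(rbind, block_list))
}

#' Simulate the metacognition (confidence-rating) session
#'
#' Trials at the two extracted difficulty levels in equal proportion,
#' randomly interleaved, sides balanced within level; every responded trial
#' carries a 1-6 confidence rating.
#'
#' @inheritParams simulate_main_session
#' @return Tidy trial data.frame with the `confidence` column populated.
#' @export
simulate_metacog_session <- function(params = observer_params(),
                                     design = design_params(),
                                     easy_delta, hard_delta,
                                     subject = 1L, seed = NULL) {
  check_levels(easy_delta, hard_delta)
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_metacog_trials
  if (n %% 2L != 0L) stop_param("`n_metacog_trials` must be even")
  half <- n %/% 2L
  delta <- rep(c(easy_delta, hard_delta), each = half)
  side <- c(balanced_sides(half), balanced_sides(half))
  ord <- sample(n)
  tr <- simulate_trials(delta[ord], side[ord], params, design)
  data.frame(subject = subject, session = "metacog", block = 0L,
             trial = seq_len(n), task = NA_character_,
             tr[, c("delta", "side", "response", "accuracy", "rt_ms")],
             confidence = tr$rating, chosen_task = NA_character_,
             rating = tr$rating, evidence = tr$evidence,
             meta_evidence = tr$meta_evidence, stringsAsFactors = FALSE)
}

check_levels <- function(easy_delta, hard_delta) {
  if (!(easy_delta > hard_delta && hard_delta > 0))
    stop_param("need `easy_delta` > `hard_delta` > 0")
  invisible(TRUE)
}

#' Closed-form accuracy of the observer at a square difference
#'
#' `P(correct | delta) = lapse/2 + (1 - lapse) * Phi(delta / sigma_p)`;
#' the generative counterpart of the fitted psychometric function.
#'
#' @param delta Square difference(s).
#' @param params An [observer_params()] object.
#' @return Numeric vector of accuracies.
#' @export
observer_accuracy <- function(delta, params = observer_params()) {
  params$lapse / 2 + (1 - params$lapse) * stats::pnorm(delta / params$sigma_p)
}
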