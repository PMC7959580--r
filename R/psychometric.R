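## Calibration-phase psychometric fitting and inversion.
##
## Accuracy in the 2AFC square-difference task is modelled as
##   P(correct | delta) = lapse/2 + (1 - lapse) * Phi(delta / sigma_f),
## a cumulative normal through 0.5 at delta = 0 with guess rate fixed at 0.5.
## The lapse term is fixed to 0 by default and can be freed (bounded at 0.1)
## for robustness checks.

#' Fit the cumulative-normal psychometric function
#'
#' Maximizes the Bernoulli log-likelihood of trial accuracy over the
#' psychometric scale `sigma_f` (and optionally a lapse rate) with a
#' deterministic multistart over a `sigma_f` grid to avoid local optima.
#' All-correct (or at/below-chance) data yield a fit flagged non-identifiable
#' with `sigma_f` at a bound rather than an error.
#'
#' @param trials Data.frame with columns `delta` (positive) and `accuracy`
#'   (0/1); rows with `response == "none"` are dropped if present.
#' @param fix_lapse Fix the lapse rate to 0 (default) or estimate it in
#'   \[0, 0.1\].
#' @return An object of class `psychometric_fit`: `sigma_f`, `lapse_hat`,
#'   `log_likelihood`, `converged`, `identifiable`, `n_trials`.
#' @export
fit_psychometric <- function(trials, fix_lapse = TRUE) {
  if (!is.null(trials$response)) trials <- trials[trials$response != "none", ]
  if (length(unique(trials$delta)) < 2L)
    stop_param("need trials at >= 2 distinct `delta` levels")
  if (any(trials$delta <= 0)) stop_param("`delta` must be positive")
  ## aggregate to binomial counts per level (sufficient statistics)
  agg <- stats::aggregate(accuracy ~ delta, data = trials,
                          FUN = function(x) c(k = sum(x), n = length(x)))
  delta <- agg$delta
  k <- agg$accuracy[, "k"]
  n <- agg$accuracy[, "n"]

  loglik <- function(sigma, lapse) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm(delta / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(k * log(p) + (n - k) * log1p(-p))
  }
  lo <- log(1e-2)
  hi <- log(1e5)
  starts <- log(c(1, 2, 5, 10, 20, 40, 80, 200))
  best <- NULL
  for (s0 in starts) {
    fit <- if (fix_lapse) {
      stats::nlminb(s0, function(ls) -loglik(exp(ls), 0),
                    lower = lo, upper = hi)
    } else {
      stats::nlminb(c(s0, 0.02),
                    function(p) -loglik(exp(p[1]), p[2]),
                    lower = c(lo, 0), upper = c(hi, 0.1))
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  log_sigma <- best$par[1]
  lapse_hat <- if (fix_lapse) 0 else best$par[2]
  ## all-correct (or all-error) data leave sigma_f unconstrained up to a
  ## likelihood plateau against the bound
  at_bound <- log_sigma <= lo + 1e-6 || log_sigma >= hi - 1e-6 ||
    all(k == n) || all(k == 0)
  structure(list(sigma_f = exp(log_sigma), lapse_hat = lapse_hat,
                 log_likelihood = -best$objective,
                 converged = best$convergence == 0,
                 identifiable = !at_bound,
                 fix_lapse = fix_lapse,
                 n_trials = sum(n)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-normal psychometric fit (n = %d trials)\n  sigma_f = %.3f, lapse = %.4f, logLik = %.2f%s\n",
    x$n_trials, x$sigma_f, x$lapse_hat, x$log_likelihood,
    if (x$identifiable) "" else "  [non-identifiable: sigma_f at bound]"))
  invisible(x)
}

#' Invert the fitted psychometric at a target accuracy
#'
#' Closed form: `delta = sigma_f * qnorm((p - lapse/2) / (1 - lapse))`. The
#' unrounded level is returned alongside its rounding to the nearest positive
#' integer square difference (stimuli are discrete square counts).
#'
#' @param fit A [fit_psychometric()] object.
#' @param p_target Target accuracy, strictly between `lapse/2` and
#'   `1 - lapse/2`.
#' @return List with `delta` (unrounded) and `delta_int` (nearest positive
#'   integer).
#' @export
invert_psychometric <- function(fit, p_target) {
  lo <- fit$lapse_hat / 2
  if (p_target <= lo || p_target >= 1 - lo)
    stop_param("`p_target` outside the attainable range (", lo, ", ", 1 - lo, ")")
  delta <- fit$sigma_f * stats::qnorm((p_target - lo) / (1 - fit$lapse_hat))
  list(delta = delta, delta_int = max(1L, as.integer(round(delta))))
}

#' Extract easy/difficult stimulus levels from a calibration fit
#'
#' Inverts the fitted psychometric at the two target accuracies (defaults
#' 70% and 85%) and returns integer square differences for the main and
#' metacognition sessions; a rounding collision is resolved by incrementing
#' the easy level.
#'
#' @param fit A [fit_psychometric()] object.
#' @param targets Two target accuracies; the larger defines the easy level.
#' @return List with `easy_delta`, `hard_delta` (integers,
#'   `easy_delta > hard_delta >= 1`) and the unrounded `easy_raw`, `hard_raw`.
#' @export
extract_difficulty_levels <- function(fit, targets = c(0.70, 0.85)) {
  targets <- sort(targets)
  hard <- invert_psychometric(fit, targets[1])
  easy <- invert_psychometric(fit, targets[2])
  easy_int <- easy$delta_int
  hard_int <- hard$delta_int
  if (easy_int <= hard_int) easy_int <- hard_int + 1L
  list(easy_delta = easy_int, hard_delta = hard_int,
       easy_raw = easy$delta, hard_raw = hard$delta)
}
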