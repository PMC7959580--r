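## Ordinal regression of confidence on trial features, and its transfer to
## sessions without confidence reports.
##
## The model is a cumulative-link (proportional-odds) regression: a latent
## continuum eta = X beta cut by ordered thresholds zeta into the 6 rating
## categories, P(Y <= j | x) = F(zeta_j - eta) with F the logistic (default)
## or normal CDF. Fitted on the metacognition session, its coefficients are
## applied to the main session's (re-z-scored) features to produce a
## predicted trial-wise confidence on the 1-6 scale.

FEATURE_COLS <- c("difficulty", "accuracy", "log_rt", "diff_x_acc")

#' Build the z-scored feature table for the confidence model
#'
#' Difficulty (square difference), accuracy and log RT are z-scored within
#' the supplied trial set (one subject, one session); the interaction is the
#' product of the already-z-scored difficulty and accuracy columns. Constant
#' columns (e.g. accuracy in an all-correct subset) are dropped with a
#' warning, along with any interaction involving them.
#'
#' @param trials Post-exclusion trials of a single subject/session with
#'   `delta`, `accuracy`, `rt_ms`.
#' @return Data.frame with (a subset of) columns `difficulty`, `accuracy`,
#'   `log_rt`, `diff_x_acc`; attribute `dropped` lists removed columns.
#' @export
build_features <- function(trials) {
  if (nrow(trials) < 20L)
    stop_param("need >= 20 usable trials, got ", nrow(trials))
  if (any(trials$response == "none") || anyNA(trials$rt_ms))
    stop_param("trials must be filtered through exclude_trials() first")
  cols <- list(difficulty = zscore_or_null(trials$delta),
               accuracy = zscore_or_null(trials$accuracy),
               log_rt = zscore_or_null(log(trials$rt_ms)))
  dropped <- names(cols)[vapply(cols, is.null, TRUE)]
  cols <- cols[!vapply(cols, is.null, TRUE)]
  if (all(c("difficulty", "accuracy") %in% names(cols))) {
    cols$diff_x_acc <- cols$difficulty * cols$accuracy
  } else {
    dropped <- c(dropped, "diff_x_acc")
  }
  if (length(dropped))
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- as.data.frame(cols)
  attr(out, "dropped") <- dropped
  out
}

#' Fit the cumulative-link ordinal regression
#'
#' Maximum likelihood proportional-odds fit with cutpoint monotonicity
#' enforced by a positive-increment reparameterization and deterministic
#' initialization from the empirical cumulative logits (probits). Rating
#' categories unobserved in the data are collapsed (flagged via `collapsed`).
#' On non-convergence or runaway coefficients (complete separation) the fit
#' falls back to a small ridge penalty (1e-4) and is flagged
#' `converged = FALSE`.
#'
#' @param features Data.frame of numeric predictors (0 columns = intercept
#'   only), e.g. from [build_features()].
#' @param ratings Integer confidence ratings in 1..`n_levels`; at least two
#'   distinct values.
#' @param link `"logit"` (default) or `"probit"`.
#' @param n_levels Number of rating categories (default 6).
#' @return Object of class `ordinal_fit`: `cutpoints` (strictly increasing),
#'   `betas` (named), `deviance` (= -2 logLik), `n_trials`, `converged`,
#'   `collapsed`, `levels` (observed category values), `link`.
#' @export
fit_ordinal <- function(features, ratings, link = c("logit", "probit"),
                        n_levels = 6L) {
  link <- match.arg(link)
  cdf <- if (link == "logit") stats::plogis else stats::pnorm
  qf <- if (link == "logit") stats::qlogis else stats::qnorm
  x <- as.matrix(features)
  if (nrow(x) == 0L) x <- matrix(0, length(ratings), 0L)
  if (!all(ratings %in% seq_len(n_levels)) || anyNA(ratings))
    stop_param("ratings must lie in 1..", n_levels)
  if (nrow(x) != length(ratings))
    stop_param("features and ratings differ in length")
  obs <- sort(unique(ratings))
  j <- length(obs)
  if (j < 2L) stop_param("need >= 2 distinct rating values")
  y <- match(ratings, obs)
  n <- length(y)
  p_feat <- ncol(x)

  unpack <- function(par) {
    zeta <- if (j == 2L) par[1] else cumsum(c(par[1], exp(par[2:(j - 1L)])))
    beta <- if (p_feat) par[j:(j - 1L + p_feat)] else numeric(0)
    list(zeta = zeta, beta = beta)
  }
  nll <- function(par, ridge = 0) {
    u <- unpack(par)
    eta <- if (p_feat) drop(x %*% u$beta) else rep(0, n)
    upper <- c(u$zeta, Inf)[y]
    lower <- c(-Inf, u$zeta)[y]
    p <- cdf(upper - eta) - cdf(lower - eta)
    -sum(log(pmax(p, 1e-12))) + ridge * sum(u$beta^2)
  }

  cum <- cumsum(tabulate(y, j))[1:(j - 1L)] / n
  zeta0 <- qf(cum)
  par0 <- c(zeta0[1],
            if (j > 2L) log(pmax(diff(zeta0), 1e-3)),
            rep(0, p_feat))
  fit <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  u <- unpack(fit$par)
  separated <- p_feat > 0 && any(abs(u$beta) > 15)
  converged <- fit$convergence == 0 && !separated
  if (!converged) {
    fit <- stats::optim(par0, nll, ridge = 1e-4, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    u <- unpack(fit$par)
  }
  betas <- u$beta
  names(betas) <- colnames(x)
  structure(list(cutpoints = u$zeta, betas = betas,
                 deviance = 2 * nll(fit$par, ridge = 0),
                 n_trials = n, converged = converged,
                 collapsed = j < n_levels, levels = obs,
                 link = link, n_levels = as.integer(n_levels)),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Cumulative-%s ordinal fit (n = %d, deviance = %.2f)\n",
              x$link, x$n_trials, x$deviance))
  if (length(x$betas)) {
    cat("  betas: ",
        paste(sprintf("%s = %.3f", names(x$betas), x$betas), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Category probabilities under an ordinal fit
#' @param fit An [fit_ordinal()] object.
#' @param features Data.frame with exactly the fitted feature columns.
#' @return Matrix (n x length(fit$levels)) of rating probabilities.
#' @export
ordinal_probs <- function(fit, features) {
  x <- as.matrix(features)
  want <- names(fit$betas) %||% character(0)
  have <- colnames(x) %||% character(0)
  if (!identical(have, want))
    stop_param("feature set mismatch: fit uses (",
               paste(want, collapse = ", "), "), got (",
               paste(have, collapse = ", "), ")")
  cdf <- if (fit$link == "logit") stats::plogis else stats::pnorm
  n <- if (length(want) == 0L && nrow(x) == 0L) 1L else nrow(x)
  eta <- if (length(fit$betas)) drop(x %*% fit$betas) else rep(0, n)
  cum <- vapply(fit$cutpoints, function(z) cdf(z - eta), numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  cbind(cum, 1) - cbind(0, cum)
}

#' Predicted trial-wise confidence from a fitted ordinal model
#'
#' The transfer step: the expected rating
#' `sum_k k * P(rating = k | x)` under the fitted model, a continuous value
#' on the 1-6 scale, computed on (typically main-session) features z-scored
#' within the session being scored.
#'
#' @inheritParams ordinal_probs
#' @return Numeric vector in \[1, 6\].
#' @export
predict_confidence <- function(fit, features) {
  p <- ordinal_probs(fit, features)
  drop(p %*% fit$levels)
}

#' Default candidate regressor sets for the confidence-model comparison
#' @return Named list of character vectors over the feature columns.
#' @export
default_candidate_sets <- function() {
  list(acc = "accuracy",
       rt = "log_rt",
       diff = "difficulty",
       acc_rt = c("accuracy", "log_rt"),
       acc_diff = c("accuracy", "difficulty"),
       rt_diff = c("log_rt", "difficulty"),
       acc_rt_diff = c("accuracy", "log_rt", "difficulty"),
       full = c("accuracy", "log_rt", "difficulty", "diff_x_acc"))
}

#' Compare candidate confidence models by summed deviance
#'
#' Fits every candidate regressor set per subject on the metacognition
#' session and sums deviances across subjects; lower is better. Subjects
#' whose fit fails for a given set are skipped with a logged reason.
#'
#' @param trials Multi-subject post-exclusion metacognition trials with
#'   `subject`, `delta`, `accuracy`, `rt_ms`, `confidence`.
#' @param candidate_sets Named list of feature-column subsets; defaults to
#'   [default_candidate_sets()].
#' @param link Passed to [fit_ordinal()].
#' @return Data.frame (one row per candidate, ranked ascending by summed
#'   deviance) with `model`, `sum_deviance`, `n_subjects`, `rank`; attribute
#'   `per_subject` holds the subject x model deviance matrix, attribute
#'   `skipped` any skip reasons.
#' @export
compare_models <- function(trials, candidate_sets = default_candidate_sets(),
                           link = "logit") {
  subjects <- unique(trials$subject)
  dev <- matrix(NA_real_, length(subjects), length(candidate_sets),
                dimnames = list(as.character(subjects), names(candidate_sets)))
  skipped <- character(0)
  for (si in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[si], , drop = FALSE]
    feats <- tryCatch(suppressWarnings(build_features(tr)),
                      error = function(e) e)
    if (inherits(feats, "error")) {
      skipped <- c(skipped, sprintf("subject %s: %s", subjects[si],
                                    conditionMessage(feats)))
      next
    }
    ratings <- tr$confidence %||% tr$rating
    for (mi in seq_along(candidate_sets)) {
      want <- intersect(candidate_sets[[mi]], colnames(feats))
      f <- tryCatch(
        fit_ordinal(feats[, want, drop = FALSE], ratings, link = link),
        error = function(e) e)
      if (inherits(f, "error")) {
        skipped <- c(skipped, sprintf("subject %s, model %s: %s",
                                      subjects[si], names(candidate_sets)[mi],
                                      conditionMessage(f)))
      } else {
        dev[si, mi] <- f$deviance
      }
    }
  }
  sums <- colSums(dev, na.rm = TRUE)
  n_sub <- colSums(!is.na(dev))
  out <- data.frame(model = names(candidate_sets), sum_deviance = sums,
                    n_subjects = n_sub, row.names = NULL)
  out$rank <- rank(out$sum_deviance, ties.method = "min")
  out <- out[order(out$rank), ]
  attr(out, "per_subject") <- dev
  attr(out, "skipped") <- skipped
  out
}

#' Group-level one-sample t tests on ordinal coefficients
#'
#' @param fits List of [fit_ordinal()] objects, one per subject, sharing a
#'   feature set.
#' @return Data.frame with `coef`, `mean`, `t`, `df`, `p`.
#' @export
group_coefficient_tests <- function(fits) {
  if (length(fits) < 3L) stop_param("need >= 3 subjects")
  coefs <- unique(unlist(lapply(fits, function(f) names(f$betas))))
  rows <- lapply(coefs, function(cn) {
    b <- vapply(fits, function(f)
      if (cn %in% names(f$betas)) f$betas[[cn]] else NA_real_, 0)
    b <- b[!is.na(b)]
    if (stats::sd(b) == 0) {
      t <- if (mean(b) == 0) 0 else Inf * sign(mean(b))
      p <- if (t == 0) 1 else 0
      data.frame(coef = cn, mean = mean(b), t = t, df = length(b) - 1L, p = p)
    } else {
      tt <- stats::t.test(b)
      data.frame(coef = cn, mean = mean(b), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  do.call(rbind, rows)
}
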