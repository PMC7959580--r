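# Shared fixtures and independent oracles for the suite.

# Noise-free-metacognition observer (confidence uses the decision evidence
# itself), used wherever an SDT-ideal rater is required.
ideal_observer <- function(sigma_p = 10, ...) {
  observer_params(sigma_p = sigma_p, sigma_m = 0, lapse = 0, miss_rate = 0,
                  ...)
}

# Single-difficulty confidence-rating trials at a fixed square difference.
rate_trials <- function(n, delta, params, seed) {
  set.seed(seed)
  side <- balanced_sides_test(n)
  tr <- simulate_trials(rep(delta, n), side, params)
  tr$confidence <- tr$rating
  tr
}

balanced_sides_test <- function(n) {
  sample(rep(c("left", "right"), length.out = n))
}

# Independent fixed-grid quadrature oracle for the JZS Bayes factor
# (log-spaced trapezoid over g; no reuse of the package's integrate() path).
jzs_bf_quadrature <- function(t_stat, n, rscale = sqrt(2) / 2,
                              n_grid = 20001L) {
  nu <- n - 1
  g <- exp(seq(log(1e-8), log(1e6), length.out = n_grid))
  log_null <- -(nu + 1) / 2 * log1p(t_stat^2 / nu)
  log_f <- -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t_stat^2 / ((1 + n * g) * nu)) +
    log(rscale) - 0.5 * log(2 * pi) - 1.5 * log(g) - rscale^2 / (2 * g) -
    log_null
  f <- exp(log_f)
  sum(diff(g) * (head(f, -1) + tail(f, -1)) / 2)
}

# Brute-force ordinal deviance: -2 sum log P(rating_i | x_i) evaluated
# directly from the fitted cutpoints/betas, independent of the fit's own
# bookkeeping.
ordinal_deviance_brute <- function(fit, features, ratings) {
  cdf <- if (fit$link == "logit") plogis else pnorm
  x <- as.matrix(features)
  eta <- if (length(fit$betas)) drop(x %*% fit$betas) else rep(0, nrow(x))
  j <- match(ratings, fit$levels)
  zu <- c(fit$cutpoints, Inf)[j]
  zl <- c(-Inf, fit$cutpoints)[j]
  -2 * sum(log(cdf(zu - eta) - cdf(zl - eta)))
}

# Draw ratings from a known proportional-odds model.
draw_proportional_odds <- function(x, beta, zeta) {
  eta <- drop(as.matrix(x) %*% beta)
  cum <- vapply(zeta, function(z) plogis(z - eta), numeric(length(eta)))
  rowSums(runif(length(eta)) > cum) + 1
}

# Directly constructed block-summary table for the choice regressions.
# Per-block first-minus-second differences are supplied; the end-of-block
# choice of the first-cued task is drawn by a logistic rule on `lp`.
make_block_summaries <- function(subject, lp, delta_diff, acc_diff,
                                 conf_diff = 0, logrt_diff = 0) {
  n_blocks <- length(lp)
  first_task <- sample(c("A", "B"), n_blocks, replace = TRUE)
  chose_first <- runif(n_blocks) < plogis(lp)
  sgn <- ifelse(first_task == "A", 1, -1)  # maps first/second to A/B
  chosen_task <- ifelse(chose_first, first_task,
                        ifelse(first_task == "A", "B", "A"))
  delta_A <- 12 + sgn * delta_diff / 2
  delta_B <- 12 - sgn * delta_diff / 2
  acc_A <- pmin(1, pmax(0, 0.75 + sgn * acc_diff / 2))
  acc_B <- pmin(1, pmax(0, 0.75 - sgn * acc_diff / 2))
  easy_task <- ifelse(delta_A >= delta_B, "A", "B")
  acc_easy <- ifelse(easy_task == "A", acc_A, acc_B)
  acc_hard <- ifelse(easy_task == "A", acc_B, acc_A)
  data.frame(subject = subject, block = seq_len(n_blocks),
             easy_task = easy_task, first_task = first_task,
             chosen_task = chosen_task,
             delta_A = delta_A, delta_B = delta_B,
             acc_A = acc_A, acc_B = acc_B,
             logrt_A = 6.7 + sgn * logrt_diff / 2,
             logrt_B = 6.7 - sgn * logrt_diff / 2,
             conf_A = 3.5 + sgn * conf_diff / 2,
             conf_B = 3.5 - sgn * conf_diff / 2,
             n_A = 6L, n_B = 6L,
             acc_diff = acc_easy - acc_hard,
             perf_class = ifelse(acc_easy > acc_hard, "positive",
                                 ifelse(acc_easy < acc_hard, "negative",
                                        "null")),
             easy_chosen = chosen_task == easy_task,
             chose_first = chose_first,
             stringsAsFactors = FALSE)
}
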