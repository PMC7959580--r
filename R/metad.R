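## Maximum likelihood meta-d'.
##
## The type-2 model: a Gaussian SDT observer with sensitivity meta-d' (class
## means at +/- meta-d'/2, unit variance) whose type-1 criterion is pinned at
## the empirically scaled position c' = c * meta-d'/d', and 2(K-1) free
## type-2 criteria (K-1 below c' for "left" responses, K-1 above for
## "right"), monotone by construction via a positive-increment
## reparameterization. The fit maximizes the multinomial log-likelihood of
## the response-conditional rating counts; meta-d'/d' (the M-ratio) is 1 for
## an observer whose confidence uses the same evidence as the decision.

#' Fit meta-d' by maximum likelihood
#'
#' @param counts A [tabulate_ratings()] object (padded counts are used).
#' @return Object of class `metad_fit`: `d_prime`, `criterion` (type-1, from
#'   [type1_sdt()]), `meta_d`, `m_ratio`, `t2_criteria_s1`/`t2_criteria_s2`
#'   (ordered, on the meta evidence axis), `log_likelihood`, `converged`.
#' @export
fit_metad <- function(counts) {
  k <- counts$k
  t1 <- type1_sdt(counts)
  d1 <- t1$d_prime
  c1 <- t1$criterion

  nll <- function(par) -metad_loglik(par, counts, d1, c1)

  ## deterministic multistart over meta-d'; criteria start at 0.5 spacings
  inc0 <- rep(log(0.5), k - 1L)
  starts <- lapply(c(0.5, 1, 1.5), function(f)
    c(f * d1, inc0, inc0))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop_param("meta-d' optimization failed from every start")
  meta_d <- best$par[1]
  cr <- metad_criteria(best$par, k, c1, d1)
  structure(list(d_prime = d1, criterion = c1, meta_d = meta_d,
                 m_ratio = meta_d / d1,
                 t2_criteria_s1 = cr$s1, t2_criteria_s2 = cr$s2,
                 log_likelihood = -best$value,
                 converged = best$convergence == 0),
            class = "metad_fit")
}

#' @export
print.metad_fit <- function(x, ...) {
  cat(sprintf(
    "meta-d' fit: d' = %.3f, c = %.3f, meta-d' = %.3f, M-ratio = %.3f\n",
    x$d_prime, x$criterion, x$meta_d, x$m_ratio))
  invisible(x)
}

## Criteria on the meta evidence axis for a parameter vector
## par = (meta_d, log-increments below c', log-increments above c')
metad_criteria <- function(par, k, c1, d1) {
  meta_d <- par[1]
  c_prime <- c1 * meta_d / d1
  below <- c_prime - rev(cumsum(exp(par[2:k])))
  above <- c_prime + cumsum(exp(par[(k + 1L):(2L * k - 1L)]))
  list(c_prime = c_prime, s1 = below, s2 = above)
}

#' Response-conditional rating log-likelihood of a meta-d' model
#'
#' Exposed for the grid-search cross-checks: evaluates the multinomial
#' log-likelihood maximized by [fit_metad()] at an arbitrary parameter
#' vector.
#'
#' @param par Parameter vector `(meta_d, log-increments S1 side,
#'   log-increments S2 side)` of length `2K - 1`.
#' @param counts A [tabulate_ratings()] object.
#' @param d1,c1 Type-1 sensitivity and criterion pinning the scaled type-1
#'   criterion.
#' @return The log-likelihood (a scalar, <= 0 up to the padding).
#' @export
metad_loglik <- function(par, counts, d1, c1) {
  k <- counts$k
  meta_d <- par[1]
  cr <- metad_criteria(par, k, c1, d1)
  bounds <- c(-Inf, cr$s1, cr$c_prime, cr$s2, Inf)  # 2K+1 ascending bounds
  ll <- 0
  for (stim in 1:2) {
    mu <- if (stim == 1) -meta_d / 2 else meta_d / 2
    cdf <- stats::pnorm(bounds - mu)
    cell <- diff(cdf)                       # 2K interval masses
    p_left <- cdf[k + 1L]                   # P(x < c' | stim)
    denom <- c(rep(p_left, k), rep(1 - p_left, k))
    p <- pmax(cell / pmax(denom, 1e-12), 1e-12)
    n <- if (stim == 1) counts$padded_s1 else counts$padded_s2
    ll <- ll + sum(n * log(p))
  }
  ll
}
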