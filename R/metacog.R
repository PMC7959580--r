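## Type-1 / type-2 signal detection metrics on confidence-rating data.
##
## Conventions: stimulus class S1 = "left", S2 = "right"; hit rate is
## P(respond right | right), false-alarm rate P(respond right | left).
## Rating counts follow the standard meta-d' layout: for each stimulus class
## a vector of length 2K runs from high-confidence S1 responses down to
## confidence 1, then confidence 1 up to high-confidence S2 responses.

#' Tabulate (response, rating) counts per stimulus class
#'
#' Builds the 2K-cell response-conditional rating counts for each stimulus
#' class and adds the standard zero-count remedy of 1/(2K) to every cell for
#' downstream SDT computations; raw counts are preserved alongside.
#'
#' @param trials Data.frame with `side`, `response` and a rating column
#'   (`confidence`, falling back to `rating`). Rows with `response == "none"`
#'   are dropped; responded rows with a missing rating are an error.
#' @param n_rating_levels Number of confidence categories K (default 6).
#' @return List of class `rating_counts`: `raw_s1`, `raw_s2`, `padded_s1`,
#'   `padded_s2` (each length 2K), `k`, `n_s1`, `n_s2`.
#' @export
tabulate_ratings <- function(trials, n_rating_levels = 6L) {
  k <- as.integer(n_rating_levels)
  rating <- trials$confidence %||% trials$rating
  if (is.null(rating)) stop_param("no `confidence` (or `rating`) column")
  keep <- trials$response != "none"
  trials <- trials[keep, , drop = FALSE]
  rating <- rating[keep]
  if (anyNA(rating))
    stop_param("missing ratings on responded trials (rows ",
               paste(utils::head(which(is.na(rating)), 10L), collapse = ", "), ")")
  if (!all(rating %in% seq_len(k)))
    stop_param("ratings must lie in 1..", k)
  for (cls in c("left", "right"))
    if (!any(trials$side == cls))
      stop_param("no trials with stimulus class `", cls, "`")

  cell_counts <- function(stim) {
    sel <- trials$side == stim
    out <- numeric(2L * k)
    for (r in seq_len(k)) {
      ## cells 1..K: "left" responses, confidence K..1; K+1..2K: "right", 1..K
      out[k - r + 1L] <- sum(sel & trials$response == "left" & rating == r)
      out[k + r] <- sum(sel & trials$response == "right" & rating == r)
    }
    out
  }
  raw_s1 <- cell_counts("left")
  raw_s2 <- cell_counts("right")
  pad <- 1 / (2 * k)
  structure(list(raw_s1 = raw_s1, raw_s2 = raw_s2,
                 padded_s1 = raw_s1 + pad, padded_s2 = raw_s2 + pad,
                 k = k, n_s1 = sum(raw_s1), n_s2 = sum(raw_s2)),
            class = "rating_counts")
}

#' Type-1 sensitivity and criterion
#'
#' Collapses the padded rating counts over confidence and returns
#' `d' = z(HR) - z(FAR)` and `c = -0.5 * (z(HR) + z(FAR))`.
#'
#' @param counts A [tabulate_ratings()] object.
#' @return List with `d_prime` and `criterion`.
#' @export
type1_sdt <- function(counts) {
  k <- counts$k
  hr <- sum(counts$padded_s2[(k + 1L):(2L * k)]) / sum(counts$padded_s2)
  far <- sum(counts$padded_s1[(k + 1L):(2L * k)]) / sum(counts$padded_s1)
  list(d_prime = stats::qnorm(hr) - stats::qnorm(far),
       criterion = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)))
}

#' Type-2 ROC area (AUROC2)
#'
#' Model-free metacognitive sensitivity: sweeps the K-1 confidence thresholds
#' over the cumulative rating distributions conditional on correct (type-2
#' hits) versus incorrect (type-2 false alarms) responses, closes the curve
#' at (0,0) and (1,1), and integrates by the trapezoid rule. Ties are handled
#' by the cumulative distributions themselves; no random tie-breaking.
#'
#' @param accuracy 0/1 vector.
#' @param rating Confidence ratings in 1..K.
#' @param n_rating_levels K (default 6).
#' @return List of class `auroc2`: `area` (NA with `defined = FALSE` when
#'   either outcome class is empty), `tpr`, `fpr`.
#' @export
auroc2 <- function(accuracy, rating, n_rating_levels = 6L) {
  k <- as.integer(n_rating_levels)
  ok <- !is.na(accuracy) & !is.na(rating)
  accuracy <- accuracy[ok]
  rating <- rating[ok]
  n_c <- sum(accuracy == 1)
  n_e <- sum(accuracy == 0)
  if (n_c == 0L || n_e == 0L)
    return(structure(list(area = NA_real_, tpr = NA, fpr = NA,
                          defined = FALSE), class = "auroc2"))
  ## P(rating >= t | correct/incorrect) for thresholds t = K..2, ascending ROC
  tpr <- vapply(k:2, function(t) mean(rating[accuracy == 1] >= t), 0)
  fpr <- vapply(k:2, function(t) mean(rating[accuracy == 0] >= t), 0)
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(area = area, tpr = tpr, fpr = fpr, defined = TRUE),
            class = "auroc2")
}

#' Metacognitive metrics per difficulty condition
#'
#' Computes the M-ratio (via [fit_metad()]) and AUROC2 separately at each of
#' the two difficulty levels present in the trials (the larger square
#' difference is the easy condition), then averages the two conditions
#' arithmetically, as SDT assumes constant stimulus strength within a fit.
#'
#' @param trials Metacognition-session trials (post-exclusion) with `delta`,
#'   `side`, `response`, `accuracy` and `confidence`.
#' @param n_rating_levels K (default 6).
#' @return List with per-condition fits (`easy`, `hard`), `m_ratio_avg` and
#'   `auroc2_avg` (NA if undefined in either condition).
#' @export
per_condition_metrics <- function(trials, n_rating_levels = 6L) {
  lev <- sort(unique(trials$delta), decreasing = TRUE)
  if (length(lev) != 2L)
    stop_param("expected exactly 2 difficulty levels, found ", length(lev))
  one <- function(d) {
    tr <- trials[trials$delta == d, , drop = FALSE]
    fit <- fit_metad(tabulate_ratings(tr, n_rating_levels))
    resp <- tr[tr$response != "none", , drop = FALSE]
    roc <- auroc2(resp$accuracy, resp$confidence %||% resp$rating,
                  n_rating_levels)
    list(metad = fit, auroc2 = roc)
  }
  easy <- one(lev[1])
  hard <- one(lev[2])
  list(easy = easy, hard = hard,
       m_ratio_avg = mean(c(easy$metad$m_ratio, hard$metad$m_ratio)),
       auroc2_avg = mean(c(easy$auroc2$area, hard$auroc2$area)))
}

#' Two-way ANOVA of confidence on Accuracy and Difficulty
#'
#' Regression-formulated 2 x 2 ANOVA with interaction on trial-level
#' confidence; unbalanced cells are handled by Type-II nested-model F tests
#' (each main effect adjusted for the other; the interaction adjusted for
#' both).
#'
#' @param trials Data.frame with `confidence` (or `rating`), `accuracy`
#'   (0/1) and `delta` at exactly two levels.
#' @return Data.frame with rows Accuracy, Difficulty, Interaction and columns
#'   `F`, `df1`, `df2`, `p`.
#' @export
anova_2x2 <- function(trials) {
  conf <- trials$confidence %||% trials$rating
  keep <- !is.na(conf) & trials$response != "none"
  conf <- conf[keep]
  acc <- factor(trials$accuracy[keep], levels = c(0, 1))
  lev <- sort(unique(trials$delta[keep]))
  if (length(lev) != 2L) stop_param("expected exactly 2 difficulty levels")
  diffic <- factor(ifelse(trials$delta[keep] == lev[2], "easy", "hard"))
  tab <- table(acc, diffic)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop_param("empty design cell: accuracy=", rownames(tab)[empty[1]],
               ", difficulty=", colnames(tab)[empty[2]])
  }
  d <- data.frame(conf = conf, acc = acc, diffic = diffic)
  if (sum((conf - mean(conf))^2) < 1e-10)
    return(data.frame(effect = c("Accuracy", "Difficulty", "Interaction"),
                      F = 0, df1 = 1L, df2 = length(conf) - 4L, p = 1))
  rss <- function(f) sum(stats::resid(stats::lm(f, data = d))^2)
  rss_full <- rss(conf ~ acc * diffic)
  rss_add <- rss(conf ~ acc + diffic)
  rss_a <- rss(conf ~ diffic)   # without accuracy
  rss_d <- rss(conf ~ acc)      # without difficulty
  df2 <- nrow(d) - 4L
  ## Type-II reductions, all referenced to the full-model residual variance
  f <- c((rss_a - rss_add) / (rss_full / df2),
         (rss_d - rss_add) / (rss_full / df2),
         (rss_add - rss_full) / (rss_full / df2))
  f[!is.finite(f)] <- 0
  f <- pmax(f, 0)
  data.frame(effect = c("Accuracy", "Difficulty", "Interaction"),
             F = f, df1 = 1L, df2 = df2,
             p = stats::pf(f, 1, df2, lower.tail = FALSE),
             row.names = NULL)
}
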