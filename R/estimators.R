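# Bayesian 2-D-histogram estimation of the useful anomalous correlation and
# of the substructure atomic displacement factor, plus binned empirical
# estimators for the probability of substructure solution and expected map
# quality.

#' Train a Bayesian histogram estimator
#'
#' Bins a training set of (predictor, target) pairs over a target grid and
#' stores, per target bin, the mean and variance of the predictor (a
#' Gaussian conditional model), along with the marginal target distribution
#' of the training set as the training prior. Sparse target bins are
#' smoothed with a triangular kernel over three bins, and the conditional
#' standard deviation is floored at one predictor-bin width so likelihoods
#' never become singular.
#'
#' @param table Data frame whose last column is the target and whose other
#'   columns are predictors (or supply `predictors`/`target` names).
#' @param target_bins Number of target bins (default 50) or an explicit
#'   vector of bin edges.
#' @param predictor_bins Number of predictor bins used for the variance
#'   floor (default 50).
#' @param target_range Range of the target grid; defaults to the data range
#'   padded by one bin.
#' @return Object of class `anomsig_bayes`: per-predictor conditional
#'   tables, target-bin centers, and the training prior.
#' @export
train_bayes_estimator <- function(table, target_bins = 50, predictor_bins = 50,
                                  target_range = NULL) {
  table <- as.data.frame(table)
  if (!nrow(table)) abort("empty training table")
  if (ncol(table) < 2) abort("training table needs at least one predictor and a target")
  target <- table[[ncol(table)]]
  preds <- table[, -ncol(table), drop = FALSE]
  if (any(!is.finite(target))) abort("training targets must be finite")
  if (length(target_bins) == 1) {
    rng <- target_range %||% range(target)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = target_bins + 1)
  } else edges <- target_bins
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  bin <- findInterval(target, edges, rightmost.closed = TRUE, all.inside = TRUE)

  tri_smooth <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      idx <- max(1, i - 1):min(n, i + 1)
      wts <- c(0.5, 1, 0.5)[idx - i + 2]
      ok <- !is.na(v[idx])
      out[i] <- if (any(ok)) sum(wts[ok] * v[idx][ok]) / sum(wts[ok]) else NA
    }
    out
  }

  cond <- lapply(preds, function(p) {
    ok <- is.finite(p)
    mu <- tapply(p[ok], factor(bin[ok], levels = seq_along(centers)), mean)
    va <- tapply(p[ok], factor(bin[ok], levels = seq_along(centers)), var)
    nn <- tapply(rep(1, sum(ok)), factor(bin[ok], levels = seq_along(centers)), sum)
    nn[is.na(nn)] <- 0
    mu_s <- tri_smooth(as.numeric(mu))
    va_s <- tri_smooth(as.numeric(va))
    # fill remaining gaps from the nearest populated bin
    if (anyNA(mu_s)) {
      okb <- which(!is.na(mu_s))
      if (!length(okb)) abort("predictor has no finite training values")
      for (i in which(is.na(mu_s))) {
        j <- okb[which.min(abs(okb - i))]
        mu_s[i] <- mu_s[j]; va_s[i] <- va_s[j]
      }
    }
    pw <- diff(range(p[ok])) / predictor_bins
    sd_floor <- max(pw, 1e-9)
    sd_s <- sqrt(pmax(va_s, 0, na.rm = FALSE))
    sd_s[is.na(sd_s)] <- sd_floor
    sd_s <- pmax(sd_s, sd_floor)
    list(mean = mu_s, sd = sd_s, n = as.numeric(nn))
  })

  prior_counts <- tabulate(bin, nbins = length(centers))
  prior <- tri_smooth(prior_counts + 0.5)
  prior <- prior / sum(prior)
  structure(list(centers = centers, edges = edges, conditionals = cond,
                 prior = prior, n_train = nrow(table),
                 predictor_names = names(preds)),
            class = "anomsig_bayes")
}

#' @export
print.anomsig_bayes <- function(x, ...) {
  cat(sprintf("Bayesian histogram estimator: predictors [%s], %d target bins on [%.3g, %.3g], %d training rows\n",
              paste(x$predictor_names, collapse = ", "), length(x$centers),
              min(x$edges), max(x$edges), x$n_train))
  invisible(x)
}

#' Posterior for the target given observed predictors
#'
#' `P(target | obs) propto prior(target) * prod_k P(obs_k | target)`,
#' assuming independent predictors with the stored Gaussian conditionals.
#' `prior_mode = "training"` (the default) uses the marginal target
#' distribution of the training set; `"flat"` uses a uniform prior.
#' Observations outside the trained support use the nearest bin's
#' conditional, with a warning.
#'
#' @param estimator An `anomsig_bayes` object.
#' @param observations Named list/vector of observed predictor values
#'   (`NA` entries are ignored).
#' @param prior_mode `"training"` or `"flat"`.
#' @return Object of class `anomsig_posterior`: tibble of target-bin
#'   centers and probabilities plus `mean`, `sd`, and a central 90%
#'   interval.
#' @export
bayes_posterior <- function(estimator, observations, prior_mode = c("training", "flat")) {
  prior_mode <- match.arg(prior_mode)
  centers <- estimator$centers
  logp <- log(if (prior_mode == "training") estimator$prior
              else rep(1 / length(centers), length(centers)))
  obs_used <- 0L
  for (nm in names(observations)) {
    v <- observations[[nm]]
    if (is.null(v) || is.na(v)) next
    cond <- estimator$conditionals[[nm]]
    if (is.null(cond)) abort(sprintf("estimator has no predictor named '%s'", nm))
    rng <- range(cond$mean + 3 * cond$sd, cond$mean - 3 * cond$sd)
    if (v < rng[1] || v > rng[2]) {
      warn(sprintf("observation %s = %.4g lies outside the trained support; nearest-bin likelihood used", nm, v))
    }
    logp <- logp + dnorm(v, cond$mean, cond$sd, log = TRUE)
    obs_used <- obs_used + 1L
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  mu <- sum(p * centers)
  sdv <- sqrt(max(sum(p * centers^2) - mu^2, 0))
  cdf <- cumsum(p)
  interval <- c(lower = centers[which(cdf >= 0.05)[1]],
                upper = centers[which(cdf >= 0.95)[1]])
  structure(list(grid = tibble(target = centers, prob = p),
                 mean = mu, sd = sdv, interval = interval,
                 n_predictors = obs_used, prior_mode = prior_mode),
            class = "anomsig_posterior")
}

#' @export
print.anomsig_posterior <- function(x, ...) {
  cat(sprintf("Posterior (%s prior, %d predictor(s)): mean %.4g, sd %.3g, 90%% interval [%.3g, %.3g]\n",
              x$prior_mode, x$n_predictors, x$mean, x$sd,
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' @export
tidy.anomsig_posterior <- function(x, ...) x$grid

#' @export
glance.anomsig_posterior <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, lower = x$interval[1], upper = x$interval[2],
         n_predictors = x$n_predictors, prior_mode = x$prior_mode)
}

#' Estimate the useful anomalous correlation from quality metrics
#'
#' Combines whichever of the three data-quality metrics are available -
#' the estimated squared anomalous correlation `E2`, the Patterson skew `s`
#' and the normalized error `e` - in a Bayesian posterior over CC_ano.
#' `E2` may be absent (e.g. when only merged data exist and no half-set
#' correlation can be formed).
#'
#' @param metrics An `anomsig_metrics` object, or a named list with any of
#'   `e2`, `skew`, `e`.
#' @param estimator A trained `anomsig_bayes` with predictors named `e2`,
#'   `skew`, `e` (see [train_cc_ano_estimator()]).
#' @param prior_mode Passed to [bayes_posterior()].
#' @return An `anomsig_posterior` over CC_ano.
#' @export
estimate_cc_ano <- function(metrics, estimator, prior_mode = "training") {
  obs <- list(e2 = metrics$e2 %||% NA_real_,
              skew = metrics$skew %||% NA_real_,
              e = metrics$e %||% NA_real_)
  if (all(is.na(unlist(obs)))) abort("at least one quality metric is required")
  bayes_posterior(estimator, obs, prior_mode)
}

#' Train the CC_ano estimator on a synthetic corpus
#'
#' Runs the scaling/merging pipeline and quality metrics over a
#' [graded_corpus()] and trains the Bayesian estimator on
#' (E2, skew, e) versus the true useful anomalous correlation. This stands
#' in, at desk scale, for training on a large archive of solved structures.
#'
#' @param corpus From [graded_corpus()]; generated with the default seed
#'   when omitted.
#' @param target_bins Bins over CC_ano in `[0, 1]` (default 50).
#' @param ... Passed to [scale_and_merge()].
#' @return List with `estimator` (class `anomsig_bayes`) and `table`, the
#'   training tibble (columns `e2`, `skew`, `e`, `cc_ano`).
#' @export
train_cc_ano_estimator <- function(corpus = NULL, target_bins = 50, ...) {
  if (is.null(corpus)) corpus <- graded_corpus(seed = 20331)
  rows <- lapply(corpus, function(member) {
    sm <- scale_and_merge(member$datasets, ...)
    qm <- quality_metrics(sm, unmerged = member$datasets, ...)
    truth <- member$truth
    cc <- useful_anomalous_correlation(
      sm$merged, truth$reflections[, c("h", "k", "l", "dano_ideal")])
    tibble(e2 = qm$e2, skew = qm$skew, e = qm$e, cc_ano = cc)
  })
  tab <- bind_rows(rows)
  est <- train_bayes_estimator(tab, target_bins = target_bins,
                               target_range = c(0, 1))
  list(estimator = est, table = tab)
}

#' Estimate the substructure displacement factor from the Wilson B
#'
#' Posterior over the mean atomic displacement factor of the anomalous
#' substructure given the overall Wilson B value of the data. The packaged
#' default training table is synthetic (seeded, versioned): it encodes a
#' substructure B about 40% larger than the Wilson B on average, with
#' realistic scatter.
#'
#' @param wilson_b Wilson B of the data set (angstrom^2, > 0).
#' @param estimator Optional trained `anomsig_bayes`; the packaged default
#'   is used when omitted.
#' @param prior_mode Passed to [bayes_posterior()].
#' @return An `anomsig_posterior` over the substructure B.
#' @export
estimate_substructure_b <- function(wilson_b, estimator = NULL,
                                    prior_mode = "training") {
  stopifnot(wilson_b > 0)
  if (is.null(estimator)) estimator <- default_b_estimator()
  bayes_posterior(estimator, list(wilson_b = wilson_b), prior_mode)
}

#' Packaged synthetic training table linking Wilson B to substructure B
#'
#' @param n Rows (default 600).
#' @param seed Seed (fixed default so the packaged estimator is versioned).
#' @param slope Mean ratio of substructure B to Wilson B (default 1.4).
#' @return Tibble with `wilson_b` and `b_sub`.
#' @export
synthetic_b_table <- function(n = 600, seed = 48121, slope = 1.4) {
  set.seed(seed)
  wb <- exp(runif(n, log(8), log(150)))
  bs <- slope * wb * exp(rnorm(n, -0.015, 0.18))  # mean multiplier = slope
  tibble(wilson_b = wb, b_sub = bs)
}

default_b_estimator <- function() {
  if (is.null(.anomsig_env$b_estimator)) {
    edges <- exp(seq(log(5), log(200), length.out = 41))  # log-spaced B grid
    .anomsig_env$b_estimator <-
      train_bayes_estimator(synthetic_b_table(), target_bins = edges)
  }
  .anomsig_env$b_estimator
}

#' Binned empirical estimator (success fraction or mean outcome)
#'
#' Groups a training table into bins of the input statistic and stores the
#' per-bin mean outcome (for 0/1 outcomes, the success fraction). Sparse
#' bins (< `min_per_bin`) are smoothed with a triangular kernel over three
#' bins; empty bins fall back to the nearest populated bin.
#'
#' @param x Input statistic values of the training set.
#' @param outcome Numeric outcome (0/1 for solved/not-solved labels).
#' @param n_bins Number of bins over the range of `x` (default 12).
#' @param min_per_bin Counts below which smoothing applies.
#' @return Object of class `anomsig_binned` with `edges`, `value` and
#'   `count` per bin.
#' @export
binned_estimator <- function(x, outcome, n_bins = 12, min_per_bin = 5) {
  stopifnot(length(x) == length(outcome), length(x) > 0)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  if (diff(range(x)) == 0) edges <- x[1] + seq(-0.5, 0.5, length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  agg <- tapply(outcome, factor(bin, levels = seq_len(n_bins)), mean)
  val <- as.numeric(agg)
  sparse <- cnt < min_per_bin
  if (any(sparse)) {
    sm <- val
    for (i in which(sparse)) {
      idx <- max(1, i - 1):min(n_bins, i + 1)
      wts <- c(0.5, 1, 0.5)[idx - i + 2] * cnt[idx]
      ok <- !is.na(val[idx]) & wts > 0
      sm[i] <- if (any(ok)) sum(wts[ok] * val[idx][ok]) / sum(wts[ok]) else NA
    }
    val <- sm
  }
  if (anyNA(val)) {
    okb <- which(!is.na(val))
    for (i in which(is.na(val))) val[i] <- val[okb[which.min(abs(okb - i))]]
  }
  structure(list(edges = edges, value = val, count = cnt), class = "anomsig_binned")
}

predict_binned <- function(est, x) {
  bin <- findInterval(x, est$edges, rightmost.closed = TRUE, all.inside = TRUE)
  est$value[bin]
}

#' Probability of substructure solution from the anomalous signal
#'
#' The estimator is the fraction of training substructures with similar
#' anomalous signal that were solved, where "solved" means at least half of
#' the substructure sites were recovered within 3 angstroms of a true site.
#'
#' @param s_ano Anomalous signal value(s).
#' @param solved_table Data frame with columns `s_ano` and `solved`
#'   (logical/0-1); the packaged synthetic table is used when omitted.
#' @return Probability (vector) in `[0, 1]`.
#' @export
probability_of_solution <- function(s_ano, solved_table = NULL) {
  if (is.null(solved_table)) solved_table <- synthetic_solved_table()
  est <- binned_estimator(solved_table$s_ano, as.numeric(solved_table$solved))
  pmin(pmax(predict_binned(est, s_ano), 0), 1)
}

#' Expected map correlation from the useful anomalous correlation
#'
#' The mean model-phased map correlation of training data sets with similar
#' useful anomalous correlation (bin means).
#'
#' @param cc_ano Useful anomalous correlation value(s).
#' @param mapcc_table Data frame with columns `cc_ano` and `map_cc`;
#'   packaged synthetic table used when omitted.
#' @return Expected map correlation (vector).
#' @export
expected_map_cc <- function(cc_ano, mapcc_table = NULL) {
  if (is.null(mapcc_table)) mapcc_table <- synthetic_mapcc_table()
  est <- binned_estimator(mapcc_table$cc_ano, mapcc_table$map_cc)
  predict_binned(est, cc_ano)
}

#' Packaged synthetic outcome tables
#'
#' Stand-ins for archival training corpora, generated from fixed seeds. The
#' solved/not-solved table places the 50% success point near an anomalous
#' signal of 10 and saturates above 20, consistent with the working target
#' of an anomalous signal of about 15 for a confident experiment; the map
#' correlation table rises monotonically with CC_ano and saturates near
#' 0.9.
#'
#' @param n Rows.
#' @param seed Seed.
#' @return Tibbles (`s_ano`, `solved`) and (`cc_ano`, `map_cc`).
#' @export
synthetic_solved_table <- function(n = 800, seed = 55501) {
  set.seed(seed)
  s <- exp(runif(n, log(0.8), log(60)))
  p <- stats::plogis((s - 10) / 2.5)
  tibble(s_ano = s, solved = runif(n) < p)
}

#' @rdname synthetic_solved_table
#' @export
synthetic_mapcc_table <- function(n = 800, seed = 55502) {
  set.seed(seed)
  cc <- runif(n, 0, 1)
  mcc <- pmin(pmax(0.92 * sqrt(cc) + rnorm(n, 0, 0.06), 0), 1)
  tibble(cc_ano = cc, map_cc = mcc)
}
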