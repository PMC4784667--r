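# Anomalous-data-quality metrics: half-data-set anomalous correlation and
# the derived CC* estimate, Patterson skew, sigma rescaling and the
# normalized error, plus ground-truth metrics for validation.

#' Split data into two half data sets
#'
#' With several crystals (`strategy = "by_crystal"`), data sets are divided
#' into two approximately equal groups, keeping each crystal's reflections
#' together so systematic inter-crystal differences do not masquerade as
#' noise. With a single unmerged data set (`strategy = "by_observation"`),
#' each unique reflection's observations are split into the first and second
#' half as they appear in the file when they are grouped, otherwise
#' randomly (seeded). Each half is then scaled and merged with local scaling
#' before any correlation is computed.
#'
#' @param datasets A list of `anomsig_unmerged` objects or a single one.
#' @param strategy `"by_crystal"` or `"by_observation"`.
#' @param seed Seed for the random single-file split.
#' @param ... Passed to [scale_and_merge()].
#' @return List of class `anomsig_halfset`: merged halves `half1`, `half2`,
#'   and `w`, the fraction of unique acentric reflections present in both.
#' @export
split_half_datasets <- function(datasets, strategy = c("by_crystal", "by_observation"),
                                seed = 1, ...) {
  strategy <- match.arg(strategy)
  datasets <- split_input_datasets(datasets)
  if (strategy == "by_crystal" && length(datasets) >= 2) {
    counts <- vapply(datasets, nrow, integer(1))
    ord <- order(counts, decreasing = TRUE)
    tot <- c(0, 0); groups <- list(integer(0), integer(0))
    for (i in ord) {            # greedy balance of observation counts
      g <- which.min(tot)
      groups[[g]] <- c(groups[[g]], i); tot[g] <- tot[g] + counts[i]
    }
    h1 <- datasets[groups[[1]]]; h2 <- datasets[groups[[2]]]
  } else {
    if (length(datasets) > 1) {
      datasets <- list(do.call(rbind_unmerged, datasets))
    }
    ds <- datasets[[1]]
    key <- hkl_key(ds$h, ds$k, ds$l)
    grouped <- !is.unsorted(match(key, unique(key)))
    pick_first <- if (grouped) {
      stats::ave(rep(1, nrow(ds)), key, FUN = function(v)
        seq_along(v) <= ceiling(length(v) / 2))
    } else {
      set.seed(seed)
      stats::ave(rep(1, nrow(ds)), key, FUN = function(v) {
        n1 <- ceiling(length(v) / 2)
        out <- c(rep(1, n1), rep(0, length(v) - n1))
        if (length(v) > 1) sample(out) else out
      })
    }
    mk <- function(rows) unmerged_dataset(
      as_tibble(ds)[rows, c("h", "k", "l", "i_obs", "sig_i", "dataset_id")],
      get_cell(ds), get_spacegroup(ds), get_wavelength(ds))
    h1 <- list(mk(pick_first == 1)); h2 <- list(mk(pick_first == 0))
  }
  m1 <- scale_and_merge(h1, ...)$merged
  m2 <- scale_and_merge(h2, ...)$merged
  k1 <- hkl_key(m1$h, m1$k, m1$l); k2 <- hkl_key(m2$h, m2$k, m2$l)
  w <- length(intersect(k1, k2)) / length(union(k1, k2))
  structure(list(half1 = m1, half2 = m2, w = w), class = "anomsig_halfset")
}

rbind_unmerged <- function(...) {
  parts <- list(...)
  obs <- bind_rows(lapply(parts, function(p)
    as_tibble(p)[, c("h", "k", "l", "i_obs", "sig_i", "dataset_id")]))
  unmerged_dataset(obs, get_cell(parts[[1]]), get_spacegroup(parts[[1]]),
                   get_wavelength(parts[[1]]))
}

#' Half-data-set anomalous correlation
#'
#' Pearson correlation of anomalous differences between the two merged
#' halves over their common acentric reflections.
#'
#' @param pair An `anomsig_halfset` from [split_half_datasets()].
#' @return List with `cc_half`, `n_common`, and `w`; `cc_half` is `NA` with
#'   a warning when fewer than 3 common reflections exist.
#' @export
half_dataset_cc_ano <- function(pair) {
  j <- inner_join(as_tibble(pair$half1)[, c("h", "k", "l", "dano")],
                  as_tibble(pair$half2)[, c("h", "k", "l", "dano")],
                  by = c("h", "k", "l"))
  if (nrow(j) < 3) {
    warn("fewer than 3 reflections common to the half data sets; CC_1/2 undefined")
    return(list(cc_half = NA_real_, n_common = nrow(j), w = pair$w))
  }
  list(cc_half = cor(j$dano.x, j$dano.y), n_common = nrow(j), w = pair$w)
}

#' Estimated squared anomalous correlation (CC*^2) from CC_1/2
#'
#' The expected correlation of merged anomalous differences with the true
#' anomalous differences, derived from the half-data-set correlation and
#' the fraction `w` of reflections measured more than once:
#' `E2 = 2 CC_half / (2 - w + w CC_half)`.
#' At `w = 1` this reduces to the familiar `CC*^2 = 2 CC_half / (1 + CC_half)`.
#' Squaring keeps the metric defined when `CC_half` is negative (the value
#' then carries the negative sign of `CC_half`).
#'
#' @param cc_half Half-data-set anomalous correlation in `[-1, 1]`.
#' @param w Fraction of unique reflections measured in both halves.
#' @return `E2`, the estimated squared anomalous correlation.
#' @export
estimated_cc_star_squared <- function(cc_half, w = 1) {
  stopifnot(w >= 0, w <= 1)
  if (is.na(cc_half)) return(NA_real_)
  if (cc_half < -1 || cc_half > 1) abort("cc_half must lie in [-1, 1]")
  denom <- 2 - w + w * cc_half
  if (denom <= 0) {
    warn("CC_1/2 = -1 with w = 1: estimated correlation undefined")
    return(NA_real_)
  }
  2 * cc_half / denom
}

#' Rescale uncertainties against the highest-resolution anomalous differences
#'
#' Finds the factor `beta` such that, in the highest resolution shell, the
#' mean-square rescaled uncertainty of the anomalous differences equals the
#' mean-square observed anomalous difference (there the anomalous signal is
#' assumed negligible, so the differences are pure noise). Highest-shell
#' values are extrapolated from a linear fit of the shell means of
#' `<dano^2>` and `<sig_dano^2>` against 1/d^2 over the outer half of the
#' shells; if an extrapolation goes non-positive the raw highest-shell means
#' are used with a warning.
#'
#' @param merged Merged anomalous data with `dano` and `sig_dano`.
#' @param n_bins Resolution shells (default 10; at least 3 required).
#' @return List with `beta`, the per-shell table, and the extrapolated
#'   highest-shell mean squares.
#' @export
rescale_sigmas <- function(merged, n_bins = 10) {
  shell <- resolution_shells(merged$d, n_bins)
  tab <- tibble(shell = shell, ssq = 1 / merged$d^2,
                dano = merged$dano, sig = merged$sig_dano) |>
    group_by(.data$shell) |>
    summarise(ssq = mean(.data$ssq), msq_dano = mean(.data$dano^2),
              msq_sig = mean(.data$sig^2), n = dplyr::n(), .groups = "drop") |>
    arrange(.data$ssq)
  if (nrow(tab) < 3) abort("at least 3 resolution shells are required to rescale sigmas")
  outer_half <- tab[tab$ssq >= median(tab$ssq), ]
  top_ssq <- max(tab$ssq)
  extrap <- function(y) {
    fit <- lm(y ~ ssq, data = data.frame(y = y, ssq = outer_half$ssq))
    unname(coef(fit)[1] + coef(fit)[2] * top_ssq)
  }
  e_dano <- extrap(outer_half$msq_dano)
  e_sig <- extrap(outer_half$msq_sig)
  if (!is.finite(e_dano) || !is.finite(e_sig) || e_dano <= 0 || e_sig <= 0) {
    warn("non-positive extrapolated highest-shell mean squares; using raw shell means")
    e_dano <- tab$msq_dano[nrow(tab)]
    e_sig <- tab$msq_sig[nrow(tab)]
  }
  list(beta = sqrt(e_dano / e_sig), shells = tab,
       highest_shell = c(msq_dano = e_dano, msq_sig = e_sig))
}

#' Normalized error of the anomalous differences
#'
#' `e = sqrt(<(beta sig_dano)^2> / <dano^2>)` over the whole data set: the
#' ratio of rescaled measurement uncertainty to observed anomalous
#' difference. By construction `e` is close to 1 in the highest resolution
#' shell; a data set that is pure noise has `e` near 1 overall.
#'
#' @param merged Merged anomalous data.
#' @param beta Uncertainty rescale factor from [rescale_sigmas()].
#' @return Normalized error `e`.
#' @export
normalized_error <- function(merged, beta = 1) {
  msq_d <- mean(merged$dano^2)
  if (msq_d == 0) {
    warn("zero anomalous-difference variance; normalized error undefined")
    return(NA_real_)
  }
  sqrt(mean((beta * merged$sig_dano)^2) / msq_d)
}

#' Expected useful anomalous correlation from the normalized error
#'
#' With no minor anomalous scatterers the observed mean-square anomalous
#' difference is signal plus noise, so the correlation with the true
#' differences is `CC_ano = sqrt(1 - e^2)`: 1 for perfect measurement
#' (e = 0), 0 for pure noise (e = 1).
#'
#' @param e Normalized error in `[0, 1]`; values above 1 are clamped to
#'   `CC = 0` with a warning.
#' @return Expected CC_ano.
#' @export
cc_ano_expected_from_e <- function(e) {
  out <- e
  high <- !is.na(e) & e > 1
  if (any(high)) {
    warn("normalized error above 1; expected CC_ano clamped to 0")
  }
  out[high] <- 1
  sqrt(pmax(1 - out^2, 0))
}

#' Useful anomalous correlation against ideal differences
#'
#' The Pearson correlation of observed anomalous differences with the ideal
#' anomalous differences of the (known or refined) substructure-only model,
#' over matched acentric reflections: the quantity the quality metrics try
#' to predict. Scale-invariant in the observed differences.
#'
#' @param merged Merged anomalous data.
#' @param ideal Tibble with `h`, `k`, `l` and `dano_ideal`.
#' @return `CC_ano` (`NA` with a warning below 3 matched reflections).
#' @export
useful_anomalous_correlation <- function(merged, ideal) {
  j <- inner_join(as_tibble(merged)[, c("h", "k", "l", "dano")],
                  ideal[, c("h", "k", "l", "dano_ideal")], by = c("h", "k", "l"))
  if (nrow(j) < 3) {
    warn("fewer than 3 matched reflections; CC_ano undefined")
    return(NA_real_)
  }
  cor(j$dano, j$dano_ideal)
}

#' All quality metrics for a merged data set
#'
#' Convenience wrapper computing the estimated squared anomalous correlation
#' `E2` (when unmerged data allow half data sets), the Patterson skew `s`,
#' the uncertainty rescale factor `beta` and the normalized error `e`.
#'
#' @param merged Merged anomalous data (from [scale_and_merge()], its
#'   `$merged` element, or [read_merged()]).
#' @param unmerged Optional list of `anomsig_unmerged` objects for the
#'   half-data-set correlation.
#' @param n_bins Resolution shells for sigma rescaling.
#' @param grid_spacing Patterson grid spacing (default `d_min/3`).
#' @param seed Seed for any random half-set split.
#' @param ... Passed to [scale_and_merge()] for the half-set scaling.
#' @return Object of class `anomsig_metrics`: list with `e2`, `cc_half`,
#'   `w`, `skew`, `beta`, `e`, `shells`.
#' @export
quality_metrics <- function(merged, unmerged = NULL, n_bins = 10,
                            grid_spacing = NULL, seed = 1, ...) {
  if (inherits(merged, "anomsig_merge")) merged <- merged$merged
  cc_half <- NA_real_; w <- NA_real_; e2 <- NA_real_
  if (!is.null(unmerged)) {
    pair <- split_half_datasets(unmerged, seed = seed, ...)
    hc <- half_dataset_cc_ano(pair)
    cc_half <- hc$cc_half; w <- hc$w
    e2 <- estimated_cc_star_squared(cc_half, w)
  }
  pat <- anomalous_difference_patterson(merged, grid_spacing)
  skew <- patterson_skew(pat)
  rs <- rescale_sigmas(merged, n_bins)
  e <- normalized_error(merged, rs$beta)
  structure(list(e2 = e2, cc_half = cc_half, w = w, skew = skew,
                 beta = rs$beta, e = e, shells = rs$shells),
            class = "anomsig_metrics")
}

#' @export
print.anomsig_metrics <- function(x, ...) {
  cat("Anomalous data-quality metrics\n")
  cat(sprintf("  E2 (estimated CC*^2): %s   (CC_1/2 = %s, w = %s)\n",
              fmt_or_na(x$e2), fmt_or_na(x$cc_half), fmt_or_na(x$w)))
  cat(sprintf("  Patterson skew s:     %.3f\n", x$skew))
  cat(sprintf("  sigma rescale beta:   %.3f\n", x$beta))
  cat(sprintf("  normalized error e:   %.3f\n", x$e))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' @export
tidy.anomsig_metrics <- function(x, ...) {
  tibble(metric = c("e2", "cc_half", "w", "skew", "beta", "e"),
         value = c(x$e2, x$cc_half, x$w, x$skew, x$beta, x$e))
}

#' @export
glance.anomsig_metrics <- function(x, ...) {
  tibble(e2 = x$e2, cc_half = x$cc_half, w = x$w, skew = x$skew,
         beta = x$beta, e = x$e)
}
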