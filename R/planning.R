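# Experiment planning and post-collection evaluation: composition-based
# reflection counts, anomalous scattering factors, the second moment f_B of
# the substructure scattering factors, and the anomalous-signal relation
# S_ano = CC_ano * sqrt(N_refl / n_sites) / f_B.

#' Estimate the number of unique reflections
#'
#' Sphere-counting estimate from the asymmetric-unit volume:
#' `N_refl = (2 pi / 3) V_au / d_min^3` (reciprocal-sphere lattice count,
#' halved for Friedel pairs, expressed per asymmetric-unit volume). The
#' count includes centric reflections, which carry no anomalous difference;
#' plan reports note this caveat rather than correcting for it.
#'
#' @param v_au Asymmetric-unit volume in cubic angstroms.
#' @param d_min Resolution limit in angstroms.
#' @return Estimated number of unique reflections.
#' @export
n_refl_estimate <- function(v_au, d_min) {
  stopifnot(v_au > 0, d_min > 0)
  (2 * pi / 3) * v_au / d_min^3
}

#' Anomalous scattering factors f' and f'' for an element
#'
#' Interpolates the bundled Cromer-Liberman tabulation in energy at the
#' requested wavelength. Explicit `fp`/`fdp` overrides always win. Note
#' that tabulated f'' near white-line edge peaks (e.g. selenium at its
#' K-edge peak) is a lower bound on what a scan-calibrated experiment
#' achieves; override with measured values when available.
#'
#' @param element Element symbol (e.g. `"Se"`, `"S"`).
#' @param wavelength Wavelength in angstroms.
#' @param fp,fdp Optional user overrides (electrons).
#' @return List with `fp` and `fdp` (electrons).
#' @export
anomalous_scattering_factors <- function(element, wavelength, fp = NULL, fdp = NULL) {
  if (!is.null(fp) && !is.null(fdp)) return(list(fp = fp, fdp = fdp))
  path <- system.file("extdata", "anomalous_factors.tsv", package = "anomsig")
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("element", "z", "energy_kev", "fprime", "fdoubleprime"),
                    stringsAsFactors = FALSE)
  rows <- tab[tab$element == element, ]
  if (!nrow(rows)) {
    abort(sprintf("element '%s' is not in the bundled anomalous-factor table; supply fp and fdp explicitly", element))
  }
  energy <- 12.398419843 / wavelength  # keV
  if (energy < min(rows$energy_kev) || energy > max(rows$energy_kev)) {
    abort(sprintf("wavelength %.4g A (%.3g keV) is outside the tabulated range for %s; supply fp and fdp explicitly",
                  wavelength, energy, element))
  }
  list(fp = fp %||% approx(rows$energy_kev, rows$fprime, xout = energy)$y,
       fdp = fdp %||% approx(rows$energy_kev, rows$fdoubleprime, xout = energy)$y)
}

#' Second moment of the substructure scattering factors
#'
#' For each reflection the substructure's effective anomalous scattering
#' factor is `f_{h,B} = f'' exp(-B s^2)` with `s = sin(theta)/lambda = 1/(2 d)`; the factor
#' `f_B` is its root-mean-square over all reflections divided by its mean:
#' `f_B = sqrt(<f^2>) / <f> >= 1`. It grows as high-resolution data widen
#' the spread of `f_{h,B}`, damping the growth of the anomalous signal with
#' reflection count. (A resolution-independent scattering factor gives
#' `f_B = 1` and the constant cancels.)
#'
#' @param fdp Imaginary anomalous scattering factor f'' (electrons).
#' @param b Substructure atomic displacement factor (angstrom^2, >= 0).
#' @param d Vector of d-spacings of the reflections in the data set, or a
#'   resolution limit from which a sphere-weighted quadrature is drawn when
#'   `quadrature = TRUE`.
#' @param quadrature Treat `d` as a scalar d_min and integrate over a
#'   reflection sphere instead of using an explicit reflection list.
#' @return `f_B` (dimensionless, >= 1).
#' @export
f_b_second_moment <- function(fdp, b, d, quadrature = FALSE) {
  stopifnot(b >= 0, length(d) >= 1)
  if (quadrature) {
    stopifnot(length(d) == 1)
    u <- (seq_len(512) - 0.5) / 512          # uniform in (s/s_max)^3
    s <- u^(1 / 3) / (2 * d)
  } else {
    s <- 1 / (2 * d)
  }
  f <- fdp * exp(-b * s^2)
  if (all(f == 0)) abort("substructure scattering factors are identically zero")
  sqrt(mean(f^2)) / mean(f)
}

#' Normalized error expected from the mean intensity signal-to-noise
#'
#' The empirical relationship `e = 0.88 / <I/sigma(I)>`, capped at 1.
#'
#' @param ios Mean intensity-to-uncertainty ratio (> 0).
#' @return Normalized error `e` in `(0, 1]`.
#' @export
e_from_i_over_sigma <- function(ios) {
  stopifnot(all(ios > 0))
  pmin(0.88 / ios, 1)
}

#' Anomalous signal from the useful anomalous correlation
#'
#' The anomalous signal (expected model-phased anomalous difference Fourier
#' peak height at substructure sites, in map-rms units) follows
#' `S_ano = CC_ano * sqrt(N_refl / n_sites) / f_B`:
#' proportional to the useful anomalous correlation, growing with the
#' square root of the number of reflections, diluted across sites and
#' damped by the spread of the substructure scattering factors.
#'
#' @param cc_ano Useful anomalous correlation.
#' @param n_refl Number of unique reflections.
#' @param n_sites Number of substructure sites in the asymmetric unit.
#' @param f_b Second moment factor from [f_b_second_moment()].
#' @return Predicted anomalous signal.
#' @export
anomalous_signal <- function(cc_ano, n_refl, n_sites, f_b) {
  stopifnot(n_refl > 0, n_sites > 0, f_b > 0)
  cc_ano * sqrt(n_refl / n_sites) / f_b
}

#' Crystal composition for planning
#'
#' Derives the asymmetric-unit volume from a residue count (110 Da per
#' residue, 1.23 cubic angstroms per Dalton of protein) and the solvent
#' fraction, and guesses the substructure site count from the sequence for
#' selenium (methionine count) or sulfur (methionine + cysteine) when not
#' given.
#'
#' @param sequence One-letter amino-acid sequence (optional if `n_residues`
#'   given).
#' @param n_residues Residue count (derived from `sequence` if omitted).
#' @param solvent_fraction Solvent fraction of the crystal (default 0.50).
#' @param element Anomalous scatterer element symbol.
#' @param wavelength Wavelength in angstroms.
#' @param n_sites Substructure sites per asymmetric unit; guessed from the
#'   sequence for Se/S, otherwise required.
#' @param fp,fdp Optional scattering-factor overrides.
#' @return List of class `anomsig_composition`.
#' @export
crystal_composition <- function(sequence = NULL, n_residues = NULL,
                                solvent_fraction = 0.50, element = "Se",
                                wavelength = 0.9792, n_sites = NULL,
                                fp = NULL, fdp = NULL) {
  stopifnot(solvent_fraction > 0, solvent_fraction < 1)
  if (is.null(n_residues)) {
    if (is.null(sequence)) abort("supply a sequence or a residue count")
    sequence <- toupper(gsub("[^A-Za-z]", "", sequence))
    n_residues <- nchar(sequence)
  }
  if (is.null(n_sites)) {
    if (is.null(sequence)) abort("n_sites must be given when no sequence is available")
    counts <- table(strsplit(sequence, "")[[1]])
    met <- sum(counts[names(counts) == "M"])
    cys <- sum(counts[names(counts) == "C"])
    n_sites <- switch(element,
                      Se = max(met, 1),
                      S = max(met + cys, 1),
                      abort(sprintf("cannot guess n_sites for element '%s'; supply it explicitly", element)))
  }
  stopifnot(n_sites >= 1)
  mass_da <- n_residues * 110
  v_protein <- mass_da * 1.23
  v_au <- v_protein / (1 - solvent_fraction)
  sf <- anomalous_scattering_factors(element, wavelength, fp, fdp)
  structure(list(n_residues = n_residues, solvent_fraction = solvent_fraction,
                 v_au = v_au, n_sites = n_sites, element = element,
                 wavelength = wavelength, fp = sf$fp, fdp = sf$fdp),
            class = "anomsig_composition")
}

#' @export
print.anomsig_composition <- function(x, ...) {
  cat(sprintf("Crystal composition: %d residues, V_au %.0f A^3 (solvent %.0f%%), %d x %s site(s), f'=%.2f f''=%.2f at %.4f A\n",
              x$n_residues, x$v_au, 100 * x$solvent_fraction, x$n_sites,
              x$element, x$fp, x$fdp, x$wavelength))
  invisible(x)
}

#' Plan a SAD experiment
#'
#' For each candidate resolution limit and each anticipated `<I/sigma(I)>`,
#' predicts the normalized error, the useful anomalous correlation (via the
#' Bayesian estimator when supplied, else the no-minor-scatterer closed
#' form `sqrt(1 - e^2)`), the anomalous signal, the probability of
#' substructure solution and the expected map correlation, and flags the
#' `<I/sigma(I)>` needed to reach the target anomalous signal (about 15 for
#' a confident experiment).
#'
#' @param composition From [crystal_composition()].
#' @param dmin_grid Candidate resolution limits (angstroms).
#' @param ios_targets Candidate `<I/sigma(I)>` values.
#' @param b_sub Substructure displacement factor; estimated from
#'   `wilson_b` via the packaged Bayesian estimator when omitted.
#' @param wilson_b Anticipated Wilson B (default 25 angstrom^2).
#' @param cc_estimator Optional `anomsig_bayes` trained with an `e`
#'   predictor to refine CC_ano from the normalized error.
#' @param s_ano_target Anomalous-signal target used for flagging
#'   (default 15).
#' @return Object of class `anomsig_plan`: tibble rows over
#'   (`d_min`, `i_over_sigma`) with `n_refl`, `f_b`, `e`, `cc_ano`,
#'   `s_ano`, `p_solve`, `map_cc`, `reaches_target`.
#' @export
plan_sad_experiment <- function(composition, dmin_grid = c(2.0, 2.5, 3.0, 3.5),
                                ios_targets = c(5, 10, 20, 30),
                                b_sub = NULL, wilson_b = 25,
                                cc_estimator = NULL, s_ano_target = 15) {
  if (is.null(b_sub)) b_sub <- estimate_substructure_b(wilson_b)$mean
  rows <- list(); ri <- 1L
  for (dm in sort(dmin_grid)) {
    n_refl <- n_refl_estimate(composition$v_au, dm)
    f_b <- f_b_second_moment(composition$fdp, b_sub, dm, quadrature = TRUE)
    for (ios in ios_targets) {
      e <- e_from_i_over_sigma(ios)
      cc <- if (!is.null(cc_estimator)) {
        bayes_posterior(cc_estimator, list(e = e))$mean
      } else cc_ano_expected_from_e(e)
      s_ano <- anomalous_signal(cc, n_refl, composition$n_sites, f_b)
      rows[[ri]] <- tibble(d_min = dm, i_over_sigma = ios, n_refl = n_refl,
                           f_b = f_b, b_sub = b_sub, e = e, cc_ano = cc,
                           s_ano = s_ano,
                           p_solve = probability_of_solution(s_ano),
                           map_cc = expected_map_cc(cc),
                           reaches_target = s_ano >= s_ano_target)
      ri <- ri + 1L
    }
  }
  out <- bind_rows(rows)
  structure(list(table = out, composition = composition,
                 s_ano_target = s_ano_target,
                 note = "n_refl includes centric reflections, which do not contribute anomalous differences"),
            class = "anomsig_plan")
}

#' @export
print.anomsig_plan <- function(x, ...) {
  cat("SAD experiment plan\n")
  print(x$composition)
  tab <- x$table
  for (dm in unique(tab$d_min)) {
    sub <- tab[tab$d_min == dm, ]
    ok <- sub$i_over_sigma[sub$reaches_target]
    cat(sprintf("  d_min %.2f A (N_refl ~ %d): S_ano target %.0f %s\n",
                dm, round(sub$n_refl[1]), x$s_ano_target,
                if (length(ok)) sprintf("reached at <I/sig> >= %.3g", min(ok))
                else "not reached at the examined <I/sig> values"))
  }
  cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' @export
tidy.anomsig_plan <- function(x, ...) x$table

#' @export
glance.anomsig_plan <- function(x, ...) {
  tibble(n_sites = x$composition$n_sites, v_au = x$composition$v_au,
         element = x$composition$element,
         best_s_ano = max(x$table$s_ano), s_ano_target = x$s_ano_target,
         target_reachable = any(x$table$reaches_target))
}

#' Wilson B from the intensity fall-off
#'
#' Wilson-plot fit: shell-mean intensities are first normalized by the
#' squared carbon form factor (the form-factor fall-off of an average
#' protein would otherwise masquerade as extra B), then `ln <I/f_C^2>` is
#' regressed against `(sin theta / lambda)^2` over the outer half of the
#' resolution range; the slope is `-2B`.
#'
#' @param merged Merged data (uses `f_mean^2`) or an `anomsig_unmerged`
#'   object (uses intensities).
#' @param n_bins Shells for the fit.
#' @return Wilson B estimate (angstrom^2).
#' @export
wilson_b_estimate <- function(merged, n_bins = 20) {
  if (inherits(merged, "anomsig_unmerged")) {
    d <- d_spacing(merged$h, merged$k, merged$l, get_cell(merged))
    inten <- pmax(merged$i_obs, NA)
  } else {
    d <- merged$d
    inten <- merged$f_mean^2
  }
  ok <- is.finite(inten) & inten > 0
  d <- d[ok]; inten <- inten[ok]
  stol <- 1 / (2 * d)
  inten <- inten / f0_lookup("C", stol)^2
  shell <- resolution_shells(d, n_bins)
  tab <- tibble(shell = shell, stol2 = stol^2, i = inten) |>
    group_by(.data$shell) |>
    summarise(stol2 = mean(.data$stol2), logi = log(mean(.data$i)),
              .groups = "drop")
  outer_half <- tab[tab$stol2 >= median(tab$stol2), ]
  fit <- lm(logi ~ stol2, data = outer_half)
  max(-coef(fit)[[2]] / 2, 0.1)
}

#' Evaluate a measured SAD data set
#'
#' Post-collection analogue of [plan_sad_experiment()]: computes the
#' quality metrics, estimates CC_ano with the Bayesian estimator, the
#' substructure B from the Wilson B, `f_B` from the actual reflection
#' list, and the anomalous signal with the actual unique-reflection count,
#' then the probability of substructure solution and the expected map
#' correlation.
#'
#' @param merged Merged anomalous data (or an `anomsig_merge` result).
#' @param cc_estimator Trained `anomsig_bayes` for CC_ano (predictors
#'   `e2`, `skew`, `e`).
#' @param unmerged Optional unmerged data sets enabling the half-set
#'   correlation.
#' @param n_sites Substructure site count (required).
#' @param fdp f'' of the anomalous scatterer (electrons).
#' @param metrics Precomputed `anomsig_metrics` (computed when omitted).
#' @param seed Seed for any random half-set split.
#' @return Object of class `anomsig_evaluation`: one-row tibble in
#'   `$table` plus the posterior and metrics.
#' @export
evaluate_measured_data <- function(merged, cc_estimator, unmerged = NULL,
                                   n_sites, fdp = 4, metrics = NULL, seed = 1) {
  if (inherits(merged, "anomsig_merge")) merged <- merged$merged
  if (is.null(metrics)) metrics <- quality_metrics(merged, unmerged, seed = seed)
  post <- estimate_cc_ano(metrics, cc_estimator)
  cc <- post$mean
  wb <- wilson_b_estimate(merged)
  b_sub <- estimate_substructure_b(wb)$mean
  f_b <- f_b_second_moment(fdp, b_sub, merged$d)
  n_refl <- nrow(merged)
  s_ano <- anomalous_signal(cc, n_refl, n_sites, f_b)
  tab <- tibble(cc_ano_est = cc, cc_ano_sd = post$sd, wilson_b = wb,
                b_sub = b_sub, f_b = f_b, n_refl = n_refl, n_sites = n_sites,
                s_ano_est = s_ano,
                p_solve = probability_of_solution(s_ano),
                map_cc = expected_map_cc(cc),
                e2 = metrics$e2, skew = metrics$skew, e = metrics$e,
                beta = metrics$beta)
  structure(list(table = tab, posterior = post, metrics = metrics),
            class = "anomsig_evaluation")
}

#' @export
print.anomsig_evaluation <- function(x, ...) {
  t <- x$table
  cat("SAD data evaluation\n")
  cat(sprintf("  estimated CC_ano: %.3f (sd %.3f)\n", t$cc_ano_est, t$cc_ano_sd))
  cat(sprintf("  anomalous signal: %.1f  (N_refl %d, n_sites %d, f_B %.3f, B_sub %.1f)\n",
              t$s_ano_est, t$n_refl, t$n_sites, t$f_b, t$b_sub))
  cat(sprintf("  P(substructure solved): %.2f   expected map CC: %.2f\n",
              t$p_solve, t$map_cc))
  invisible(x)
}

#' @export
tidy.anomsig_evaluation <- function(x, ...) x$table

#' @export
glance.anomsig_evaluation <- function(x, ...) x$table
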