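# Map synthesis on a unit-cell grid via FFT.
#
# Conventions: rho(x) = Re sum_h C(h) exp(-2 pi i h.x); coefficients are
# supplied for ASU representatives and expanded over the symmetry orbit
# (with Friedel mates conjugated) before synthesis, so the result is real.

#' Synthesize a real map from ASU Fourier coefficients
#'
#' @param hkl Integer matrix (n x 3) of ASU Miller indices.
#' @param coef Complex (or real) coefficients for those indices.
#' @param cell A [unit_cell()].
#' @param spacegroup Sohncke space-group symbol or number.
#' @param grid_spacing Approximate grid spacing in angstroms.
#' @return A 3-d array of map values over one unit cell, with attributes
#'   `cell` and `rms` (root-mean-square about the mean).
#' @export
fourier_map <- function(hkl, coef, cell, spacegroup, grid_spacing) {
  if (!nrow(hkl)) abort("no coefficients supplied for map synthesis")
  ex <- expand_to_p1(hkl, as.complex(coef), spacegroup, friedel = TRUE)
  lens <- c(cell$a, cell$b, cell$c)
  dims <- integer(3)
  for (i in 1:3) {
    need <- max(2L * max(abs(ex$hkl[, i])) + 2L,
                ceiling(lens[i] / grid_spacing))
    dims[i] <- stats::nextn(need, c(2, 3, 5))
  }
  arr <- array(0 + 0i, dim = dims)
  idx <- cbind(ex$hkl[, 1] %% dims[1], ex$hkl[, 2] %% dims[2],
               ex$hkl[, 3] %% dims[3]) + 1L
  arr[idx] <- ex$f
  m <- Re(fft(arr))
  m <- m - mean(m)
  attr(m, "cell") <- cell
  attr(m, "rms") <- sqrt(mean(m^2))
  m
}

#' Trilinear interpolation of a cell map at fractional coordinates
#'
#' Coordinates outside the cell are wrapped by lattice translation.
#'
#' @param map A 3-d array from [fourier_map()].
#' @param frac Matrix (n x 3) of fractional coordinates.
#' @return Numeric vector of interpolated map values.
#' @export
interpolate_map <- function(map, frac) {
  dims <- dim(map)
  out <- numeric(nrow(frac))
  for (i in seq_len(nrow(frac))) {
    g <- (frac[i, ] %% 1) * dims
    g0 <- floor(g); fr <- g - g0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      ii <- (c(g0[1] + dx, g0[2] + dy, g0[3] + dz)) %% dims + 1
      acc <- acc + w * map[ii[1], ii[2], ii[3]]
    }
    out[i] <- acc
  }
  out
}

#' Anomalous difference and native Patterson maps
#'
#' The Patterson synthesis uses squared anomalous differences (`dano^2`,
#' anomalous) or squared mean amplitudes (`f_mean^2`, native) as
#' coefficients. The origin peak is removed by subtracting the
#' resolution-shell mean from the coefficients before synthesis, which also
#' forces the map mean to zero.
#'
#' @param merged Merged anomalous data ([new_merged()]).
#' @param grid_spacing Grid spacing in angstroms; default `d_min / 3`.
#' @param n_bins Resolution shells used for origin removal.
#' @return A centrosymmetric 3-d map array (see [fourier_map()]).
#' @export
anomalous_difference_patterson <- function(merged, grid_spacing = NULL, n_bins = 10) {
  patterson_impl(merged, merged$dano^2, grid_spacing, n_bins)
}

#' @rdname anomalous_difference_patterson
#' @export
native_patterson <- function(merged, grid_spacing = NULL, n_bins = 10) {
  patterson_impl(merged, merged$f_mean^2, grid_spacing, n_bins)
}

patterson_impl <- function(merged, coef, grid_spacing, n_bins) {
  if (!nrow(merged)) abort("empty merged data")
  ok <- is.finite(coef)
  merged <- merged[ok, , drop = FALSE]; coef <- coef[ok]
  shell <- resolution_shells(merged$d, n_bins)
  coef <- coef - stats::ave(coef, shell, FUN = mean)
  if (is.null(grid_spacing)) grid_spacing <- min(merged$d) / 3
  fourier_map(cbind(merged$h, merged$k, merged$l), coef,
              get_cell(merged), attr(merged, "spacegroup"), grid_spacing)
}

#' Skew of a (difference) Patterson map
#'
#' The map is adjusted to zero mean, its rms is computed, values are
#' truncated at `truncate_high` sigma, and optionally further truncated at
#' `tns_truncate` sigma wherever a native Patterson on the same grid lies
#' outside that range (a guard against translational noncrystallographic
#' symmetry; off by default). The skew is the third central moment of the
#' truncated map divided by the cube of its standard deviation.
#'
#' @param anom_map Map array from [anomalous_difference_patterson()].
#' @param native_map Optional native Patterson on the identical grid.
#' @param truncate_high Truncation level in map-sigma units (default 4).
#' @param tns_truncate Secondary truncation level used with `native_map`.
#' @param use_tns Apply the native-Patterson truncation (default `FALSE`).
#' @return Skew `s` (dimensionless); 0 for a zero-variance map.
#' @export
patterson_skew <- function(anom_map, native_map = NULL, truncate_high = 4.0,
                           tns_truncate = 3.0, use_tns = FALSE) {
  v <- as.numeric(anom_map)
  v <- v - mean(v)
  sig <- sqrt(mean(v^2))
  if (sig == 0) return(0)
  v <- pmin(pmax(v, -truncate_high * sig), truncate_high * sig)
  if (use_tns) {
    if (is.null(native_map)) abort("native_map is required when use_tns = TRUE")
    if (!identical(dim(anom_map), dim(native_map))) {
      abort("anomalous and native Patterson maps must share the same grid")
    }
    nv <- as.numeric(native_map) - mean(native_map)
    nsig <- sqrt(mean(nv^2))
    mask <- abs(nv) > tns_truncate * nsig
    v[mask] <- pmin(pmax(v[mask], -tns_truncate * sig), tns_truncate * sig)
  }
  v <- v - mean(v)
  s2 <- mean(v^2)
  if (s2 == 0) return(0)
  mean(v^3) / s2^1.5
}

#' Model-phased anomalous difference Fourier and the observed anomalous signal
#'
#' Synthesizes the anomalous difference Fourier with coefficients
#' `|dano| exp(i (phi_model - pi/2))` (the standard convention that places
#' positive peaks at anomalous scatterers), and reports the mean map value at
#' the substructure sites in map-rms units - the observed anomalous signal.
#' Site values are obtained by trilinear interpolation; sites outside the
#' cell are wrapped.
#'
#' @param merged Merged anomalous data.
#' @param phi_model Model phases in radians, one per row of `merged`.
#' @param sites Matrix or data frame of fractional site coordinates (n x 3).
#' @param grid_spacing Grid spacing in angstroms; default `d_min / 3`.
#' @return A list with `s_ano` (mean site peak height / map rms),
#'   `site_values` (per-site, rms units) and `map`.
#' @export
anomalous_signal_observed <- function(merged, phi_model, sites,
                                      grid_spacing = NULL) {
  stopifnot(nrow(merged) == length(phi_model))
  if (is.null(grid_spacing)) grid_spacing <- min(merged$d) / 3
  coef <- abs(merged$dano) * exp(1i * (phi_model +
            ifelse(merged$dano >= 0, 0, pi) - pi / 2))
  map <- fourier_map(cbind(merged$h, merged$k, merged$l), coef,
                     get_cell(merged), attr(merged, "spacegroup"), grid_spacing)
  sites <- as.matrix(sites)
  vals <- interpolate_map(map, sites) / attr(map, "rms")
  list(s_ano = mean(vals), site_values = vals, map = map)
}
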