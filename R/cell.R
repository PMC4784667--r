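#' Construct a unit cell
#'
#' A unit cell is described by its three edge lengths (angstroms) and three
#' angles (degrees). All downstream resolution and reciprocal-space geometry
#' derives from the cell through its metric tensors.
#'
#' @param a,b,c Cell edge lengths in angstroms (must be positive).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named list with the six
#'   parameters plus the cell volume (`volume`, cubic angstroms).
#' @examples
#' unit_cell(50, 60, 70)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) abort("unit cell parameters must be finite numbers")
  if (any(p[1:3] <= 0)) abort("unit cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    abort("unit cell angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) abort("unit cell angles do not describe a valid cell (volume <= 0)")
  vol <- a * b * c * sqrt(arg)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f (V=%.1f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix (columns are a, b, c).
#' @noRd
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Reciprocal-space orthogonalization: `recip_cart_matrix(cell) %*% c(h,k,l)`
#' is the Cartesian reciprocal-lattice vector, whose norm is 1/d.
#' @noRd
recip_cart_matrix <- function(cell) {
  t(solve(orthogonalization_matrix(cell)))
}

#' Resolution of reflections
#'
#' Computes d-spacings (angstroms) for Miller indices under a given cell.
#'
#' @param h,k,l Integer Miller indices (vectors of equal length).
#' @param cell A [unit_cell()].
#' @return Numeric vector of d-spacings; `Inf` for (0,0,0).
#' @export
d_spacing <- function(h, k, l, cell) {
  B <- recip_cart_matrix(cell)
  x <- B %*% rbind(h, k, l)
  s <- sqrt(colSums(x^2))
  ifelse(s == 0, Inf, 1 / s)
}

#' Are two unit cells similar?
#'
#' Cells are compatible when corresponding lengths agree within a relative
#' tolerance and angles within an absolute tolerance, the criteria used when
#' grouping data sets from multiple crystals. An alternative length criterion
#' (absolute agreement within a fraction of the high-resolution limit) can be
#' selected instead.
#'
#' @param cell1,cell2 [unit_cell()] objects.
#' @param length_tol_fraction Relative tolerance on cell lengths (default 1%).
#' @param angle_tol_deg Absolute tolerance on cell angles in degrees (default 1).
#' @param alt_dmin_fraction If non-`NULL`, use the alternative criterion:
#'   lengths must agree within `alt_dmin_fraction * d_min` angstroms.
#' @param d_min High-resolution limit (angstroms), needed only by the
#'   alternative criterion.
#' @return Logical scalar.
#' @export
cells_similar <- function(cell1, cell2, length_tol_fraction = 0.01,
                          angle_tol_deg = 1.0, alt_dmin_fraction = NULL,
                          d_min = NULL) {
  len1 <- c(cell1$a, cell1$b, cell1$c); len2 <- c(cell2$a, cell2$b, cell2$c)
  ang1 <- c(cell1$alpha, cell1$beta, cell1$gamma)
  ang2 <- c(cell2$alpha, cell2$beta, cell2$gamma)
  if (!is.null(alt_dmin_fraction)) {
    if (is.null(d_min)) abort("d_min is required for the alternative cell-length criterion")
    len_ok <- all(abs(len1 - len2) <= alt_dmin_fraction * d_min)
  } else {
    len_ok <- all(abs(len1 - len2) <= length_tol_fraction * pmax(len1, len2))
  }
  len_ok && all(abs(ang1 - ang2) <= angle_tol_deg)
}

#' Assign reflections to resolution shells
#'
#' Shells contain (as nearly as possible) equal numbers of reflections,
#' constructed on 1/d^2 so that shell boundaries are monotone in resolution.
#'
#' @param d Numeric vector of d-spacings (angstroms).
#' @param n_bins Number of shells (default 10).
#' @return Integer vector of shell ids, 1 = lowest resolution (largest d),
#'   `n_bins` = highest resolution, with attribute `"edges"` giving the
#'   1/d^2 boundaries.
#' @export
resolution_shells <- function(d, n_bins = 10) {
  stopifnot(n_bins >= 1)
  ssq <- 1 / d^2
  n_bins <- max(1L, min(as.integer(n_bins), length(unique(ssq))))
  edges <- unique(quantile(ssq, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7))
  shell <- findInterval(ssq, edges, rightmost.closed = TRUE, all.inside = TRUE)
  attr(shell, "edges") <- edges
  shell
}
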