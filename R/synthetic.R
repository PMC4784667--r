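# Seeded synthetic SAD crystals with known anomalous substructures.
#
# The generator embodies the statistical structure the rest of the package
# assumes: Wilson-distributed protein structure factors, a substructure of
# anomalous scatterers summed over symmetry copies with complex scattering
# factors f0(s) + f' + i f'', proper Bijvoet asymmetry, and multi-data-set
# systematic errors (overall scale, anisotropy perturbation, smooth local
# scale field, mis-reported uncertainties, intrinsic per-data-set anomalous
# perturbations).

#' Default parameters for a synthetic ground-truth crystal
#'
#' Desk-scale defaults: a triclinic P1 cell of roughly 33-39 angstroms,
#' d_min 2.4 angstroms (about 7000 unique reflections), five anomalous
#' sites with f'' = 4 electrons (selenium-like at the peak wavelength), and
#' a protein background of 900 carbon-like atoms at Wilson B 22. The P1
#' setting keeps the number of substructure copies small relative to the
#' reflection count, so the anomalous difference Patterson has the peak
#' contrast the skew metric relies on, while a full pipeline run still takes
#' seconds. Sohncke groups with rotational symmetry (e.g. P212121) are fully
#' supported and exercised separately.
#'
#' @param ... Overrides for any element of the parameter list.
#' @return Named list of truth parameters.
#' @export
truth_params <- function(...) {
  p <- list(
    cell = unit_cell(33, 36, 39, 85, 95, 100),
    spacegroup = "P1",
    d_min = 2.4,
    n_sites = 5,
    site_b = 18,
    site_occ = 1.0,
    fp = -8,          # f' at working wavelength, electrons
    fdp = 4,          # f'' at working wavelength, electrons
    f0_element = "Se",
    n_protein_atoms = 900,
    protein_b = 22,
    n_minor_sites = 0,      # low-occupancy extra anomalous scatterers
    minor_occ = 0.2,
    wavelength = 0.9792
  )
  modifyList(p, list(...))
}

#' Enumerate unique ASU reflections to a resolution limit
#' @noRd
enumerate_asu <- function(cell, spacegroup, d_min) {
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- d_spacing(grid$h, grid$k, grid$l, cell)
  grid <- grid[d >= d_min, ]
  asu <- map_to_asu(grid$h, grid$k, grid$l, spacegroup)
  uni <- distinct(asu[c("h", "k", "l")])
  uni$d <- d_spacing(uni$h, uni$k, uni$l, cell)
  uni$centric <- is_centric(uni$h, uni$k, uni$l, spacegroup)
  arrange(uni, dplyr::desc(.data$d), .data$h, .data$k, .data$l)
}

#' IT92 four-Gaussian form factor f0(s), s = sin(theta)/lambda = 1/(2d)
#' @noRd
f0_lookup <- function(element, s) {
  path <- system.file("extdata", "it92_formfactors.tsv", package = "anomsig")
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  row <- tab[tab$V1 == element, ]
  if (!nrow(row)) abort(sprintf("no f0 coefficients for element '%s'", element))
  a <- as.numeric(row[1, 2:5]); b <- as.numeric(row[1, 6:9]); cc <- as.numeric(row[1, 10])
  ssq <- s^2
  out <- rep(cc, length(s))
  for (i in 1:4) out <- out + a[i] * exp(-b[i] * ssq)
  out
}

# structure-factor sum over (symmetry-expanded) sites:
# G(h) = sum_j occ_j exp(-B_j s^2) exp(2 pi i h . x_j), s = sin(theta)/lambda
site_sum <- function(hkl, d, sites, spacegroup) {
  sg <- sg_ops(spacegroup)
  xs <- list()
  for (op in sg$ops) {
    xs[[length(xs) + 1]] <- cbind(
      frac = as.matrix(sites[, c("x", "y", "z")]) %*% t(op$R) +
        matrix(op$t, nrow(sites), 3, byrow = TRUE),
      occ = sites$occ, b = sites$b)
  }
  X <- do.call(rbind, xs)
  frac <- X[, 1:3] %% 1
  s <- 1 / (2 * d)
  phase <- (cbind(hkl) %*% t(frac)) # n_refl x n_sites, in cycles
  damp <- exp(-outer(s^2, X[, "b"]))
  occ <- matrix(X[, "occ"], nrow(hkl), nrow(X), byrow = TRUE)
  g <- (occ * damp * exp(2i * pi * phase)) %*% rep(1, nrow(X))
  list(g = as.complex(g), sites_expanded = frac)
}

#' Generate a ground-truth synthetic crystal
#'
#' Draws a protein structure-factor field with Wilson statistics (complex
#' Gaussian for acentric reflections; phase-restricted real Gaussian for
#' centrics), places `n_sites` anomalous scatterers at random positions, and
#' computes Bijvoet amplitudes `F+`, `F-` with the full complex scattering
#' factor `f0(s) + f' + i f''` summed over symmetry copies. Ideal anomalous
#' differences come from the same construction restricted to the main
#' substructure; optional minor scatterers contribute additional anomalous
#' differences that the ideal set excludes.
#'
#' @param params Parameter list from [truth_params()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `anomsig_truth` with elements `reflections`
#'   (tibble: indices, d, centric flag, true amplitudes, ideal anomalous
#'   difference, model phase), `sites` (fractional coordinates of the main
#'   substructure, all symmetry copies), `params`, and true-signal summaries
#'   `cc_ano_true` (1 unless minor scatterers are present) computed from the
#'   stored vectors.
#' @export
generate_truth <- function(params = truth_params(), seed = 1) {
  set.seed(seed)
  cell <- params$cell; sgname <- sg_ops(params$spacegroup)$name
  refl <- enumerate_asu(cell, sgname, params$d_min)
  n <- nrow(refl)
  s <- 1 / (2 * refl$d)

  # Wilson-like protein field
  f_c <- f0_lookup("C", s)
  sigma_n <- params$n_protein_atoms * f_c^2 * exp(-2 * params$protein_b * s^2)
  fp_re <- rnorm(n, 0, sqrt(sigma_n / 2))
  fp_im <- rnorm(n, 0, sqrt(sigma_n / 2))
  f_prot <- complex(real = fp_re, imaginary = fp_im)
  if (any(refl$centric)) {
    cen <- which(refl$centric)
    theta0 <- centric_phase(as.matrix(refl[cen, c("h", "k", "l")]), sgname)
    amp <- rnorm(length(cen), 0, sqrt(sigma_n[cen]))
    f_prot[cen] <- amp * exp(1i * theta0)
  }

  sites <- tibble(x = runif(params$n_sites), y = runif(params$n_sites),
                  z = runif(params$n_sites),
                  occ = params$site_occ, b = params$site_b)
  ss <- site_sum(as.matrix(refl[, c("h", "k", "l")]), refl$d, sites, sgname)
  f0s <- f0_lookup(params$f0_element, s)

  g_main <- ss$g
  g_all <- g_main
  if (params$n_minor_sites > 0) {
    minors <- tibble(x = runif(params$n_minor_sites), y = runif(params$n_minor_sites),
                     z = runif(params$n_minor_sites),
                     occ = params$minor_occ, b = params$site_b)
    g_all <- g_all + site_sum(as.matrix(refl[, c("h", "k", "l")]), refl$d,
                              minors, sgname)$g
  }

  bijvoet <- function(g) {
    f_r <- f_prot + (f0s + params$fp) * g
    list(f_plus = Mod(f_r + 1i * params$fdp * g),
         f_minus = Mod(f_r - 1i * params$fdp * g),
         phi = Arg(f_r))
  }
  tot <- bijvoet(g_all)
  ideal <- bijvoet(g_main)

  refl$f_plus <- tot$f_plus
  refl$f_minus <- tot$f_minus
  refl$dano_true <- tot$f_plus - tot$f_minus
  refl$dano_ideal <- ideal$f_plus - ideal$f_minus
  refl$phi_model <- tot$phi

  ac <- !refl$centric
  cc_true <- if (params$n_minor_sites > 0)
    cor(refl$dano_true[ac], refl$dano_ideal[ac]) else 1.0

  sites_tbl <- tibble(x = ss$sites_expanded[, 1], y = ss$sites_expanded[, 2],
                      z = ss$sites_expanded[, 3])
  structure(list(reflections = refl, sites = sites_tbl,
                 cell = cell, spacegroup = sgname,
                 params = params, cc_ano_true = cc_true, seed = seed),
            class = "anomsig_truth")
}

# restricted phase for centric h: phi = pi * (h . t) for the op with hR = -h
centric_phase <- function(hkl, spacegroup) {
  sg <- sg_ops(spacegroup)
  out <- numeric(nrow(hkl))
  done <- rep(FALSE, nrow(hkl))
  for (op in sg$ops) {
    img <- hkl %*% op$R
    hit <- !done & (rowSums(img == -hkl) == 3)
    if (any(hit)) {
      out[hit] <- pi * as.numeric(hkl[hit, , drop = FALSE] %*% op$t)
      done[hit] <- TRUE
    }
  }
  out
}

#' @export
print.anomsig_truth <- function(x, ...) {
  cat(sprintf("Synthetic SAD truth: %s, %d unique reflections to %.2f A, %d site(s), f''=%.2f e-\n",
              x$spacegroup, nrow(x$reflections), x$params$d_min,
              x$params$n_sites, x$params$fdp))
  invisible(x)
}

#' Default noise model for simulated unmerged observations
#'
#' `sig_f_frac` expresses measurement noise on amplitudes as a fraction of
#' the rms ideal anomalous difference, so a value of 1 puts the noise at the
#' size of the signal. `sig_truth_c` mis-reports uncertainties (reported
#' sigma = true sigma / c), `d_intrinsic_frac` adds an antisymmetric
#' per-data-set perturbation of the Bijvoet pair (an intrinsic inter-data-set
#' difference) as a fraction of the rms anomalous difference, and the smooth
#' local field emulates slowly varying systematic errors that local scaling
#' should remove.
#'
#' @param ... Overrides for any element.
#' @return Named list describing the per-data-set error model.
#' @export
noise_model <- function(...) {
  p <- list(
    sig_f_frac = 0.5,
    sig_f_abs = NULL,       # absolute per-amplitude sigma; overrides sig_f_frac
    noise_b = 22,           # A^2; sigma grows as exp(noise_b s^2), s = sin(theta)/lambda
    scale_sd = 0.15,        # lognormal overall scale spread
    aniso_sd = 3,           # A^2 spread of anisotropy perturbation tensors
    local_amp = 0.10,       # amplitude of smooth local-scale field (log scale)
    local_waves = 3,        # cosine components of the field
    local_bandwidth = 1.5,  # cycles across the index range (low = smooth)
    sig_truth_c = 1.0,      # reported sigma = true sigma / c
    d_intrinsic_frac = 0.0, # intrinsic anomalous perturbation / rms(dano)
    d_intrinsic_sym_frac = NULL, # intrinsic mean-amplitude perturbation;
                                 # default half the anomalous one (crystal-to-
                                 # crystal differences hit the anomalous
                                 # differences harder than the averaged
                                 # amplitudes, as when wavelengths drift)
    multiplicity = 2L,      # observations of each Bijvoet mate
    coverage = 0.97         # fraction of unique reflections observed
  )
  modifyList(p, list(...))
}

#' Simulate unmerged multi-crystal observations from a truth object
#'
#' Each data set applies its own overall scale, anisotropy perturbation and
#' smooth local scale field to the true amplitudes, adds Gaussian
#' measurement noise, optionally perturbs the Bijvoet pair antisymmetrically
#' (intrinsic inter-data-set differences), and emits intensity observations
#' grouped by unique reflection in measurement order, Bijvoet-plus records
#' before Bijvoet-minus records, so the order-based sub-data-set splitting
#' rule applies.
#'
#' @param truth From [generate_truth()].
#' @param n_datasets Number of data sets (crystals) to simulate.
#' @param noise A [noise_model()]; either one model for all data sets or a
#'   list of one model per data set.
#' @param seed Integer seed.
#' @return List of `anomsig_unmerged` objects, one per data set.
#' @export
simulate_unmerged <- function(truth, n_datasets = 2, noise = noise_model(),
                              seed = 1) {
  set.seed(seed + 7919L)
  per_ds <- if (!is.null(noise$multiplicity)) rep(list(noise), n_datasets)
            else noise
  stopifnot(length(per_ds) == n_datasets)
  refl <- truth$reflections
  B <- recip_cart_matrix(truth$cell)
  xyz <- t(B %*% t(as.matrix(refl[, c("h", "k", "l")])))
  rms_dano <- sqrt(mean(refl$dano_ideal[!refl$centric]^2))
  hmax <- apply(abs(as.matrix(refl[, c("h", "k", "l")])), 2, max)

  out <- vector("list", n_datasets)
  for (ds in seq_len(n_datasets)) {
    nm <- per_ds[[ds]]
    scale <- exp(rnorm(1, 0, nm$scale_sd))
    U <- random_sym_tensor(nm$aniso_sd)
    aniso_fac <- exp(-rowSums((xyz %*% U) * xyz) / 4)
    field_fn <- smooth_field_fn(hmax, nm$local_amp, nm$local_waves,
                                nm$local_bandwidth)
    H <- as.matrix(refl[, c("h", "k", "l")])
    field_plus <- field_fn(H)    # mates sit at opposite reciprocal positions,
    field_minus <- field_fn(-H)  # so each sees its own value of the field
    base_sig <- if (!is.null(nm$sig_f_abs)) nm$sig_f_abs
                else nm$sig_f_frac * rms_dano / sqrt(2)
    s_refl <- 1 / (2 * refl$d)
    prof <- exp(nm$noise_b * s_refl^2)
    sig_f <- base_sig * prof / sqrt(mean(prof^2))  # per-reflection sigma
    keep <- runif(nrow(refl)) < nm$coverage
    delta <- if (nm$d_intrinsic_frac > 0)
      rnorm(nrow(refl), 0, nm$d_intrinsic_frac * rms_dano) else numeric(nrow(refl))
    sym_frac <- nm$d_intrinsic_sym_frac %||% (0.5 * nm$d_intrinsic_frac)
    delta_sym <- if (sym_frac > 0)
      rnorm(nrow(refl), 0, sym_frac * rms_dano) else numeric(nrow(refl))

    rows <- list(); ri <- 1L
    mult <- nm$multiplicity
    g_plus <- scale * aniso_fac * field_plus
    g_minus <- scale * aniso_fac * field_minus
    for (m in seq_len(mult)) {
      fp_obs <- (refl$f_plus + delta / 2 + delta_sym) * g_plus +
        rnorm(nrow(refl), 0, sig_f)
      fm_obs <- (refl$f_minus - delta / 2 + delta_sym) * g_minus +
        rnorm(nrow(refl), 0, sig_f)
      rows[[ri]] <- tibble(uid = seq_len(nrow(refl)), pass = m, mate = 1L,
                           h = refl$h, k = refl$k, l = refl$l, f = fp_obs)
      ri <- ri + 1L
      acn <- !refl$centric
      rows[[ri]] <- tibble(uid = which(acn), pass = m, mate = 2L,
                           h = -refl$h[acn], k = -refl$k[acn], l = -refl$l[acn],
                           f = fm_obs[acn])
      ri <- ri + 1L
    }
    obs <- bind_rows(rows)
    obs <- obs[keep[obs$uid], ]
    # group by unique reflection, mates interleaved in measurement order
    obs <- arrange(obs, .data$uid, .data$pass, .data$mate)
    f_pos <- pmax(obs$f, 0)
    sig_true <- sig_f[obs$uid]
    obs$i_obs <- sign(obs$f) * obs$f^2
    obs$sig_i <- 2 * pmax(f_pos, sig_true) * sig_true / nm$sig_truth_c
    obs$dataset_id <- sprintf("xtal%02d", ds)
    out[[ds]] <- unmerged_dataset(obs[, c("h", "k", "l", "i_obs", "sig_i", "dataset_id")],
                                  truth$cell, truth$spacegroup,
                                  truth$params$wavelength)
  }
  out
}

random_sym_tensor <- function(sd) {
  if (sd <= 0) return(matrix(0, 3, 3))
  d <- rnorm(3, 0, sd); o <- rnorm(3, 0, sd / 2)
  m <- diag(d)
  m[1, 2] <- m[2, 1] <- o[1]; m[1, 3] <- m[3, 1] <- o[2]; m[2, 3] <- m[3, 2] <- o[3]
  m - diag(rep(mean(d), 3))  # trace-free: overall scale handled separately
}

# returns a function evaluating one realization of a smooth log-scale field
# at arbitrary Miller indices (so Bijvoet mates at +h and -h get their own
# values)
smooth_field_fn <- function(hmax, amp, n_waves, bandwidth) {
  if (amp <= 0 || n_waves == 0) return(function(hkl) rep(1, nrow(hkl)))
  us <- lapply(seq_len(n_waves), function(w) {
    u <- rnorm(3); u / sqrt(sum(u^2)) * bandwidth / (2 * pmax(hmax, 1))
  })
  phs <- runif(n_waves, 0, 2 * pi)
  function(hkl) {
    lg <- numeric(nrow(hkl))
    for (w in seq_len(n_waves)) {
      lg <- lg + (amp / sqrt(n_waves)) *
        cos(2 * pi * as.numeric(hkl %*% us[[w]]) + phs[w])
    }
    exp(lg)
  }
}

#' Seeded corpus of graded synthetic SAD cases
#'
#' Generates `n` crystals whose measurement noise and site counts are graded
#' so the true useful anomalous correlation spans roughly 0.05-0.95,
#' standing in for a large trained corpus at desk scale. Used for estimator
#' training and cross-validation.
#'
#' @param seed Integer seed.
#' @param n Number of corpus members (default 30).
#' @param n_datasets Data sets per member (default 2).
#' @param d_min Resolution limit for all members.
#' @param sig_truth_range If non-`NULL`, a length-2 range from which each
#'   member's sigma-truthfulness factor is drawn (log-uniform).
#' @return List of `n` elements, each a list with `truth`, `datasets`, and
#'   the member's `noise` model.
#' @export
graded_corpus <- function(seed = 1, n = 30, n_datasets = 2, d_min = 2.4,
                          sig_truth_range = NULL) {
  set.seed(seed)
  noise_levels <- exp(seq(log(0.25), log(6), length.out = n))
  site_counts <- rep(c(5L, 6L, 7L, 8L), length.out = n)
  member_seeds <- sample.int(1e6, 2 * n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    params <- truth_params(n_sites = site_counts[i], d_min = d_min)
    truth <- generate_truth(params, seed = member_seeds[i])
    ctruth <- if (is.null(sig_truth_range)) 1.0 else
      exp(runif(1, log(sig_truth_range[1]), log(sig_truth_range[2])))
    nm <- noise_model(sig_f_frac = noise_levels[i], sig_truth_c = ctruth)
    datasets <- simulate_unmerged(truth, n_datasets, nm,
                                  seed = member_seeds[n + i])
    out[[i]] <- list(truth = truth, datasets = datasets, noise = nm)
  }
  out
}
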