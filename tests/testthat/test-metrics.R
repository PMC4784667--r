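test_that("the CC* estimate has the right closed forms and limits", {
  # w = 1 closed form at CC_1/2 in {0, 1/3, 1}
  expect_equal(estimated_cc_star_squared(0, 1), 0)
  expect_equal(estimated_cc_star_squared(1 / 3, 1), 0.5)
  expect_equal(estimated_cc_star_squared(1, 1), 1)
  # monotone increasing in cc_half at fixed w
  for (w in c(0.3, 0.7, 1)) {
    vals <- vapply(seq(-0.5, 1, 0.1), estimated_cc_star_squared,
                   numeric(1), w = w)
    expect_true(all(diff(vals) > 0))
  }
  # negative cc_half carries its sign through
  expect_lt(estimated_cc_star_squared(-0.2, 1), 0)
  # singular point flagged
  expect_warning(out <- estimated_cc_star_squared(-1, 1), "undefined")
  expect_true(is.na(out))
  # fewer repeated measurements shrink the estimate toward cc_half
  expect_lt(estimated_cc_star_squared(0.5, 0.2), estimated_cc_star_squared(0.5, 1))
})

test_that("half data sets from identical crystals correlate perfectly", {
  truth <- tiny_truth()
  nm <- noise_model(sig_f_frac = 0, scale_sd = 0, aniso_sd = 0, local_amp = 0,
                    multiplicity = 1L, coverage = 1)
  ds <- simulate_unmerged(truth, 1, nm, seed = 41)[[1]]
  twin <- ds
  twin$dataset_id <- "twin"
  twin <- unmerged_dataset(tibble::as_tibble(twin)[, c("h", "k", "l", "i_obs",
                                                       "sig_i", "dataset_id")],
                           truth$cell, truth$spacegroup)
  pair <- suppressWarnings(split_half_datasets(list(ds, twin), anisotropy = FALSE))
  hc <- half_dataset_cc_ano(pair)
  expect_equal(hc$cc_half, 1, tolerance = 1e-8)
  expect_gt(hc$w, 0.99)
})

test_that("half-set correlation is -1 when one half's differences are negated", {
  set.seed(5)
  cell <- unit_cell(30, 35, 40)
  base <- tibble::tibble(h = 1:100, k = 2L, l = 3L, d = 3,
                         f_plus = runif(100, 50, 150), sig_plus = 1,
                         f_minus = runif(100, 50, 150), sig_minus = 1, n_obs = 1L)
  m1 <- new_merged(base, cell, "P1")
  flipped <- base
  flipped$f_plus <- base$f_minus; flipped$f_minus <- base$f_plus
  m2 <- new_merged(flipped, cell, "P1")
  pair <- structure(list(half1 = m1, half2 = m2, w = 1), class = "anomsig_halfset")
  expect_equal(half_dataset_cc_ano(pair)$cc_half, -1)
  short <- structure(list(half1 = m1[1:2, ], half2 = m2[1:2, ], w = 1),
                     class = "anomsig_halfset")
  expect_warning(out <- half_dataset_cc_ano(short), "undefined")
  expect_true(is.na(out$cc_half))
})

test_that("half-set correlation reflects the signal-to-noise construction", {
  # two halves sharing a common signal with independent noise of equal
  # variance have expected correlation 1/2
  set.seed(9)
  cell <- unit_cell(30, 35, 40)
  n <- 4000
  signal <- rnorm(n, 0, 3)
  mk <- function(noise) {
    new_merged(tibble::tibble(h = seq_len(n), k = 0L, l = 1L, d = 3,
                              f_plus = 100 + (signal + noise) / 2, sig_plus = 1,
                              f_minus = 100 - (signal + noise) / 2, sig_minus = 1,
                              n_obs = 1L), cell, "P1")
  }
  pair <- structure(list(half1 = mk(rnorm(n, 0, 3)), half2 = mk(rnorm(n, 0, 3)),
                         w = 1), class = "anomsig_halfset")
  expect_equal(half_dataset_cc_ano(pair)$cc_half, 0.5, tolerance = 0.05)
})

test_that("map synthesis matches a direct Fourier summation oracle", {
  cell <- unit_cell(20, 24, 28)
  hkl <- matrix(c(2, 1, 3), 1, 3)
  coef <- complex(modulus = 5, argument = 0.7)
  map <- fourier_map(hkl, coef, cell, "P1", grid_spacing = 2.5)
  dims <- dim(map)
  # direct sum: rho(x) = 2 * Re(C exp(-2 pi i h.x)) for one index + its mate
  for (pt in list(c(0, 0, 0), c(1, 2, 3), c(4, 1, 5))) {
    x <- pt / dims
    direct <- 2 * Re(coef * exp(-2i * pi * sum(hkl * x)))
    expect_equal(map[pt[1] + 1, pt[2] + 1, pt[3] + 1], direct, tolerance = 1e-9)
  }
})

test_that("Patterson maps are centrosymmetric and flat for constant coefficients", {
  truth <- tiny_truth()
  m <- merged_from_truth(truth)
  pat <- anomalous_difference_patterson(m[1:400, ])
  dims <- dim(pat)
  idx <- rbind(c(2, 3, 4), c(5, 1, 2), c(3, 3, 3))
  for (i in seq_len(nrow(idx))) {
    u <- idx[i, ]
    mu <- ((dims - u) %% dims) + 1   # -u modulo grid, 1-based
    expect_equal(pat[u[1] + 1, u[2] + 1, u[3] + 1],
                 pat[mu[1], mu[2], mu[3]], tolerance = 1e-8)
  }
  # all dano^2 equal within a shell -> origin removal zeroes every coefficient
  flat <- m[1:400, ]
  flat$dano <- 3
  flat$f_plus <- flat$f_mean + 1.5; flat$f_minus <- flat$f_mean - 1.5
  flat <- new_merged(tibble::as_tibble(flat)[, c("h", "k", "l", "d", "f_plus",
                                                 "sig_plus", "f_minus",
                                                 "sig_minus", "n_obs")],
                     truth$cell, truth$spacegroup)
  pat0 <- anomalous_difference_patterson(flat)
  expect_lt(max(abs(pat0)), 1e-8)
})

test_that("skew follows brute-force moments, flips sign, and ignores scale", {
  set.seed(13)
  base <- array(rnorm(4000), dim = c(20, 20, 10))
  spike <- base
  spike[1, 1, 1] <- 50   # one strong positive peak
  s <- patterson_skew(spike)
  # brute-force oracle with the same truncation recipe
  v <- as.numeric(spike); v <- v - mean(v)
  sg <- sqrt(mean(v^2))
  v <- pmin(pmax(v, -4 * sg), 4 * sg); v <- v - mean(v)
  expect_equal(s, mean(v^3) / mean(v^2)^1.5)
  expect_gt(s, 0)
  expect_equal(patterson_skew(-spike), -s)
  expect_equal(patterson_skew(spike * 7.3), s)
  sym <- array(c(-2, -1, 0, 1, 2), dim = c(5, 1, 1))
  expect_equal(patterson_skew(sym), 0)
  expect_equal(patterson_skew(array(1, dim = c(3, 3, 3))), 0)
})

test_that("native-Patterson truncation only acts where the native map is extreme", {
  set.seed(14)
  anom <- array(rnorm(1000), dim = c(10, 10, 10))
  anom[2, 2, 2] <- 3.9 * sd(anom)     # below 4 sigma, above 3 sigma
  native <- array(0, dim = c(10, 10, 10))
  s_plain <- patterson_skew(anom)
  expect_equal(patterson_skew(anom, native, use_tns = TRUE), s_plain,
               tolerance = 1e-6)
  native[2, 2, 2] <- 100              # flag that point as tNCS-like
  s_tns <- patterson_skew(anom, native, use_tns = TRUE)
  expect_lt(s_tns, s_plain)
  expect_error(patterson_skew(anom, native[1:5, , ], use_tns = TRUE), "grid")
})

test_that("sigma rescaling recovers flat trends and mis-scaled uncertainties", {
  cell <- unit_cell(30, 35, 40)
  set.seed(17)
  n <- 2000
  # flat trends: rms dano = 3, rms sigma = 1 in every shell -> beta = 3
  m <- new_merged(tibble::tibble(h = seq_len(n), k = 0L, l = 1L,
                                 d = seq(8, 2.5, length.out = n),
                                 f_plus = 100 + rnorm(n, 0, 3) / 2, sig_plus = sqrt(0.5),
                                 f_minus = 100 - rnorm(n, 0, 3) / 2, sig_minus = sqrt(0.5),
                                 n_obs = 1L), cell, "P1")
  m$dano <- rnorm(n, 0, 3)
  beta <- rescale_sigmas(m)$beta
  expect_equal(beta, 3, tolerance = 0.1)
  # idempotence: after applying beta, re-estimation gives ~1
  m2 <- m
  m2$sig_dano <- m2$sig_dano * beta
  expect_equal(rescale_sigmas(m2)$beta, 1, tolerance = 0.05)
  expect_error(rescale_sigmas(m[1:5, ], n_bins = 2), "3 resolution shells")
})

test_that("sigma rescaling recovers the truthfulness factor through the pipeline", {
  truth <- generate_truth(truth_params(fdp = 0, d_min = 3.0), seed = 55)
  ds <- simulate_unmerged(truth, 1, noise_model(sig_f_abs = 4, sig_truth_c = 2),
                          seed = 56)
  sm <- suppressWarnings(scale_and_merge(ds, variance_mode = "off"))
  beta <- rescale_sigmas(sm$merged)$beta
  expect_equal(beta, 2, tolerance = 0.1)
  # highest-shell normalized error is ~1 after rescaling, by construction
  shell <- resolution_shells(sm$merged$d, 10)
  hs <- sm$merged[shell == max(shell), ]
  expect_equal(normalized_error(hs, beta), 1, tolerance = 0.15)
})

test_that("normalized error reflects the variance bookkeeping", {
  cell <- unit_cell(30, 35, 40)
  set.seed(19)
  n <- 5000
  noise_sd <- 2
  signal <- rnorm(n, 0, sqrt(3) * noise_sd)   # signal variance 3x noise
  m <- new_merged(tibble::tibble(h = seq_len(n), k = 0L, l = 1L, d = 3,
                                 f_plus = 100, sig_plus = noise_sd / sqrt(2),
                                 f_minus = 100, sig_minus = noise_sd / sqrt(2),
                                 n_obs = 1L), cell, "P1")
  m$dano <- signal + rnorm(n, 0, noise_sd)
  expect_equal(normalized_error(m, beta = 1), 0.5, tolerance = 0.03)
  # monotone: growing signal lowers e
  es <- vapply(c(0, 1, 2, 4), function(a) {
    mm <- m; mm$dano <- a * signal + rnorm(n, 0, noise_sd)
    normalized_error(mm, 1)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
  m0 <- m; m0$dano <- rep(0, n)
  expect_warning(out <- normalized_error(m0, 1), "undefined")
  expect_true(is.na(out))
})

test_that("expected CC_ano from e has the right limits and matches simulation", {
  expect_equal(cc_ano_expected_from_e(0), 1)
  expect_equal(cc_ano_expected_from_e(1), 0)
  ee <- seq(0, 1, 0.05)
  expect_true(all(diff(cc_ano_expected_from_e(ee)) < 0))
  expect_warning(out <- cc_ano_expected_from_e(1.2), "clamped")
  expect_equal(out, 0)
  # simulation cross-check: noise scaled so e = 0.6 -> CC = sqrt(1 - 0.36)
  set.seed(23)
  n <- 20000
  true_d <- rnorm(n, 0, 4)
  e_target <- 0.6
  noise_sd <- 4 * e_target / sqrt(1 - e_target^2)
  obs <- true_d + rnorm(n, 0, noise_sd)
  e_emp <- sqrt(noise_sd^2 / mean(obs^2))
  expect_equal(cor(obs, true_d), cc_ano_expected_from_e(e_emp), tolerance = 0.02)
})

test_that("useful anomalous correlation is scale-invariant and matches cor()", {
  truth <- tiny_truth()
  m <- merged_from_truth(truth)
  ideal <- truth$reflections[, c("h", "k", "l", "dano_ideal")]
  expect_equal(useful_anomalous_correlation(m, ideal), 1)
  m2 <- m
  m2$dano <- 2 * m2$dano
  expect_equal(useful_anomalous_correlation(m2, ideal), 1)
  set.seed(29)
  m3 <- m
  m3$dano <- m3$dano + rnorm(nrow(m3), 0, 5)
  j <- dplyr::inner_join(tibble::as_tibble(m3)[, c("h", "k", "l", "dano")],
                         ideal, by = c("h", "k", "l"))
  expect_equal(useful_anomalous_correlation(m3, ideal),
               cor(j$dano, j$dano_ideal))
})

test_that("the observed anomalous signal peaks at substructure sites", {
  truth <- tiny_truth()
  r <- truth$reflections
  m <- merged_from_truth(truth)
  sa <- anomalous_signal_observed(m, r$phi_model, truth$sites)
  expect_gt(sa$s_ano, 5)
  expect_true(all(sa$site_values > 2))
  # rms normalization: doubling all differences leaves S_ano unchanged
  m2 <- m
  m2$f_plus <- m2$f_mean + m2$dano; m2$f_minus <- m2$f_mean - m2$dano
  m2 <- new_merged(tibble::as_tibble(m2)[, c("h", "k", "l", "d", "f_plus",
                                             "sig_plus", "f_minus", "sig_minus",
                                             "n_obs")], truth$cell, truth$spacegroup)
  sa2 <- anomalous_signal_observed(m2, r$phi_model, truth$sites)
  expect_equal(sa2$s_ano, sa$s_ano, tolerance = 1e-6)
  # null case: random differences give no mean site signal
  set.seed(31)
  vals <- vapply(1:5, function(i) {
    mr <- m
    mr$dano <- rnorm(nrow(mr), 0, 5)
    mr$f_plus <- mr$f_mean + mr$dano / 2; mr$f_minus <- mr$f_mean - mr$dano / 2
    mr <- new_merged(tibble::as_tibble(mr)[, c("h", "k", "l", "d", "f_plus",
                                               "sig_plus", "f_minus", "sig_minus",
                                               "n_obs")], truth$cell, truth$spacegroup)
    anomalous_signal_observed(mr, r$phi_model, truth$sites)$s_ano
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("site peak heights match a direct summation oracle", {
  truth <- tiny_truth()
  r <- truth$reflections
  m <- merged_from_truth(truth)
  coef <- m$dano * exp(1i * (r$phi_model - pi / 2))
  ex <- expand_to_p1(as.matrix(m[, c("h", "k", "l")]), coef, truth$spacegroup)
  site <- as.numeric(truth$sites[1, ])
  direct <- Re(sum(ex$f * exp(-2i * pi * as.numeric(ex$hkl %*% site))))
  sa <- anomalous_signal_observed(m, r$phi_model, truth$sites,
                                  grid_spacing = 0.5)
  map_rms <- attr(sa$map, "rms")
  expect_equal(sa$site_values[1], direct / map_rms, tolerance = 0.05)
})

test_that("quality metrics are packaged consistently", {
  dss <- tiny_datasets()
  sm <- tiny_merge()
  qm <- suppressWarnings(quality_metrics(sm, unmerged = dss))
  g <- glance(qm)
  expect_true(all(c("e2", "cc_half", "w", "skew", "beta", "e") %in% names(g)))
  expect_gt(g$e2, 0)
  expect_gt(g$beta, 0)
  expect_true(g$e > 0 && g$e < 1.2)
  expect_equal(estimated_cc_star_squared(g$cc_half, g$w), g$e2)
  td <- tidy(qm)
  expect_equal(nrow(td), 6)
})
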