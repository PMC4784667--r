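# Seven-step scaling and merging of multi-crystal SAD data:
# (i) group data sets by unit cell, (ii) homogenize anisotropy,
# (iii) split into sub-data sets with one observation per full-sphere index,
# (iv) local scaling, (v) overall scaling to a provisional merge,
# (vi) inter-data-set variance estimation, (vii) variance-weighted merging.

#' Group data sets with similar unit cells
#'
#' Builds groups of mutually compatible cells (lengths within
#' `length_tol_fraction`, angles within `angle_tol_deg`, or the alternative
#' d_min-fraction criterion) and returns the group with the largest total
#' number of measured reflections; the rest are set aside and reported.
#'
#' @param datasets List of `anomsig_unmerged` objects.
#' @inheritParams cells_similar
#' @return List with `selected` (data sets in the winning group),
#'   `discarded` (the rest) and `group_index` (the winning indices).
#' @export
group_by_unit_cell <- function(datasets, length_tol_fraction = 0.01,
                               angle_tol_deg = 1.0, alt_dmin_fraction = NULL) {
  if (!length(datasets)) abort("no data sets supplied")
  n <- length(datasets)
  counts <- vapply(datasets, nrow, integer(1))
  d_min <- min(vapply(datasets, function(d)
    min(d_spacing(d$h, d$k, d$l, get_cell(d))), numeric(1)))
  compat <- function(i, j) cells_similar(get_cell(datasets[[i]]), get_cell(datasets[[j]]),
                                         length_tol_fraction, angle_tol_deg,
                                         alt_dmin_fraction, d_min = d_min)
  best <- integer(0); best_total <- -1
  order_by_count <- order(counts, decreasing = TRUE)
  for (seed_i in seq_len(n)) {
    grp <- seed_i
    for (j in order_by_count) {
      if (j == seed_i) next
      if (all(vapply(grp, function(g) compat(g, j), logical(1)))) grp <- c(grp, j)
    }
    tot <- sum(counts[grp])
    if (tot > best_total) { best_total <- tot; best <- sort(grp) }
  }
  list(selected = datasets[best], discarded = datasets[setdiff(seq_len(n), best)],
       group_index = best)
}

#' Anisotropic fall-off model of a data set
#'
#' Fits `ln I = c - x' U x / 2` where `x` is the Cartesian
#' reciprocal-lattice vector, so that for isotropic decay `U` equals the
#' Wilson B value times the identity. Rank-deficient fits fall back to an
#' isotropic model with a warning.
#'
#' @param dataset An `anomsig_unmerged` object.
#' @param min_obs Minimum positive-intensity observations required.
#' @return List of class `anomsig_aniso` with symmetric 3x3 tensor `U`
#'   (angstrom^2) and overall `log_scale`.
#' @export
fit_anisotropy <- function(dataset, min_obs = 50) {
  obs <- dataset[dataset$i_obs > 0, ]
  if (nrow(obs) < min_obs) abort("too few positive observations to fit anisotropy")
  B <- recip_cart_matrix(get_cell(dataset))
  x <- t(B %*% t(cbind(obs$h, obs$k, obs$l)))
  X <- cbind(x[, 1]^2, x[, 2]^2, x[, 3]^2,
             x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3])
  fit <- lm.fit(cbind(1, X), log(obs$i_obs))
  cf <- fit$coefficients
  if (any(is.na(cf))) {
    warn("anisotropy fit is rank-deficient; falling back to isotropic model")
    ssq <- rowSums(x^2)
    iso <- lm.fit(cbind(1, ssq), log(obs$i_obs))$coefficients
    U <- diag(rep(-2 * iso[2], 3))
    return(structure(list(U = U, log_scale = unname(iso[1])), class = "anomsig_aniso"))
  }
  U <- matrix(c(-2 * cf[2], -cf[5], -cf[6],
                -cf[5], -2 * cf[3], -cf[7],
                -cf[6], -cf[7], -2 * cf[4]), 3, 3)
  structure(list(U = U, log_scale = unname(cf[1])), class = "anomsig_aniso")
}

#' @rdname fit_anisotropy
#' @param models List of `anomsig_aniso` fits.
#' @export
average_anisotropy <- function(models) {
  U <- Reduce(`+`, lapply(models, `[[`, "U")) / length(models)
  structure(list(U = U,
                 log_scale = mean(vapply(models, `[[`, numeric(1), "log_scale"))),
            class = "anomsig_aniso")
}

#' @rdname fit_anisotropy
#' @param own_model,avg_model This data set's fit and the ensemble average.
#' @return [apply_to_average_anisotropy()] returns the adjusted data set:
#'   intensities multiplied by `exp(-x'(U_avg - U_own)x / 2)` so that
#'   re-fitting recovers the average tensor while the ensemble mean fall-off
#'   is preserved.
#' @export
apply_to_average_anisotropy <- function(dataset, own_model, avg_model) {
  B <- recip_cart_matrix(get_cell(dataset))
  x <- t(B %*% t(cbind(dataset$h, dataset$k, dataset$l)))
  dU <- avg_model$U - own_model$U
  fac <- exp(-rowSums((x %*% dU) * x) / 2)
  dataset$i_obs <- dataset$i_obs * fac
  dataset$sig_i <- dataset$sig_i * fac
  dataset
}

#' Split a data set into sub-data sets with unique indices
#'
#' Observations are processed in file order; an observation whose
#' full-sphere index has already appeared n times goes to sub-data set
#' n + 1, so symmetry-related groups ordered by measurement fall into
#' successive sub-data sets, each holding at most one observation of every
#' index. Sub-data sets with fewer than `discard_frac` of the largest
#' sibling's reflections are discarded, and acentric observations whose
#' Bijvoet mate is absent from the same sub-data set are excluded.
#'
#' @param dataset An `anomsig_unmerged` object (a single crystal's data).
#' @param discard_frac Discard threshold relative to the largest sub-data
#'   set (default 0.30).
#' @return List of sub-data set tibbles (columns of the parent plus ASU
#'   columns `ah`, `ak`, `al`, `friedel_minus`, `centric`), with attribute
#'   `"n_discarded"`.
#' @export
split_into_subdatasets <- function(dataset, discard_frac = 0.30) {
  key <- hkl_key(dataset$h, dataset$k, dataset$l)
  occ <- stats::ave(rep(1, nrow(dataset)), key, FUN = cumsum)
  asu <- map_to_asu(dataset$h, dataset$k, dataset$l, get_spacegroup(dataset))
  dat <- as_tibble(dataset)
  dat$ah <- asu$h; dat$ak <- asu$k; dat$al <- asu$l
  dat$friedel_minus <- asu$friedel_minus
  dat$centric <- is_centric(asu$h, asu$k, asu$l, get_spacegroup(dataset))
  dat$sub_id <- as.integer(occ)
  subs <- split(dat, dat$sub_id)
  sizes <- vapply(subs, nrow, integer(1))
  keep <- sizes >= discard_frac * max(sizes)
  n_discarded <- sum(!keep)
  subs <- subs[keep]
  subs <- lapply(subs, function(s) {
    akey <- hkl_key(s$ah, s$ak, s$al)
    has_plus <- akey %in% akey[!s$friedel_minus]
    has_minus <- akey %in% akey[s$friedel_minus]
    s[s$centric | (has_plus & has_minus), ]
  })
  attr(subs, "n_discarded") <- n_discarded
  subs
}

# ordered integer offsets around the origin, sorted by Cartesian
# reciprocal-space norm, symmetric pairs (+d, -d) adjacent
neighbor_offsets <- function(cell, radius) {
  g <- expand.grid(h = -radius:radius, k = -radius:radius, l = -radius:radius)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  B <- recip_cart_matrix(cell)
  nrm <- sqrt(colSums((B %*% t(as.matrix(g)))^2))
  # keep one of each +-pair, then interleave with its mate
  lead <- g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  gl <- g[lead, ]; nl <- nrm[lead]
  ord <- order(nl)
  gl <- gl[ord, ]
  out <- matrix(0L, 2 * nrow(gl), 3)
  out[seq(1, nrow(out), 2), ] <- as.matrix(gl)
  out[seq(2, nrow(out), 2), ] <- -as.matrix(gl)
  out
}

#' Per-reflection local scale factors
#'
#' For each query reflection, at least `k_neighbors` nearby reflections
#' (nearest in Cartesian reciprocal space, taken in symmetric +/- offset
#' pairs when both are present) are gathered from the data set, and the
#' scale is the ratio of summed target amplitudes to summed own amplitudes
#' over the neighborhood. If too few neighbors are found the search radius
#' widens; queries that still fail get unit scale with a warning.
#'
#' @param query_hkl Integer matrix (m x 3) of reflections to scale.
#' @param data_hkl Integer matrix (n x 3) of reflections available as
#'   neighbors (the data set being scaled).
#' @param f_own,f_target Own and target amplitudes aligned with `data_hkl`.
#' @param cell Unit cell (defines the neighbor metric).
#' @param k_neighbors Minimum neighbors per scale factor (default 30).
#' @param min_neighbors Hard floor below which unit scale is used.
#' @return Numeric vector of scale factors, one per query.
#' @export
local_scale_factors <- function(query_hkl, data_hkl, f_own, f_target, cell,
                                k_neighbors = 30, min_neighbors = 10) {
  dkeys <- hkl_key(data_hkl[, 1], data_hkl[, 2], data_hkl[, 3])
  qkeys <- hkl_key(query_hkl[, 1], query_hkl[, 2], query_hkl[, 3])
  run <- function(qk, offs) {
    # hkl_key is linear in (h, k, l), so neighbor keys are additive offsets
    okeys <- offs[, 1] * 1048576 + offs[, 2] * 1024 + offs[, 3]
    idx <- matrix(match(outer(qk, okeys, "+"), dkeys), length(qk), length(okeys))
    P <- !is.na(idx)
    cnt <- t(apply(P, 1, cumsum))
    include <- P & (cnt <= k_neighbors)
    tv <- matrix(f_target[idx], nrow(idx)); tv[!include] <- 0
    ov <- matrix(f_own[idx], nrow(idx)); ov[!include] <- 0
    list(num = rowSums(tv), den = rowSums(ov),
         cnt = pmin(cnt[, ncol(cnt)], k_neighbors))
  }
  offs_near <- neighbor_offsets(cell, 3L)
  k_first <- min(nrow(offs_near), max(2L * k_neighbors, 64L))
  r <- run(qkeys, offs_near[seq_len(k_first), , drop = FALSE])
  short <- r$cnt < k_neighbors
  if (any(short)) {
    r2 <- run(qkeys[short], neighbor_offsets(cell, 6L))
    r$num[short] <- r2$num; r$den[short] <- r2$den; r$cnt[short] <- r2$cnt
  }
  scale <- ifelse(r$den > 0, r$num / r$den, 1)
  bad <- r$cnt < min_neighbors
  if (any(bad)) {
    warn(sprintf("%d reflection(s) had fewer than %d local-scaling neighbors; unit scale used",
                 sum(bad), min_neighbors))
    scale[bad] <- 1
  }
  scale
}

# aggregate a sub-data set to one amplitude per (ASU index, Bijvoet mate),
# inverse-variance weighted; vectorized via rowsum for speed
aggregate_amplitudes <- function(sub) {
  fa <- intensity_to_amplitude(sub$i_obs, sub$sig_i)
  key <- hkl_key(sub$ah, sub$ak, sub$al) * 2 + sub$friedel_minus
  w <- 1 / pmax(fa$sig_f^2, 1e-12)
  sums <- rowsum(cbind(wf = w * fa$f, w = w), key)
  ukey <- sort(unique(key))
  first <- !duplicated(key)
  meta <- tibble(key = key[first], ah = sub$ah[first], ak = sub$ak[first],
                 al = sub$al[first], friedel_minus = sub$friedel_minus[first],
                 centric = sub$centric[first])
  meta <- meta[match(ukey, meta$key), ]
  tibble(ah = meta$ah, ak = meta$ak, al = meta$al,
         friedel_minus = meta$friedel_minus, centric = meta$centric,
         f = unname(sums[, "wf"] / sums[, "w"]),
         sig_f = unname(sqrt(1 / sums[, "w"])))
}

#' Local scaling of one sub-data set
#'
#' Implements single-data-set local scaling: all observations of each unique
#' ASU reflection are averaged (both Bijvoet mates) to form the scaling
#' target; the Bijvoet-plus and Bijvoet-minus partial sets are then each
#' locally scaled to that target and recombined without further scaling.
#'
#' @param sub A sub-data set from [split_into_subdatasets()].
#' @param cell,spacegroup Crystal metadata.
#' @param k_neighbors Neighbors per local scale factor.
#' @return Tibble with one row per unique ASU reflection: `h`, `k`, `l`,
#'   `d`, `centric`, `f_plus`, `sig_plus`, `f_minus`, `sig_minus` (the last
#'   two `NA` for centrics).
#' @export
local_scale <- function(sub, cell, spacegroup, k_neighbors = 30) {
  agg <- aggregate_amplitudes(sub)
  akey <- hkl_key(agg$ah, agg$ak, agg$al)
  tsum <- rowsum(cbind(f = agg$f, n = 1), akey)
  tkey <- sort(unique(akey))
  f_target_all <- tsum[, "f"] / tsum[, "n"]
  scale_side <- function(side_rows) {
    dat <- agg[side_rows, ]
    dat$f_target <- f_target_all[match(akey[side_rows], tkey)]
    H <- as.matrix(dat[, c("ah", "ak", "al")])
    sc <- local_scale_factors(H, H, dat$f, dat$f_target, cell, k_neighbors)
    dat$f <- dat$f * sc
    dat$sig_f <- dat$sig_f * sc
    dat
  }
  plus <- scale_side(which(!agg$friedel_minus))
  minus <- scale_side(which(agg$friedel_minus))
  out <- plus |>
    select(h = "ah", k = "ak", l = "al", centric = "centric",
           f_plus = "f", sig_plus = "sig_f") |>
    left_join(minus |>
                select(h = "ah", k = "ak", l = "al",
                       f_minus = "f", sig_minus = "sig_f"),
              by = c("h", "k", "l"))
  out$d <- d_spacing(out$h, out$k, out$l, cell)
  out
}

#' Overall scale of a sub-data set to a reference
#'
#' Least-squares scalar `k` minimizing `sum((k F_sub - F_ref)^2)` over
#' reflections common to both: `k = sum(F_ref F_sub) / sum(F_sub^2)`.
#'
#' @param sub Locally scaled sub-data set table (from [local_scale()]).
#' @param reference Reference table with the same index columns and a
#'   `f_mean`-like column named `f_ref`.
#' @return Scalar scale factor.
#' @export
overall_scale <- function(sub, reference) {
  j <- inner_join(sub, reference, by = c("h", "k", "l"))
  if (!nrow(j)) abort("no reflections in common for overall scaling")
  f_sub <- ifelse(is.na(j$f_minus), j$f_plus, (j$f_plus + j$f_minus) / 2)
  sum(j$f_ref * f_sub) / sum(f_sub^2)
}

# Eq-3 style provisional merge: inverse-variance weights from experimental
# uncertainties only; vectorized via rowsum
provisional_merge <- function(subs_tbl) {
  key <- hkl_key(subs_tbl$h, subs_tbl$k, subs_tbl$l)
  ukey <- sort(unique(key))
  wm <- 1 / pmax(subs_tbl$sig_mean^2, 1e-12)
  wd <- 1 / pmax(subs_tbl$sig_dano^2, 1e-12)
  has_d <- !is.na(subs_tbl$dano)
  sums <- rowsum(cbind(wfm = wm * subs_tbl$f_mean, wm = wm,
                       wdd = ifelse(has_d, wd * subs_tbl$dano, 0),
                       wd = ifelse(has_d, wd, 0),
                       n = 1), key)
  first <- !duplicated(key)
  meta <- tibble(key = key[first], h = subs_tbl$h[first], k = subs_tbl$k[first],
                 l = subs_tbl$l[first], d = subs_tbl$d[first],
                 centric = subs_tbl$centric[first])
  meta <- meta[match(ukey, meta$key), ]
  tibble(h = meta$h, k = meta$k, l = meta$l, d = meta$d, centric = meta$centric,
         f_ref = unname(sums[, "wfm"] / sums[, "wm"]),
         dano_m = unname(ifelse(sums[, "wd"] > 0, sums[, "wdd"] / sums[, "wd"], NA_real_)),
         sig_dano_m = unname(ifelse(sums[, "wd"] > 0, sqrt(1 / sums[, "wd"]), Inf)),
         n_obs = unname(as.integer(sums[, "n"])))
}

#' Inter-data-set variance of one sub-data set
#'
#' In each resolution bin, the variance of this sub-data set's anomalous
#' differences about the provisional merged values beyond what measurement
#' error explains:
#' `D^2 = max(0, <(d_i - d_m)^2> - <sig_i^2> - <sig_m^2>)`.
#' The mean-square error of the merged value is taken as the inverse of the
#' summed inverse variances of its contributors (the self-inclusion bias
#' this carries is small and is ignored). Bins with fewer than `min_pairs`
#' contributing reflections borrow the nearest populated bin's value.
#'
#' @param sub_tbl Scaled sub-data set with columns `h`, `k`, `l`, `centric`,
#'   `dano`, `sig_dano` (and `f_mean`/`sig_mean` when `use_mean = TRUE`).
#' @param reference Provisional merge joined with shells: columns `h`, `k`,
#'   `l`, `shell`, `dano_m`, `sig_dano_m`, `f_ref`.
#' @param use_mean Estimate the variance from Bijvoet-averaged amplitudes
#'   instead of anomalous differences.
#' @param min_pairs Minimum reflections per bin; sparser bins borrow the
#'   nearest populated bin's value.
#' @return Tibble with `shell`, `d2` and diagnostic columns `msd`,
#'   `mean_sig2_i`, `mean_sig2_m`, `n`.
#' @export
estimate_interdataset_variance <- function(sub_tbl, reference = NULL, use_mean = FALSE,
                                           min_pairs = 20) {
  need <- setdiff(c("shell", "dano_m", "sig_dano_m", "f_ref"), names(sub_tbl))
  j <- if (length(need)) {
    inner_join(sub_tbl, reference[, c("h", "k", "l", "shell", "dano_m",
                                      "sig_dano_m", "f_ref")],
               by = c("h", "k", "l"))
  } else sub_tbl
  j <- j[!j$centric, ]
  if (use_mean) {
    v <- j |>
      group_by(.data$shell) |>
      summarise(msd = mean((.data$f_mean - .data$f_ref)^2),
                mean_sig2_i = mean(.data$sig_mean^2),
                mean_sig2_m = 0, n = dplyr::n(), .groups = "drop") |>
      mutate(d2 = pmax(.data$msd - .data$mean_sig2_i, 0))
  } else {
    v <- j |>
      filter(!is.na(.data$dano), !is.na(.data$dano_m)) |>
      group_by(.data$shell) |>
      summarise(msd = mean((.data$dano - .data$dano_m)^2),
                mean_sig2_i = mean(.data$sig_dano^2),
                mean_sig2_m = mean(.data$sig_dano_m^2),
                n = dplyr::n(), .groups = "drop") |>
      mutate(d2 = pmax(.data$msd - .data$mean_sig2_i - .data$mean_sig2_m, 0))
  }
  borrow_sparse_bins(v, min_pairs)
}

#' Variance-weighted merge of scaled sub-data sets
#'
#' Anomalous differences are merged with weights proportional to
#' `1 / (sig_i^2 + D_i^2)` (experimental variance plus the sub-data set's
#' inter-data-set variance in that resolution bin); mean amplitudes are
#' merged with plain inverse-variance weights. Bijvoet amplitudes are
#' reconstituted as `F+ = f_mean + dano/2`, `F- = f_mean - dano/2`.
#' Centric reflections are excluded from the output.
#'
#' @param subs_tbl Long table of scaled sub-data sets (internal columns
#'   `sub`, `h`, `k`, `l`, `d`, `centric`, `f_mean`, `sig_mean`, `dano`,
#'   `sig_dano`, `shell`).
#' @param d2_tbl Tibble of (`sub`, `shell`, `d2`) from
#'   [estimate_interdataset_variance()]; missing entries mean `D^2 = 0`.
#' @param cell,spacegroup Crystal metadata for the output object.
#' @return An `anomsig_merged` tibble.
#' @export
merge_weighted <- function(subs_tbl, d2_tbl, cell, spacegroup) {
  dat <- subs_tbl[!subs_tbl$centric & !is.na(subs_tbl$dano), ]
  dat <- left_join(dat, d2_tbl[, c("sub", "shell", "d2")], by = c("sub", "shell"))
  dat$d2[is.na(dat$d2)] <- 0
  key <- hkl_key(dat$h, dat$k, dat$l)
  ukey <- sort(unique(key))
  wm <- 1 / pmax(dat$sig_mean^2, 1e-12)
  wd <- 1 / pmax(dat$sig_dano^2 + dat$d2, 1e-12)
  sums <- rowsum(cbind(wfm = wm * dat$f_mean, wm = wm,
                       wdd = wd * dat$dano, wd = wd, n = 1), key)
  first <- !duplicated(key)
  meta <- tibble(key = key[first], h = dat$h[first], k = dat$k[first],
                 l = dat$l[first], d = dat$d[first])
  meta <- meta[match(ukey, meta$key), ]
  merged <- tibble(h = meta$h, k = meta$k, l = meta$l, d = meta$d,
                   f_mean = unname(sums[, "wfm"] / sums[, "wm"]),
                   sig_f_mean = unname(sqrt(1 / sums[, "wm"])),
                   dano_w = unname(sums[, "wdd"] / sums[, "wd"]),
                   sig_dano_w = unname(sqrt(1 / sums[, "wd"])),
                   n_obs = unname(as.integer(sums[, "n"])))
  out <- tibble(h = merged$h, k = merged$k, l = merged$l, d = merged$d,
                f_plus = merged$f_mean + merged$dano_w / 2,
                sig_plus = sqrt(merged$sig_f_mean^2 + merged$sig_dano_w^2 / 4),
                f_minus = merged$f_mean - merged$dano_w / 2,
                sig_minus = sqrt(merged$sig_f_mean^2 + merged$sig_dano_w^2 / 4),
                n_obs = merged$n_obs)
  new_merged(arrange(out, dplyr::desc(.data$d), .data$h, .data$k, .data$l),
             cell, spacegroup)
}

#' Scale and merge SAD data from one or more crystals
#'
#' Runs the full pipeline: unit-cell grouping, anisotropy homogenization,
#' order-based splitting into sub-data sets, local scaling, overall scaling
#' against a provisional merge, inter-data-set variance estimation, and
#' variance-weighted merging.
#'
#' @param datasets A single `anomsig_unmerged` object (possibly holding
#'   several `dataset_id`s) or a list of them.
#' @param variance_mode `"anom"` (inter-data-set variance from anomalous
#'   differences, the default), `"mean"` (from Bijvoet-averaged amplitudes)
#'   or `"off"` (no inter-data-set weighting).
#' @param n_bins Resolution bins for variance estimation (default 10).
#' @param k_neighbors Local-scaling neighbor count (default 30).
#' @param length_tol_fraction,angle_tol_deg,alt_dmin_fraction Cell-grouping
#'   tolerances (defaults 1% and 1 degree).
#' @param discard_frac Sub-data-set discard threshold (default 0.30).
#' @param anisotropy Homogenize anisotropy across data sets (default `TRUE`).
#' @param min_pairs Minimum reflections per variance bin.
#' @return An object of class `anomsig_merge`: list with `merged` (an
#'   `anomsig_merged` tibble), `d2_table`, `scales`, `report`.
#' @export
scale_and_merge <- function(datasets, variance_mode = c("anom", "mean", "off"),
                            n_bins = 10, k_neighbors = 30,
                            length_tol_fraction = 0.01, angle_tol_deg = 1.0,
                            alt_dmin_fraction = NULL, discard_frac = 0.30,
                            anisotropy = TRUE, min_pairs = 20) {
  variance_mode <- match.arg(variance_mode)
  scaled <- scale_datasets(datasets, n_bins = n_bins, k_neighbors = k_neighbors,
                           length_tol_fraction = length_tol_fraction,
                           angle_tol_deg = angle_tol_deg,
                           alt_dmin_fraction = alt_dmin_fraction,
                           discard_frac = discard_frac, anisotropy = anisotropy)
  merge_scaled(scaled, variance_mode = variance_mode, min_pairs = min_pairs)
}

#' Scale data sets without merging
#'
#' The scaling phase of [scale_and_merge()]: unit-cell grouping, anisotropy
#' homogenization, splitting, local scaling, and overall scaling against a
#' provisional merge. The result can be merged under different variance
#' modes with [merge_scaled()] without repeating the scaling work.
#'
#' @inheritParams scale_and_merge
#' @return Object of class `anomsig_scaled`.
#' @export
scale_datasets <- function(datasets, n_bins = 10, k_neighbors = 30,
                           length_tol_fraction = 0.01, angle_tol_deg = 1.0,
                           alt_dmin_fraction = NULL, discard_frac = 0.30,
                           anisotropy = TRUE) {
  datasets <- split_input_datasets(datasets)
  grp <- group_by_unit_cell(datasets, length_tol_fraction, angle_tol_deg,
                            alt_dmin_fraction)
  sel <- grp$selected
  if (!length(sel)) abort("no data sets remain after unit-cell grouping")
  cell <- get_cell(sel[[1]]); sgname <- get_spacegroup(sel[[1]])

  if (anisotropy && length(sel) > 1) {
    models <- lapply(sel, function(d) tryCatch(fit_anisotropy(d),
                                               error = function(e) NULL))
    ok <- !vapply(models, is.null, logical(1))
    if (sum(ok) >= 2) {
      avg <- average_anisotropy(models[ok])
      sel[ok] <- purrr::map2(sel[ok], models[ok],
                             apply_to_average_anisotropy, avg_model = avg)
    }
  }

  n_discarded_subs <- 0L
  sub_tables <- list(); si <- 1L
  for (ds in sel) {
    subs <- split_into_subdatasets(ds, discard_frac)
    n_discarded_subs <- n_discarded_subs + attr(subs, "n_discarded")
    for (s in subs) {
      tab <- local_scale(s, cell, sgname, k_neighbors)
      tab$sub <- sprintf("%s/%d", s$dataset_id[1], s$sub_id[1])
      sub_tables[[si]] <- tab; si <- si + 1L
    }
  }
  long <- bind_rows(sub_tables) |>
    mutate(f_mean = ifelse(is.na(.data$f_minus), .data$f_plus,
                           (.data$f_plus + .data$f_minus) / 2),
           sig_mean = ifelse(is.na(.data$sig_minus), .data$sig_plus,
                             sqrt(.data$sig_plus^2 + .data$sig_minus^2) / 2),
           dano = .data$f_plus - .data$f_minus,
           sig_dano = sqrt(.data$sig_plus^2 + .data$sig_minus^2))

  # provisional reference and overall scaling of each sub-data set
  ref <- provisional_merge(long)
  scales <- long |>
    group_by(.data$sub) |>
    summarise(scale = overall_scale(dplyr::pick(dplyr::everything()),
                                    ref[, c("h", "k", "l", "f_ref")]),
              .groups = "drop")
  long <- left_join(long, scales, by = "sub") |>
    mutate(across(all_of(c("f_plus", "sig_plus", "f_minus", "sig_minus",
                           "f_mean", "sig_mean", "dano", "sig_dano")),
                  ~ .x * .data$scale)) |>
    select(-"scale")
  ref <- provisional_merge(long)

  shell_of <- resolution_shells(ref$d, n_bins)
  ref$shell <- shell_of
  long <- left_join(long, ref[, c("h", "k", "l", "shell", "dano_m", "sig_dano_m", "f_ref")],
                    by = c("h", "k", "l"))

  structure(list(
    long = long, scales = scales, cell = cell, spacegroup = sgname,
    report = list(
      n_datasets_in = length(datasets),
      n_datasets_used = length(sel),
      datasets_discarded = length(grp$discarded),
      subdatasets_discarded = n_discarded_subs,
      config = list(n_bins = n_bins, k_neighbors = k_neighbors,
                    length_tol_fraction = length_tol_fraction,
                    angle_tol_deg = angle_tol_deg,
                    discard_frac = discard_frac)
    )),
    class = "anomsig_scaled")
}

#' Merge scaled sub-data sets under a variance mode
#'
#' The merging phase of [scale_and_merge()]: inter-data-set variance
#' estimation followed by the variance-weighted merge.
#'
#' @param scaled An `anomsig_scaled` object from [scale_datasets()].
#' @param n_variance_passes Number of variance-estimation passes (default 2:
#'   after the first weighted merge, the inter-data-set variances are
#'   re-estimated against the improved reference and the merge repeated;
#'   this stops strongly deviating data sets from contaminating the
#'   reference the deviations are measured against).
#' @inheritParams scale_and_merge
#' @return An `anomsig_merge` object.
#' @export
merge_scaled <- function(scaled, variance_mode = c("anom", "mean", "off"),
                         min_pairs = 20, n_variance_passes = 2) {
  variance_mode <- match.arg(variance_mode)
  long <- scaled$long
  d2_tbl <- tibble(sub = character(), shell = integer(), d2 = numeric())
  estimate_all <- function(long_tbl) {
    pieces <- lapply(unique(long_tbl$sub), function(sb) {
      v <- estimate_interdataset_variance(long_tbl[long_tbl$sub == sb, ],
                                          use_mean = variance_mode == "mean",
                                          min_pairs = min_pairs)
      v$sub <- sb
      v
    })
    bind_rows(pieces)
  }
  if (variance_mode != "off") {
    d2_tbl <- estimate_all(long)
    merged <- merge_weighted(long, d2_tbl, scaled$cell, scaled$spacegroup)
    for (pass in seq_len(max(n_variance_passes - 1, 0))) {
      ref2 <- tibble(h = merged$h, k = merged$k, l = merged$l,
                     dano_m = merged$dano, sig_dano_m = merged$sig_dano,
                     f_ref2 = merged$f_mean)
      long2 <- long |> select(-"dano_m", -"sig_dano_m") |>
        left_join(ref2, by = c("h", "k", "l"))
      if (variance_mode == "mean") {
        long2$f_ref <- ifelse(is.na(long2$f_ref2), long2$f_ref, long2$f_ref2)
      }
      long2$f_ref2 <- NULL
      d2_tbl <- estimate_all(long2)
      merged <- merge_weighted(long, d2_tbl, scaled$cell, scaled$spacegroup)
    }
  } else {
    merged <- merge_weighted(long, d2_tbl, scaled$cell, scaled$spacegroup)
  }
  report <- scaled$report
  report$n_unique <- nrow(merged)
  report$variance_mode <- variance_mode
  report$config$min_pairs <- min_pairs
  report$config$n_variance_passes <- n_variance_passes
  structure(list(merged = merged, d2_table = d2_tbl, scales = scaled$scales,
                 long = long, report = report),
            class = "anomsig_merge")
}

borrow_sparse_bins <- function(v, min_pairs) {
  sparse <- v$n < min_pairs
  if (any(sparse) && !all(sparse)) {
    ok <- which(!sparse)
    for (i in which(sparse)) v$d2[i] <- v$d2[ok[which.min(abs(ok - i))]]
  }
  v
}

split_input_datasets <- function(datasets) {
  if (inherits(datasets, "anomsig_unmerged")) {
    ids <- unique(datasets$dataset_id)
    datasets <- lapply(ids, function(id) {
      d <- datasets[datasets$dataset_id == id, ]
      unmerged_dataset(as_tibble(d)[, c("h", "k", "l", "i_obs", "sig_i", "dataset_id")],
                       get_cell(datasets), get_spacegroup(datasets),
                       get_wavelength(datasets))
    })
  }
  if (!is.list(datasets) || !length(datasets)) abort("no data sets supplied")
  datasets
}

#' @export
print.anomsig_merge <- function(x, ...) {
  r <- x$report
  cat(sprintf("Scaled and merged SAD data: %d unique acentric reflections from %d data set(s) (%d discarded), variance mode '%s'\n",
              r$n_unique, r$n_datasets_used, r$datasets_discarded, r$variance_mode))
  invisible(x)
}

#' @export
tidy.anomsig_merge <- function(x, ...) as_tibble(x$merged)

#' @export
glance.anomsig_merge <- function(x, ...) {
  tibble(n_unique = x$report$n_unique,
         n_datasets = x$report$n_datasets_used,
         datasets_discarded = x$report$datasets_discarded,
         subdatasets_discarded = x$report$subdatasets_discarded,
         variance_mode = x$report$variance_mode,
         d_min = min(x$merged$d),
         mean_d2 = if (nrow(x$d2_table)) mean(x$d2_table$d2) else 0)
}
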