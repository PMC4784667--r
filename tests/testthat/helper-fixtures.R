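# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small clean truth + simulated data sets used across unit tests
tiny_truth <- function() memo("tiny_truth", function() {
  generate_truth(truth_params(d_min = 3.2), seed = 101)
})

tiny_datasets <- function() memo("tiny_datasets", function() {
  simulate_unmerged(tiny_truth(), n_datasets = 2,
                    noise_model(sig_f_frac = 0.6), seed = 102)
})

tiny_merge <- function() memo("tiny_merge", function() {
  suppressWarnings(scale_and_merge(tiny_datasets()))
})

# brute-force symmetry orbit of one reflection (rotations only)
orbit_of <- function(h, k, l, spacegroup) {
  ops <- sg_ops(spacegroup)$ops
  img <- t(vapply(ops, function(op) as.integer(c(h, k, l) %*% op$R),
                  integer(3)))
  unique(img)
}

# noise-free merged object straight from a truth table (no pipeline)
merged_from_truth <- function(truth, sig = 1) {
  r <- truth$reflections[!truth$reflections$centric, ]
  new_merged(tibble::tibble(h = r$h, k = r$k, l = r$l, d = r$d,
                            f_plus = r$f_plus, sig_plus = sig,
                            f_minus = r$f_minus, sig_minus = sig,
                            n_obs = 1L),
             truth$cell, truth$spacegroup)
}

# the graded corpus with per-member pipeline results: the expensive shared
# fixture behind the metric-validity and end-to-end acceptance checks
corpus_results <- function() memo("corpus_results", function() {
  corpus <- graded_corpus(seed = 424243, n = 30)
  rows <- lapply(seq_along(corpus), function(i) {
    member <- corpus[[i]]
    sm <- suppressWarnings(scale_and_merge(member$datasets))
    qm <- suppressWarnings(quality_metrics(sm, unmerged = member$datasets))
    truth <- member$truth
    ideal <- truth$reflections[, c("h", "k", "l", "dano_ideal")]
    cc_true <- useful_anomalous_correlation(sm$merged, ideal)
    # measured anomalous signal: model-phased difference Fourier peak height
    ph <- truth$reflections[!truth$reflections$centric, ]
    mj <- dplyr::inner_join(tibble::as_tibble(sm$merged),
                            ph[, c("h", "k", "l", "phi_model")],
                            by = c("h", "k", "l"))
    mm <- new_merged(mj[, c("h", "k", "l", "d", "f_plus", "sig_plus",
                            "f_minus", "sig_minus", "n_obs")],
                     truth$cell, truth$spacegroup)
    sa <- anomalous_signal_observed(mm, mj$phi_model,
                                    truth$sites[seq_len(truth$params$n_sites), ])
    wb <- wilson_b_estimate(sm$merged)
    b_sub <- estimate_substructure_b(wb)$mean
    f_b <- f_b_second_moment(truth$params$fdp, b_sub, sm$merged$d)
    list(member = i, e2 = qm$e2, skew = qm$skew, e = qm$e, beta = qm$beta,
         cc_true = cc_true, s_ano_obs = sa$s_ano,
         n_acentric = nrow(sm$merged), n_sites = truth$params$n_sites,
         fdp = truth$params$fdp, site_b = truth$params$site_b,
         wilson_b = wb, b_sub = b_sub, f_b = f_b,
         d = list(sm$merged$d))
  })
  tibble::tibble(
    member = vapply(rows, `[[`, numeric(1), "member"),
    e2 = vapply(rows, `[[`, numeric(1), "e2"),
    skew = vapply(rows, `[[`, numeric(1), "skew"),
    e = vapply(rows, `[[`, numeric(1), "e"),
    beta = vapply(rows, `[[`, numeric(1), "beta"),
    cc_true = vapply(rows, `[[`, numeric(1), "cc_true"),
    s_ano_obs = vapply(rows, `[[`, numeric(1), "s_ano_obs"),
    n_acentric = vapply(rows, `[[`, numeric(1), "n_acentric"),
    n_sites = vapply(rows, `[[`, numeric(1), "n_sites"),
    fdp = vapply(rows, `[[`, numeric(1), "fdp"),
    site_b = vapply(rows, `[[`, numeric(1), "site_b"),
    wilson_b = vapply(rows, `[[`, numeric(1), "wilson_b"),
    b_sub = vapply(rows, `[[`, numeric(1), "b_sub"),
    f_b = vapply(rows, `[[`, numeric(1), "f_b"),
    d = lapply(rows, function(r) r$d[[1]])
  )
})

# leave-one-out Bayesian CC_ano estimates over the corpus table
loo_cc_estimates <- function(res) {
  vapply(seq_len(nrow(res)), function(i) {
    tab <- data.frame(e2 = res$e2[-i], skew = res$skew[-i], e = res$e[-i],
                      cc_ano = res$cc_true[-i])
    est <- train_bayes_estimator(tab, target_bins = 50, target_range = c(0, 1))
    suppressWarnings(estimate_cc_ano(list(e2 = res$e2[i], skew = res$skew[i],
                                          e = res$e[i]), est)$mean)
  }, numeric(1))
}
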