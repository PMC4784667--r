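# autoplot() methods for the package's result objects.

#' Plot methods
#'
#' `autoplot()` is defined for the main result classes: merged data
#' (anomalous difference vs resolution with per-shell rms), quality metrics
#' (shell table of rms anomalous difference and rescaled uncertainty),
#' posteriors (probability over the target grid), plan reports (predicted
#' anomalous signal vs `<I/sigma>` per resolution limit) and Bayesian
#' estimators (conditional mean +/- sd per target bin).
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name anomsig-autoplot
NULL

#' @rdname anomsig-autoplot
#' @export
autoplot.anomsig_merge <- function(object, ...) {
  m <- as_tibble(object$merged)
  m$shell <- resolution_shells(m$d, 10)
  sh <- m |>
    group_by(.data$shell) |>
    summarise(ssq = mean(1 / .data$d^2), rms_dano = sqrt(mean(.data$dano^2)),
              rms_sig = sqrt(mean(.data$sig_dano^2)), .groups = "drop") |>
    pivot_longer(c("rms_dano", "rms_sig"), names_to = "series")
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$ssq, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(labels = c(rms_dano = "rms anomalous difference",
                                              rms_sig = "rms uncertainty")) +
    ggplot2::labs(x = expression(1 / d^2 ~ (ring(A)^-2)), y = "amplitude",
                  colour = NULL, title = "Merged anomalous differences by resolution")
}

#' @rdname anomsig-autoplot
#' @export
autoplot.anomsig_metrics <- function(object, ...) {
  sh <- object$shells |>
    mutate(rms_dano = sqrt(.data$msq_dano),
           rms_sig_rescaled = object$beta * sqrt(.data$msq_sig)) |>
    pivot_longer(c("rms_dano", "rms_sig_rescaled"), names_to = "series")
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$ssq, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(1 / d^2 ~ (ring(A)^-2)), y = "amplitude",
                  colour = NULL,
                  title = sprintf("Uncertainty rescaling (beta = %.2f, e = %.2f)",
                                  object$beta, object$e))
}

#' @rdname anomsig-autoplot
#' @export
autoplot.anomsig_posterior <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$target, y = .data$prob)) +
    ggplot2::geom_col(width = diff(object$grid$target[1:2]), fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "target", y = "posterior probability",
                  title = sprintf("Posterior mean %.3g (sd %.2g)", object$mean, object$sd))
}

#' @rdname anomsig-autoplot
#' @export
autoplot.anomsig_plan <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$i_over_sigma, y = .data$s_ano,
                               colour = factor(.data$d_min))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$s_ano_target, linetype = 2) +
    ggplot2::labs(x = expression("<I/" * sigma * "(I)>"), y = "predicted anomalous signal",
                  colour = expression(d[min] ~ (ring(A))),
                  title = "Planned anomalous signal")
}

#' @rdname anomsig-autoplot
#' @export
autoplot.anomsig_bayes <- function(object, ...) {
  tabs <- imap(object$conditionals, function(cd, nm)
    tibble(target = object$centers, mean = cd$mean, sd = cd$sd, predictor = nm))
  tab <- bind_rows(tabs)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$target, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~predictor, scales = "free_y") +
    ggplot2::labs(x = "target", y = "predictor (mean +/- sd)",
                  title = "Conditional predictor model per target bin")
}
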