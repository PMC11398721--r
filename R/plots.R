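# ggplot2 figures for the result types.  These are diagnostic plots;
# styling is deliberately minimal.

#' @exportS3Method
autoplot.sync_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(t = object$t, R = object$R,
           `mean resource` = object$mean_lambda),
    -"t", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL)
}

#' @exportS3Method
autoplot.hysteresis_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$Lambda, .data$R_stat,
                                   colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Lambda), y = "stationary R")
}

#' @exportS3Method
autoplot.bifurcation_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda_o)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$R_min,
                                         ymax = .data$R_max,
                                         colour = .data$state_class)) +
    ggplot2::labs(x = expression(lambda[o]), y = "R range",
                  colour = "state")
}

#' @exportS3Method
autoplot.cluster_lineage <- function(object, ...) {
  sizes <- object$membership %>%
    dplyr::count(.data$time, .data$cluster)
  ggplot2::ggplot(sizes, ggplot2::aes(.data$time, .data$n,
                                      group = .data$cluster,
                                      colour = factor(.data$cluster))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time in window", y = "cluster size")
}

#' Intramodular-synchrony trace plot
#'
#' One line per community, trial-averaged, over the transient window.
#'
#' @param ims an [intramodular_synchrony()] table.
#' @return a ggplot object.
#' @export
plot_ims <- function(ims) {
  ggplot2::ggplot(ims, ggplot2::aes(.data$time, .data$ims_mean,
                                    colour = factor(.data$community))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from onset", y = "intramodular synchrony",
                  colour = "community")
}
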