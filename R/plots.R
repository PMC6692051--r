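#' Plot an experiment result table
#'
#' `autoplot()` methods for the tidy result tables produced by the
#' `run_*` experiment pipelines: information versus primacy dimension
#' (with the capacity curve), discriminability versus the sweep variable
#' (Monte Carlo points with standard-error bars and the analytic line),
#' scheme comparison (faceted by metric), and heterogeneity sweeps.
#'
#' @param object a `primacy_results` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.primacy_results <- function(object, ...) {
  experiment <- attr(object, "experiment")
  df <- tibble::as_tibble(object)
  switch(
    experiment,
    information = ggplot2::ggplot(df, ggplot2::aes(x = .data$n_primacy,
                                                   y = .data$value,
                                                   colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(data = df[df$metric == "information", ]) +
      ggplot2::labs(x = "primacy dimension N_C", y = "information [bits]",
                    colour = NULL),
    lesion = ggplot2::ggplot(
      df[df$metric == "capacity_loss", ],
      ggplot2::aes(x = .data$n_primacy, y = .data$value,
                   colour = factor(.data$n_receptors))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "primacy dimension N_C",
                    y = "capacity lost by halving N_R [bits]",
                    colour = "N_R"),
    discrimination = {
      sweep_col <- setdiff(names(df), c("metric", "value", "se",
                                        "n_trials", "seed"))[1]
      mc <- df[df$metric == "eta", ]
      th <- df[df$metric == "eta_theory", ]
      ggplot2::ggplot(mc, ggplot2::aes(x = .data[[sweep_col]],
                                       y = .data$value)) +
        ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                              ymax = .data$value + .data$se)) +
        ggplot2::geom_line(data = th, colour = "steelblue") +
        ggplot2::labs(x = sweep_col, y = "discriminability eta")
    },
    scheme_comparison = ggplot2::ggplot(
      df, ggplot2::aes(x = .data$mixture_size, y = .data$value,
                       colour = .data$scheme)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "mixture size s", y = NULL, colour = NULL),
    {
      sweep_col <- intersect(c("xi1", "factor_cv2"), names(df))[1]
      ggplot2::ggplot(df, ggplot2::aes(x = .data[[sweep_col]],
                                       y = .data$value)) +
        ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                              ymax = .data$value + .data$se)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = sweep_col, y = "information [bits]")
    }
  )
}
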