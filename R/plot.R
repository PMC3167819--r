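#' Plot a dose-response curve
#'
#' Mean window-averaged stem-cell count against exogenous Dkk1 dose, with
#' +/- 1 SEM error bars. Requires ggplot2.
#'
#' @param result A [run_dose_sweep()] result (or a list of them, named by
#'   scenario, drawn as separate colored curves).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dose_response requires the ggplot2 package")
  }
  if (inherits(result, "dose_response")) result <- list(tissue = result)
  nm <- names(result)
  if (is.null(nm)) nm <- paste("sweep", seq_along(result))
  df <- do.call(rbind, lapply(seq_along(result), function(i)
    cbind(scenario = nm[i], result[[i]]$summary)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$mean_sc,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_sc - .data$sem_sc,
                                          ymax = .data$mean_sc + .data$sem_sc)) +
    ggplot2::labs(x = "Dkk1 dose (ng/mL)",
                  y = "Mean SC count (last 3 days)", colour = NULL) +
    ggplot2::theme_minimal()
}
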