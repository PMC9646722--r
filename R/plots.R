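# ggplot2 displays for the main result types.

#' @export
autoplot.ap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$vm_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Plot an adaptive trace over its target
#'
#' @param adaptive,target Traces (the target drawn in red underneath).
#' @return A ggplot.
#' @export
plot_fit <- function(adaptive, target) {
  a <- as_single_cycle(adaptive)
  b <- as_single_cycle(target)
  df <- dplyr::bind_rows(
    tibble::tibble(time_ms = b$time_ms, vm_mV = b$vm_mV, which = "target"),
    tibble::tibble(time_ms = a$time_ms, vm_mV = a$vm_mV, which = "adaptive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$vm_mV,
                                   colour = .data$which)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(target = "red",
                                            adaptive = "black")) +
    ggplot2::labs(x = "time (ms)", y = "Vm (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.orp_result <- function(object, ...) {
  sc <- orp_scatter(object)
  fin <- tidyr::pivot_longer(object$finals,
                             dplyr::all_of(paste0("sf_", object$selected)),
                             names_to = "current", values_to = "sf")
  fin$current <- sub("^sf_", "", fin$current)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$sf, y = log10(.data$mse))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3) +
    ggplot2::geom_point(data = fin,
                        ggplot2::aes(y = log10(.data$final_mse)),
                        colour = "red", size = 0.8) +
    ggplot2::facet_wrap(~current, scales = "free_x") +
    ggplot2::labs(x = "scaling factor", y = "log10 MSE (mV^2)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.landscape <- function(object, ..., sf_cap = 3) {
  free <- attr(object, "free")
  long <- tidyr::pivot_longer(object, dplyr::all_of(free),
                              names_to = "current", values_to = "sf")
  # presentation filter only: configurations above the cap are unrealistic
  long <- long[long$sf <= sf_cap & !long$quiescent, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sf, y = .data$log10_mse)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3) +
    ggplot2::facet_wrap(~current, scales = "free_x") +
    ggplot2::labs(x = "scaling factor", y = "log10 MSE (mV^2)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sf_pca <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$loading,
                                   fill = .data$term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "loading", fill = NULL) +
    ggplot2::theme_minimal()
}
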