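#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot netpert_weights
#' @export
autoplot.netpert_weights <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$weight)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "perturbation weight",
                  title = "Perturbation weights by rank") +
    ggplot2::theme_minimal()
}

#' @method autoplot netpert_ranking
#' @export
autoplot.netpert_ranking <- function(object, ...) {
  score_cols <- grep("_score$", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(score_cols),
    names_to = "method", values_to = "score"
  )
  long$method <- sub("_score$", "", long$method)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "vertex category", y = "score",
                  title = "Method scores by vertex category") +
    ggplot2::theme_minimal()
}

#' Plot escaped- and response-density diagnostics against time
#'
#' Visualizes the diffusion-time diagnostics: the exact fraction of
#' driver density that has escaped, its single-driver non-returning
#' approximation, and the total density at the response genes
#' (normalized to its maximum).
#'
#' @param network a `netpert_network`.
#' @param times numeric vector of times; defaults to a grid up to
#'   several relaxation times.
#' @return A ggplot object.
#' @export
plot_density_profile <- function(network, times = NULL) {
  if (is.null(times)) {
    tau <- relaxation_time(network, 0.5)$tau
    times <- seq(0, 8 * tau, length.out = 40)
  }
  prof <- density_profile(network, times)
  rmax <- max(prof$response_density)
  if (rmax > 0) prof$response_density <- prof$response_density / rmax
  long <- tidyr::pivot_longer(prof, -"time",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "diffusion time", y = "density fraction",
                  colour = NULL,
                  title = "Driver escape and response-gene density") +
    ggplot2::theme_minimal()
}
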