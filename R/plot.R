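# ggplot2 visualizations of fitted dose-response models

#' Plot a fitted quantal dose-response model
#'
#' Observed incidence proportions with the fitted curve; dashed guides mark
#' the BMD (and BMDL) at the benchmark response level.
#'
#' @param object A `quantal_fit`.
#' @param n_curve Number of points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantal_fit <- function(object, n_curve = 200, ...) {
  d <- tibble::as_tibble(object$data)
  grid <- tibble::tibble(dose = seq(0, max(d$dose), length.out = n_curve))
  grid$p <- predict(object, grid$dose)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       color = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$affected / .data$n), size = 2) +
    ggplot2::labs(x = "dose (mg/kg bw/day)", y = "incidence",
                  title = object$model,
                  subtitle = endpoint_label(object)) +
    ggplot2::theme_minimal()
  gg + .bmd_guides(object)
}

#' Plot a fitted continuous dose-response model
#'
#' Group means with +/- 1 SD error bars and the fitted mean curve; dashed
#' guides mark the BMD and BMDL.
#'
#' @inheritParams autoplot.quantal_fit
#' @param object A `continuous_fit`.
#' @return A ggplot object.
#' @export
autoplot.continuous_fit <- function(object, n_curve = 200, ...) {
  d <- tibble::as_tibble(object$data)
  grid <- tibble::tibble(dose = seq(0, max(d$dose), length.out = n_curve))
  grid$m <- predict(object, grid$dose)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$m),
                       color = "#2166ac") +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "dose (mg/kg bw/day)", y = "response",
                  title = object$model,
                  subtitle = endpoint_label(object)) +
    ggplot2::theme_minimal()
  gg + .bmd_guides(object)
}

.bmd_guides <- function(fit) {
  out <- list()
  if (!is.na(fit$bmd) && fit$bmd <= max(fit$data$dose)) {
    out <- c(out, list(ggplot2::geom_vline(xintercept = fit$bmd,
                                           linetype = "dashed",
                                           color = "grey40")))
  }
  if (!is.na(fit$bmdl) && fit$bmdl <= max(fit$data$dose)) {
    out <- c(out, list(ggplot2::geom_vline(xintercept = fit$bmdl,
                                           linetype = "dotted",
                                           color = "grey40")))
  }
  out
}

#' @export
plot.bmd_fit <- function(x, ...) print(autoplot(x, ...))
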