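#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a harmonic fit over its data
#'
#' Observed points with the fitted annual sine/cosine curve overlaid.
#'
#' @param object a `harmonic_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.harmonic_fit <- function(object, ...) {
  obs <- tibble(t = object$t, y = object$y)
  grid <- tibble(t = seq(min(object$t), max(object$t), length.out = 400))
  grid$y <- object$intercept + object$a * sin(2 * pi * grid$t) +
    object$b * cos(2 * pi * grid$t)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = grid, colour = "#c0392b", linewidth = 0.8) +
    ggplot2::labs(
      x = "time (years)", y = "value",
      title = sprintf(
        "Annual harmonic fit (R² = %.2f, peak at %.2f yr)",
        object$r2, object$peak_time
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a monthly climatology
#'
#' Mean with a +/- 1 sd ribbon per calendar month, as produced by
#' [aggregate_monthly()].
#'
#' @param monthly tibble with `month`, `mean`, `sd`.
#' @param name series name for the title.
#' @return a ggplot.
#' @export
plot_monthly_profile <- function(monthly, name = "series") {
  ggplot2::ggplot(monthly, ggplot2::aes(x = .data$month, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = name, title = paste("Monthly profile:", name)) +
    ggplot2::theme_minimal()
}

#' Plot a correlation network
#'
#' Circular layout with solid positive and dashed negative edges,
#' coloured by node class; a quick structural view (layout polish is
#' left to Cytoscape via the GraphML export).
#'
#' @param object a `cor_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cor_network <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  pos <- tibble(
    name = nodes$name, class = nodes$class,
    x = cos(ang), y = sin(ang)
  )
  e <- object$edges %>%
    left_join(pos %>% select(name, x, y), by = c("from" = "name")) %>%
    rename(x0 = x, y0 = y) %>%
    left_join(pos %>% select(name, x, y), by = c("to" = "name")) %>%
    rename(x1 = x, y1 = y)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linetype = .data$sign, linewidth = abs(.data$rho)
      ),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class), size = 3
    ) +
    ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y, label = .data$name),
      size = 2.8
    ) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed")
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot event effects
#'
#' Per-event before/during/after mean abundance on the log10 scale.
#'
#' @param object an `event_effect`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.event_effect <- function(object, ...) {
  d <- object$per_event %>%
    tidyr::pivot_longer(c("before", "during", "after"),
      names_to = "window", values_to = "abundance"
    ) %>%
    mutate(
      window = factor(.data$window, levels = c("before", "during", "after"))
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$window, y = log10(.data$abundance),
      group = .data$event
    )
  ) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "log10 abundance",
      title = sprintf(
        "Dust-event effect (%d events)", object$n_events
      )
    ) +
    ggplot2::theme_minimal()
}

#' Tidy an annual harmonic fit
#'
#' @param x a `harmonic_fit`.
#' @param ... unused.
#' @return tibble of the three regression terms with estimates and
#'   standard errors.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(
    term = c("intercept", "sin", "cos"),
    estimate = c(x$intercept, x$a, x$b),
    std_error = sm[c("(Intercept)", "s", "c_"), "Std. Error"],
    p_value = sm[c("(Intercept)", "s", "c_"), "Pr(>|t|)"]
  )
}

#' Glance at an annual harmonic fit
#'
#' @param x a `harmonic_fit`.
#' @param ... unused.
#' @return one-row tibble: `amplitude`, `phase_rad`, `peak_time`,
#'   `r2`, `p_value`, `n`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble(
    amplitude = x$amplitude, phase_rad = x$phase_rad,
    peak_time = x$peak_time, r2 = x$r2, p_value = x$pvalue, n = x$n
  )
}
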