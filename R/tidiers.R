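#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a logistic fit
#'
#' @param x A `km_logit` from [fit_logistic()].
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std_error`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @method tidy km_logit
#' @export
tidy.km_logit <- function(x, ...) x$coefficients

#' One-row model summary of a logistic fit
#'
#' `pseudo_r_squared` is the squared Pearson correlation between the outcome
#' and the fitted probabilities; `mcfadden` is the likelihood-ratio analog.
#'
#' @inheritParams tidy.km_logit
#' @return A one-row tibble.
#' @method glance km_logit
#' @export
glance.km_logit <- function(x, ...) {
  fit <- x$fit
  yb <- fit$y
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(glm(yb ~ 1, family = binomial())))
  tibble(
    category = x$category,
    n = x$n,
    pseudo_r_squared = cor(yb, stats::fitted(fit))^2,
    mcfadden = 1 - ll1 / ll0,
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance,
    converged = fit$converged,
    ci_method = x$ci_method
  )
}

#' Tidy a relative-weights result
#'
#' @param x A `km_relweights` from [relative_weights()] or [johnson_weights()].
#' @param ... Unused.
#' @return One row per predictor: `term`, `weight`.
#' @method tidy km_relweights
#' @export
tidy.km_relweights <- function(x, ...) x$weights

#' One-row summary of a relative-weights result
#'
#' @inheritParams tidy.km_relweights
#' @return A one-row tibble with the summed explained variance.
#' @method glance km_relweights
#' @export
glance.km_relweights <- function(x, ...) {
  tibble(
    category = x$category %||% NA_character_,
    n = x$n,
    r_squared = x$rsq,
    r2_type = x$r2_type,
    family = x$family
  )
}

#' Plot landmark trajectories of a motion sequence
#'
#' Draws every landmark's path over the sequence, coloured by landmark, in
#' pixel coordinates (y up).
#'
#' @param object A `motion_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motion_tbl
#' @export
autoplot.motion_tbl <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, colour = .data$landmark,
                               group = .data$landmark)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)",
      title = if (nzchar(motion_label(object))) motion_label(object) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of relative importance weights
#'
#' @param object A `km_relweights`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_relweights
#' @export
autoplot.km_relweights <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(.data$term, .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "relative weight (explained variance)",
      title = object$category,
      subtitle = sprintf("total = %.3f (%s)", object$rsq, object$r2_type)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an expansiveness series with its maximal window
#'
#' @param series An expansiveness tibble from [expansiveness()].
#' @param window Optional one-row tibble from [max_window()]; when given, the
#'   selected window is shaded.
#' @return A ggplot object.
#' @export
plot_expansiveness <- function(series, window = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = "frame", y = "expansiveness (px)",
      title = paste0(series$axis[1], " expansiveness",
                     if (nzchar(series$label[1])) paste0(" - ", series$label[1]) else "")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    frames <- sort(unique(series$frame))
    p <- p + ggplot2::annotate(
      "rect",
      xmin = frames[window$start], xmax = frames[window$start + window$length - 1L],
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue"
    )
  }
  p
}
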