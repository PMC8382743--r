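#' Plot a moving-median profile
#'
#' Line for the moving median, shaded band for the interquartile range —
#' the standard presentation of distance-resolved single-cell intensities.
#'
#' @param object A `memic_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot memic_profile
#' @export
autoplot.memic_profile <- function(object, ...) {
  value <- attr(object, "value_col") %||% "value"
  dat <- dplyr::filter(object, !is.na(.data$median))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$center_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "Distance from opening (µm)",
                  y = paste0(value, " (moving median ± IQR)")) +
    ggplot2::theme_classic()
}

#' Plot binned positive fractions
#'
#' One point per replicate and bin plus the per-bin mean, mirroring
#' percent-positive-per-distance-bin panels.
#'
#' @param object A `memic_binned` from [binned_fraction()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot memic_binned
#' @export
autoplot.memic_binned <- function(object, ...) {
  dat <- dplyr::mutate(object, mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$replicate), alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Distance from opening (µm)",
                  y = "Fraction positive") +
    ggplot2::theme_classic()
}

#' Plot a steady-state gradient
#'
#' Concentration (and reporter signal, if attached) against distance from
#' the opening.
#'
#' @param object A `memic_steady` from [steady_state()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot memic_steady
#' @export
autoplot.memic_steady <- function(object, ...) {
  dat <- tidyr::pivot_longer(as.data.frame(object), -"x_um",
                             names_to = "quantity")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x_um, y = .data$value,
                                    linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from opening (µm)", y = "Level",
                  linetype = NULL) +
    ggplot2::theme_classic()
}

#' Plot a gradient time course
#'
#' Concentration against distance, one line per saved frame, coloured by
#' time — the standard view of gradient formation dynamics.
#'
#' @param object A `memic_timecourse` from [time_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot memic_timecourse
#' @export
autoplot.memic_timecourse <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x_um, y = .data$conc,
                                    colour = .data$time_h,
                                    group = .data$time_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from opening (µm)",
                  y = "Concentration", colour = "Time (h)") +
    ggplot2::theme_classic()
}

#' Plot a parameter sweep
#'
#' Reporter profiles for every swept value, coloured by the parameter.
#'
#' @param object A `memic_sweep` from [predict_effects()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot memic_sweep
#' @export
autoplot.memic_sweep <- function(object, ...) {
  profs <- attr(object, "profiles")
  dat <- purrr::map2_dfr(profs, object$value, function(p, v) {
    tibble::tibble(x_um = p$x_um, reporter = p$reporter, value = v)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x_um, y = .data$reporter,
                                    colour = factor(.data$value),
                                    group = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from opening (µm)",
                  y = "Reporter signal",
                  colour = unique(object$param)) +
    ggplot2::theme_classic()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
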