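reporter_activation <- function(conc, rep) {
  cstar <- rep$hypoxia_threshold
  if (is.infinite(rep$hill_n)) {
    (conc < cstar) * 1.0
  } else {
    cstar^rep$hill_n / (cstar^rep$hill_n + conc^rep$hill_n)
  }
}

#' Hypoxia-reporter signal from a concentration field
#'
#' Maps concentrations to reporter signal in `[0, 1]`: instantaneous
#' activation `a = c*^n / (c*^n + c^n)` (a hard step `a = 1` iff `c < c*`
#' when `hill_n = Inf`), low-pass filtered in time with the maturation
#' time constant tau (exact exponential update between frames;
#' `signal = activation` when tau is 0 or the input is a steady state).
#'
#' @param conc A `memic_steady` profile or `memic_timecourse`.
#' @param rep A [reporter_spec()].
#' @return For a steady profile, the tibble with a `reporter` column
#'   added; for a time course, the object with a `signal` matrix added
#'   (the signal starts dark: `s(x, 0) = 0`).
#' @export
reporter_profile <- function(conc, rep) {
  stopifnot(inherits(rep, "reporter_spec"))
  UseMethod("reporter_profile")
}

#' @export
reporter_profile.memic_steady <- function(conc, rep) {
  conc$reporter <- reporter_activation(conc$conc, rep)
  conc
}

#' @export
reporter_profile.memic_timecourse <- function(conc, rep) {
  act <- reporter_activation(conc$conc, rep)
  tau_s <- rep$maturation_delay_h * 3600
  if (tau_s == 0) {
    conc$signal <- act
    return(conc)
  }
  sig <- act
  sig[, 1] <- 0
  for (j in 2:ncol(act)) {
    decay <- exp(-(conc$times_s[j] - conc$times_s[j - 1]) / tau_s)
    sig[, j] <- act[, j] + (sig[, j - 1] - act[, j]) * decay
  }
  conc$signal <- sig
  conc
}

#' Predicted effect of a chamber parameter on the gradient
#'
#' Sweeps one chamber parameter (cell density, medium height or opening
#' width), computes the steady-state reporter profile for each value, and
#' summarises each profile by its half-max position.  Denser cultures
#' steepen the gradient and pull the half-max toward the opening; taller
#' chambers push it deeper; the opening width leaves the profile
#' bit-identical, since a well-mixed reservoir boundary already encodes
#' any opening.
#'
#' @param spec Base [chamber_spec()].
#' @param param One of `"cell_density"`, `"medium_height_um"`,
#'   `"opening_width_um"`.
#' @param values Numeric values to sweep.
#' @param rep A [reporter_spec()] (default hard-threshold reporter).
#' @return A `memic_sweep` tibble: `param`, `value`, `half_max_um` (`NA`
#'   when the reporter stays silent, e.g. densities too low to exhaust
#'   oxygen anywhere), `max_signal`; the profiles themselves are in the
#'   `profiles` attribute (named list of reporter-annotated steady
#'   states).
#' @export
#' @examples
#' sw <- predict_effects(chamber_spec(dx_um = 50), "medium_height_um",
#'                       c(250, 500, 1000))
#' sw$half_max_um
predict_effects <- function(spec, param, values, rep = reporter_spec()) {
  stopifnot(inherits(spec, "chamber_spec"))
  param <- match.arg(param, c("cell_density", "medium_height_um",
                              "opening_width_um"))
  if (length(values) < 1L) abort("`values` must be non-empty")
  profiles <- purrr::map(values, function(v) {
    sp <- spec
    sp[[param]] <- v
    reporter_profile(steady_state(sp), rep)
  })
  names(profiles) <- paste0(param, "=", values)
  out <- tibble::tibble(
    param = param,
    value = values,
    half_max_um = unname(vapply(profiles, function(p) {
      if (max(p$reporter) <= min(p$reporter)) NA_real_
      else first_crossing(p$x_um, p$reporter, 0.5)
    }, numeric(1))),
    max_signal = unname(vapply(profiles, function(p) max(p$reporter),
                               numeric(1)))
  )
  attr(out, "profiles") <- profiles
  class(out) <- c("memic_sweep", class(out))
  out
}
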