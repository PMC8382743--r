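#' Chamber geometry and kinetics for the gradient simulator
#'
#' Parameters of a minimal one-dimensional diffusion-consumption model of
#' metabolite gradients in a gradient chamber.  The opening sits at
#' `x = 0`, where a well-mixed reservoir clamps the concentration at
#' `reservoir_concentration`; the far wall at `x = length_um` is sealed
#' (zero flux).  Cells sit on the chamber floor and consume from a medium
#' column of height `medium_height_um`, so the volumetric consumption rate
#' is `cell_density * per_cell_consumption / medium_height_um` — this
#' 1/height scaling is what makes chamber height a key determinant of
#' gradient position, while the opening width does not enter the equations
#' at all (the reservoir boundary condition already encodes a well-mixed
#' opening, whatever its width).
#'
#' Consumption follows Michaelis-Menten kinetics `u(c) = c / (c + Km)`;
#' `Km = 0` gives zeroth-order consumption with a hard floor at `c = 0`
#' (an anoxic free boundary beyond which nothing is consumed).
#'
#' Defaults are normalised: unit reservoir concentration, oxygen-like
#' diffusivity 2000 um^2/s and a 5 mm chamber.  Only profile shapes and
#' orderings are meaningful, not absolute concentrations.
#'
#' @param length_um Chamber length L (um), opening at `x = 0`.
#' @param medium_height_um Medium column height h (um).
#' @param opening_width_um Opening width w (um); documented no-op on the
#'   profile shape, carried only as metadata.
#' @param reservoir_concentration Reservoir concentration c0 (normalised
#'   units).
#' @param diffusivity Diffusivity D (um^2/s).
#' @param per_cell_consumption Maximal consumption per cell q (amount per
#'   cell per second, same amount units as c0 * um^3).
#' @param cell_density Areal cell density rho (cells/um^2).
#' @param Km Michaelis constant (concentration units); 0 for zeroth-order
#'   consumption.
#' @param dx_um Grid spacing (um); must resolve the chamber
#'   (`dx_um < length_um / 10`).
#' @param duration_s,dt_s Time-course length and step (s).
#' @param scheme `"crank-nicolson"` (implicit, default) or `"explicit"`
#'   (forward Euler, subject to the stability bound
#'   `D * dt / dx^2 <= 0.5`).
#'
#' @return An object of class `chamber_spec`.
#' @export
#' @examples
#' spec <- chamber_spec()
#' anoxic_front(spec) # 2000 um for the defaults
chamber_spec <- function(length_um = 5000,
                         medium_height_um = 500,
                         opening_width_um = 1000,
                         reservoir_concentration = 1,
                         diffusivity = 2000,
                         per_cell_consumption = 250,
                         cell_density = 0.002,
                         Km = 0,
                         dx_um = 10,
                         duration_s = 86400,
                         dt_s = 60,
                         scheme = c("crank-nicolson", "explicit")) {
  scheme <- match.arg(scheme)
  if (length_um <= 0 || medium_height_um <= 0 || diffusivity <= 0 ||
      reservoir_concentration <= 0) {
    abort("length, height, diffusivity and reservoir concentration must be positive")
  }
  if (cell_density < 0 || per_cell_consumption < 0 || Km < 0) {
    abort("cell_density, per_cell_consumption and Km must be >= 0")
  }
  if (opening_width_um <= 0) abort("`opening_width_um` must be positive")
  if (!(dx_um > 0 && dx_um < length_um / 10)) {
    abort("`dx_um` must satisfy 0 < dx_um < length_um / 10")
  }
  if (duration_s <= 0 || dt_s <= 0) {
    abort("`duration_s` and `dt_s` must be positive")
  }
  if (scheme == "explicit" &&
      diffusivity * dt_s / dx_um^2 > 0.5) {
    abort(sprintf(paste0("explicit scheme unstable: D*dt/dx^2 = %.3g > 0.5; ",
                         "reduce dt_s or use the Crank-Nicolson scheme"),
                  diffusivity * dt_s / dx_um^2))
  }
  structure(
    list(length_um = length_um, medium_height_um = medium_height_um,
         opening_width_um = opening_width_um,
         reservoir_concentration = reservoir_concentration,
         diffusivity = diffusivity,
         per_cell_consumption = per_cell_consumption,
         cell_density = cell_density, Km = Km, dx_um = dx_um,
         duration_s = duration_s, dt_s = dt_s, scheme = scheme),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(paste0("<chamber_spec> L = %g um, h = %g um, w = %g um, ",
                     "c0 = %g, D = %g um^2/s\n  rho = %g cells/um^2, ",
                     "q = %g, Km = %g; dx = %g um, %s scheme\n"),
              x$length_um, x$medium_height_um, x$opening_width_um,
              x$reservoir_concentration, x$diffusivity, x$cell_density,
              x$per_cell_consumption, x$Km, x$dx_um, x$scheme))
  invisible(x)
}

#' Read a chamber spec from a YAML config file
#'
#' @param path YAML file whose keys are [chamber_spec()] arguments.
#' @return A `chamber_spec`.
#' @export
read_chamber_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  do.call(chamber_spec, yaml::read_yaml(path))
}

#' Analytic anoxic-front position
#'
#' In the zeroth-order (`Km = 0`) regime the steady state is the parabola
#' `c(x) = c0 - rho q / (2 D h) * x * (2 x* - x)`, anoxic beyond
#' `x* = sqrt(2 D h c0 / (rho q))`.  Returns `min(length_um, x*)` (the
#' front cannot lie outside the chamber); infinite when nothing is
#' consumed.
#'
#' @param spec A [chamber_spec()].
#' @return The anoxic-front position (um).
#' @export
anoxic_front <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  rate <- spec$cell_density * spec$per_cell_consumption
  if (rate == 0) return(Inf)
  xstar <- sqrt(2 * spec$diffusivity * spec$medium_height_um *
                  spec$reservoir_concentration / rate)
  min(spec$length_um, xstar)
}

#' Hypoxia-reporter response parameters
#'
#' A threshold-type reporter of hypoxia: instantaneous activation follows a
#' Hill function of concentration centred on `hypoxia_threshold` (a sharp
#' oxygen-tension threshold -- the digital stabilise-or-degrade behaviour
#' of HIF1a -- corresponds to `hill_n = Inf`), and the visible signal lags
#' activation through a first-order low-pass filter with time constant
#' `maturation_delay_h` (fluorophore maturation and accumulation).
#'
#' @param hypoxia_threshold Concentration c* below which the reporter
#'   activates; must be positive (and at most the reservoir concentration
#'   to ever matter).
#' @param hill_n Hill coefficient (>= 1); `Inf` gives a hard step
#'   (activation 1 iff `c < c*`).
#' @param maturation_delay_h Filter time constant tau (hours); 0 means the
#'   signal equals activation instantaneously.
#' @return An object of class `reporter_spec`.
#' @export
reporter_spec <- function(hypoxia_threshold = 0.1, hill_n = Inf,
                          maturation_delay_h = 0) {
  if (hypoxia_threshold <= 0) abort("`hypoxia_threshold` must be positive")
  if (hill_n < 1) abort("`hill_n` must be >= 1 (or Inf for a hard step)")
  if (maturation_delay_h < 0) abort("`maturation_delay_h` must be >= 0")
  structure(list(hypoxia_threshold = hypoxia_threshold, hill_n = hill_n,
                 maturation_delay_h = maturation_delay_h),
            class = "reporter_spec")
}
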