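#' Parameters for a synthetic chamber scene
#'
#' Defines the geometry, cell population and optics of a simulated gradient
#' chamber monolayer: disk-like nuclei with a uniform nuclear stain, plus any
#' number of reporter channels whose per-cell true intensity is a known
#' function of distance from the chamber opening.  By convention the opening
#' edge is at `x = 0` (the image's left border), so a cell's x coordinate IS
#' its distance from the opening and no registration is needed.
#'
#' @param field_width,field_height Field size in um.
#' @param pixel_size Pixel size in um/px (the magnification is configurable;
#'   1 um/px by default).
#' @param n_cells Number of cells to place.
#' @param nucleus_radius_mean,nucleus_radius_sd Nuclear radius distribution
#'   (um); radii are drawn from a normal truncated at 1 um.
#' @param min_center_spacing Minimum pairwise distance between nucleus
#'   centres (um).  Set it below twice the mean radius to generate touching
#'   nuclei on purpose (e.g. to exercise watershed splitting).
#' @param reporter_functions Named list mapping channel name to a function of
#'   distance x (um) returning the true mean intensity (a.u.) of a cell
#'   centred at x.
#' @param nuclear_intensity True intensity of the nuclear stain (a.u.).
#' @param background_level Background intensity outside cells (a.u.).
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.).
#' @param poisson_noise If `TRUE`, pixel values are additionally replaced by
#'   Poisson draws with the noiseless value as mean (shot noise).
#' @param edge_sigma Width (um) of the Gaussian edge profile of each nucleus
#'   (a hard disk blurred by a small Gaussian); 0 gives hard-edged disks.
#' @param bit_depth Bit depth of the rendered images (default 16).
#' @param rng_seed Integer seed; identical parameters give byte-identical
#'   scenes.
#'
#' @return An object of class `scene_params`.
#' @export
#' @examples
#' p <- scene_params(field_width = 200, field_height = 200, n_cells = 10,
#'                   rng_seed = 1)
#' p$n_cells
scene_params <- function(field_width = 1000,
                         field_height = 1000,
                         pixel_size = 1,
                         n_cells = 100,
                         nucleus_radius_mean = 5,
                         nucleus_radius_sd = 0.5,
                         min_center_spacing = 2.5 * nucleus_radius_mean,
                         reporter_functions = list(),
                         nuclear_intensity = 10000,
                         background_level = 200,
                         noise_sd = 0,
                         poisson_noise = FALSE,
                         edge_sigma = 0,
                         bit_depth = 16L,
                         rng_seed = 1L) {
  if (field_width <= 0 || field_height <= 0) {
    abort("field dimensions must be positive")
  }
  if (n_cells < 0) abort("`n_cells` must be >= 0")
  if (min_center_spacing < 0) abort("`min_center_spacing` must be >= 0")
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  if (nucleus_radius_mean <= 0) abort("`nucleus_radius_mean` must be positive")
  if (noise_sd < 0 || edge_sigma < 0) abort("noise_sd and edge_sigma must be >= 0")
  if (length(reporter_functions) &&
      (is.null(names(reporter_functions)) ||
       any(names(reporter_functions) == ""))) {
    abort("`reporter_functions` must be a fully named list")
  }
  if (any(names(reporter_functions) == "nuclear")) {
    abort("'nuclear' is reserved for the nuclear stain channel")
  }
  structure(
    list(field_width = field_width, field_height = field_height,
         pixel_size = pixel_size, n_cells = as.integer(n_cells),
         nucleus_radius_mean = nucleus_radius_mean,
         nucleus_radius_sd = nucleus_radius_sd,
         min_center_spacing = min_center_spacing,
         reporter_functions = reporter_functions,
         nuclear_intensity = nuclear_intensity,
         background_level = background_level,
         noise_sd = noise_sd, poisson_noise = isTRUE(poisson_noise),
         edge_sigma = edge_sigma,
         bit_depth = as.integer(bit_depth),
         rng_seed = as.integer(rng_seed)),
    class = "scene_params"
  )
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("<scene_params> %g x %g um @ %g um/px, %d cells, seed %d\n",
              x$field_width, x$field_height, x$pixel_size, x$n_cells,
              x$rng_seed))
  cat(sprintf("  reporters: %s\n",
              if (length(x$reporter_functions))
                paste(names(x$reporter_functions), collapse = ", ")
              else "(none)"))
  invisible(x)
}
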