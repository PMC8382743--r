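#' Place cells in the field
#'
#' Draws nucleus centres uniformly over the field (keeping every nucleus
#' fully inside it) by rejection sampling until all pairwise centre
#' distances reach `min_center_spacing`.  Placement is deterministic for a
#' given `rng_seed`.
#'
#' @param params A [scene_params()].
#' @param max_tries Attempts per cell before giving up; exhaustion raises a
#'   placement-infeasible error (field too small for `n_cells` at the
#'   requested spacing).
#'
#' @return A tibble of true cells: `id`, `x_um`, `y_um`, `radius_um`.
#' @export
#' @examples
#' cells <- place_cells(scene_params(n_cells = 5, rng_seed = 1))
#' nrow(cells)
place_cells <- function(params, max_tries = 200L) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$n_cells
  empty <- tibble::tibble(id = integer(), x_um = double(), y_um = double(),
                          radius_um = double())
  if (n == 0L) return(empty)

  withr::with_seed(params$rng_seed, {
    radii <- pmax(rnorm(n, params$nucleus_radius_mean,
                        params$nucleus_radius_sd), 1)
    margin <- radii
    if (any(2 * margin > params$field_width |
              2 * margin > params$field_height)) {
      abort("field too small to contain a nucleus")
    }
    xs <- ys <- numeric(n)
    sp2 <- params$min_center_spacing^2
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, margin[i], params$field_width - margin[i])
        y <- runif(1, margin[i], params$field_height - margin[i])
        if (i == 1L ||
            all((xs[seq_len(i - 1L)] - x)^2 +
                (ys[seq_len(i - 1L)] - y)^2 >= sp2)) {
          xs[i] <- x; ys[i] <- y
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(paste0("placement infeasible: could not place cell %d ",
                             "of %d at spacing %g um after %d tries"),
                      i, n, params$min_center_spacing, max_tries),
              class = "memic_placement_infeasible")
      }
    }
    tibble::tibble(id = seq_len(n), x_um = xs, y_um = ys, radius_um = radii)
  })
}
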