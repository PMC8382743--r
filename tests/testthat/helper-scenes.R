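# Shared fixture builders; everything is generated in code.

# hard-disk image: nuclei as filled circles of `value` over `background`
disk_image <- function(centers, radius_px, dim = c(128, 128),
                       value = 10000, background = 200, pixel_size = 1,
                       channel = "nuclear") {
  px <- matrix(background, dim[1], dim[2])
  cc <- matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2])
  rr <- matrix(rep(seq_len(dim[1]) - 1, dim[2]), dim[1], dim[2])
  for (ctr in centers) {
    px[(cc - ctr[1])^2 + (rr - ctr[2])^2 <= radius_px^2] <- value
  }
  channel_image(px, pixel_size = pixel_size, channel = channel)
}

# two disks whose centres are `gap_frac * radius` short of tangency
touching_pair_image <- function(radius_px = 8, overlap_frac = 0.3, ...) {
  d <- (2 - overlap_frac) * radius_px
  disk_image(list(c(50, 64), c(50 + d, 64)), radius_px, ...)
}

# standard small test scene with a linear reporter
small_scene <- function(n_cells = 30, noise_sd = 0, seed = 3,
                        field = c(400, 300),
                        reporter = function(x) 500 + 10 * x) {
  generate_scene(scene_params(
    field_width = field[1], field_height = field[2], n_cells = n_cells,
    reporter_functions = list(gfp = reporter),
    nuclear_intensity = 10000, background_level = 200,
    noise_sd = noise_sd, rng_seed = seed))
}

# greedy 1-1 matching of detected cells to true cells within `tol_um`
match_cells <- function(measured, truth, tol_um = 2) {
  used <- rep(FALSE, nrow(measured))
  match_idx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d2 <- (measured$x_um - truth$x_um[i])^2 +
      (measured$y_um - truth$y_um[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] < tol_um^2) {
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  match_idx
}

# closed-form steady state for zeroth-order consumption
closed_form_conc <- function(spec) {
  xs <- seq(0, spec$length_um, by = spec$dx_um)
  rate <- spec$cell_density * spec$per_cell_consumption
  if (rate == 0) return(rep(spec$reservoir_concentration, length(xs)))
  xstar <- sqrt(2 * spec$diffusivity * spec$medium_height_um *
                  spec$reservoir_concentration / rate)
  k <- rate / (2 * spec$diffusivity * spec$medium_height_um)
  ifelse(xs <= xstar,
         pmax(spec$reservoir_concentration - k * xs * (2 * xstar - xs), 0),
         0)
}
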