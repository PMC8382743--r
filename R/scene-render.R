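#' Render a synthetic scene
#'
#' Renders the nuclear channel (every nucleus as a Gaussian-edged disk at
#' `nuclear_intensity` over `background_level`) and one image per reporter
#' channel, where each cell's disk carries the true intensity
#' `reporter_function(x_center)`.  Additive Gaussian noise (and optional
#' Poisson shot noise) is applied afterwards, then values are quantised to
#' the bit depth with saturation clipping.
#'
#' @param cells Tibble of true cells from [place_cells()].
#' @param params The [scene_params()] used to place them.
#'
#' @return A `memic_scene`: list with `params`, `cells` (the ground truth,
#'   with per-channel true intensity columns `<channel>_true`) and `images`
#'   (named list of [channel_image()], `"nuclear"` first).
#' @export
#' @examples
#' p <- scene_params(field_width = 120, field_height = 80, n_cells = 4,
#'                   reporter_functions = list(gfp = function(x) 50 + 2 * x),
#'                   rng_seed = 7)
#' sc <- render_scene(place_cells(p), p)
#' names(sc$images)
render_scene <- function(cells, params) {
  stopifnot(inherits(params, "scene_params"))
  ps <- params$pixel_size
  nx <- max(1L, as.integer(round(params$field_width / ps)))
  ny <- max(1L, as.integer(round(params$field_height / ps)))
  channels <- c("nuclear", names(params$reporter_functions))

  truth <- cells
  truth$nuclear_true <- rep(params$nuclear_intensity, nrow(cells))
  for (ch in names(params$reporter_functions)) {
    f <- params$reporter_functions[[ch]]
    truth[[paste0(ch, "_true")]] <-
      if (nrow(cells)) vapply(cells$x_um, f, numeric(1)) else numeric(0)
  }

  # pixel centre coordinates (um): 0-based index * pixel size
  xs <- (seq_len(nx) - 1) * ps
  ys <- (seq_len(ny) - 1) * ps
  maxval <- 2^params$bit_depth - 1

  base <- matrix(params$background_level, nrow = ny, ncol = nx)
  imgs <- setNames(rep(list(base), length(channels)), channels)

  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]; r <- cells$radius_um[i]
    reach <- r + 4 * params$edge_sigma
    c0 <- max(1L, findInterval(cx - reach, xs))
    c1 <- min(nx, findInterval(cx + reach, xs) + 1L)
    r0 <- max(1L, findInterval(cy - reach, ys))
    r1 <- min(ny, findInterval(cy + reach, ys) + 1L)
    dx <- xs[c0:c1] - cx
    dy <- ys[r0:r1] - cy
    d <- sqrt(outer(dy^2, dx^2, `+`))
    w <- if (params$edge_sigma > 0) {
      pnorm((r - d) / params$edge_sigma)
    } else {
      (d <= r) * 1.0
    }
    for (ch in channels) {
      val <- truth[[paste0(ch, "_true")]][i]
      imgs[[ch]][r0:r1, c0:c1] <-
        imgs[[ch]][r0:r1, c0:c1] + (val - params$background_level) * w
    }
  }

  # noise uses its own stream so placement and rendering are independently
  # reproducible
  withr::with_seed(params$rng_seed + 1L, {
    for (ch in channels) {
      img <- imgs[[ch]]
      if (params$poisson_noise) {
        img <- matrix(rpois(length(img), pmax(img, 0)) * 1.0,
                      nrow = nrow(img))
      }
      if (params$noise_sd > 0) {
        img <- img + rnorm(length(img), 0, params$noise_sd)
      }
      imgs[[ch]] <- pmin(pmax(round(img), 0), maxval)
    }
  })

  images <- purrr::imap(imgs, function(px, ch) {
    channel_image(px, pixel_size = ps, channel = ch,
                  bit_depth = params$bit_depth)
  })

  structure(list(params = params, cells = truth, images = images),
            class = "memic_scene")
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: [place_cells()] then [render_scene()].
#'
#' @inheritParams place_cells
#' @return A `memic_scene`.
#' @export
generate_scene <- function(params, max_tries = 200L) {
  render_scene(place_cells(params, max_tries = max_tries), params)
}

#' @export
print.memic_scene <- function(x, ...) {
  cat(sprintf("<memic_scene> %d cells, channels: %s\n", nrow(x$cells),
              paste(names(x$images), collapse = ", ")))
  print(x$params)
  invisible(x)
}
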