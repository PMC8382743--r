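#' Moving median profile along the chamber
#'
#' Summarises a per-cell value as a function of distance from the opening:
#' for each window centre `c` on a regular grid covering `[0, max distance]`,
#' the median and interquartile bounds of the value over cells whose
#' distance lies in `[c - w/2, c + w/2)`.  Windows holding fewer than
#' `min_cells` cells are kept in the grid but flagged absent (`NA`
#' statistics), so sparse chamber ends never produce unstable medians.
#'
#' Cells flagged `outside_chamber` are excluded by default.
#'
#' @param table Cell table with `distance_um` assigned.
#' @param value Name of the value column (e.g. `"gfp_mean"` or a ratio
#'   column from [normalize_channel()]).
#' @param window_width Window width in um (default 100).
#' @param step Grid spacing in um (default 25).
#' @param min_cells Minimum cells per window (default 20).
#' @param include_outside Include cells flagged outside the chamber.
#'
#' @return A `memic_profile` tibble: `center_um`, `median`, `q25`, `q75`,
#'   `n`, with the call's parameters as attributes.  An empty table gives an
#'   empty profile.
#' @export
moving_profile <- function(table, value, window_width = 100, step = 25,
                           min_cells = 20, include_outside = FALSE) {
  if (!value %in% names(table)) abort(paste0("column not found: ", value))
  if (!"distance_um" %in% names(table) ||
      (nrow(table) > 0 && all(is.na(table$distance_um)))) {
    abort("distances not assigned; run assign_distance() first")
  }
  if (window_width <= 0 || step <= 0) {
    abort("`window_width` and `step` must be positive")
  }
  dat <- table
  if (!include_outside && "outside_chamber" %in% names(dat)) {
    dat <- dat[!dat$outside_chamber, , drop = FALSE]
  }
  dat <- dat[!is.na(dat[[value]]) & !is.na(dat$distance_um), , drop = FALSE]

  empty <- tibble::tibble(center_um = double(), median = double(),
                          q25 = double(), q75 = double(), n = integer())
  if (nrow(dat) == 0L) {
    return(new_memic_profile(empty, value, window_width, step, min_cells))
  }

  centers <- seq(0, max(dat$distance_um), by = step)
  d <- dat$distance_um
  v <- dat[[value]]
  prof <- purrr::map_dfr(centers, function(ctr) {
    inside <- d >= ctr - window_width / 2 & d < ctr + window_width / 2
    n <- sum(inside)
    if (n < min_cells) {
      tibble::tibble(center_um = ctr, median = NA_real_, q25 = NA_real_,
                     q75 = NA_real_, n = n)
    } else {
      q <- quantile(v[inside], c(0.25, 0.5, 0.75), names = FALSE)
      tibble::tibble(center_um = ctr, median = q[2], q25 = q[1], q75 = q[3],
                     n = n)
    }
  })
  new_memic_profile(prof, value, window_width, step, min_cells)
}

new_memic_profile <- function(tbl, value, window_width, step, min_cells) {
  attr(tbl, "value_col") <- value
  attr(tbl, "window_width") <- window_width
  attr(tbl, "step") <- step
  attr(tbl, "min_cells") <- min_cells
  class(tbl) <- c("memic_profile", class(tbl))
  tbl
}

# first distance at which the piecewise-linear curve (x, y) reaches
# ymin + frac * (ymax - ymin); NA when the curve is flat
first_crossing <- function(x, y, frac = 0.5) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 2L) return(NA_real_)
  lo <- min(y); hi <- max(y)
  if (hi <= lo) return(NA_real_)
  target <- lo + frac * (hi - lo)
  for (i in seq_len(length(y) - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((y0 - target) * (y1 - target) <= 0) {
      if (y1 == y0) return(x[i])
      t <- (target - y0) / (y1 - y0)
      if (t >= 0 && t <= 1) return(x[i] + t * (x[i + 1L] - x[i]))
    }
  }
  NA_real_
}

#' Half-maximal signal position
#'
#' The distance at which a spatial profile first reaches 50% of its maximal
#' signal: the smallest distance where the median curve crosses
#' `min + 0.5 * (max - min)`, linearly interpolated between adjacent window
#' centres.  The profile's own minimum is used as the baseline (robust to
#' non-zero background fluorescence).  A flat profile has no gradient and
#' raises an error, mirroring the exclusion of no-gradient controls from
#' such comparisons.
#'
#' @param profile A `memic_profile` from [moving_profile()], or any data
#'   frame with `center_um` and `median` columns.
#' @return The half-max position (um).
#' @export
#' @examples
#' prof <- tibble::tibble(center_um = c(100, 200, 300, 400, 500),
#'                        median = c(0, 0, 50, 100, 100))
#' half_max_position(prof)
half_max_position <- function(profile) {
  med <- profile$median
  ok <- !is.na(med)
  if (sum(ok) < 3L) {
    abort("need at least 3 populated windows to locate a half-max position")
  }
  if (max(med[ok]) <= min(med[ok])) {
    abort("flat profile: half-max position undefined (no gradient)",
          class = "memic_flat_profile")
  }
  first_crossing(profile$center_um, med, frac = 0.5)
}

#' Export a profile to CSV
#'
#' @param profile A `memic_profile`.
#' @param path Output CSV path (columns `center_um, median, q25, q75, n`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
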