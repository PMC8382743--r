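#' Measure cells: position, area and per-channel intensity
#'
#' The image-cytometry measurement step: for every labelled cell region,
#' computes the centroid (um), area (um^2) and the mean raw pixel intensity
#' in each channel.  Intensities are reported unnormalised; any
#' normalisation (e.g. reporter over nuclear stain) is an explicit
#' downstream step, see [normalize_channel()].
#'
#' Coordinates follow the 0-based pixel convention: a one-pixel cell at
#' 0-based pixel (x = 10, y = 20) with 2 um/px has centroid (20, 40) um and
#' area 4 um^2.
#'
#' @param labels Integer cell label matrix from [detect_nuclei()] or
#'   [segment_cells()].
#' @param channels List of [channel_image()]s to measure; all must match the
#'   label map's dimensions and pixel size.
#' @param chamber_id,condition Optional chamber metadata carried along as
#'   attributes (and into exported CSVs).
#'
#' @return A tibble with one row per label, in ascending label order:
#'   `cell_id`, `x_um`, `y_um`, `area_um2`, one `<channel>_mean` column per
#'   channel, and `distance_um` (`NA` until [assign_distance()] is called).
#'   Attributes `pixel_size`, `chamber_id` and `condition` hold the
#'   metadata.  Zero labels give an empty table with intact metadata.
#' @export
measure_cells <- function(labels, channels, chamber_id = NA_character_,
                          condition = NA_character_) {
  stopifnot(is.matrix(labels))
  ps <- attr(labels, "pixel_size")
  if (is.null(ps)) abort("`labels` must carry a pixel_size attribute")
  if (inherits(channels, "channel_image")) channels <- list(channels)
  ch_names <- vapply(channels, function(ch) ch$channel, character(1))
  for (ch in channels) {
    if (!identical(dim(ch$pixels), dim(labels))) {
      abort(sprintf("channel '%s' dimensions do not match the label map",
                    ch$channel))
    }
    if (!isTRUE(all.equal(ch$pixel_size, ps))) {
      abort(sprintf("channel '%s' pixel size does not match the label map",
                    ch$channel))
    }
  }

  n <- max(labels, 0L)
  present <- which(tabulate(labels, nbins = max(n, 1L)) > 0L)

  if (length(present) == 0L) {
    tab <- tibble::tibble(cell_id = integer(), x_um = double(),
                          y_um = double(), area_um2 = double())
    for (nm in ch_names) tab[[paste0(nm, "_mean")]] <- double()
    tab$distance_um <- double()
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    # 0-based pixel coordinates: rows are y, columns are x
    row0 <- (idx - 1L) %% nrow(labels)
    col0 <- (idx - 1L) %/% nrow(labels)
    cnt <- as.vector(rowsum(rep(1, length(lab)), lab))
    f <- sort(unique(lab))
    tab <- tibble::tibble(
      cell_id = as.integer(f),
      x_um = as.vector(rowsum(col0 * ps, lab)) / cnt,
      y_um = as.vector(rowsum(row0 * ps, lab)) / cnt,
      area_um2 = cnt * ps^2
    )
    for (ch in channels) {
      tab[[paste0(ch$channel, "_mean")]] <-
        as.vector(rowsum(ch$pixels[idx], lab)) / cnt
    }
    tab$distance_um <- NA_real_
  }

  attr(tab, "pixel_size") <- ps
  attr(tab, "chamber_id") <- chamber_id
  attr(tab, "condition") <- condition
  tab
}

#' Write a cell table to CSV
#'
#' Plain CSV export of a measured cell table; metadata attributes are not
#' serialised (keep them in the chamber's metadata record).
#'
#' @param table Cell table from [measure_cells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' @param path CSV written by [write_cell_table()].
#' @param pixel_size Optional pixel size (um/px) restored as an attribute.
#' @return A tibble.
#' @export
read_cell_table <- function(path, pixel_size = NULL) {
  tab <- tibble::as_tibble(read.csv(path))
  if (!is.null(pixel_size)) attr(tab, "pixel_size") <- pixel_size
  tab
}
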