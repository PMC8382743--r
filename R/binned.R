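#' Binned positive fractions along the chamber
#'
#' For one or more replicate cell tables, bins cells along the distance from
#' the opening into contiguous half-open intervals `[lo, hi)` anchored at 0,
#' and reports per replicate and bin the fraction of cells whose marker
#' value exceeds the threshold (e.g. the percentage of phospho-H3-positive
#' cells per distance bin).  Bins a replicate leaves empty are absent from
#' its rows.
#'
#' @param tables A cell table or list of replicate cell tables, each with
#'   `distance_um` assigned.
#' @param marker Name of the marker column.
#' @param threshold Positivity threshold: a cell is positive when
#'   `marker > threshold` (strict).
#' @param bin_width Bin width in um.
#' @param include_outside Include cells flagged outside the chamber.
#'
#' @return A `memic_binned` tibble: `replicate`, `bin_lo`, `bin_hi`,
#'   `n`, `n_positive`, `fraction`; `threshold` and `bin_width` attributes.
#' @export
binned_fraction <- function(tables, marker, threshold, bin_width = 500,
                            include_outside = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (bin_width <= 0) abort("`bin_width` must be positive")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("rep", seq_along(tables))
  }
  out <- purrr::imap_dfr(tables, function(tab, nm) {
    if (!marker %in% names(tab)) abort(paste0("column not found: ", marker))
    if (!"distance_um" %in% names(tab)) {
      abort("distances not assigned; run assign_distance() first")
    }
    if (!include_outside && "outside_chamber" %in% names(tab)) {
      tab <- tab[!tab$outside_chamber, , drop = FALSE]
    }
    if (nrow(tab) == 0L) return(NULL)
    bin <- floor(tab$distance_um / bin_width)
    tibble::tibble(replicate = nm, bin = bin, value = tab[[marker]]) |>
      dplyr::group_by(.data$replicate, .data$bin) |>
      dplyr::summarise(n = dplyr::n(),
                       n_positive = sum(.data$value > threshold),
                       .groups = "drop") |>
      dplyr::mutate(bin_lo = .data$bin * bin_width,
                    bin_hi = (.data$bin + 1) * bin_width,
                    fraction = .data$n_positive / .data$n) |>
      dplyr::select("replicate", "bin_lo", "bin_hi", "n", "n_positive",
                    "fraction")
  })
  out <- dplyr::arrange(out, .data$replicate, .data$bin_lo)
  attr(out, "threshold") <- threshold
  attr(out, "bin_width") <- bin_width
  class(out) <- c("memic_binned", class(out))
  out
}
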