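#' Opening-edge specification
#'
#' Identifies the chamber opening: the edge of the top coverslip, which is
#' the reference point for all distance measurements.  `edge_axis` names the
#' image border the opening sits on and `edge_offset` its position in image
#' coordinates (um).
#'
#' @param edge_axis One of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param edge_offset Position of the edge along the perpendicular axis
#'   (um); e.g. `left` with offset 0 puts the opening at `x = 0`.
#' @return An object of class `opening_spec`.
#' @export
opening_spec <- function(edge_axis = c("left", "right", "top", "bottom"),
                         edge_offset = 0) {
  edge_axis <- match.arg(edge_axis)
  if (!is.numeric(edge_offset) || length(edge_offset) != 1L) {
    abort("`edge_offset` must be a single number (um)")
  }
  structure(list(edge_axis = edge_axis, edge_offset = edge_offset),
            class = "opening_spec")
}

#' Assign distance from the chamber opening
#'
#' Adds `distance_um`: the perpendicular coordinate from the opening edge,
#' increasing into the chamber and never negative.  Cells lying on the
#' reservoir side of the edge get distance 0 and `outside_chamber = TRUE`;
#' such cells are excluded from profiles downstream by default.
#'
#' @param table Cell table with `x_um`, `y_um` centroids.
#' @param opening An [opening_spec()].
#' @return The table with `distance_um` and `outside_chamber` columns.
#' @export
#' @examples
#' tab <- tibble::tibble(x_um = c(350, -20), y_um = c(0, 0))
#' assign_distance(tab, opening_spec("left", 0))$distance_um
assign_distance <- function(table, opening) {
  if (missing(opening) || !inherits(opening, "opening_spec")) {
    abort("`opening` must be an opening_spec()")
  }
  coord <- switch(opening$edge_axis,
                  left = table$x_um - opening$edge_offset,
                  right = opening$edge_offset - table$x_um,
                  top = table$y_um - opening$edge_offset,
                  bottom = opening$edge_offset - table$y_um)
  out <- dplyr::mutate(table,
                       distance_um = pmax(coord, 0),
                       outside_chamber = coord < 0)
  for (a in c("pixel_size", "chamber_id", "condition")) {
    attr(out, a) <- attr(table, a, exact = TRUE)
  }
  out
}
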