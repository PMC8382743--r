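#' Segmentation parameters
#'
#' Controls nuclei detection and cell expansion.  All length-like values are
#' in physical units (um, um^2) and are converted to pixels internally using
#' the image's pixel size.
#'
#' @param smoothing_sigma Gaussian pre-smoothing of the nuclear channel (um);
#'   0 disables smoothing.
#' @param threshold_method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_threshold Threshold in raw intensity units (a.u.), required
#'   when `threshold_method = "fixed"`; useful for dim stains where Otsu
#'   misbehaves.
#' @param min_nucleus_area,max_nucleus_area Area filter (um^2) applied to
#'   detected nuclei.
#' @param split_touching Split merged blobs by marker-based watershed on the
#'   Euclidean distance transform.
#' @param h_minima_depth Depth (um) below which neighbouring distance-map
#'   maxima are merged into one seed (h-minima suppression); larger values
#'   split less.
#' @param cell_expansion_radius How far (um) each nucleus is grown outward
#'   into a whole-cell territory by [segment_cells()]; 0 keeps nuclei only.
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_nucleus_area = 20,
                                max_nucleus_area = 400,
                                split_touching = TRUE,
                                h_minima_depth = 1,
                                cell_expansion_radius = 0) {
  threshold_method <- match.arg(threshold_method)
  if (smoothing_sigma < 0) abort("`smoothing_sigma` must be >= 0")
  if (!(min_nucleus_area > 0 && min_nucleus_area < max_nucleus_area)) {
    abort("need 0 < min_nucleus_area < max_nucleus_area")
  }
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || !is.numeric(fixed_threshold))) {
    abort("`fixed_threshold` must be given for threshold_method = 'fixed'")
  }
  if (h_minima_depth < 0) abort("`h_minima_depth` must be >= 0")
  if (cell_expansion_radius < 0) abort("`cell_expansion_radius` must be >= 0")
  structure(
    list(smoothing_sigma = smoothing_sigma,
         threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         min_nucleus_area = min_nucleus_area,
         max_nucleus_area = max_nucleus_area,
         split_touching = isTRUE(split_touching),
         h_minima_depth = h_minima_depth,
         cell_expansion_radius = cell_expansion_radius),
    class = "segmentation_params"
  )
}

#' Detect nuclei in the uniform-stain channel
#'
#' Smooths the nuclear channel, thresholds it (Otsu by default), labels
#' connected components and optionally splits touching nuclei by watershed
#' on the Euclidean distance transform with h-minima-suppressed seeds.
#' Regions outside the `[min_nucleus_area, max_nucleus_area]` filter are
#' discarded and the survivors relabelled `1..n`; background is 0.
#'
#' @param nuclear A [channel_image()] of the uniform nuclear stain (e.g.
#'   Hoechst).
#' @param params A [segmentation_params()].
#'
#' @return An integer label matrix (same size as the image) with attribute
#'   `pixel_size`.  A blank image yields zero labels (not an error).
#' @export
detect_nuclei <- function(nuclear, params = segmentation_params()) {
  stopifnot(inherits(nuclear, "channel_image"),
            inherits(params, "segmentation_params"))
  ps <- nuclear$pixel_size
  px <- nuclear$pixels
  sigma_px <- params$smoothing_sigma / ps
  smoothed <- if (sigma_px > 0) {
    EBImage::imageData(EBImage::gblur(EBImage::as.Image(px),
                                      sigma = sigma_px))
  } else px

  thr <- if (params$threshold_method == "otsu") {
    maxval <- 2^nuclear$bit_depth - 1
    EBImage::otsu(EBImage::as.Image(smoothed / maxval),
                  range = c(0, 1), levels = 256L) * maxval
  } else {
    params$fixed_threshold
  }
  mask <- smoothed > thr
  if (!any(mask)) {
    warn("no pixels above threshold: returning an empty label map")
    lab <- matrix(0L, nrow(px), ncol(px))
    attr(lab, "pixel_size") <- ps
    return(lab)
  }

  if (params$split_touching) {
    dm <- EBImage::distmap(EBImage::as.Image(mask))
    lab <- EBImage::watershed(dm, tolerance = params$h_minima_depth / ps,
                              ext = 1L)
  } else {
    lab <- EBImage::bwlabel(EBImage::as.Image(mask))
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(px), ncol(px))

  # area filter in um^2, then compact relabelling in ascending label order
  counts <- tabulate(lab, nbins = max(lab))
  areas <- counts * ps^2
  keep <- which(counts > 0 & areas >= params$min_nucleus_area &
                  areas <= params$max_nucleus_area)
  remap <- integer(max(lab, 1L))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(px), ncol(px))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  attr(out, "pixel_size") <- ps
  out
}

#' Expand nuclei into cell territories
#'
#' Grows each nucleus label outward by up to `cell_expansion_radius` (um),
#' assigning every contested pixel to the nearest nucleus pixel (exact
#' Euclidean distance), i.e. a Voronoi-constrained dilation.  Nucleus pixels
#' keep their label; an expansion radius of 0 returns the input unchanged.
#' Labels are never merged or dropped.
#'
#' @param nuclei Integer label matrix from [detect_nuclei()].
#' @param params A [segmentation_params()]; only `cell_expansion_radius`
#'   is used.
#'
#' @return An integer cell label matrix with attribute `pixel_size`.
#' @export
segment_cells <- function(nuclei, params = segmentation_params()) {
  stopifnot(is.matrix(nuclei), inherits(params, "segmentation_params"))
  ps <- attr(nuclei, "pixel_size")
  if (is.null(ps)) abort("`nuclei` must carry a pixel_size attribute")
  r_px <- params$cell_expansion_radius / ps
  if (r_px == 0 || !any(nuclei > 0L)) return(nuclei)

  storage.mode(nuclei) <- "integer"
  res <- edt_nearest_label(nuclei)
  out <- nuclei
  grow <- nuclei == 0L & res$dist2 <= r_px^2
  out[grow] <- res$label[grow]
  attr(out, "pixel_size") <- ps
  out
}
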