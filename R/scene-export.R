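#' Export a synthetic scene to disk
#'
#' Writes one 16-bit grayscale TIFF per channel, the ground-truth cell table
#' as CSV (`truth.csv`) and a flat YAML metadata record (`metadata.yml`)
#' holding the pixel size, field dimensions and the opening-edge convention
#' (left edge, offset 0 um).  The export is byte-stable: identical scenes
#' produce identical files, and re-reading the TIFFs reproduces the pixel
#' values bit-exactly.
#'
#' @param scene A `memic_scene` from [render_scene()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
export_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "memic_scene"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort(paste0("could not create directory: ", directory))
  }
  files <- character(0)
  for (ch in names(scene$images)) {
    path <- file.path(directory, paste0(ch, ".tif"))
    write_channel_tiff(scene$images[[ch]], path)
    files <- c(files, path)
  }
  truth_path <- file.path(directory, "truth.csv")
  write.csv(scene$cells, truth_path, row.names = FALSE)
  files <- c(files, truth_path)

  p <- scene$params
  meta <- list(
    pixel_size_um = p$pixel_size,
    field_width_um = p$field_width,
    field_height_um = p$field_height,
    bit_depth = p$bit_depth,
    opening_edge_axis = "left",
    opening_edge_offset_um = 0,
    channels = names(scene$images),
    n_cells = nrow(scene$cells),
    rng_seed = p$rng_seed
  )
  meta_path <- file.path(directory, "metadata.yml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(files, meta_path))
}

#' Load an exported scene's images and metadata
#'
#' Counterpart of [export_scene()]: reads `metadata.yml`, all channel TIFFs
#' and the ground-truth CSV back into a list.
#'
#' @param directory Directory written by [export_scene()].
#' @return A list with `images` (named list of [channel_image()]), `truth`
#'   (tibble) and `metadata` (list).
#' @export
load_scene <- function(directory) {
  meta_path <- file.path(directory, "metadata.yml")
  if (!file.exists(meta_path)) {
    abort(paste0("no metadata.yml in ", directory))
  }
  meta <- yaml::read_yaml(meta_path)
  images <- purrr::map(setNames(meta$channels, meta$channels), function(ch) {
    read_channel_tiff(file.path(directory, paste0(ch, ".tif")),
                      pixel_size = meta$pixel_size_um, channel = ch,
                      bit_depth = meta$bit_depth)
  })
  truth <- tibble::as_tibble(read.csv(file.path(directory, "truth.csv")))
  list(images = images, truth = truth, metadata = meta)
}
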