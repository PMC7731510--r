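#' Read and write intensity fields as 32-bit TIFF
#'
#' Intensities are arbitrary units, so fields are stored as 32-bit float
#' TIFF normalized by a scale factor recorded in a JSON sidecar
#' (`<path>.json`), making the round trip exact to float precision.
#'
#' @param field numeric matrix of nonnegative intensities.
#' @param path output `.tif` path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns the matrix.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(is.matrix(field), all(is.finite(field)))
  scale <- max(field, 1e-12)
  tiff::writeTIFF(field / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  img * meta$scale
}

#' Read and write polarization stacks as multi-page TIFF
#'
#' Frames are stored as pages of one multi-page 32-bit TIFF; the polarizer
#' angles and intensity scale go to a JSON sidecar.
#'
#' @param stack a [polarization_stack()].
#' @param path output `.tif` path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "polarization_stack"))
  k <- dim(stack$frames)[1]
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(k), function(i) stack$frames[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, angles_deg = stack$angles_deg),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * meta$scale
  polarization_stack(frames, meta$angles_deg)
}

#' Write an RGB stain image as 8-bit TIFF
#'
#' @param image a [stain_image()].
#' @param path output `.tif` path.
#' @export
write_stain_tiff <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  tiff::writeTIFF(image$rgb / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_stain_tiff
#' @param stain,pixel_pitch metadata for the reconstructed [stain_image()].
#' @export
read_stain_tiff <- function(path, stain, pixel_pitch = 1) {
  img <- tiff::readTIFF(path)
  stain_image(round(img[, , 1:3] * 255), stain, pixel_pitch)
}

#' Write all files of a phantom dataset to a directory
#'
#' Lays a dataset out the way the pipeline documents its inputs: one TIFF
#' per TPEF channel, a multi-page polarization stack, RGB stain TIFFs, the
#' ROI JSON and a truth summary JSON.
#'
#' @param ds a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(ds$channels))
    for (nm in names(ds$channels))
      write_field_tiff(ds$channels[[nm]], file.path(dir, paste0(nm, ".tif")))
  if (!is.null(ds$stack))
    write_stack_tiff(ds$stack, file.path(dir, "polarization_stack.tif"))
  if (!is.null(ds$psr)) write_stain_tiff(ds$psr, file.path(dir, "psr.tif"))
  if (!is.null(ds$ars)) write_stain_tiff(ds$ars, file.path(dir, "ars.tif"))
  write_roi_json(ds$annotation, file.path(dir, "regions.json"))
  truth <- list(effect = ds$effect, seed = ds$seed,
                region_calcium = as.list(ds$truth$region_calcium))
  jsonlite::write_json(truth, file.path(dir, "truth_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
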