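# Slab image IO: 16-bit PNG/TIFF with a JSON provenance sidecar.

#' Write a slab to a 16-bit TIFF or 8-bit PNG with a provenance sidecar
#'
#' Intensities are affinely mapped to the full sample range (16 bits for
#' TIFF, the preferred format; 8 bits for PNG); the mapping
#' endpoints and the slab provenance (density label, filter flag, seed)
#' are stored in a JSON sidecar at `<path>.json` so [read_slab()] can
#' restore the original floating-point intensities. The mask is written
#' only when it is not all-`TRUE`, as a run-length-free 0/1 PNG/TIFF at
#' `<path base>_mask.<ext>`.
#'
#' @param slab An [image_slab()].
#' @param path Output file; format chosen from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_slab <- function(slab, path) {
  stopifnot(inherits(slab, "image_slab"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) {
    stop("Unsupported image format: .", ext, " (use png or tif/tiff).",
         call. = FALSE)
  }
  mn <- min(slab$pixels)
  mx <- max(slab$pixels)
  scaled <- if (mx > mn) (slab$pixels - mn) / (mx - mn)
            else matrix(0, nrow(slab$pixels), ncol(slab$pixels))
  if (ext == "png") {
    png::writePNG(round(scaled * 255) / 255, target = path, dpi = NULL)
  } else {
    # quantize explicitly to 16 bits so the sidecar mapping is exact
    tiff::writeTIFF(round(scaled * 65535) / 65535, where = path,
                    bits.per.sample = 16L)
  }
  if (!all(slab$mask)) {
    mask_path <- paste0(tools::file_path_sans_ext(path), "_mask.", ext)
    m <- slab$mask * 1
    if (ext == "png") png::writePNG(m, target = mask_path)
    else tiff::writeTIFF(m, where = mask_path, bits.per.sample = 8L)
  }
  sidecar <- list(
    intensity_min = mn,
    intensity_max = mx,
    density_label = slab$density_label,
    filtered = slab$filtered,
    seed = slab$seed,
    height = nrow(slab$pixels),
    width = ncol(slab$pixels),
    has_mask = !all(slab$mask)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a slab from PNG/TIFF, restoring provenance when available
#'
#' If `<path>.json` (written by [write_slab()]) exists, intensities are
#' mapped back to their original range and provenance is restored;
#' otherwise raw values in `[0, 1]` are returned with empty provenance.
#'
#' @param path Image file written by [write_slab()] or any grayscale
#'   PNG/TIFF.
#' @return An [image_slab()].
#' @export
read_slab <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("Unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    return(image_slab(img))
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  px <- img * (meta$intensity_max - meta$intensity_min) + meta$intensity_min
  mask <- NULL
  if (isTRUE(meta$has_mask)) {
    mask_path <- paste0(tools::file_path_sans_ext(path), "_mask.", ext)
    m <- switch(ext, png = png::readPNG(mask_path),
                tif = , tiff = tiff::readTIFF(mask_path))
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0.5
  }
  image_slab(px, mask,
             density_label = if (is.null(meta$density_label)) NA_real_
                             else meta$density_label,
             filtered = isTRUE(meta$filtered),
             seed = if (is.null(meta$seed)) NA_integer_
                    else as.integer(meta$seed))
}
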