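#' En-face angiogram image
#'
#' The unit every pipeline stage consumes and produces: a 2-D grayscale
#' matrix in grey levels (0--255 for 8-bit data), with the physical pixel
#' pitch and a provenance tag recording which study arm produced it.
#'
#' @param pixels numeric matrix of grey levels.
#' @param pixel_pitch physical pixel size in mm/pixel (default 3/232, the
#'   3 x 3 mm macular cube sampled by 232 x 232 A-scans).
#' @param provenance one of `"single"`, `"denoised"`, `"averaged"`, or
#'   `"averaged(n)"`; free-form tags are allowed for intermediates.
#' @return an object of class `en_face_image` (a matrix with attributes).
#' @export
en_face_image <- function(pixels, pixel_pitch = 3 / 232, provenance = "single") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels) | is.na(pixels))) {
    stop("`pixels` must contain only finite or NA values", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be a single positive number (mm/pixel)", call. = FALSE)
  }
  structure(pixels,
    pixel_pitch = pixel_pitch,
    provenance = as.character(provenance),
    class = c("en_face_image", "matrix", "array")
  )
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf(
    "<en_face_image> %d x %d px, pitch %.4f mm/px, provenance: %s\n",
    nrow(x), ncol(x), attr(x, "pixel_pitch"), attr(x, "provenance")
  ))
  rng <- range(x, na.rm = TRUE)
  cat(sprintf(
    "  grey levels: [%.1f, %.1f], mean %.1f\n",
    rng[1], rng[2], mean(x, na.rm = TRUE)
  ))
  invisible(x)
}

# Rebuild an en_face_image from raw pixels, inheriting metadata from a donor.
as_enface <- function(pixels, like, provenance = attr(like, "provenance")) {
  en_face_image(pixels, pixel_pitch = attr(like, "pixel_pitch"), provenance = provenance)
}

pixels_of <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_pitch") <- NULL
  attr(m, "provenance") <- NULL
  attr(m, "roi_mask") <- NULL
  attr(m, "bbox") <- NULL
  m
}

#' Read and write grayscale en-face images
#'
#' PNG and TIFF round-trips are bit-exact at the stored bit depth. PNG is
#' written 8-bit; TIFF supports 8- or 16-bit via `bits`. Colour (RGB) inputs
#' are rejected: angiograms are single-channel.
#'
#' @param path file path; format selected by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param pixel_pitch,provenance metadata attached to the returned image.
#' @return `read_image()` returns an [en_face_image()]; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path, pixel_pitch = 3 / 232, provenance = "single") {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = FALSE, info = TRUE),
    stop(sprintf("unsupported image format '.%s' for %s (use png/tif/tiff)", ext, path),
      call. = FALSE
    )
  )
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] == 1) {
      arr <- arr[, , 1]
    } else {
      stop(sprintf("multi-channel (RGB/RGBA) image rejected: %s is not grayscale", path),
        call. = FALSE
      )
    }
  }
  bits <- attr(arr, "bits.per.sample")
  scale <- if (!is.null(bits) && bits == 16) 65535 else 255
  # readPNG/readTIFF normalise to [0,1]; recover integer grey levels, then
  # express on the 0-255 grey scale used throughout the pipeline
  levels <- round(arr * scale)
  px <- if (scale == 65535) levels / 257 else levels
  en_face_image(px, pixel_pitch = pixel_pitch, provenance = provenance)
}

#' @rdname read_image
#' @param img an [en_face_image()] (or plain matrix) of grey levels 0--255.
#' @param bits bit depth for TIFF output: 8 or 16.
#' @export
write_image <- function(img, path, bits = 8) {
  px <- pixels_of(img)
  px[is.na(px)] <- 0
  ext <- tolower(tools::file_ext(path))
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16", call. = FALSE)
  if (ext == "png") {
    png::writePNG(quantize8(px) / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (bits == 8) {
      tiff::writeTIFF(quantize8(px) / 255, where = path, bits.per.sample = 8L)
    } else {
      tiff::writeTIFF(round(clamp(px, 0, 255) * 257) / 65535, where = path, bits.per.sample = 16L)
    }
  } else {
    stop(sprintf("unsupported image format '.%s' (use png/tif/tiff)", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as 8-bit PNG with values 0/255; any nonzero pixel reads
#' back as `TRUE`.
#'
#' @param path PNG file path.
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path), call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] == 1) arr <- arr[, , 1] else {
      stop(sprintf("multi-channel mask rejected: %s", path), call. = FALSE)
    }
  }
  arr > 0.5
}

#' @rdname read_mask
#' @param mask logical (or 0/1) matrix.
#' @export
write_mask <- function(mask, path) {
  m <- (mask > 0) * 1
  png::writePNG(m, target = path)
  invisible(path)
}
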