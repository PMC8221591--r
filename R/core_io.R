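#' Read a calibrated multichannel scene from disk
#'
#' Reads a multipage TIFF of intensity channels plus an integer-label mask
#' image (multipage TIFF, one page per mask layer, or a single PNG) into a
#' [Scene]. Intensities are read bit-exactly (integer TIFF samples are
#' returned unscaled).
#'
#' Channel and mask-layer names are taken from `channel_names`/`region_names`
#' if given, otherwise from the JSON sidecar `<image_path>.json` written by
#' [writeScene()], otherwise they default to `ch1, ch2, ...` and
#' `mask1, ...`.
#'
#' @param image_path multipage TIFF, one page per channel (8/16-bit).
#' @param mask_path integer-label TIFF (possibly multipage) or PNG of the
#'   same shape as the image.
#' @param calibration microns per pixel, or `NULL` to take it from the
#'   sidecar.
#' @param channel_names,region_names optional character vectors.
#' @return a [Scene]
#' @export
readScene <- function(image_path, mask_path, calibration = NULL,
                      channel_names = NULL, region_names = NULL) {
  if (!file.exists(image_path)) stop("image not found: ", image_path)
  if (!file.exists(mask_path)) stop("mask not found: ", mask_path)
  pages <- tiff::readTIFF(image_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, .dropAlpha)

  sidecar <- paste0(image_path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(channel_names)) channel_names <- meta$channels
  if (is.null(region_names)) region_names <- meta$regions
  if (is.null(calibration)) calibration <- meta$calibration
  if (is.null(calibration)) stop("calibration (um/px) must be supplied or present in the sidecar")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(pages))
  if (length(channel_names) != length(pages)) {
    stop(sprintf("image has %d channels but %d channel names were given",
                 length(pages), length(channel_names)))
  }

  masks <- .readMaskLayers(mask_path)
  if (is.null(region_names)) region_names <- paste0("mask", seq_along(masks))
  if (length(region_names) != length(masks)) {
    stop(sprintf("mask has %d layers but %d layer names were given",
                 length(masks), length(region_names)))
  }
  for (m in masks) {
    if (!identical(dim(m), dim(pages[[1L]]))) {
      stop("mask shape does not match the image shape")
    }
  }
  Scene(setNames(pages, channel_names), calibration, setNames(masks, region_names))
}

.dropAlpha <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  p
}

.readMaskLayers <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    list(matrix(as.integer(round(.dropAlpha(img) * (2^depth - 1))),
                nrow = nrow(as.matrix(.dropAlpha(img)))))
  } else {
    layers <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(layers)) layers <- list(layers)
    lapply(layers, function(m) {
      m <- .dropAlpha(m)
      storage.mode(m) <- "integer"
      m
    })
  }
}

#' Write a scene to disk
#'
#' Writes the channels as a multipage TIFF (8- or 16-bit chosen from the
#' intensity range), the region masks as a multipage 16-bit TIFF, and a JSON
#' sidecar (`<image_path>.json`) with channel names, mask names and the
#' calibration. Intensities must be non-negative integers; the
#' write/read round trip is lossless.
#'
#' @param scene a [Scene]
#' @param image_path,mask_path output paths (TIFF).
#' @return invisibly, the sidecar path.
#' @export
writeScene <- function(scene, image_path, mask_path) {
  stopifnot(is(scene, "Scene"))
  mx <- max(vapply(scene@channels, max, numeric(1)), 0)
  mn <- min(vapply(scene@channels, min, numeric(1)), 0)
  notInt <- any(vapply(scene@channels, function(m) any(m != round(m)), logical(1)))
  if (mn < 0 || notInt || mx > 65535) {
    stop("writeScene() stores 8/16-bit images: intensities must be integers in [0, 65535]")
  }
  bits <- if (mx <= 255) 8L else 16L
  scale <- 2^bits - 1
  tiff::writeTIFF(lapply(scene@channels, function(m) m / scale),
                  image_path, bits.per.sample = bits)
  if (length(scene@regionMasks) == 0L) {
    stop("scene has no region masks to write")
  }
  if (max(vapply(scene@regionMasks, max, numeric(1))) > 65535) {
    stop("mask labels exceed the 16-bit range")
  }
  tiff::writeTIFF(lapply(scene@regionMasks, function(m) m / 65535),
                  mask_path, bits.per.sample = 16L)
  sidecar <- paste0(image_path, ".json")
  jsonlite::write_json(
    list(channels = names(scene@channels),
         regions = names(scene@regionMasks),
         calibration = scene@calibration),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Long-format CT table input/output and validation
#'
#' A CT table is a long-format data.frame with one row per measured
#' amplification well: columns `gene`, `sample`, `ct` are required;
#' `group`, `region`, `fraction` and `replicate` are carried through the
#' analysis when present. CT values must be finite.
#'
#' @param df a candidate CT table.
#' @param require_group if TRUE, a `group` column is also required.
#' @return the validated data.frame (invisibly for the writer).
#' @export
validateCtTable <- function(df, require_group = FALSE) {
  need <- c("gene", "sample", "ct")
  if (require_group) need <- c(need, "group")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("CT table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$ct) || any(!is.finite(df$ct))) {
    stop("CT values must be finite numbers")
  }
  if (nrow(df) == 0L) stop("CT table is empty")
  df
}

#' @rdname validateCtTable
#' @param path CSV path.
#' @export
readCtTable <- function(path, require_group = FALSE) {
  validateCtTable(read.csv(path, stringsAsFactors = FALSE), require_group)
}

#' @rdname validateCtTable
#' @export
writeCtTable <- function(df, path) {
  validateCtTable(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
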