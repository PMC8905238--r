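#' 4-channel multispectral images
#'
#' A `msimage` is an `H x W x 4` integer array of 8-bit values with channels
#' fixed in the order R, G, B, NIR. This mirrors the output of a 4-channel
#' multispectral camera (8 bits per channel) at a nominal scene resolution of
#' 1296 x 964. Scenes are stored either as a pair of lossless PNG files
#' (`<stem>.png` for RGB plus `<stem>_nir.png` for the NIR plane) or as a
#' single 4-sample-per-pixel 8-bit TIFF; both round-trip bit-exactly.
#'
#' @param pixels numeric or integer `H x W x 4` array with values in
#'   `[0, 255]`.
#' @param source_path optional path the image was read from.
#' @return An object of class `msimage`.
#' @examples
#' img <- msimage(array(rep(0:3, each = 25), c(5, 5, 4)))
#' dim(img)
#' @export
msimage <- function(pixels, source_path = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop_invalid("`pixels` must be an H x W x 4 array")
  d <- dim(pixels)
  if (d[3] != 4L)
    stop_invalid(sprintf("a multispectral image needs exactly 4 channels, got %d", d[3]))
  if (d[1] < 1L || d[2] < 1L)
    stop_invalid("image height and width must be at least 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_invalid("pixel values must lie in [0, 255]")
  px <- as.integer(round(pixels))
  dim(px) <- d
  structure(px,
            channel_roles = ms_channel_roles,
            source_path = source_path,
            class = c("msimage", "array"))
}

#' @export
print.msimage <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<msimage> %d x %d, channels %s\n", d[1], d[2],
              paste(attr(x, "channel_roles"), collapse = ",")))
  invisible(x)
}

# fixed channel order used everywhere in the package
ms_channel_roles <- c("R", "G", "B", "NIR")

is_msimage <- function(x) inherits(x, "msimage")

#' Extract one channel plane
#'
#' Returns a copy of the requested plane as a plain numeric matrix; modifying
#' the result does not alter the source image.
#'
#' @param img a [msimage()].
#' @param role one of `"R"`, `"G"`, `"B"`, `"NIR"`.
#' @return An `H x W` numeric matrix of 8-bit values.
#' @export
ms_channel <- function(img, role) {
  if (!is_msimage(img)) stop_invalid("`img` must be a msimage")
  i <- match(role, ms_channel_roles)
  if (is.na(i))
    stop_invalid(sprintf("unknown channel role '%s' (expected R, G, B or NIR)", role))
  matrix(as.numeric(img[, , i]), nrow = dim(img)[1])
}

read_plane_png <- function(path) {
  x <- png::readPNG(path)
  round(x * 255)
}

#' Read a 4-channel multispectral image
#'
#' Accepts either an RGB PNG plus a single-channel NIR PNG of identical size,
#' or a single 4-sample 8-bit TIFF holding all four planes. Channels are
#' always returned in R, G, B, NIR order. A missing NIR source is an error:
#' the package never fabricates a channel.
#'
#' @param rgb_path path to a 3-channel PNG, or to a 4-channel TIFF
#'   (`.tif`/`.tiff`).
#' @param nir_path optional path to a 1-channel PNG with the NIR plane.
#'   If `NULL` and `rgb_path` is a PNG, the sibling file `<stem>_nir.png` is
#'   used when present.
#' @return A [msimage()].
#' @export
read_msimage <- function(rgb_path, nir_path = NULL) {
  if (!file.exists(rgb_path))
    stop_invalid(sprintf("file not found: %s", rgb_path))
  if (grepl("\\.tiff?$", rgb_path, ignore.case = TRUE)) {
    x <- suppressWarnings(tiff::readTIFF(rgb_path))
    if (length(dim(x)) != 3L || dim(x)[3] != 4L)
      stop_invalid(sprintf("%s: expected a 4-sample TIFF, got %s channels",
                           rgb_path, paste(dim(x)[3] %||% 1, collapse = "")))
    return(msimage(round(x * 255), source_path = rgb_path))
  }
  rgb <- read_plane_png(rgb_path)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop_invalid(sprintf("%s: expected a 3-channel image", rgb_path))
  rgb <- rgb[, , 1:3, drop = FALSE]
  if (is.null(nir_path)) {
    cand <- sub("\\.png$", "_nir.png", rgb_path, ignore.case = TRUE)
    if (file.exists(cand)) nir_path <- cand
    else stop_invalid(sprintf(
      "no NIR source for %s: supply `nir_path` or provide %s", rgb_path, cand))
  }
  if (!file.exists(nir_path))
    stop_invalid(sprintf("file not found: %s", nir_path))
  nir <- read_plane_png(nir_path)
  if (length(dim(nir)) == 3L) {
    if (dim(nir)[3] != 1L)
      stop_invalid(sprintf("%s: NIR image must have a single channel", nir_path))
    nir <- nir[, , 1]
  }
  if (!all(dim(nir) == dim(rgb)[1:2]))
    stop_invalid(sprintf(
      "dimension mismatch: RGB is %dx%d but NIR is %dx%d",
      dim(rgb)[1], dim(rgb)[2], dim(nir)[1], dim(nir)[2]))
  px <- array(0, c(dim(rgb)[1:2], 4L))
  px[, , 1:3] <- rgb
  px[, , 4] <- nir
  msimage(px, source_path = rgb_path)
}

#' Write a multispectral image losslessly
#'
#' `.tif`/`.tiff` paths get a single 4-sample 8-bit TIFF; `.png` paths get the
#' paired-file layout `<stem>.png` (RGB) plus `<stem>_nir.png` (NIR). Reading
#' the result back reproduces the pixel values bit-exactly.
#'
#' @param img a [msimage()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_msimage <- function(img, path) {
  if (!is_msimage(img)) stop_invalid("`img` must be a msimage")
  if (!dir.exists(dirname(path)))
    stop_invalid(sprintf("directory does not exist: %s", dirname(path)))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    arr <- array(as.numeric(img) / 255, dim(img))
    suppressWarnings(tiff::writeTIFF(arr, path, bits.per.sample = 8L))
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(array(as.numeric(img[, , 1:3]) / 255, c(dim(img)[1:2], 3L)), path)
    png::writePNG(matrix(as.numeric(img[, , 4]) / 255, nrow = dim(img)[1]),
                  sub("\\.png$", "_nir.png", path, ignore.case = TRUE))
  } else {
    stop_invalid("`path` must end in .png, .tif or .tiff")
  }
  invisible(path)
}

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with columns `image`, `nir`, `label`, `truth`, `split`
#' listing scene or chip files and optional class labels. Relative paths are
#' resolved against the manifest's directory. At read time every referenced
#' file must exist and labels must be `"good"` or `"bad"` (or empty).
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced files exist (default `TRUE`).
#' @return A tibble with columns `image`, `nir`, `label`, `truth`, `split`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  m <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  for (col in c("image", "nir", "label", "truth", "split"))
    if (!col %in% names(m)) m[[col]] <- NA_character_
  m <- as_tibble(m[, c("image", "nir", "label", "truth", "split")])
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(base, p))
  m$image <- resolve(m$image)
  m$nir <- resolve(m$nir)
  m$truth <- resolve(m$truth)
  bad_label <- !is.na(m$label) & !(m$label %in% c("good", "bad", ""))
  if (any(bad_label))
    stop_invalid(sprintf("labels must be 'good' or 'bad'; found: %s",
                         paste(unique(m$label[bad_label]), collapse = ", ")))
  if (check_files) {
    refs <- stats::na.omit(c(m$image, m$nir, m$truth))
    refs <- refs[refs != ""]
    missing <- refs[!file.exists(refs)]
    if (length(missing))
      stop_invalid(sprintf("manifest references missing files: %s",
                           paste(head(missing, 5), collapse = ", ")))
  }
  m
}

#' @rdname read_manifest
#' @param manifest a tibble with (a subset of) the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  for (col in c("image", "nir", "label", "truth", "split"))
    if (!col %in% names(manifest)) manifest[[col]] <- NA_character_
  readr::write_csv(manifest[, c("image", "nir", "label", "truth", "split")], path,
                   progress = FALSE)
  invisible(path)
}
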