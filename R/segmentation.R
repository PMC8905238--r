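#' Segmentation parameters
#'
#' Knobs of the watershed pipeline. Seeds are darker than the backlit
#' background, so binarization keeps pixels *below* the Otsu threshold by
#' default (`invert = TRUE`). `min_area` is stated at the nominal
#' 1296 x 964 scene scale and is rescaled by (scene area / nominal area) for
#' other sizes.
#'
#' @param open_kernel radius in pixels of the elliptical (disc) structuring
#'   element used for opening and dilation.
#' @param open_iterations erosion/dilation repetitions of the opening.
#' @param dilate_iterations dilations applied before marker computation; the
#'   complement of the dilated mask is sure background.
#' @param dist_frac fraction of each component's distance-transform maximum
#'   used to threshold sure-foreground markers (per-component normalization
#'   keeps large seeds from suppressing small seeds' markers).
#' @param min_area instances smaller than this many pixels (nominal scale)
#'   are discarded as noise.
#' @param invert `TRUE` when seeds are darker than the background.
#' @return A validated `seg_params` object.
#' @export
seg_params <- function(open_kernel = 3, open_iterations = 2,
                       dilate_iterations = 3, dist_frac = 0.5,
                       min_area = 200, invert = TRUE) {
  if (dist_frac <= 0 || dist_frac >= 1)
    stop_invalid("`dist_frac` must lie strictly between 0 and 1")
  if (open_kernel < 0 || open_iterations < 0 || dilate_iterations < 0)
    stop_invalid("kernel radius and iteration counts must be >= 0")
  if (min_area < 0) stop_invalid("`min_area` must be >= 0")
  structure(list(open_kernel = open_kernel, open_iterations = open_iterations,
                 dilate_iterations = dilate_iterations, dist_frac = dist_frac,
                 min_area = min_area, invert = invert),
            class = "seg_params")
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

ebi_op <- function(m, fun, brush) {
  EBImage::imageData(fun(m * 1, brush)) > 0.5
}

#' Otsu threshold of an 8-bit plane
#'
#' Maximizes between-class variance on the 256-bin histogram; returns the
#' threshold `T` such that the lower class is `{0..T}`. Errors on
#' constant-intensity input, where the threshold is undefined.
#'
#' @param x matrix of integer-valued intensities in `[0, 255]`.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(x) {
  h <- tabulate(as.integer(round(x)) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L)
    stop("Otsu threshold undefined: constant-intensity image")
  p <- h / sum(h)
  lv <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  between <- (mu[256] * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  which.max(between[1:255]) - 1L
}

#' Binarize a scene on the blue channel
#'
#' Among the four planes the blue channel separates the yellow-orange seeds
#' from the bright background best, so it drives binarization. The Otsu
#' threshold is computed on B; with `invert = TRUE` (seeds darker than
#' background) pixels at or below the threshold become foreground.
#'
#' @param img a [msimage()].
#' @param params a [seg_params()].
#' @return Logical `H x W` mask, `TRUE` on seeds.
#' @export
binarize <- function(img, params = seg_params()) {
  B <- ms_channel(img, "B")
  th <- otsu_threshold(B)
  if (params$invert) B <= th else B > th
}

#' Remove binarization noise by morphological opening
#'
#' Opening with the configured disc element (`open_iterations` erosions then
#' as many dilations) deletes specks smaller than the element while leaving
#' large components nearly unchanged.
#'
#' @param mask logical matrix.
#' @inheritParams binarize
#' @return Cleaned logical mask.
#' @export
clean_mask <- function(mask, params = seg_params()) {
  if (params$open_iterations == 0 || params$open_kernel == 0) return(mask)
  br <- disc_brush(params$open_kernel)
  m <- mask
  for (i in seq_len(params$open_iterations)) m <- ebi_op(m, EBImage::erode, br)
  for (i in seq_len(params$open_iterations)) m <- ebi_op(m, EBImage::dilate, br)
  m
}

#' Compute watershed markers from a cleaned mask
#'
#' The mask is dilated (`dilate_iterations` times); the complement of the
#' dilation is sure background. The Euclidean distance transform of the mask,
#' thresholded at `dist_frac` of each connected component's own maximum,
#' yields the sure-foreground seed cores, labeled 1..K by 8-connected
#' components. The remaining ring (dilated mask minus sure foreground) is the
#' unknown region; the three regions partition the scene.
#'
#' @inheritParams clean_mask
#' @return A list with `markers` (integer label matrix, 0 outside),
#'   `sure_bg`, `unknown` (logical masks), `dist` (distance transform),
#'   `dilated` and `n_markers`.
#' @export
compute_markers <- function(mask, params = seg_params()) {
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) {
    return(list(markers = matrix(0L, H, W), sure_bg = !mask,
                unknown = mask, dist = matrix(0, H, W),
                dilated = mask, n_markers = 0L))
  }
  br <- disc_brush(max(params$open_kernel, 1))
  dil <- mask
  for (i in seq_len(params$dilate_iterations)) dil <- ebi_op(dil, EBImage::dilate, br)
  dist <- EBImage::imageData(EBImage::distmap(mask * 1, metric = "euclidean"))
  comp <- cpp_label8(mask)
  k <- max(comp)
  cmax <- vapply(seq_len(k), function(i) max(dist[comp == i]), numeric(1))
  thr <- matrix(Inf, H, W)
  thr[mask] <- params$dist_frac * cmax[comp[mask]]
  sure_fg <- mask & dist >= thr
  markers <- cpp_label8(sure_fg)
  list(markers = markers, sure_bg = !dil, unknown = dil & !sure_fg,
       dist = dist, dilated = dil, n_markers = max(markers))
}

# turn an instance label matrix into the package's instance tibble
label_matrix_to_instances <- function(lab, min_area = 0) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  rows <- list()
  for (id in ids) {
    hit <- lab == id
    area <- sum(hit)
    if (area < min_area || area == 0) next
    mr <- range(which(rowSums(hit) > 0)); mc <- range(which(colSums(hit) > 0))
    cropped <- hit[mr[1]:mr[2], mc[1]:mc[2], drop = FALSE]
    pix <- which(cropped, arr.ind = TRUE)
    rows[[length(rows) + 1]] <- tibble(
      instance_id = 0L, area = area,
      r0 = mr[1] - 1, c0 = mc[1] - 1, r1 = mr[2], c1 = mc[2],
      centroid_r = mean(pix[, 1] - 1) + mr[1] - 1,
      centroid_c = mean(pix[, 2] - 1) + mc[1] - 1,
      mask = list(cropped))
  }
  if (!length(rows)) {
    return(tibble(instance_id = integer(), area = numeric(),
                  r0 = numeric(), c0 = numeric(), r1 = numeric(), c1 = numeric(),
                  centroid_r = numeric(), centroid_c = numeric(), mask = list()))
  }
  out <- bind_rows(rows)
  out <- out[order(out$centroid_r, out$centroid_c), ]
  out$instance_id <- seq_len(nrow(out))
  out
}

#' Watershed segmentation of a seed scene
#'
#' Runs the full chain [binarize()] -> [clean_mask()] -> [compute_markers()]
#' -> marker-controlled flooding on the inverted distance transform. Every
#' foreground pixel (including watershed ridge pixels) is assigned to the
#' basin of the nearer marker, so instance masks tile the cleaned foreground;
#' instances smaller than the rescaled `min_area` are discarded and IDs are
#' ordered by centroid (row, then column).
#'
#' @inheritParams binarize
#' @return An instance tibble: `instance_id`, `area`, 0-based half-open bbox
#'   (`r0`, `c0`, `r1`, `c1`), `centroid_r`, `centroid_c` and the
#'   bbox-cropped logical `mask`. Masks are pairwise disjoint.
#' @export
watershed_segment <- function(img, params = seg_params()) {
  fg <- clean_mask(binarize(img, params), params)
  mk <- compute_markers(fg, params)
  d <- dim(img)
  min_area <- params$min_area * (d[1] * d[2]) / (1296 * 964)
  if (mk$n_markers == 0L) return(label_matrix_to_instances(matrix(0L, d[1], d[2])))
  flood <- cpp_marker_flood(-mk$dist, mk$markers, mk$dilated)
  flood[!fg] <- 0L
  label_matrix_to_instances(flood, min_area = min_area)
}

# Jaccard overlap of two bbox-cropped masks given 0-based half-open bboxes
jaccard_cropped <- function(r0a, c0a, r1a, c1a, ma,
                            r0b, c0b, r1b, c1b, mb) {
  r0 <- max(r0a, r0b); c0 <- max(c0a, c0b)
  r1 <- min(r1a, r1b); c1 <- min(c1a, c1b)
  inter <- 0
  if (r1 > r0 && c1 > c0) {
    sa <- ma[(r0 - r0a + 1):(r1 - r0a), (c0 - c0a + 1):(c1 - c0a), drop = FALSE]
    sb <- mb[(r0 - r0b + 1):(r1 - r0b), (c0 - c0b + 1):(c1 - c0b), drop = FALSE]
    inter <- sum(sa & sb)
  }
  un <- sum(ma) + sum(mb) - inter
  if (un == 0) 0 else inter / un
}

#' Pairwise Jaccard between two instance tables
#'
#' @param a,b instance tibbles (from [watershed_segment()] or a scene truth)
#'   with bbox columns and cropped `mask` list-columns.
#' @return A `nrow(a) x nrow(b)` matrix of Jaccard indices.
#' @export
instance_jaccard <- function(a, b) {
  J <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      J[i, j] <- jaccard_cropped(a$r0[i], a$c0[i], a$r1[i], a$c1[i], a$mask[[i]],
                                 b$r0[j], b$c0[j], b$r1[j], b$c1[j], b$mask[[j]])
  J
}

#' Extract per-seed chips from a segmented scene
#'
#' Crops all four channels with each instance's bounding box (identical
#' coordinates for the NIR plane), replaces out-of-mask pixels with the
#' scene's per-channel background median so neighboring seeds inside a bbox
#' cannot leak label information, and resizes to `size x size` with bilinear
#' interpolation (identity when the bbox is already at the target size).
#'
#' @param img the source [msimage()].
#' @param instances instance tibble from [watershed_segment()] (or a scene
#'   truth table with the same columns).
#' @param size chip side length (default 224).
#' @param fill `"background"` (default) replaces out-of-mask pixels with the
#'   scene background median; `"none"` keeps the raw crop.
#' @return A chip tibble: `instance_id`, `label` (carried over when
#'   `instances` has one, else `NA`), `pixels`, `mask`.
#' @export
extract_chips <- function(img, instances, size = 224,
                          fill = c("background", "none")) {
  fill <- match.arg(fill)
  d <- dim(img)
  n <- nrow(instances)
  union <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(n)) {
    rs <- (instances$r0[i] + 1):instances$r1[i]
    cs <- (instances$c0[i] + 1):instances$c1[i]
    blk <- union[rs, cs, drop = FALSE]
    union[rs, cs] <- blk | instances$mask[[i]]
  }
  med <- vapply(1:4, function(ch) {
    plane <- img[, , ch]
    median(plane[!union])
  }, numeric(1))
  out_px <- vector("list", n); out_mk <- vector("list", n)
  for (i in seq_len(n)) {
    stopifnot(instances$r0[i] >= 0, instances$c0[i] >= 0,
              instances$r1[i] <= d[1], instances$c1[i] <= d[2])
    rs <- (instances$r0[i] + 1):instances$r1[i]
    cs <- (instances$c0[i] + 1):instances$c1[i]
    m <- instances$mask[[i]]
    crop <- array(0, c(length(rs), length(cs), 4))
    for (ch in 1:4) {
      plane <- matrix(as.numeric(img[rs, cs, ch]), length(rs))
      if (fill == "background") plane[!m] <- med[ch]
      crop[, , ch] <- plane
    }
    chip <- cpp_clip_round_u8(cpp_resize(crop, size, size))
    out_px[[i]] <- chip
    out_mk[[i]] <- cpp_resize(array(m * 1, c(dim(m), 1)), size, size)[, , 1] >= 0.5
  }
  tibble(instance_id = instances$instance_id %||% instances$seed_id,
         label = if ("label" %in% names(instances)) instances$label else NA_character_,
         pixels = out_px, mask = out_mk)
}
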