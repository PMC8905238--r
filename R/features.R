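#' Hand-crafted seed features
#'
#' Five classical descriptors computed on single-seed chips, used with an
#' RBF-SVM as baselines against the two-pathway network: morphological
#' characteristics (MC), RGB color histograms, histograms of oriented
#' gradients (HOG), gray-level co-occurrence matrix statistics (GLCM) and
#' rotation-invariant uniform local binary patterns (LBP). Where a seed mask
#' is available the features are computed over mask pixels only; without one
#' the full chip is used.
#'
#' @name handcrafted-features
NULL

luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Crofton-style perimeter: pi/4 times the count of exposed 4-neighbor edges.
# Exact for digital disks; a few percent high/low on elongated shapes.
mask_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  exposed <- 0
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    exposed <- exposed + sum(pad & !shift_mask(pad, sh[1], sh[2]))
  (pi / 4) * exposed
}

#' Morphological characteristics (5 features)
#'
#' In order: perimeter / equivalent-circle diameter; the equivalent-circle
#' diameter `sqrt(4 * area / pi)` itself (pixels); eccentricity of the
#' area-moment-fitted ellipse; major/minor axis ratio; area / bounding-box
#' area (extent). For a perfect disk the first feature is pi and the axis
#' ratio 1.
#'
#' @param mask non-empty logical seed mask.
#' @return Named numeric vector of length 5.
#' @export
mc_features <- function(mask) {
  if (!any(mask)) stop_invalid("mc_features requires a non-empty mask")
  area <- sum(mask)
  eqd <- sqrt(4 * area / pi)
  per <- mask_perimeter(mask)
  mom <- EBImage::computeFeatures.moment(mask * 1)
  ecc <- mom[1, "m.eccentricity"]
  major <- mom[1, "m.majoraxis"]
  minor <- major * sqrt(1 - ecc^2)
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  extent <- area / ((diff(rr) + 1) * (diff(cc) + 1))
  c(perimeter_ratio = per / eqd, equivalent_diameter = eqd,
    eccentricity = unname(ecc), axis_ratio = unname(major / minor),
    extent = extent)
}

#' RGB color histogram (48 features)
#'
#' 16 equal-width bins per R, G, B channel over `[0, 256)`, each channel
#' histogram normalized to sum 1 and concatenated. Position-invariant by
#' construction.
#'
#' @param pixels `H x W x 4` chip array.
#' @param mask optional logical mask restricting the pixels counted.
#' @return Named numeric vector of length 48.
#' @export
color_histogram <- function(pixels, mask = NULL) {
  sel <- if (is.null(mask)) TRUE else mask
  if (!is.null(mask) && !any(mask)) stop_invalid("empty mask")
  out <- numeric(0)
  for (ch in 1:3) {
    v <- pixels[, , ch][sel]
    h <- tabulate(pmin(floor(v / 16), 15) + 1L, nbins = 16L)
    out <- c(out, h / sum(h))
  }
  names(out) <- paste0(rep(c("R", "G", "B"), each = 16), 1:16)
  out
}

#' Histogram of oriented gradients
#'
#' HOG on the RGB luminance of a 224x224 chip: central-difference gradients,
#' 9 unsigned orientation bins over `[0, 180)`, 8x8-pixel cells, 2x2-cell
#' blocks at stride one cell, L2-hys block normalization (clip at 0.2,
#' renormalize). A constant image yields the all-zero vector.
#'
#' @param pixels `H x W x 4` chip array at 224x224.
#' @param cell_size,orientations,block_cells geometry parameters.
#' @return Numeric vector of length `27 * 27 * 36 = 26244` at the defaults.
#' @export
hog_features <- function(pixels, cell_size = 8, orientations = 9,
                         block_cells = 2) {
  g <- luminance(pixels)
  H <- nrow(g); W <- ncol(g)
  if (H %% cell_size != 0 || W %% cell_size != 0)
    stop_invalid("chip size must be a multiple of the cell size")
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  ang <- atan2(gr, gc) * 180 / pi        # gradient direction
  ang <- ang %% 180                       # unsigned orientation
  bin <- pmin(floor(ang / (180 / orientations)), orientations - 1) + 1
  nr <- H / cell_size; nc <- W / cell_size
  cell_r <- (row(g) - 1) %/% cell_size
  cell_c <- (col(g) - 1) %/% cell_size
  idx <- (cell_r + cell_c * nr) * orientations + bin  # 1-based composite
  hist3 <- rowsum(as.vector(mag), as.vector(idx))
  cells <- array(0, c(orientations, nr, nc))
  cells[as.integer(rownames(hist3))] <- hist3
  nbr <- nr - block_cells + 1; nbc <- nc - block_cells + 1
  blk_len <- orientations * block_cells^2
  out <- numeric(nbr * nbc * blk_len)
  k <- 0
  for (bc in seq_len(nbc)) for (br in seq_len(nbr)) {
    v <- as.vector(cells[, br:(br + block_cells - 1), bc:(bc + block_cells - 1)])
    v <- v / sqrt(sum(v^2) + 1e-6)
    v <- pmin(v, 0.2)
    n2 <- sqrt(sum(v^2))
    if (n2 > 0) v <- v / sqrt(n2^2 + 1e-12)
    out[(k * blk_len + 1):((k + 1) * blk_len)] <- v
    k <- k + 1
  }
  out
}

glcm_offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                     `135` = c(-1, -1))

glcm_stats_one <- function(P) {
  i <- row(P) - 1; j <- col(P) - 1
  contrast <- sum(P * (i - j)^2)
  dissim <- sum(P * abs(i - j))
  homog <- sum(P / (1 + (i - j)^2))
  asm <- sum(P^2)
  mu_i <- sum(P * i); mu_j <- sum(P * j)
  s_i <- sqrt(sum(P * (i - mu_i)^2)); s_j <- sqrt(sum(P * (j - mu_j)^2))
  corr <- if (s_i < 1e-12 || s_j < 1e-12) 1
          else sum(P * (i - mu_i) * (j - mu_j)) / (s_i * s_j)
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = sqrt(asm), correlation = corr, asm = asm)
}

#' Gray-level co-occurrence features (24 features)
#'
#' The luminance is quantized to 32 gray levels; symmetric, normalized
#' co-occurrence matrices at distance 1 are built for angles 0, 45, 90 and
#' 135 degrees (pairs restricted to the mask when one is given), and six
#' statistics — contrast, dissimilarity, homogeneity, energy, correlation,
#' angular second moment — are computed per angle and concatenated.
#'
#' @inheritParams color_histogram
#' @param levels number of gray levels after quantization.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(pixels, mask = NULL, levels = 32) {
  if (!is.null(mask) && !any(mask)) stop_invalid("empty mask")
  g <- pmin(floor(luminance(pixels) / (256 / levels)), levels - 1)
  H <- nrow(g); W <- ncol(g)
  inmask <- if (is.null(mask)) matrix(TRUE, H, W) else mask
  out <- numeric(0)
  for (aname in names(glcm_offsets)) {
    off <- glcm_offsets[[aname]]
    r1 <- max(1, 1 - off[1]):min(H, H - off[1])
    c1 <- max(1, 1 - off[2]):min(W, W - off[2])
    a <- g[r1, c1]; b <- g[r1 + off[1], c1 + off[2]]
    ok <- inmask[r1, c1] & inmask[r1 + off[1], c1 + off[2]]
    counts <- tabulate(a[ok] * levels + b[ok] + 1L, nbins = levels^2)
    P <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + t(P)                         # symmetric
    P <- P / sum(P)
    st <- glcm_stats_one(P)
    names(st) <- paste0("a", aname, "_", names(st))
    out <- c(out, st)
  }
  out
}

# 10-bin rotation-invariant uniform LBP (P = 8 neighbors at radius 1, using
# the 8 adjacent pixels). Bin k (k = 0..8) counts uniform patterns with k
# set bits; bin 10 collects non-uniform patterns.
lbp_codes <- local({
  bits <- function(x) as.integer(intToBits(x))[1:8]
  vapply(0:255, function(code) {
    b <- bits(code)
    trans <- sum(b != c(b[-1], b[1]))
    if (trans <= 2) sum(b) + 1L else 10L
  }, integer(1))
})

#' Rotation-invariant uniform LBP histogram (10 features)
#'
#' Each interior pixel is coded by comparing its 8 neighbors to the center
#' (`neighbor >= center`); uniform codes (at most two 0/1 transitions around
#' the circle) are binned by their number of set bits (0-8), all others share
#' a tenth bin. The histogram over (masked) interior pixels is normalized to
#' sum 1. Invariant to monotone gray-level shifts and to 90-degree rotations
#' exactly.
#'
#' @inheritParams color_histogram
#' @return Named numeric vector of length 10.
#' @export
lbp_histogram <- function(pixels, mask = NULL) {
  if (!is.null(mask) && !any(mask)) stop_invalid("empty mask")
  g <- luminance(pixels)
  H <- nrow(g); W <- ncol(g)
  ctr <- g[2:(H - 1), 2:(W - 1)]
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  code <- matrix(0L, H - 2, W - 2)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- g[2:(H - 1) + o[1], 2:(W - 1) + o[2]]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1L)
  }
  binmat <- matrix(lbp_codes[code + 1L], H - 2, W - 2)
  sel <- if (is.null(mask)) TRUE else mask[2:(H - 1), 2:(W - 1)]
  h <- tabulate(binmat[sel], nbins = 10L)
  setNames(h / sum(h), c(paste0("u", 0:8), "nonuniform"))
}

#' Extract features for a chip table
#'
#' @param chips a chip tibble with `pixels` (and optionally `mask`).
#' @param method one of `"mc"`, `"color"`, `"hog"`, `"glcm"`, `"lbp"`.
#' @return A tibble with `chip_id`, `label` and one column per feature.
#' @export
extract_features <- function(chips, method = c("mc", "color", "hog", "glcm", "lbp")) {
  method <- match.arg(method)
  has_mask <- "mask" %in% names(chips)
  feat <- lapply(seq_len(nrow(chips)), function(i) {
    px <- chips$pixels[[i]]
    m <- if (has_mask) chips$mask[[i]] else NULL
    switch(method,
           mc = mc_features(if (is.null(m))
             matrix(TRUE, dim(px)[1], dim(px)[2]) else m),
           color = color_histogram(px, m),
           hog = hog_features(px),
           glcm = glcm_features(px, m),
           lbp = lbp_histogram(px, m))
  })
  X <- do.call(rbind, feat)
  if (is.null(colnames(X))) colnames(X) <- paste0(method, seq_len(ncol(X)))
  id <- if ("chip_id" %in% names(chips)) chips$chip_id else seq_len(nrow(chips))
  lab <- if ("label" %in% names(chips)) chips$label else NA_character_
  bind_cols(tibble(chip_id = id, label = lab), as_tibble(X))
}

#' RBF-SVM baseline on hand-crafted features
#'
#' Features are standardized with training-set statistics, then an RBF
#' kernel SVM (`C = 1`, `gamma = 1 / (d * var(X))`) is fit. Deterministic
#' given its inputs.
#'
#' @param features numeric feature matrix (rows = seeds) or a tibble from
#'   [extract_features()].
#' @param labels character vector of `"good"`/`"bad"` labels (taken from the
#'   tibble's `label` column when omitted).
#' @return An object of class `svm_baseline`.
#' @export
train_svm_baseline <- function(features, labels = NULL) {
  if (is_tibble(features)) {
    labels <- labels %||% features$label
    features <- as.matrix(features[, setdiff(names(features), c("chip_id", "label"))])
  }
  if (length(unique(labels)) < 2)
    stop_invalid("training set must contain both classes")
  if (min(table(labels)) < 2)
    stop_invalid("need at least 2 samples per class")
  mu <- colMeans(features)
  sdev <- apply(features, 2, sd); sdev[sdev < 1e-12] <- 1
  Xs <- scale(features, center = mu, scale = sdev)
  gamma <- 1 / (ncol(Xs) * max(var(as.vector(Xs)), 1e-12))
  fit <- e1071::svm(x = Xs, y = factor(labels, levels = c("good", "bad")),
                    kernel = "radial", cost = 1, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = mu, scale = sdev, gamma = gamma),
            class = "svm_baseline")
}

#' @rdname train_svm_baseline
#' @param model an `svm_baseline`.
#' @export
predict_svm_baseline <- function(model, features) {
  stopifnot(inherits(model, "svm_baseline"))
  if (is_tibble(features))
    features <- as.matrix(features[, setdiff(names(features), c("chip_id", "label"))])
  Xs <- scale(features, center = model$center, scale = model$scale)
  as.character(predict(model$fit, Xs))
}

#' Benchmark feature/SVM baselines on one split
#'
#' Extracts each requested feature family, fits the SVM on the training
#' split and reports held-out accuracy — used to compare descriptor families
#' on the same data.
#'
#' @param chips a labeled chip tibble.
#' @param methods feature families to benchmark.
#' @param test_fraction,rng_seed passed to [split_dataset()].
#' @return A tibble with `method` and `accuracy`.
#' @export
baseline_benchmark <- function(chips, methods = c("mc", "color", "hog", "glcm", "lbp"),
                               test_fraction = 0.25, rng_seed = 1) {
  sp <- split_dataset(chips, test_fraction, rng_seed)
  rows <- lapply(methods, function(m) {
    tr <- extract_features(sp$train, m)
    te <- extract_features(sp$test, m)
    fit <- train_svm_baseline(tr)
    pred <- predict_svm_baseline(fit, te)
    tibble(method = m, accuracy = mean(pred == te$label))
  })
  bind_rows(rows)
}
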