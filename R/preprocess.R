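#' Augmentation settings for chip datasets
#'
#' The three augmentation families are multiplicative brightness changes,
#' rotations about the chip center, and additive Gaussian pixel noise.
#' Rotations by multiples of 90 degrees are lossless array moves; other
#' angles use bilinear resampling.
#'
#' @param brightness_deltas multiplicative brightness factors.
#' @param rotation_angles rotation angles in degrees, in `[0, 360)`.
#' @param gaussian_sigma standard deviation of the additive noise (8-bit).
#' @param target_per_class optional per-class size the augmented set should
#'   reach.
#' @param rng_seed integer seed controlling which (chip, op) combinations are
#'   drawn.
#' @return A validated `aug_spec` object.
#' @export
aug_spec <- function(brightness_deltas = c(0.8, 1.2),
                     rotation_angles = c(90, 180, 270),
                     gaussian_sigma = 5, target_per_class = NULL,
                     rng_seed = 1) {
  if (any(brightness_deltas <= 0)) stop_invalid("brightness factors must be > 0")
  if (any(rotation_angles < 0 | rotation_angles >= 360))
    stop_invalid("rotation angles must lie in [0, 360)")
  if (gaussian_sigma < 0) stop_invalid("`gaussian_sigma` must be >= 0")
  structure(list(brightness_deltas = brightness_deltas,
                 rotation_angles = rotation_angles,
                 gaussian_sigma = gaussian_sigma,
                 target_per_class = target_per_class, rng_seed = rng_seed),
            class = "aug_spec")
}

aug_op <- function(type, value) list(type = type, value = value)

ops_from_spec <- function(spec) {
  c(lapply(spec$brightness_deltas, function(f) aug_op("brightness", f)),
    lapply(spec$rotation_angles, function(a) aug_op("rotate", a)),
    if (spec$gaussian_sigma > 0) list(aug_op("noise", spec$gaussian_sigma)))
}

rot90k <- function(plane, k) {
  k <- k %% 4
  for (i in seq_len(k)) plane <- t(plane)[ncol(plane):1, , drop = FALSE]
  plane
}

#' Apply one augmentation to a chip
#'
#' Label, shape and (for intensity ops) the mask are preserved. Brightness
#' scales all four channels; rotation by a 90-degree multiple is exact, other
#' angles resample bilinearly about the center filling uncovered corners with
#' the channel median; noise is drawn per pixel and channel. Values are
#' clipped to `[0, 255]`.
#'
#' @param pixels an `H x W x 4` chip array.
#' @param op a list `list(type = , value = )` with type `"brightness"`
#'   (factor), `"rotate"` (degrees) or `"noise"` (sigma).
#' @param mask optional logical matrix, rotated alongside the pixels.
#' @param rng_seed optional seed for the noise op.
#' @return A list with `pixels` and `mask`.
#' @export
augment_chip <- function(pixels, op, mask = NULL, rng_seed = NULL) {
  d <- dim(pixels)
  out <- switch(op$type,
    brightness = pmin(pmax(pixels * op$value, 0), 255),
    rotate = {
      ang <- op$value %% 360
      if (ang %% 90 == 0) {
        k <- ang %/% 90
        r <- array(0, d)
        for (ch in 1:4) r[, , ch] <- rot90k(pixels[, , ch], k)
        if (!is.null(mask)) mask <- rot90k(mask, k)
        r
      } else {
        med <- vapply(1:4, function(ch) median(pixels[, , ch]), numeric(1))
        r <- array(0, d)
        for (ch in 1:4) {
          rc <- cpp_rotate(array(pixels[, , ch], c(d[1], d[2], 1)),
                           ang * pi / 180, med[ch])
          r[, , ch] <- rc[, , 1]
        }
        if (!is.null(mask))
          mask <- cpp_rotate(array(mask * 1, c(d[1], d[2], 1)),
                             ang * pi / 180, 0)[, , 1] >= 0.5
        pmin(pmax(r, 0), 255)
      }
    },
    noise = with_seed(rng_seed,
      pmin(pmax(pixels + array(rnorm(prod(d), sd = op$value), d), 0), 255)),
    stop_invalid(sprintf("unknown augmentation op '%s'", op$type)))
  out <- round(out)
  dim(out) <- d
  list(pixels = out, mask = mask)
}

#' Grow a chip dataset by augmentation
#'
#' Originals are always retained. With `target_per_class` set, (chip, op)
#' pairs are drawn deterministically under `rng_seed` until each class
#' reaches the target (a target at or below the input count returns the
#' originals unchanged — never subsampling). Without a target, every single
#' augmentation op is applied to every chip.
#'
#' @param chips a chip tibble (`chip_id`, `label`, `pixels`, optional `mask`).
#' @param spec an [aug_spec()].
#' @return An augmented chip tibble; new rows get fresh `chip_id`s.
#' @export
build_augmented_dataset <- function(chips, spec = aug_spec()) {
  stopifnot(is_tibble(chips), all(c("label", "pixels") %in% names(chips)))
  ops <- ops_from_spec(spec)
  has_mask <- "mask" %in% names(chips)
  classes <- sort(unique(chips$label))
  target <- spec$target_per_class
  if (!is.null(target)) {
    # for good/bad chip sets both classes must be present to reach a target
    expected <- if (all(chips$label %in% c("good", "bad"))) c("bad", "good")
                else classes
    for (cl in setdiff(expected, classes))
      stop_invalid(sprintf("class '%s' has no chips to augment", cl))
  }
  with_seed(spec$rng_seed, {
    new_rows <- list()
    for (cl in classes) {
      idx <- which(chips$label == cl)
      n_new <- if (is.null(target)) length(idx) * length(ops)
               else max(0, target - length(idx))
      if (n_new == 0) next
      pick_chip <- if (is.null(target)) rep(idx, each = length(ops))
                   else sample(idx, n_new, replace = TRUE)
      pick_op <- if (is.null(target)) rep(seq_along(ops), times = length(idx))
                 else sample(seq_along(ops), n_new, replace = TRUE)
      for (i in seq_len(n_new)) {
        src <- pick_chip[i]
        a <- augment_chip(chips$pixels[[src]], ops[[pick_op[i]]],
                          mask = if (has_mask) chips$mask[[src]] else NULL)
        row <- chips[src, ]
        row$pixels <- list(a$pixels)
        if (has_mask) row$mask <- list(a$mask)
        new_rows[[length(new_rows) + 1]] <- row
      }
    }
    out <- bind_rows(chips, bind_rows(new_rows))
    out$chip_id <- seq_len(nrow(out))
    out
  })
}

#' Stratified train/test split
#'
#' Splits a chip tibble into disjoint train and test sets, stratified by
#' class. The overall test size is `floor(n * test_fraction + 0.5)`;
#' per-class sizes follow largest-remainder allocation (ties broken by class
#' order), so each class is within one chip of its exact fraction. With 7,826
#' chips split at the default fraction this yields 5,869 train and 1,957 test
#' chips.
#'
#' @param chips a chip tibble with a `label` column.
#' @param test_fraction fraction of each class assigned to the test set,
#'   strictly between 0 and 1 (default 0.25).
#' @param rng_seed integer seed; identical seeds give identical splits.
#' @return `list(train = , test = )` of chip tibbles.
#' @export
split_dataset <- function(chips, test_fraction = 0.25, rng_seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_invalid("`test_fraction` must lie strictly between 0 and 1")
  classes <- sort(unique(chips$label))
  counts <- vapply(classes, function(cl) sum(chips$label == cl), numeric(1))
  if (any(counts < 2))
    stop_invalid("every class needs at least 2 chips to split")
  n_test_total <- floor(nrow(chips) * test_fraction + 0.5)
  exact <- counts * test_fraction
  base <- floor(exact)
  short <- n_test_total - sum(base)
  rem_order <- order(exact - base, decreasing = TRUE)  # ties: class order
  take <- base
  if (short > 0) take[rem_order[seq_len(short)]] <- take[rem_order[seq_len(short)]] + 1
  with_seed(rng_seed, {
    test_idx <- integer()
    for (k in seq_along(classes)) {
      idx <- which(chips$label == classes[k])
      test_idx <- c(test_idx, sample(idx, take[k]))
    }
    list(train = chips[setdiff(seq_len(nrow(chips)), test_idx), ],
         test = chips[sort(test_idx), ])
  })
}
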