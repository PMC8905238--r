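test_that("Otsu binarization finds the disk and respects intensity inversion", {
  img <- disk_image()
  mask <- binarize(img)
  truth <- disk_mask(120, 140, 60, 70, 20)
  inter <- sum(mask & truth); un <- sum(mask | truth)
  expect_gte(inter / un, 0.98)
  # inverting intensities with the invert flag toggled gives the same mask
  inv <- msimage(255 - unclass(img)[, , ])
  mask_inv <- binarize(inv, seg_params(invert = FALSE))
  expect_identical(mask, mask_inv)
  # constant image: threshold undefined
  flat <- msimage(array(255, c(10, 10, 4)))
  expect_error(binarize(flat), "constant")
})

test_that("opening removes specks, preserves large components, and is idempotent", {
  set.seed(4)
  H <- 150; W <- 150
  disk <- disk_mask(H, W, 75, 75, 20)
  speck_idx <- sample(which(!cornseed:::dilate1(cornseed:::dilate1(disk))), 30)
  noisy <- disk
  noisy[speck_idx] <- TRUE
  cleaned <- clean_mask(noisy, seg_params())
  expect_true(all(!cleaned[speck_idx]))          # all specks gone
  expect_lt(abs(sum(cleaned) - sum(disk)) / sum(disk), 0.15)
  expect_identical(clean_mask(cleaned, seg_params()), cleaned)
  expect_identical(clean_mask(matrix(FALSE, 20, 20), seg_params()),
                   matrix(FALSE, 20, 20))
})

test_that("markers split touching disks and sit at disk centers", {
  H <- 120; W <- 160
  two <- disk_mask(H, W, 60, 60, 15) | disk_mask(H, W, 60, 90, 15)
  mk <- compute_markers(two, seg_params())
  expect_equal(mk$n_markers, 2)
  one <- disk_mask(H, W, 60, 80, 15)
  mk1 <- compute_markers(one, seg_params())
  expect_equal(mk1$n_markers, 1)
  pix <- which(mk1$markers == 1, arr.ind = TRUE)
  expect_lt(sqrt((mean(pix[, 1]) - 60)^2 + (mean(pix[, 2]) - 80)^2), 2)
  # the three regions partition the scene
  expect_true(all(mk1$sure_bg + mk1$unknown + (mk1$markers > 0) == 1))
  empty <- compute_markers(matrix(FALSE, 30, 30), seg_params())
  expect_equal(empty$n_markers, 0)
})

test_that("watershed recovers every seed mask in a separated scene", {
  sc <- scene_separated()
  inst <- watershed_segment(sc$image)
  expect_equal(nrow(inst), nrow(sc$truth))
  J <- instance_jaccard(inst, sc$truth)
  expect_true(all(apply(J, 1, max) >= 0.9))
  # determinism
  inst2 <- watershed_segment(sc$image)
  expect_identical(inst$mask, inst2$mask)
  # instance ids ordered by centroid
  expect_true(all(diff(order(inst$centroid_r, inst$centroid_c)) > 0))
  # empty scene
  e <- generate_scene(scene_spec(width = 200, height = 150, n_seeds = 0,
                                 rng_seed = 1))
  expect_error(ws <- watershed_segment(e$image), NA)
  expect_equal(nrow(ws), 0)
})

test_that("touching disks split within 2 px of the tangent line", {
  H <- 140; W <- 180
  img_arr <- array(230, c(H, W, 4))
  two <- disk_mask(H, W, 70, 74, 15) | disk_mask(H, W, 70, 105, 15)
  for (ch in 1:4) { p <- img_arr[, , ch]; p[two] <- 90; img_arr[, , ch] <- p }
  inst <- watershed_segment(msimage(img_arr))
  expect_equal(nrow(inst), 2)
  # equal-radius disks: the equidistant locus is the vertical line col ~ 89.5
  for (i in 1:2) {
    m <- inst$mask[[i]]
    cols <- (inst$c0[i] + 1):inst$c1[i]
    border_cols <- cols[colSums(m) > 0]
    if (inst$centroid_c[i] < 89) expect_lte(max(border_cols), 92)
    else expect_gte(min(border_cols), 88)
  }
})

test_that("instance masks partition the cleaned foreground disjointly", {
  sc <- scene_touching()
  params <- seg_params()
  inst <- watershed_segment(sc$image, params)
  fg <- clean_mask(binarize(sc$image, params), params)
  lab <- cornseed:::instances_to_label_matrix(inst, dim(sc$image)[1:2])
  expect_true(all(fg[lab > 0]))     # union within cleaned foreground
  J <- instance_jaccard(inst, inst)
  expect_true(all(J[upper.tri(J)] == 0))
  # every sufficiently large foreground pixel region is labeled
  expect_true(sum(lab > 0) / sum(fg) > 0.95)
})

test_that("watershed equals connected-component labeling when nothing touches", {
  sc <- scene_separated()
  params <- seg_params()
  inst <- watershed_segment(sc$image, params)
  fg <- clean_mask(binarize(sc$image, params), params)
  cc <- cornseed:::label_matrix_to_instances(
    cornseed:::cpp_label8(fg),
    min_area = params$min_area * prod(dim(sc$image)[1:2]) / (1296 * 964))
  expect_equal(nrow(inst), nrow(cc))
  expect_equal(inst$area, cc$area)
  J <- instance_jaccard(inst, cc)
  expect_true(all(diag(J) == 1))
})

test_that("chips resample bilinearly with background fill at bbox coordinates", {
  sc <- scene_separated()
  inst <- watershed_segment(sc$image)
  chips <- extract_chips(sc$image, inst)
  expect_equal(dim(chips$pixels[[1]]), c(224, 224, 4))
  expect_equal(nrow(chips), nrow(inst))
  # native-size bbox: resize is the identity (fill leaves in-mask pixels)
  arr <- array(rep(seq(0, 255, length.out = 224), 224 * 4), c(224, 224, 4))
  ident <- cornseed:::cpp_resize(arr, 224, 224)
  expect_equal(ident, arr)
  # closed-form bilinear on a linear ramp: interior values interpolate the
  # ramp exactly; nearest-neighbor output differs
  ramp <- array(rep(0:9, each = 1) * 10, c(10, 1, 1))
  ramp <- array(rep(ramp, 10), c(10, 10, 1))
  up_b <- cornseed:::cpp_resize(ramp, 20, 20, nearest = FALSE)
  up_n <- cornseed:::cpp_resize(ramp, 20, 20, nearest = TRUE)
  # target row 10 (0-based 9) maps to source (9 + 0.5)/2 - 0.5 = 4.25,
  # i.e. 0.75 * 40 + 0.25 * 50
  expect_equal(up_b[10, 5, 1], 0.75 * 40 + 0.25 * 50, tolerance = 1e-9)
  expect_false(all(up_b == up_n))
})
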