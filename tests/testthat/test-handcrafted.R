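test_that("morphological features recover closed-form shape descriptors", {
  disk <- disk_mask(61, 61, 31, 31, 20)
  f <- mc_features(disk)
  expect_lt(abs(f["perimeter_ratio"] - pi) / pi, 0.05)
  expect_lt(f["eccentricity"], 0.1)
  expect_lt(abs(f["axis_ratio"] - 1), 0.05)
  expect_lt(abs(f["equivalent_diameter"] - 40) / 40, 0.03)
  # full rectangle: extent exactly 1
  rect <- matrix(TRUE, 20, 35)
  expect_equal(unname(mc_features(rect)["extent"]), 1)
  # 2:1 ellipse: axis ratio ~2, eccentricity ~sqrt(3)/2
  ell <- outer(1:121, 1:121, function(r, c)
    ((r - 61) / 20)^2 + ((c - 61) / 40)^2 <= 1)
  fe <- mc_features(ell)
  expect_lt(abs(fe["axis_ratio"] - 2), 0.05)
  expect_lt(abs(fe["eccentricity"] - sqrt(3) / 2), 0.01)
  expect_error(mc_features(matrix(FALSE, 5, 5)), "non-empty")
})

test_that("color histograms normalize per channel and ignore pixel positions", {
  px <- array(0, c(16, 16, 4))
  px[, , 1] <- 200; px[, , 2] <- 100; px[, , 3] <- 30
  f <- color_histogram(px)
  expect_length(f, 48)
  expect_equal(unname(f["R13"]), 1)  # 200 falls in bin 13
  expect_equal(sum(f), 3)
  set.seed(1)
  px2 <- array(sample(0:255, 16 * 16 * 4, TRUE), c(16, 16, 4))
  perm <- sample(256)
  px3 <- px2
  for (ch in 1:3) px3[, , ch] <- matrix(px2[, , ch][perm], 16)
  expect_equal(color_histogram(px2), color_histogram(px3))
})

test_that("HOG is zero on flat images and localizes a step edge", {
  flat <- array(128, c(224, 224, 4))
  expect_true(all(hog_features(flat) == 0))
  # vertical step edge: all gradient energy in the bin containing 0/180 deg
  step <- array(0, c(224, 224, 4))
  step[, 113:224, 1:3] <- 200
  f <- matrix(hog_features(step), nrow = 9)
  by_orientation <- rowSums(f)
  expect_equal(which.max(by_orientation), 1)
  expect_gt(by_orientation[1] / sum(by_orientation), 0.99)
  # unsigned gradients: a 180-degree rotation preserves the vector norm
  chip <- chips_small()$pixels[[1]]
  rot <- augment_chip(chip, list(type = "rotate", value = 180))$pixels
  expect_equal(sqrt(sum(hog_features(chip)^2)), sqrt(sum(hog_features(rot)^2)),
               tolerance = 1e-6)
})

test_that("GLCM statistics match hand-computed co-occurrence matrices", {
  flat <- array(77, c(32, 32, 4))
  f <- glcm_features(flat)
  expect_length(f, 24)
  for (a in c("a0", "a45", "a90", "a135")) {
    expect_equal(unname(f[paste0(a, "_contrast")]), 0)
    expect_equal(unname(f[paste0(a, "_dissimilarity")]), 0)
    expect_equal(unname(f[paste0(a, "_homogeneity")]), 1)
    expect_equal(unname(f[paste0(a, "_energy")]), 1)
    expect_equal(unname(f[paste0(a, "_asm")]), 1)
  }
  # energy = sqrt(ASM) on any input
  chip <- chips_small()$pixels[[2]]
  fc <- glcm_features(chip)
  for (a in c("a0", "a45", "a90", "a135"))
    expect_equal(unname(fc[paste0(a, "_energy")]),
                 sqrt(unname(fc[paste0(a, "_asm")])), tolerance = 1e-12)
  # checkerboard of extreme levels: horizontal pairs always differ by 31
  H <- 32
  board <- outer(1:H, 1:H, function(r, c) ifelse((r + c) %% 2 == 0, 0, 255))
  pxb <- array(0, c(H, H, 4))
  for (ch in 1:3) pxb[, , ch] <- board
  fb <- glcm_features(pxb)
  expect_equal(unname(fb["a0_contrast"]), 31^2)
  expect_equal(unname(fb["a90_contrast"]), 31^2)
  # diagonal neighbors are equal on a checkerboard
  expect_equal(unname(fb["a45_contrast"]), 0)
})

test_that("LBP histograms are gray-shift and 90-degree-rotation invariant", {
  flat <- array(50, c(32, 32, 4))
  f <- lbp_histogram(flat)
  expect_length(f, 10)
  expect_equal(unname(f["u8"]), 1)  # all-neighbors-equal pattern
  chip <- chips_small()$pixels[[3]]
  # headroom so adding 50 does not clip
  px <- chip; px[, , 1:3] <- pmin(px[, , 1:3], 200)
  shifted <- px; shifted[, , 1:3] <- shifted[, , 1:3] + 50
  expect_equal(lbp_histogram(px), lbp_histogram(shifted))
  rot <- augment_chip(px, list(type = "rotate", value = 90))$pixels
  expect_equal(lbp_histogram(px), lbp_histogram(rot), tolerance = 1e-3)
})

test_that("the SVM baseline separates separable clusters and responds to C", {
  set.seed(5)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  y <- rep(c("good", "bad"), each = 50)
  fit <- train_svm_baseline(X, y)
  expect_equal(mean(predict_svm_baseline(fit, X) == y), 1)
  # overlapping clusters: support vectors shrink as C grows
  Xo <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 1), 100))
  yo <- factor(rep(c("good", "bad"), each = 100), levels = c("good", "bad"))
  nsv <- vapply(c(0.01, 1, 100), function(C) {
    f <- e1071::svm(x = scale(Xo), y = yo, kernel = "radial", cost = C,
                    gamma = 1 / ncol(Xo), scale = FALSE)
    f$tot.nSV
  }, numeric(1))
  expect_true(nsv[1] >= nsv[2] && nsv[2] >= nsv[3])
  expect_gt(nsv[1], nsv[3])
  expect_error(train_svm_baseline(X, rep("good", 100)), "both classes")
})

test_that("feature extraction is deterministic with fixed lengths", {
  chips <- chips_small()[1:6, ]
  lens <- c(mc = 5, color = 48, glcm = 24, lbp = 10)
  for (m in names(lens)) {
    t1 <- extract_features(chips, m)
    t2 <- extract_features(chips, m)
    expect_identical(t1, t2)
    expect_equal(ncol(t1) - 2, unname(lens[m]))
    expect_true(all(is.finite(as.matrix(t1[, -(1:2)]))))
  }
  th <- extract_features(chips[1:2, ], "hog")
  expect_equal(ncol(th) - 2, 27 * 27 * 36)
})
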