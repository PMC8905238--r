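test_that("identity-like augmentations leave chips unchanged", {
  chip <- chips_small()$pixels[[1]]
  expect_equal(augment_chip(chip, list(type = "rotate", value = 0))$pixels, chip)
  expect_equal(augment_chip(chip, list(type = "brightness", value = 1))$pixels, chip)
  expect_equal(augment_chip(chip, list(type = "noise", value = 0),
                            rng_seed = 1)$pixels, chip)
  expect_error(augment_chip(chip, list(type = "shear", value = 1)), "unknown")
})

test_that("90-degree rotations form a cyclic group and keep labels/shape", {
  chip <- chips_small()$pixels[[2]]
  mask <- chips_small()$mask[[2]]
  out <- list(pixels = chip, mask = mask)
  for (i in 1:4)
    out <- augment_chip(out$pixels, list(type = "rotate", value = 90), out$mask)
  expect_equal(out$pixels, chip)
  expect_equal(out$mask, mask)
  r180a <- augment_chip(chip, list(type = "rotate", value = 90))$pixels
  r180a <- augment_chip(r180a, list(type = "rotate", value = 90))$pixels
  r180b <- augment_chip(chip, list(type = "rotate", value = 180))$pixels
  expect_equal(r180a, r180b)
  # arbitrary-angle rotation preserves shape and range
  r33 <- augment_chip(chip, list(type = "rotate", value = 33))$pixels
  expect_equal(dim(r33), dim(chip))
  expect_true(min(r33) >= 0 && max(r33) <= 255)
})

test_that("augmented datasets hit per-class targets deterministically", {
  chips <- chips_small()[1:20, ]
  spec <- aug_spec(target_per_class = 40, rng_seed = 5)
  out <- build_augmented_dataset(chips, spec)
  expect_true(all(table(out$label) == 40))
  out2 <- build_augmented_dataset(chips, spec)
  expect_identical(out$pixels, out2$pixels)
  # originals retained verbatim
  for (i in seq_len(nrow(chips)))
    expect_identical(out$pixels[[i]], chips$pixels[[i]])
  # target below input: unchanged
  small <- aug_spec(target_per_class = 2, rng_seed = 5)
  same <- build_augmented_dataset(chips, small)
  expect_equal(nrow(same), nrow(chips))
  # no target: every op applied to every chip
  all_ops <- build_augmented_dataset(chips, aug_spec(rng_seed = 1))
  expect_equal(nrow(all_ops), nrow(chips) * (1 + 6))
  # labels never change
  expect_true(all(out$label %in% c("good", "bad")))
  expect_error(build_augmented_dataset(chips[chips$label == "good", ],
                                       aug_spec(target_per_class = 10)),
               "no chips")
})

test_that("stratified splits partition the data at the printed ratios", {
  chips <- chips_small()
  sp <- split_dataset(chips, 0.25, rng_seed = 2)
  expect_equal(sort(c(sp$train$chip_id, sp$test$chip_id)), chips$chip_id)
  expect_length(intersect(sp$train$chip_id, sp$test$chip_id), 0)
  # per-class sizes within 1 of the exact fraction
  for (cl in c("good", "bad")) {
    n_cl <- sum(chips$label == cl)
    expect_lte(abs(sum(sp$test$label == cl) - 0.25 * n_cl), 1)
  }
  sp2 <- split_dataset(chips, 0.25, rng_seed = 2)
  expect_identical(sp$test$chip_id, sp2$test$chip_id)
  # the published totals: 7,826 chips -> 5,869 train / 1,957 test
  dummy <- tibble::tibble(chip_id = 1:7826,
                          label = rep(c("good", "bad"), each = 3913),
                          pixels = vector("list", 7826))
  big <- split_dataset(dummy, 0.25, rng_seed = 1)
  expect_equal(nrow(big$train), 5869)
  expect_equal(nrow(big$test), 1957)
  expect_error(split_dataset(dummy, 1.2), "between 0 and 1")
  expect_error(split_dataset(dummy[c(1, 3914), ], 0.25), "at least 2")
})
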