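test_that("rendered seeds have the promised geometry and defect signal", {
  s <- render_seed(20, 20, 0, defect = FALSE, rng_seed = 5)
  # circular mask (possibly tip-truncated): area within 5% of pi r^2
  expect_lt(abs(sum(s$mask) - pi * 400) / (pi * 400), 0.05)
  expect_true(all(s$patch[, , 1][!s$mask] == 0))
  # defect seeds: a blotch pixel at least 60 levels below the B median
  for (seed in 1:5) {
    d <- render_seed(25, 18, 0.8, defect = TRUE, rng_seed = seed)
    expect_gt(sum(d$blotch), 0)
    B <- d$patch[, , 3]
    expect_gte(median(B[d$mask]) - min(B[d$blotch]), 60)
  }
  # same seed, same seed render
  a <- render_seed(24, 19, 1, defect = TRUE, rng_seed = 42)
  b <- render_seed(24, 19, 1, defect = TRUE, rng_seed = 42)
  expect_identical(a$patch, b$patch)
  expect_identical(a$mask, b$mask)
  expect_error(render_seed(3, 5), "axis_a >= axis_b")
})

test_that("NIR mixes RGB and darkens further inside blotches", {
  d <- render_seed(26, 20, 0.3, defect = TRUE, rng_seed = 8)
  mix <- 0.45 * d$patch[, , 1] + 0.1 * d$patch[, , 2] + 0.45 * d$patch[, , 3]
  clean <- d$mask & !d$blotch
  expect_equal(d$patch[, , 4][clean], pmin(pmax(mix[clean], 0), 255),
               tolerance = 1e-8)
  expect_true(all(d$patch[, , 4][d$blotch] <= 0.55 * mix[d$blotch] + 1e-6))
})

test_that("scenes are deterministic with disjoint non-adherent seeds", {
  sc <- scene_separated()
  sc2 <- generate_scene(scene_spec(width = 640, height = 480, n_seeds = 6,
                                   adhesion_prob = 0, rng_seed = 7))
  expect_identical(unclass(sc$image)[, , ], unclass(sc2$image)[, , ])
  expect_identical(sc$truth$centroid_r, sc2$truth$centroid_r)
  expect_identical(sc$truth$label, sc2$truth$label)
  expect_equal(nrow(sc$truth), 6)
  # pairwise disjoint masks
  J <- instance_jaccard(sc$truth, sc$truth)
  expect_true(all(J[upper.tri(J)] == 0))
  # empty scene: background only, empty truth
  e <- generate_scene(scene_spec(width = 200, height = 150, n_seeds = 0,
                                 background_level = 230, rng_seed = 1))
  expect_equal(nrow(e$truth), 0)
  expect_lt(abs(mean(e$image[, , 1]) - 230), 2)
})

test_that("adhesive seeds touch with bounded overlap", {
  sc <- scene_touching()
  tr <- sc$truth
  J <- instance_jaccard(tr, tr)
  diag(J) <- 0
  # overlap below 10% of a seed's area implies pairwise Jaccard < ~0.06
  expect_true(all(J < 0.06))
  # at least one pair of seeds shares an 8-connected border (touches)
  full <- function(i) {
    m <- matrix(FALSE, 480, 640)
    m[(tr$r0[i] + 1):tr$r1[i], (tr$c0[i] + 1):tr$c1[i]][tr$mask[[i]]] <- TRUE
    m
  }
  touches <- FALSE
  for (i in seq_len(nrow(tr) - 1)) {
    di <- cornseed:::dilate1(full(i))
    for (j in (i + 1):nrow(tr))
      if (any(di & full(j))) touches <- TRUE
  }
  expect_true(touches)
})

test_that("labels are balanced and trivially separable at defect_fraction 0.5", {
  chips <- fixture("chips_balance", function()
    synth_chips(1000, size = 64, rng_seed = 17))
  share <- mean(chips$label == "bad")
  expect_gte(share, 0.45)
  expect_lte(share, 0.55)
  # fraction of mask pixels far below the B median separates the classes
  dark <- vapply(seq_len(nrow(chips)), function(i) {
    B <- chips$pixels[[i]][, , 3]; m <- chips$mask[[i]]
    mean(B[m] < median(B[m]) - 50)
  }, numeric(1))
  acc <- max(vapply(c(0.005, 0.01, 0.02), function(th)
    mean(ifelse(dark > th, "bad", "good") == chips$label), numeric(1)))
  expect_gte(acc, 0.9)
})

test_that("datasets on disk are complete and byte-stable under a fixed seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- scene_spec(width = 320, height = 240, n_seeds = 3, rng_seed = 5)
  man <- generate_dataset(spec, 3, dir1)
  expect_equal(nrow(man), 3)
  files <- read_manifest(file.path(dir1, "manifest.csv"))
  expect_true(all(file.exists(files$image), file.exists(files$nir),
                  file.exists(files$truth)))
  generate_dataset(spec, 3, dir2)
  expect_identical(readBin(file.path(dir1, "manifest.csv"), "raw", 1e5),
                   readBin(file.path(dir2, "manifest.csv"), "raw", 1e5))
  expect_identical(readBin(file.path(dir1, "scene_001.png"), "raw", 1e6),
                   readBin(file.path(dir2, "scene_001.png"), "raw", 1e6))
  # truth round-trip preserves labels and centroids
  tr <- read_scene_truth(file.path(dir1, "scene_001_truth.csv"))
  sc <- generate_scene(spec)
  expect_equal(tr$label, sc$truth$label)
  expect_equal(tr$centroid_r, sc$truth$centroid_r, tolerance = 1e-6)
  # all-defect datasets are labeled accordingly
  all_bad <- generate_scene(scene_spec(width = 320, height = 240, n_seeds = 3,
                                       defect_fraction = 1, rng_seed = 2))
  expect_true(all(all_bad$truth$label == "bad"))
})
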