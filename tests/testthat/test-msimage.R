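test_that("multispectral images round-trip bit-exactly through both storage dialects", {
  dir <- withr::local_tempdir()
  set.seed(1)
  for (dims in list(c(1, 1), c(10, 12))) {
    img <- msimage(array(sample(0:255, prod(dims) * 4, replace = TRUE),
                         c(dims, 4)))
    write_msimage(img, file.path(dir, "pair.png"))
    back <- read_msimage(file.path(dir, "pair.png"))
    expect_equal(unclass(back)[, , ], unclass(img)[, , ])
    write_msimage(img, file.path(dir, "one.tif"))
    back2 <- read_msimage(file.path(dir, "one.tif"))
    expect_equal(unclass(back2)[, , ], unclass(img)[, , ])
  }
  # full-resolution randomized round-trip
  big <- msimage(array(sample(0:255, 1296 * 964 * 4, replace = TRUE),
                       c(964, 1296, 4)))
  write_msimage(big, file.path(dir, "big.tif"))
  expect_identical(unclass(read_msimage(file.path(dir, "big.tif")))[, , ],
                   unclass(big)[, , ])
})

test_that("channels keep their identity and order through read/write", {
  dir <- withr::local_tempdir()
  # distinct constant planes catch any silent reorder or drop
  arr <- array(0, c(6, 8, 4))
  for (ch in 1:4) arr[, , ch] <- ch * 10
  img <- msimage(arr)
  write_msimage(img, file.path(dir, "planes.png"))
  back <- read_msimage(file.path(dir, "planes.png"))
  for (ch in 1:4)
    expect_true(all(ms_channel(back, c("R", "G", "B", "NIR")[ch]) == ch * 10))
  # channel() returns a copy
  b <- ms_channel(img, "B")
  b[1, 1] <- 0
  expect_equal(ms_channel(img, "B")[1, 1], 30)
  expect_error(ms_channel(img, "X"), "unknown channel")
})

test_that("reader enforces its contract", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0.5, c(10, 10, 3)), file.path(dir, "rgb.png"))
  png::writePNG(matrix(0.5, 12, 10), file.path(dir, "bad_nir.png"))
  expect_error(read_msimage(file.path(dir, "rgb.png"),
                            file.path(dir, "bad_nir.png")),
               "dimension mismatch")
  expect_error(read_msimage(file.path(dir, "rgb.png")), "no NIR source")
  expect_error(read_msimage(file.path(dir, "nope.png")), "not found")
  # sibling _nir convention is picked up automatically
  png::writePNG(matrix(0.25, 10, 10), file.path(dir, "rgb_nir.png"))
  img <- read_msimage(file.path(dir, "rgb.png"))
  expect_equal(dim(img)[3], 4)
  expect_error(msimage(array(0, c(5, 5, 3))), "4 channels")
  expect_error(msimage(array(300, c(5, 5, 4))), "\\[0, 255\\]")
})

test_that("manifests round-trip and validate labels and file existence", {
  dir <- withr::local_tempdir()
  img <- msimage(array(100, c(5, 5, 4)))
  write_msimage(img, file.path(dir, "s.png"))
  m <- tibble::tibble(image = "s.png", nir = "s_nir.png",
                      label = "good", truth = NA, split = "train")
  write_manifest(m, file.path(dir, "manifest.csv"))
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(back), 1)
  expect_equal(back$label, "good")
  expect_true(file.exists(back$image))
  m$label <- "mediocre"
  write_manifest(m, file.path(dir, "m2.csv"))
  expect_error(read_manifest(file.path(dir, "m2.csv")), "good")
  m$label <- "bad"; m$image <- "missing.png"
  write_manifest(m, file.path(dir, "m3.csv"))
  expect_error(read_manifest(file.path(dir, "m3.csv")), "missing")
})
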