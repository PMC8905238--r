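#' Read and write chip datasets on disk
#'
#' A chip dataset directory holds one 4-sample 8-bit TIFF per chip, an
#' optional 1-channel PNG mask per chip, and a `chips.csv` manifest with
#' columns `image`, `mask`, `label`. Round-trips are lossless.
#'
#' @param chips a chip tibble (`chip_id`, `label`, `pixels`, optional
#'   `mask`).
#' @param dir dataset directory (created if missing).
#' @return `write_chips()`: the manifest path, invisibly; `read_chips()`:
#'   a chip tibble.
#' @export
write_chips <- function(chips, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  has_mask <- "mask" %in% names(chips)
  rows <- vector("list", nrow(chips))
  for (i in seq_len(nrow(chips))) {
    img_name <- sprintf("chip_%05d.tif", i)
    arr <- chips$pixels[[i]]
    suppressWarnings(tiff::writeTIFF(array(arr / 255, dim(arr)),
                                     file.path(dir, img_name),
                                     bits.per.sample = 8L))
    mask_name <- NA_character_
    if (has_mask && !is.null(chips$mask[[i]])) {
      mask_name <- sprintf("chip_%05d_mask.png", i)
      png::writePNG(chips$mask[[i]] * 1, file.path(dir, mask_name))
    }
    rows[[i]] <- tibble(image = img_name, mask = mask_name,
                        label = chips$label[i] %||% NA_character_)
  }
  readr::write_csv(bind_rows(rows), file.path(dir, "chips.csv"),
                   progress = FALSE)
  invisible(file.path(dir, "chips.csv"))
}

#' @rdname write_chips
#' @export
read_chips <- function(dir) {
  man_path <- if (grepl("\\.csv$", dir)) dir else file.path(dir, "chips.csv")
  if (!file.exists(man_path))
    stop_invalid(sprintf("chip manifest not found: %s", man_path))
  base <- dirname(man_path)
  man <- readr::read_csv(man_path, col_types = "ccc", progress = FALSE)
  px <- vector("list", nrow(man)); mk <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    arr <- suppressWarnings(tiff::readTIFF(file.path(base, man$image[i])))
    arr <- round(arr * 255)
    dim(arr) <- c(dim(arr)[1], dim(arr)[2], if (length(dim(arr)) == 3) dim(arr)[3] else 1L)
    px[[i]] <- arr
    mk[[i]] <- if (!is.na(man$mask[i]))
      png::readPNG(file.path(base, man$mask[i])) >= 0.5 else NULL
  }
  out <- tibble(chip_id = seq_len(nrow(man)), label = man$label, pixels = px)
  if (any(!vapply(mk, is.null, logical(1)))) out$mask <- mk
  out
}

# full-scene integer label matrix from an instance tibble (later rows win on
# the rare overlapping pixels)
instances_to_label_matrix <- function(instances, scene_dim) {
  lab <- matrix(0L, scene_dim[1], scene_dim[2])
  ids <- if ("instance_id" %in% names(instances)) instances$instance_id
         else instances$seed_id
  for (i in seq_len(nrow(instances))) {
    rs <- (instances$r0[i] + 1):instances$r1[i]
    cs <- (instances$c0[i] + 1):instances$c1[i]
    blk <- lab[rs, cs, drop = FALSE]
    blk[instances$mask[[i]]] <- ids[i]
    lab[rs, cs] <- blk
  }
  lab
}
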