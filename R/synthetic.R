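#' Synthetic seed scenes with known ground truth
#'
#' The original corn-seed image set is not deposited, so the package ships a
#' generator that emulates the imaging setup: a bright backlit background,
#' convex kernel-shaped seeds in yellow-orange tones, optional adhesion
#' (touching) between seeds, defect seeds carrying dark blotches and boundary
#' notches, and an NIR channel that is a deterministic RGB mixture plus a
#' defect-specific attenuation, so the 4th channel carries class signal beyond
#' RGB. Every scene comes with per-seed masks and labels for oracle testing.
#'
#' @param width,height scene size in pixels (nominal 1296 x 964).
#' @param n_seeds number of seeds to place.
#' @param defect_fraction probability a seed is rendered defective (`"bad"`).
#' @param adhesion_prob probability a seed (after the first) is placed
#'   touching a previously placed seed.
#' @param seed_axis_range `(min, max)` semi-axis lengths in pixels.
#' @param background_level 8-bit intensity of the backlit background.
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @param rng_seed integer seed; identical specs give identical scenes.
#' @return For `scene_spec()`, a validated spec object (list).
#' @export
scene_spec <- function(width = 1296, height = 964, n_seeds = 15,
                       defect_fraction = 0.5, adhesion_prob = 0.3,
                       seed_axis_range = c(22, 34), background_level = 230,
                       noise_sigma = 3, rng_seed = 1) {
  if (n_seeds < 0) stop_invalid("`n_seeds` must be >= 0")
  if (defect_fraction < 0 || defect_fraction > 1)
    stop_invalid("`defect_fraction` must be in [0, 1]")
  if (adhesion_prob < 0 || adhesion_prob > 1)
    stop_invalid("`adhesion_prob` must be in [0, 1]")
  if (length(seed_axis_range) != 2 || diff(seed_axis_range) < 0)
    stop_invalid("`seed_axis_range` must be an ordered (min, max) pair")
  if (seed_axis_range[1] < 2) stop_invalid("seed semi-axes must be >= 2 px")
  if (background_level < 0 || background_level > 255)
    stop_invalid("`background_level` must be an 8-bit intensity")
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  structure(list(width = width, height = height, n_seeds = n_seeds,
                 defect_fraction = defect_fraction,
                 adhesion_prob = adhesion_prob,
                 seed_axis_range = seed_axis_range,
                 background_level = background_level,
                 noise_sigma = noise_sigma, rng_seed = rng_seed),
            class = "scene_spec")
}

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
  }
  force(code)
}

shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-connected single-pixel dilation
dilate1 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out | shift_mask(m, dr, dc)
  out
}

# band-limited texture: coarse white noise bilinearly upsampled
smooth_noise <- function(h, w, amplitude, grid = 8) {
  gh <- max(2, ceiling(h / grid)); gw <- max(2, ceiling(w / grid))
  coarse <- array(rnorm(gh * gw, sd = amplitude), c(gh, gw, 1))
  cpp_resize(coarse, h, w)[, , 1]
}

#' Render a single synthetic seed
#'
#' Draws one kernel-shaped seed: a filled ellipse, optionally truncated flat
#' at one end to mimic the kernel base, with yellow-orange RGB shading and
#' smooth texture. Defective seeds receive 1-3 dark blotches and possibly a
#' boundary notch; the NIR plane is `clip(0.45 R + 0.1 G + 0.45 B)` inside the
#' mask, further darkened by a fixed factor inside blotches so the NIR channel
#' carries defect signal beyond RGB. Blotch positions are returned so tests
#' can assert against the generator's own bookkeeping.
#'
#' Defects emulate discoloration and mold: the blotches darken the blue band
#' strongly (to 5-20% of base) while reducing R and G only mildly, and the
#' whole seed surface gains a correlated fine-texture anomaly, so the defect
#' is conspicuous in B/NIR and in local texture rather than in raw
#' luminance.
#'
#' @param axis_a,axis_b semi-axis lengths in pixels (`axis_a >= axis_b >= 2`).
#' @param orientation major-axis angle in radians.
#' @param defect render defect features?
#' @param rng_seed optional seed; `NULL` uses the current RNG stream.
#' @return A list with `mask` (logical matrix), `patch` (h x w x 4 array,
#'   zero outside the mask) and `blotch` (logical matrix of blotch pixels).
#' @export
render_seed <- function(axis_a, axis_b, orientation = 0, defect = FALSE,
                        rng_seed = NULL) {
  if (axis_b < 2 || axis_a < axis_b)
    stop_invalid("need axis_a >= axis_b >= 2")
  with_seed(rng_seed, {
    S <- 2L * ceiling(axis_a) + 5L
    ctr <- (S + 1) / 2
    dr <- matrix(rep(seq_len(S) - ctr, S), S)          # row offsets
    dc <- matrix(rep(seq_len(S) - ctr, each = S), S)   # col offsets
    u <- dr * cos(orientation) + dc * sin(orientation)
    v <- -dr * sin(orientation) + dc * cos(orientation)
    rho2 <- (u / axis_a)^2 + (v / axis_b)^2
    mask <- rho2 <= 1
    if (runif(1) < 0.5) mask <- mask & (u >= -0.86 * axis_a)  # flat kernel base
    blotch <- matrix(FALSE, S, S)
    if (defect && runif(1) < 0.4) {
      phi <- runif(1, 0, 2 * pi)
      nr <- axis_a * cos(phi) * cos(orientation) - axis_b * sin(phi) * sin(orientation)
      nc <- axis_a * cos(phi) * sin(orientation) + axis_b * sin(phi) * cos(orientation)
      rad <- 0.18 * axis_b
      mask <- mask & ((dr - nr)^2 + (dc - nc)^2 > rad^2)      # boundary notch
    }
    base <- c(210, 168, 92) + rnorm(3, sd = c(6, 6, 5))
    shade <- 1 - 0.22 * pmin(rho2, 1)
    tex <- smooth_noise(S, S, amplitude = 5)
    patch <- array(0, c(S, S, 4))
    chan_tex <- c(1, 0.9, 0.6)
    for (ch in 1:3)
      patch[, , ch] <- (base[ch] * shade + chan_tex[ch] * tex) * mask
    # healthy kernels carry benign luminance markings (tip cap, scratches,
    # shading spots): mild proportional darkening of all bands, far above
    # the defect threshold in B
    if (!defect && runif(1) < 0.7) {
      n_mk <- sample(1:2, 1)
      for (i in seq_len(n_mk)) {
        theta <- runif(1, 0, 2 * pi); r0 <- sqrt(runif(1)) * 0.7
        mu <- r0 * axis_a * cos(theta); mv <- r0 * axis_b * sin(theta)
        mr <- mu * cos(orientation) - mv * sin(orientation)
        mc <- mu * sin(orientation) + mv * cos(orientation)
        rad <- runif(1, 0.15, 0.3) * axis_b
        f <- runif(1, 0.8, 0.95)
        mm <- mask & ((dr - mr)^2 + (dc - mc)^2 <= rad^2)
        for (ch in 1:3) patch[, , ch][mm] <- patch[, , ch][mm] * f
      }
    }
    if (defect) {
      # discoloration/mold is chromatic and textural: the blotches collapse
      # the blue band while leaving the luminance-heavy R and G bands at
      # their normal level, and the surface gains a correlated fine-texture
      # roughness — conspicuous to sign-based local patterns, nearly
      # invisible to coarsely quantized luminance statistics
      rough <- smooth_noise(S, S, amplitude = 4, grid = 2)
      for (ch in 1:2) patch[, , ch] <- patch[, , ch] + rough * mask
      n_bl <- sample(1:3, 1)
      fch <- c(1, 1, runif(1, 0.05, 0.2))
      for (i in seq_len(n_bl)) {
        theta <- runif(1, 0, 2 * pi); r0 <- sqrt(runif(1)) * 0.65
        bu <- r0 * axis_a * cos(theta); bv <- r0 * axis_b * sin(theta)
        br <- bu * cos(orientation) - bv * sin(orientation)
        bc <- bu * sin(orientation) + bv * cos(orientation)
        rad <- runif(1, 0.12, 0.22) * axis_b
        bm <- mask & ((dr - br)^2 + (dc - bc)^2 <= rad^2)
        for (ch in 1:3) patch[, , ch][bm] <- patch[, , ch][bm] * fch[ch]
        blotch <- blotch | bm
      }
    }
    nir <- 0.45 * patch[, , 1] + 0.1 * patch[, , 2] + 0.45 * patch[, , 3]
    nir[blotch] <- nir[blotch] * 0.55
    patch[, , 4] <- nir * mask
    patch <- pmin(pmax(patch, 0), 255)
    dim(patch) <- c(S, S, 4L)
    list(mask = mask, patch = patch, blotch = blotch)
  })
}

# contact statistics of `cand` (logical, top-left at r0, c0) vs `occupied`:
# overlap pixels, contact-interface length (border pixels adjacent to
# occupied) and whether a 2-px clearance holds
window_stats <- function(occupied, cand, r0, c0) {
  S <- nrow(cand)
  rs <- r0:(r0 + S - 1); cs <- c0:(c0 + S - 1)
  occ <- occupied[rs, cs, drop = FALSE]
  d1 <- dilate1(cand)
  overlap <- sum(cand & occ)
  contact <- sum(d1 & occ)
  clear2 <- overlap == 0 && contact == 0 && sum(dilate1(d1) & occ) == 0
  list(overlap = overlap, contact = contact,
       touch = overlap > 0 || contact > 0, clear2 = clear2)
}

#' Generate a synthetic scene with ground truth
#'
#' Places `n_seeds` rendered seeds on a bright background. Non-adherent seeds
#' are pairwise disjoint and non-touching; with probability `adhesion_prob` a
#' seed is instead slid along a random direction towards an existing seed
#' until their masks share an 8-connected border, accepting the position only
#' if the mask overlap stays below 10% of the seed's area. Gaussian noise is
#' added to all four channels and clipped to `[0, 255]`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` (a [msimage()]) and `truth`, a tibble with one
#'   row per placed seed: `seed_id`, `label`, 0-based half-open bounding box
#'   (`r0`, `c0`, `r1`, `c1`), 0-based `centroid_r`, `centroid_c`, `area` and
#'   the bbox-cropped logical `mask`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, {
    H <- spec$height; W <- spec$width
    canvas <- array(spec$background_level, c(H, W, 4))
    occupied <- matrix(FALSE, H, W)
    rows <- list()
    for (i in seq_len(spec$n_seeds)) {
      defect <- runif(1) < spec$defect_fraction
      ax <- sort(runif(2, spec$seed_axis_range[1], spec$seed_axis_range[2]),
                 decreasing = TRUE)
      sd_ <- render_seed(ax[1], ax[2], orientation = runif(1, 0, pi),
                         defect = defect)
      S <- nrow(sd_$mask)
      area <- sum(sd_$mask)
      adhesive <- i > 1 && runif(1) < spec$adhesion_prob
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        if (!adhesive) {
          r0 <- sample.int(H - S - 1, 1) + 1
          c0 <- sample.int(W - S - 1, 1) + 1
          st <- window_stats(occupied, sd_$mask, r0, c0)
          if (st$clear2) { placed <- TRUE; break }
        } else {
          anchor <- rows[[sample.int(length(rows), 1)]]
          phi <- runif(1, 0, 2 * pi)
          d_hi <- anchor$reach + ceiling(ax[1]) + 3
          for (d in seq(d_hi, 2, by = -1)) {
            cr <- anchor$centroid_r + 1 + d * cos(phi)
            cc <- anchor$centroid_c + 1 + d * sin(phi)
            r0 <- round(cr - (S - 1) / 2); c0 <- round(cc - (S - 1) / 2)
            if (r0 < 2 || c0 < 2 || r0 + S > H || c0 + S > W) break
            st <- window_stats(occupied, sd_$mask, r0, c0)
            if (st$overlap > 0.1 * area) break
            # adhesion means point/edge contact, not a welded face: reject
            # interfaces longer than ~0.7 of the minor axis (a fused convex
            # union would be unsegmentable even in the true mask)
            if (st$touch) {
              if (st$contact <= 0.7 * ax[2]) placed <- TRUE
              break
            }
          }
          if (placed) break
        }
      }
      if (!placed)
        stop(sprintf("could not place seed %d after 1000 attempts: scene too crowded", i))
      rs <- r0:(r0 + S - 1); cs <- c0:(c0 + S - 1)
      for (ch in 1:4) {
        plane <- canvas[rs, cs, ch]
        plane[sd_$mask] <- sd_$patch[, , ch][sd_$mask]
        canvas[rs, cs, ch] <- plane
      }
      occupied[rs, cs] <- occupied[rs, cs] | sd_$mask
      # tight bbox of the mask, 0-based half-open scene coordinates
      mr <- range(which(rowSums(sd_$mask) > 0)); mc <- range(which(colSums(sd_$mask) > 0))
      cropped <- sd_$mask[mr[1]:mr[2], mc[1]:mc[2], drop = FALSE]
      pix <- which(cropped, arr.ind = TRUE)
      rows[[i]] <- list(
        seed_id = i, label = if (defect) "bad" else "good",
        r0 = r0 + mr[1] - 2, c0 = c0 + mc[1] - 2,
        r1 = r0 + mr[2] - 1, c1 = c0 + mc[2] - 1,
        centroid_r = mean(pix[, 1] - 1) + (r0 + mr[1] - 2),
        centroid_c = mean(pix[, 2] - 1) + (c0 + mc[1] - 2),
        area = area, mask = cropped,
        reach = ceiling(ax[1])
      )
    }
    if (spec$noise_sigma > 0)
      canvas <- canvas + rnorm(length(canvas), sd = spec$noise_sigma)
    canvas <- cpp_clip_round_u8(canvas)
    truth <- tibble(
      seed_id = map_int(rows, ~ as.integer(.x$seed_id)),
      label = map_chr(rows, "label"),
      r0 = map_dbl(rows, "r0"), c0 = map_dbl(rows, "c0"),
      r1 = map_dbl(rows, "r1"), c1 = map_dbl(rows, "c1"),
      centroid_r = map_dbl(rows, "centroid_r"),
      centroid_c = map_dbl(rows, "centroid_c"),
      area = map_dbl(rows, "area"),
      mask = map(rows, "mask"))
    list(image = msimage(canvas), truth = truth)
  })
}

#' Generate standalone seed chips
#'
#' Renders single seeds on small background canvases, adds noise, and resizes
#' to `size x size` 4-channel chips with labels and masks — the fast path for
#' building classifier training sets without full scenes.
#'
#' @param n number of chips.
#' @param defect_fraction probability of a defect chip.
#' @param size output chip side length (default 224).
#' @param background_level,noise_sigma,seed_axis_range as in [scene_spec()].
#' @param rng_seed integer seed.
#' @return A chip tibble: `chip_id`, `label`, `pixels` (list of
#'   `size x size x 4` arrays), `mask` (list of logical matrices).
#' @export
synth_chips <- function(n, defect_fraction = 0.5, size = 224,
                        background_level = 230, noise_sigma = 3,
                        seed_axis_range = c(22, 34), rng_seed = 1) {
  with_seed(rng_seed, {
    out <- vector("list", n)
    labels <- character(n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      defect <- runif(1) < defect_fraction
      ax <- sort(runif(2, seed_axis_range[1], seed_axis_range[2]),
                 decreasing = TRUE)
      sd_ <- render_seed(ax[1], ax[2], orientation = runif(1, 0, pi),
                         defect = defect)
      S <- nrow(sd_$mask)
      arr <- array(background_level, c(S, S, 4))
      for (ch in 1:4) {
        plane <- arr[, , ch]
        plane[sd_$mask] <- sd_$patch[, , ch][sd_$mask]
        arr[, , ch] <- plane + rnorm(S * S, sd = noise_sigma)
      }
      arr <- cpp_clip_round_u8(arr)
      chip <- cpp_clip_round_u8(cpp_resize(array(as.numeric(arr), dim(arr)),
                                           size, size))
      mk <- cpp_resize(array(sd_$mask * 1, c(S, S, 1)), size, size)[, , 1] >= 0.5
      out[[i]] <- chip
      masks[[i]] <- mk
      labels[i] <- if (defect) "bad" else "good"
    }
    tibble(chip_id = seq_len(n), label = labels, pixels = out, mask = masks)
  })
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_scenes` scenes from per-scene variants of `spec` (seeded
#' `rng_seed`, `rng_seed + 1`, ...), writing for scene `i`: the RGB/NIR PNG
#' pair, a 16-bit label TIFF (`0` = background, `k` = seed `k`; overlapping
#' pixels carry the later seed) and a per-seed truth CSV, plus one
#' `manifest.csv` indexing everything. Fixed seeds give byte-identical output.
#'
#' @param spec a [scene_spec()] template.
#' @param n_scenes number of scenes to generate.
#' @param out_dir output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
generate_dataset <- function(spec, n_scenes, out_dir) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_invalid(sprintf("cannot create %s", out_dir))
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- spec; sp$rng_seed <- spec$rng_seed + i - 1
    sc <- generate_scene(sp)
    stem <- sprintf("scene_%03d", i)
    write_msimage(sc$image, file.path(out_dir, paste0(stem, ".png")))
    write_scene_truth(sc$truth, dim(sc$image)[1:2],
                      file.path(out_dir, paste0(stem, "_truth")))
    rows[[i]] <- tibble(image = paste0(stem, ".png"),
                        nir = paste0(stem, "_nir.png"),
                        label = NA_character_,
                        truth = paste0(stem, "_truth.csv"),
                        split = NA_character_)
  }
  manifest <- bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param truth a truth tibble from [generate_scene()].
#' @param scene_dim `c(height, width)` of the scene.
#' @param stem output path stem; writes `<stem>.tif` and `<stem>.csv`.
#' @export
write_scene_truth <- function(truth, scene_dim, stem) {
  lab <- matrix(0L, scene_dim[1], scene_dim[2])
  for (i in seq_len(nrow(truth))) {
    m <- truth$mask[[i]]
    rs <- (truth$r0[i]:(truth$r1[i] - 1)) + 1
    cs <- (truth$c0[i]:(truth$c1[i] - 1)) + 1
    block <- lab[rs, cs, drop = FALSE]
    block[m] <- truth$seed_id[i]
    lab[rs, cs] <- block
  }
  suppressWarnings(tiff::writeTIFF(lab / 65535, paste0(stem, ".tif"),
                                   bits.per.sample = 16L))
  readr::write_csv(
    truth[, c("seed_id", "label", "centroid_r", "centroid_c", "area")],
    paste0(stem, ".csv"), progress = FALSE)
  invisible(stem)
}

#' @rdname generate_dataset
#' @param csv_path path to a `<stem>.csv` truth table written by
#'   [write_scene_truth()]; the sibling `.tif` label image is read alongside.
#' @export
read_scene_truth <- function(csv_path) {
  tab <- readr::read_csv(csv_path, col_types = "icddd", progress = FALSE)
  lab <- round(suppressWarnings(tiff::readTIFF(sub("\\.csv$", ".tif", csv_path))) * 65535)
  masks <- vector("list", nrow(tab))
  bbox <- matrix(0, nrow(tab), 4)
  for (i in seq_len(nrow(tab))) {
    id <- tab$seed_id[i]
    hit <- lab == id
    mr <- range(which(rowSums(hit) > 0)); mc <- range(which(colSums(hit) > 0))
    masks[[i]] <- hit[mr[1]:mr[2], mc[1]:mc[2], drop = FALSE]
    bbox[i, ] <- c(mr[1] - 1, mc[1] - 1, mr[2], mc[2])
  }
  mutate(as_tibble(tab),
         r0 = bbox[, 1], c0 = bbox[, 2], r1 = bbox[, 3], c1 = bbox[, 4],
         mask = masks)
}
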