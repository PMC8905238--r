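#' End-to-end defect detection on one scene
#'
#' Segments the scene by marker-based watershed, extracts 224x224x4 chips at
#' the segmented coordinates, classifies each chip and returns per-seed
#' records plus an annotated copy of the RGB planes with class-colored
#' bounding boxes.
#'
#' @param img a [msimage()] scene.
#' @param classifier a trained [corn_seed_net()], or any function taking a
#'   chip tibble and returning a tibble with `pred_label` and `prob` (one row
#'   per chip) — e.g. an oracle stub in tests.
#' @param params a [seg_params()].
#' @param chip_size chip side length fed to the classifier.
#' @return A list with `detections` (tibble: `instance_id`, bbox, centroid,
#'   `pred_label`, `prob`), `instances` (the segmentation output) and
#'   `annotated` (a [msimage()]).
#' @export
detect_scene <- function(img, classifier, params = seg_params(),
                         chip_size = 224) {
  instances <- watershed_segment(img, params)
  if (nrow(instances) == 0) {
    return(list(
      detections = tibble(instance_id = integer(), r0 = numeric(),
                          c0 = numeric(), r1 = numeric(), c1 = numeric(),
                          centroid_r = numeric(), centroid_c = numeric(),
                          pred_label = character(), prob = numeric()),
      instances = instances,
      annotated = img))
  }
  chips <- extract_chips(img, instances, size = chip_size)
  preds <- if (inherits(classifier, "corn_seed_net"))
    predict(classifier, chips) else classifier(chips)
  stopifnot(nrow(preds) == nrow(instances),
            all(c("pred_label", "prob") %in% names(preds)))
  det <- bind_cols(
    instances[, c("instance_id", "r0", "c0", "r1", "c1",
                  "centroid_r", "centroid_c")],
    preds[, c("pred_label", "prob")])
  list(detections = det, instances = instances,
       annotated = annotate_scene(img, det))
}

#' Draw detection boxes onto the RGB planes
#'
#' @param img a [msimage()].
#' @param detections tibble with bbox columns and `pred_label`.
#' @param thickness border thickness in pixels.
#' @return An annotated [msimage()] (NIR plane unchanged).
#' @export
annotate_scene <- function(img, detections, thickness = 2) {
  arr <- array(as.numeric(img), dim(img))
  H <- dim(arr)[1]; W <- dim(arr)[2]
  colors <- list(good = c(40, 200, 40), bad = c(220, 40, 40))
  for (i in seq_len(nrow(detections))) {
    col3 <- colors[[detections$pred_label[i]]] %||% c(255, 255, 0)
    r0 <- max(detections$r0[i] + 1 - thickness, 1)
    c0 <- max(detections$c0[i] + 1 - thickness, 1)
    r1 <- min(detections$r1[i] + thickness, H)
    c1 <- min(detections$c1[i] + thickness, W)
    for (ch in 1:3) {
      arr[r0:min(r0 + thickness - 1, H), c0:c1, ch] <- col3[ch]
      arr[max(r1 - thickness + 1, 1):r1, c0:c1, ch] <- col3[ch]
      arr[r0:r1, c0:min(c0 + thickness - 1, W), ch] <- col3[ch]
      arr[r0:r1, max(c1 - thickness + 1, 1):c1, ch] <- col3[ch]
    }
  }
  msimage(arr)
}

config_defaults <- function() {
  list(
    segmentation = unclass(seg_params()),
    augmentation = unclass(aug_spec())[c("brightness_deltas", "rotation_angles",
                                         "gaussian_sigma")],
    architecture = unclass(arch_spec())[c("input_channels", "input_size",
                                          "width_multiplier", "n_classes",
                                          "branch_embed_dim")],
    training = unclass(training_config())[c("optimizer", "momentum",
                                            "learning_rate", "epochs",
                                            "plateau_patience", "batch_size")],
    evaluation = list(jaccard_min = 0.5),
    rng_seed = 1)
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop_invalid(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.list(user[[key]]))
      stop_invalid(sprintf("'%s' must be a block", full))
    defaults[[key]] <- if (is.list(defaults[[key]]))
      merge_config(defaults[[key]], user[[key]], c(path, key))
    else user[[key]]
  }
  defaults
}

#' Load, validate and dump run configuration
#'
#' Configuration is a YAML file with nested blocks `segmentation`,
#' `augmentation`, `architecture`, `training`, `evaluation` and a top-level
#' `rng_seed`. Missing keys take package defaults; unknown keys are rejected
#' by name. Validation runs the same invariants as the corresponding
#' constructors, so e.g. `segmentation: {dist_frac: 1.5}` fails naming the
#' field. An empty file yields all defaults.
#'
#' @param path YAML file path (for `load_run_config`).
#' @return A validated `run_config` list; sub-objects under `$seg`, `$aug`,
#'   `$arch`, `$train` are the constructed parameter objects, `$raw` the
#'   plain list.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else yaml::read_yaml(path) %||% list()
  raw <- merge_config(config_defaults(), user)
  cfg <- list(
    seg = do.call(seg_params, raw$segmentation),
    aug = do.call(aug_spec, raw$augmentation),
    arch = do.call(arch_spec, raw$architecture),
    train = do.call(training_config,
                    c(raw$training, list(rng_seed = raw$rng_seed))),
    jaccard_min = raw$evaluation$jaccard_min,
    rng_seed = raw$rng_seed,
    raw = raw)
  if (cfg$jaccard_min <= 0 || cfg$jaccard_min > 1)
    stop_invalid("evaluation.jaccard_min must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
dump_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Write detections as CSV and JSON
#'
#' JSON output is one object per seed:
#' `{"id":, "bbox":[r0,c0,r1,c1], "centroid":[r,c], "class":, "prob":}`.
#'
#' @param detections detection tibble from [detect_scene()].
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_detections <- function(detections, stem) {
  readr::write_csv(detections, paste0(stem, ".csv"), progress = FALSE)
  objs <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(id = d$instance_id, bbox = c(d$r0, d$c0, d$r1, d$c1),
         centroid = c(d$centroid_r, d$centroid_c),
         class = d$pred_label, prob = d$prob)
  })
  jsonlite::write_json(objs, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
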