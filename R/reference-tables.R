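#' Bundled reference metric rows
#'
#' Published per-class results for the single-seed test, the
#' watershed-plus-classifier comparison (4-channel and RGB-only inputs) and
#' the hand-crafted/SVM baselines, shipped as plain CSVs. The left-hand
#' entries of each row (per-class counts, precisions, recalls) are inputs;
#' the `printed_*` columns are the published derived values the package's
#' metric arithmetic is verified against. One row carries
#' `note = "inconsistent_avg_p"`: its printed averaged precision cannot be
#' derived from its own per-class entries (the published F1 is consistent
#' with the printed average, pointing to a typo in the per-class cell).
#'
#' @param which `"single_seed"`, `"watershed"` or `"baselines"`.
#' @return A tibble.
#' @export
reference_metric_rows <- function(which = c("single_seed", "watershed",
                                            "baselines")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "cornseed", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

#' Recompute the derived columns of the reference tables
#'
#' Runs the package's own metric arithmetic over every bundled row:
#' averaged accuracy from per-class counts ([averaged_accuracy()]), macro
#' precision/recall from per-class values, and F1 from the (unrounded)
#' macros ([f1_pct()]). Returns both the recomputed and printed values with
#' their differences.
#'
#' @return A tibble with one row per derived cell: `table`, `model`,
#'   `metric`, `recomputed`, `printed`, `abs_diff`, `note`.
#' @export
recompute_reference_metrics <- function() {
  out <- list()
  ss <- reference_metric_rows("single_seed")
  for (i in seq_len(nrow(ss))) {
    r <- ss[i, ]
    acc <- averaged_accuracy(c(r$good_correct, r$bad_correct),
                             rep(r$total_per_class, 2))
    out[[length(out) + 1]] <- tibble(
      table = "single_seed", model = r$model, metric = "avg_accuracy",
      recomputed = acc$averaged, printed = r$printed_avg_acc, note = NA_character_)
  }
  ws <- reference_metric_rows("watershed")
  for (i in seq_len(nrow(ws))) {
    r <- ws[i, ]
    mp <- mean(c(r$p_good, r$p_bad)); mr <- mean(c(r$r_good, r$r_bad))
    lbl <- paste0(r$input, "_", r$model)
    out[[length(out) + 1]] <- tibble(
      table = "watershed", model = lbl,
      metric = c("avg_precision", "avg_recall", "f1"),
      recomputed = c(mp, mr, f1_pct(mp, mr)),
      printed = c(r$printed_avg_p, r$printed_avg_r, r$printed_f1),
      note = r$note)
  }
  bl <- reference_metric_rows("baselines")
  for (i in seq_len(nrow(bl))) {
    r <- bl[i, ]
    out[[length(out) + 1]] <- tibble(
      table = "baselines", model = r$model, metric = "f1",
      recomputed = f1_pct(r$avg_p, r$avg_r), printed = r$printed_f1,
      note = NA_character_)
  }
  mutate(bind_rows(out), abs_diff = abs(.data$recomputed - .data$printed))
}
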