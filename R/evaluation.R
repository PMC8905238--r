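#' Confusion counts per class
#'
#' Tallies of correctly identified (`tp`), misidentified (`fp` — predicted
#' as the class but actually another, or a spurious detection) and
#' unrecognized (`fn`) seeds, one row per class.
#'
#' @param class character vector of class names.
#' @param tp,fp,fn non-negative counts, aligned with `class`.
#' @return A `confusion_counts` tibble.
#' @export
confusion_counts <- function(class = c("good", "bad"), tp = 0, fp = 0, fn = 0) {
  if (any(c(tp, fp, fn) < 0)) stop_invalid("counts must be >= 0")
  structure(tibble(class = class, tp = tp, fp = fp, fn = fn),
            class = c("confusion_counts", class(tibble())))
}

counts_row <- function(counts, class) {
  i <- match(class, counts$class)
  if (is.na(i)) stop_invalid(sprintf("no counts for class '%s'", class))
  counts[i, ]
}

#' Precision, recall and F1 (percent)
#'
#' `precision_pct()` is `100 * tp / (tp + fp)`; `recall_pct()` is
#' `100 * tp / (tp + fn)`; `f1_pct()` is the harmonic mean `2PR / (P + R)` of
#' two percentages. A zero denominator yields `NA` with a warning (the class
#' is then excluded from macro averages); `f1_pct(0, 0)` is 0 by convention.
#'
#' @param counts a [confusion_counts()] tibble.
#' @param class which class to score.
#' @return A percentage in `[0, 100]`.
#' @export
precision_pct <- function(counts, class) {
  r <- counts_row(counts, class)
  if (r$tp + r$fp == 0) {
    warn(sprintf("precision undefined for class '%s' (no predictions)", class))
    return(NA_real_)
  }
  100 * r$tp / (r$tp + r$fp)
}

#' @rdname precision_pct
#' @export
recall_pct <- function(counts, class) {
  r <- counts_row(counts, class)
  if (r$tp + r$fn == 0) {
    warn(sprintf("recall undefined for class '%s' (no truth seeds)", class))
    return(NA_real_)
  }
  100 * r$tp / (r$tp + r$fn)
}

#' @rdname precision_pct
#' @param macro_p,macro_r macro (averaged) precision and recall, in percent.
#' @export
f1_pct <- function(macro_p, macro_r) {
  if (macro_p + macro_r == 0) return(0)
  2 * macro_p * macro_r / (macro_p + macro_r)
}

#' Per-class and averaged accuracy (percent)
#'
#' Per-class accuracy is `100 * correct / total`; the averaged accuracy is
#' the unweighted mean over classes.
#'
#' @param correct,totals per-class correct counts and class sizes.
#' @return List with `per_class` (percent vector) and `averaged` (percent).
#' @export
averaged_accuracy <- function(correct, totals) {
  if (any(totals <= 0)) stop_invalid("class totals must be > 0")
  acc <- 100 * correct / totals
  list(per_class = acc, averaged = mean(acc))
}

#' Display rounding for printed tables
#'
#' Two decimals, halves away from zero (95.625 prints as 95.63).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_metric <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Match detections to ground truth and count TP/FP/FN
#'
#' Detections and truth seeds are matched one-to-one greedily by descending
#' mask Jaccard, accepting pairs with Jaccard at least `jaccard_min`. A
#' matched pair with equal labels counts as a TP for that class; with
#' different labels as an FP for the predicted class and an FN for the true
#' class. Unmatched detections are FPs of their predicted class; unmatched
#' truth seeds are FNs of theirs. Invariant to the order of the instances.
#'
#' @param detections instance tibble with a `pred_label` column (bbox +
#'   `mask` columns as produced by [watershed_segment()]).
#' @param truth a scene truth tibble (with `label`).
#' @param jaccard_min acceptance threshold for a match (default 0.5).
#' @param classes class universe for the counts.
#' @return A [confusion_counts()] tibble with a `matches` attribute (tibble
#'   of matched index pairs and their Jaccard).
#' @export
match_detections <- function(detections, truth, jaccard_min = 0.5,
                             classes = c("good", "bad")) {
  J <- instance_jaccard(detections, truth)
  nd <- nrow(detections); nt <- nrow(truth)
  pairs <- list()
  if (nd > 0 && nt > 0) {
    Jw <- J
    repeat {
      best <- which.max(Jw)
      if (length(best) == 0 || Jw[best] < jaccard_min) break
      i <- (best - 1) %% nd + 1; j <- (best - 1) %/% nd + 1
      pairs[[length(pairs) + 1]] <- tibble(detection = i, truth = j,
                                           jaccard = J[i, j])
      Jw[i, ] <- -1; Jw[, j] <- -1
    }
  }
  matches <- if (length(pairs)) bind_rows(pairs)
             else tibble(detection = integer(), truth = integer(),
                         jaccard = numeric())
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (k in seq_len(nrow(matches))) {
    pl <- detections$pred_label[matches$detection[k]]
    tl <- truth$label[matches$truth[k]]
    if (identical(pl, tl)) tp[tl] <- tp[tl] + 1
    else { fp[pl] <- fp[pl] + 1; fn[tl] <- fn[tl] + 1 }
  }
  for (i in setdiff(seq_len(nd), matches$detection)) {
    pl <- detections$pred_label[i]; fp[pl] <- fp[pl] + 1
  }
  for (j in setdiff(seq_len(nt), matches$truth)) {
    tl <- truth$label[j]; fn[tl] <- fn[tl] + 1
  }
  out <- confusion_counts(classes, tp = unname(tp), fp = unname(fp),
                          fn = unname(fn))
  attr(out, "matches") <- matches
  out
}

# Exhaustive optimal one-to-one matching (maximize matched pairs, then total
# Jaccard) — the oracle greedy matching is tested against on small scenes.
match_detections_exhaustive <- function(detections, truth, jaccard_min = 0.5,
                                        classes = c("good", "bad")) {
  J <- instance_jaccard(detections, truth)
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd > 8 || nt > 8) stop("exhaustive matching is for small scenes only")
  best_pairs <- NULL; best_key <- c(-1, -Inf)
  assignments <- function(di, used, cur) {
    if (di > nd) {
      key <- c(nrow(cur), sum(cur$jaccard))
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best_key <<- key; best_pairs <<- cur
      }
      return(invisible())
    }
    assignments(di + 1, used, cur)  # leave detection di unmatched
    for (j in setdiff(seq_len(nt), used))
      if (J[di, j] >= jaccard_min)
        assignments(di + 1, c(used, j),
                    bind_rows(cur, tibble(detection = di, truth = j,
                                          jaccard = J[di, j])))
  }
  assignments(1, integer(), tibble(detection = integer(), truth = integer(),
                                   jaccard = numeric()))
  matches <- best_pairs
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (k in seq_len(nrow(matches))) {
    pl <- detections$pred_label[matches$detection[k]]
    tl <- truth$label[matches$truth[k]]
    if (identical(pl, tl)) tp[tl] <- tp[tl] + 1
    else { fp[pl] <- fp[pl] + 1; fn[tl] <- fn[tl] + 1 }
  }
  for (i in setdiff(seq_len(nd), matches$detection)) {
    pl <- detections$pred_label[i]; fp[pl] <- fp[pl] + 1
  }
  for (j in setdiff(seq_len(nt), matches$truth)) {
    tl <- truth$label[j]; fn[tl] <- fn[tl] + 1
  }
  confusion_counts(classes, tp = unname(tp), fp = unname(fp), fn = unname(fn))
}

#' Build an evaluation report
#'
#' Computes per-class precision/recall/accuracy and the macro (unweighted
#' class-mean) metrics. The F1 is the harmonic mean of the macro precision
#' and macro recall — this convention, not averaging per-class F1 values,
#' reproduces the printed summary columns of the reference tables.
#'
#' @param counts a [confusion_counts()] tibble covering every class.
#' @return An `evaluation_report` object.
#' @export
make_report <- function(counts) {
  per <- mutate(as_tibble(counts),
                precision = ifelse(.data$tp + .data$fp > 0,
                                   100 * .data$tp / (.data$tp + .data$fp), NA_real_),
                recall = ifelse(.data$tp + .data$fn > 0,
                                100 * .data$tp / (.data$tp + .data$fn), NA_real_),
                accuracy = .data$recall)
  if (anyNA(per$precision) || anyNA(per$recall))
    warn("some classes have undefined metrics; excluded from macro averages")
  macro_p <- mean(per$precision, na.rm = TRUE)
  macro_r <- mean(per$recall, na.rm = TRUE)
  structure(list(per_class = per,
                 macro_precision = macro_p, macro_recall = macro_r,
                 macro_accuracy = mean(per$accuracy, na.rm = TRUE),
                 f1 = f1_pct(macro_p, macro_r)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Class        Precision/%  Recall/%\n")
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("%-12s %11.2f %9.2f\n", r$class,
                round_metric(r$precision), round_metric(r$recall)))
  }
  cat(sprintf("Averaged precision/%%: %.2f\n", round_metric(x$macro_precision)))
  cat(sprintf("Averaged recall/%%:    %.2f\n", round_metric(x$macro_recall)))
  cat(sprintf("F1/%%:                 %.2f\n", round_metric(x$f1)))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(macro_precision = x$macro_precision, macro_recall = x$macro_recall,
         macro_accuracy = x$macro_accuracy, f1 = x$f1)
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class[, c("class", "precision", "recall")],
                              -"class", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$f1, linetype = 2) +
    ggplot2::labs(y = "percent", caption = sprintf("dashed line: F1 = %.2f%%",
                                                   object$f1))
}
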