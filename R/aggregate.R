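# Per-plate aggregation of colony predictions and classifier evaluation.

#' Aggregate per-colony predictions into a plate summary
#'
#' Counts predicted labels and computes the plate's non-white percentage:
#' 100 x (red + pink + variegating) / (all properly segmented colonies),
#' where properly segmented excludes the bad_segmentation class. Plates with
#' no properly segmented colony are flagged `"undefined"` (percentage `NA`,
#' never 0).
#'
#' @param predictions Tibble from [classify_crops()] for a single plate
#'   (mixed `plate_id`s error).
#' @return One-row tibble: plate_id, n_white, n_red, n_pink, n_variegating,
#'   n_bad, n_properly_segmented, pct_non_white, status.
#' @export
aggregate_plate <- function(predictions) {
  ids <- unique(predictions$plate_id)
  if (length(ids) > 1) {
    stop("predictions mix plate_ids: ", paste(ids, collapse = ", "))
  }
  lab <- predictions$label[!is.na(predictions$label)]
  cnt <- table(factor(lab, levels = colony_phenotypes()))
  n_proper <- sum(cnt) - cnt[["bad_segmentation"]]
  n_nonwhite <- cnt[["red"]] + cnt[["pink"]] + cnt[["variegating"]]
  tibble::tibble(
    plate_id = if (length(ids) == 1) ids else NA_character_,
    n_white = as.integer(cnt[["white"]]),
    n_red = as.integer(cnt[["red"]]),
    n_pink = as.integer(cnt[["pink"]]),
    n_variegating = as.integer(cnt[["variegating"]]),
    n_bad = as.integer(cnt[["bad_segmentation"]]),
    n_properly_segmented = as.integer(n_proper),
    pct_non_white = if (n_proper > 0) 100 * n_nonwhite / n_proper else NA_real_,
    status = if (n_proper > 0) "ok" else "undefined"
  )
}

#' Aggregate predictions for many plates at once
#'
#' @param predictions Tibble from [classify_crops()] covering one or more
#'   plates.
#' @return Tibble with one [aggregate_plate()] row per plate.
#' @export
aggregate_plates <- function(predictions) {
  predictions |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_split() |>
    purrr::map(aggregate_plate) |>
    dplyr::bind_rows()
}

#' Evaluate predicted labels against truth
#'
#' Builds the 5-class confusion matrix (rows = true, columns = predicted),
#' per-class sensitivity, specificity and precision, overall accuracy, and
#' the pooled white/non-white binary accuracy obtained by merging red, pink
#' and variegating into one non-white class; pairs whose true label is
#' bad_segmentation are excluded from the pooled metric, mirroring their
#' exclusion from the plate denominator.
#'
#' @param truth,predicted Equal-length character vectors of labels from
#'   [colony_phenotypes()].
#' @return A `colony_eval` object; see [tidy()] and [glance()] methods.
#' @export
evaluate_classifier <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  lv <- colony_phenotypes()
  bad_lab <- c(setdiff(unique(c(truth, predicted)), lv))
  bad_lab <- bad_lab[!is.na(bad_lab)]
  if (length(bad_lab) > 0) {
    stop("unknown label(s): ", paste(bad_lab, collapse = ", "))
  }
  tf <- factor(truth, levels = lv)
  pf <- factor(predicted, levels = lv)
  confusion <- table(truth = tf, predicted = pf)
  total <- sum(confusion)
  accuracy <- sum(diag(confusion)) / total
  per_class <- purrr::map(lv, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = cl, n = as.integer(tp + fn),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    )
  }) |> dplyr::bind_rows()
  pool <- function(x) ifelse(x %in% c("red", "pink", "variegating"), "non-white", x)
  keep <- tf != "bad_segmentation"
  tb <- pool(as.character(tf[keep]))
  pb <- pool(as.character(pf[keep]))
  pooled_confusion <- table(
    truth = factor(tb, levels = c("white", "non-white", "bad_segmentation")),
    predicted = factor(pb, levels = c("white", "non-white", "bad_segmentation"))
  )
  pooled_accuracy <- if (sum(keep) > 0) mean(tb == pb) else NA_real_
  structure(
    list(confusion = confusion, per_class = per_class, accuracy = accuracy,
         pooled_confusion = pooled_confusion, pooled_accuracy = pooled_accuracy,
         n = total),
    class = "colony_eval"
  )
}

#' @export
print.colony_eval <- function(x, ...) {
  cat(sprintf("<colony_eval> n = %d, accuracy %.1f%%, pooled white/non-white %.1f%%\n",
              x$n, 100 * x$accuracy, 100 * x$pooled_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Compare predicted plate summaries to ground truth
#'
#' Joins predictions and truth by `plate_id` and reports per-plate signed
#' and absolute differences in non-white percentage points, plus their
#' means. Plates present on only one side are an error.
#'
#' @param summaries Tibble of plate summaries with `plate_id` and
#'   `pct_non_white` (e.g. from [aggregate_plates()]).
#' @param truth Tibble with `plate_id` and a true percentage column
#'   (`true_nonwhite_pct`, as written by [generate_plate_dataset()]).
#' @return A `plate_comparison`: list with `plates` (tibble: plate_id,
#'   pct_predicted, pct_true, diff, abs_diff), `mean_abs_diff`,
#'   `mean_signed_diff`.
#' @export
compare_to_truth <- function(summaries, truth) {
  miss_p <- setdiff(truth$plate_id, summaries$plate_id)
  miss_t <- setdiff(summaries$plate_id, truth$plate_id)
  if (length(miss_p) || length(miss_t)) {
    stop("plate_ids not shared by both sides: ",
         paste(c(miss_p, miss_t), collapse = ", "))
  }
  tcol <- if ("true_nonwhite_pct" %in% names(truth)) "true_nonwhite_pct" else "pct_non_white"
  plates <- dplyr::inner_join(
    dplyr::select(summaries, "plate_id", pct_predicted = "pct_non_white"),
    dplyr::select(truth, "plate_id", pct_true = dplyr::all_of(tcol)),
    by = "plate_id"
  ) |>
    dplyr::mutate(diff = .data$pct_predicted - .data$pct_true,
                  abs_diff = abs(.data$diff))
  structure(
    list(plates = plates,
         mean_abs_diff = mean(plates$abs_diff, na.rm = TRUE),
         mean_signed_diff = mean(plates$diff, na.rm = TRUE)),
    class = "plate_comparison"
  )
}

#' @export
print.plate_comparison <- function(x, ...) {
  cat(sprintf(
    "<plate_comparison> %d plates, mean |diff| = %.2f pp, mean signed diff = %.2f pp\n",
    nrow(x$plates), x$mean_abs_diff, x$mean_signed_diff
  ))
  invisible(x)
}
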