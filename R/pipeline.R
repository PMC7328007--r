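# The full prediction pipeline: image -> mask -> regions -> crops ->
# classes -> plate summary.

#' Run the full colony quantification pipeline
#'
#' For every plate image: centre-crop and resize to the segmenter's input
#' size, predict the foreground probability mask, binarize, resize the mask
#' back to the original centre-cropped resolution, clear border artifacts,
#' apply morphological opening, label regions, filter them by eccentricity
#' and area, crop the kept colonies, classify each crop (with test-time
#' augmentation by default), and aggregate per plate. Per-image failures are
#' recorded in the report's `status` column and the run continues.
#'
#' The area threshold and opening radius default to the reference values at
#' 1024-px resolution (400 px and 2 px) scaled to the working resolution
#' (area by the square of the size ratio, the radius linearly).
#'
#' @param images Directory of JPEG/PNG plate images, a character vector of
#'   files, or a list of `plate_image` objects.
#' @param seg_fit Trained segmenter ([train_segmenter()]).
#' @param clf_fit Trained classifier ([train_classifier()]).
#' @param out_dir Optional directory for artifacts (report.csv, regions.csv,
#'   predictions.csv, crops/).
#' @param tta Use test-time augmentation for classification.
#' @param threshold Mask binarization threshold in (0, 1).
#' @param ecc_max Maximum region eccentricity (inclusive).
#' @param area_min Minimum region area in px (inclusive); `NULL` scales the
#'   1024-px reference value of 400 px to the working resolution.
#' @param opening_radius Disk radius for morphological opening; `NULL`
#'   scales the 1024-px reference value of 2 px.
#' @param padding Crop padding in px (`NULL`: 10% of the bbox side).
#' @param seed Seed for the augmentation draws (default 0).
#' @return A `pipeline_result`: list with tibbles `report` (one row per
#'   plate: counts, `pct_non_white`, `status`), `regions`, `predictions`,
#'   and the crop list.
#' @export
run_pipeline <- function(images, seg_fit, clf_fit, out_dir = NULL,
                         tta = TRUE, threshold = 0.5, ecc_max = 0.6,
                         area_min = NULL, opening_radius = NULL,
                         padding = NULL, seed = 0L) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                         full.names = TRUE)
    images <- sort(images)
  }
  if (length(images) == 0) {
    warning("no input images; returning an empty report")
    return(empty_pipeline_result(out_dir))
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "crops"), recursive = TRUE, showWarnings = FALSE)
  }
  seeds <- derive_seeds(seed, length(images))

  reports <- list(); regions_all <- list(); preds_all <- list(); crops_all <- list()
  for (i in seq_along(images)) {
    item <- images[[i]]
    res <- tryCatch(
      process_plate(item, seg_fit, clf_fit, tta, threshold, ecc_max,
                    area_min, opening_radius, padding, seeds[i], out_dir),
      error = function(e) {
        pid <- if (is.character(item)) strip_ext(basename(item)) else
          plate_id_of(item)
        list(report = tibble::tibble(
          plate_id = pid, n_white = NA_integer_, n_red = NA_integer_,
          n_pink = NA_integer_, n_variegating = NA_integer_,
          n_bad = NA_integer_, n_properly_segmented = NA_integer_,
          pct_non_white = NA_real_,
          status = paste0("error: ", conditionMessage(e))
        ), regions = NULL, predictions = NULL, crops = list())
      }
    )
    reports[[i]] <- res$report
    regions_all[[i]] <- res$regions
    preds_all[[i]] <- res$predictions
    crops_all <- c(crops_all, res$crops)
  }
  out <- structure(
    list(
      report = dplyr::bind_rows(reports),
      regions = dplyr::bind_rows(regions_all),
      predictions = dplyr::bind_rows(preds_all),
      crops = crops_all,
      seed = seed
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

process_plate <- function(item, seg_fit, clf_fit, tta, threshold, ecc_max,
                          area_min, opening_radius, padding, seed, out_dir) {
  img <- if (is.character(item)) read_plate_image(item) else item
  original <- center_crop_square(img)
  side <- dim(original)[1]
  area_min <- area_min %||% (400 * (side / 1024)^2)
  opening_radius <- opening_radius %||% max(1L, round(2 * side / 1024))

  net_in <- center_crop_resize(original, seg_fit$input_size)
  prob <- predict_mask(seg_fit, net_in)
  mask <- binarize(prob, threshold)
  mask <- resize_mask_to_original(mask, dim(original)[1:2])
  mask <- clear_border(mask)
  mask <- morphological_open(mask, opening_radius)
  regions <- label_regions(mask, plate_id = plate_id_of(img))
  fl <- filter_regions(regions, ecc_max = ecc_max, area_min = area_min)
  crops <- crop_colonies(original, fl$kept, padding = padding)
  if (!is.null(out_dir)) {
    for (cr in crops) {
      write_plate_image(cr$pixels, file.path(out_dir, "crops", crop_filename(cr)))
    }
  }
  preds <- if (length(crops) > 0) {
    classify_crops(clf_fit, crops, tta = tta, seed = seed)
  } else {
    tibble::tibble(
      plate_id = character(), region_id = integer(), label = character(),
      p_white = numeric(), p_red = numeric(), p_pink = numeric(),
      p_variegating = numeric(), p_bad = numeric(), status = character()
    )
  }
  report <- if (nrow(preds) > 0) {
    aggregate_plate(preds)
  } else {
    tibble::tibble(
      plate_id = plate_id_of(img), n_white = 0L, n_red = 0L, n_pink = 0L,
      n_variegating = 0L, n_bad = 0L, n_properly_segmented = 0L,
      pct_non_white = NA_real_, status = "undefined"
    )
  }
  regions$kept <- regions$region_id %in% fl$kept$region_id
  list(report = report, regions = regions, predictions = preds, crops = crops)
}

empty_pipeline_result <- function(out_dir) {
  out <- structure(
    list(
      report = tibble::tibble(
        plate_id = character(), n_white = integer(), n_red = integer(),
        n_pink = integer(), n_variegating = integer(), n_bad = integer(),
        n_properly_segmented = integer(), pct_non_white = numeric(),
        status = character()
      ),
      regions = tibble::tibble(), predictions = tibble::tibble(),
      crops = list(), seed = NA_integer_
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$report, file.path(out_dir, "report.csv"))
  readr::write_csv(result$regions, file.path(out_dir, "regions.csv"))
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d plate(s), %d crop(s) classified\n",
              nrow(x$report), nrow(x$predictions)))
  print(x$report)
  invisible(x)
}
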