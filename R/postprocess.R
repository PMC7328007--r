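# Mask post-processing: a predicted mask becomes filtered single-colony
# regions and cropped colony images. Coordinates are 0-based and bounding
# boxes half-open [min, max) throughout.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonally
# adjacent components are merged afterwards with a union-find over labels.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  n <- max(lab)
  if (n > 1) {
    h <- nrow(lab); w <- ncol(lab)
    p1 <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1]))   # down-right
    p2 <- cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
    pairs <- rbind(p1, p2)
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(n)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  # compact labels in scan order of first pixel
  ids <- unique(lab[lab > 0])
  if (length(ids) > 0) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Remove mask components touching the image border
#'
#' Every 8-connected foreground component with at least one pixel on the
#' first/last row or column is deleted; interior components are untouched.
#' This removes plate-rim artifacts before colony counting.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
clear_border <- function(mask) {
  lab <- label8(mask)
  h <- nrow(lab); w <- ncol(lab)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0]
  if (length(border) > 0) mask[lab %in% border] <- FALSE
  mask
}

disk_offsets <- function(radius) {
  s <- -radius:radius
  idx <- which(outer(s^2, s^2, `+`) <= radius^2, arr.ind = TRUE)
  cbind(di = s[idx[, 1]], dj = s[idx[, 2]])
}

# out[i, j] = m[i + di, j + dj], FALSE outside the image
binary_shift <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  r0 <- max(1L, 1L - di); r1 <- min(h, h - di)
  c0 <- max(1L, 1L - dj); c1 <- min(w, w - dj)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- m[(r0:r1) + di, (c0:c1) + dj]
  }
  out
}

binary_erode <- function(mask, offsets) {
  out <- mask
  for (k in seq_len(nrow(offsets))) {
    if (offsets[k, 1] == 0 && offsets[k, 2] == 0) next
    out <- out & binary_shift(mask, offsets[k, 1], offsets[k, 2])
    if (!any(out)) break
  }
  out
}

binary_dilate <- function(mask, offsets) {
  out <- mask
  for (k in seq_len(nrow(offsets))) {
    if (offsets[k, 1] == 0 && offsets[k, 2] == 0) next
    out <- out | binary_shift(mask, offsets[k, 1], offsets[k, 2])
  }
  out
}

#' Morphological opening with a disk structuring element
#'
#' Erosion followed by dilation with the discrete disk
#' `{(di, dj): di^2 + dj^2 <= radius^2}`; removes speckle and thin
#' protrusions smaller than the disk while preserving larger blobs.
#' Pixels outside the image count as background.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in px (>= 1).
#' @return Logical matrix of the same size.
#' @export
morphological_open <- function(mask, radius = 2) {
  stopifnot(radius >= 1)
  off <- disk_offsets(radius)
  binary_dilate(binary_erode(mask, off), off)
}

#' Label connected mask regions and measure them
#'
#' One region per 8-connected foreground component. Area is the pixel count,
#' the centroid and bounding box come from the member pixels (0-based rows
#' and columns, half-open bbox), and eccentricity is that of the ellipse
#' with the same normalized second central moments as the region:
#' `sqrt(1 - minor^2/major^2)`, 0 for a perfect disk.
#'
#' @param mask Logical matrix.
#' @param plate_id Identifier carried into the region table.
#' @return Tibble with columns plate_id, region_id, row_min, col_min,
#'   row_max, col_max, area, eccentricity, centroid_row, centroid_col.
#' @export
label_regions <- function(mask, plate_id = "") {
  lab <- label8(mask)
  px <- which(lab > 0L)
  empty <- tibble::tibble(
    plate_id = character(), region_id = integer(),
    row_min = integer(), col_min = integer(),
    row_max = integer(), col_max = integer(),
    area = integer(), eccentricity = numeric(),
    centroid_row = numeric(), centroid_col = numeric()
  )
  if (length(px) == 0) return(empty)
  h <- nrow(lab)
  labv <- lab[px]
  r0 <- (px - 1L) %% h          # 0-based row
  c0 <- (px - 1L) %/% h         # 0-based col
  df <- tibble::tibble(label = labv, r = r0, c = c0, lin = px)
  out <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area = dplyr::n(),
      row_min = min(.data$r), row_max = max(.data$r) + 1L,
      col_min = min(.data$c), col_max = max(.data$c) + 1L,
      centroid_row = mean(.data$r), centroid_col = mean(.data$c),
      mu20 = mean(.data$r^2) - mean(.data$r)^2,
      mu02 = mean(.data$c^2) - mean(.data$c)^2,
      mu11 = mean(.data$r * .data$c) - mean(.data$r) * mean(.data$c),
      first_px = min(.data$lin),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$first_px)
  common <- sqrt(((out$mu20 - out$mu02) / 2)^2 + out$mu11^2)
  l1 <- (out$mu20 + out$mu02) / 2 + common
  l2 <- (out$mu20 + out$mu02) / 2 - common
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(0, 1 - l2 / l1)))
  tibble::tibble(
    plate_id = plate_id,
    region_id = seq_len(nrow(out)),
    row_min = as.integer(out$row_min), col_min = as.integer(out$col_min),
    row_max = as.integer(out$row_max), col_max = as.integer(out$col_max),
    area = as.integer(out$area),
    eccentricity = ecc,
    centroid_row = out$centroid_row, centroid_col = out$centroid_col
  )
}

#' Select colony regions by shape and size
#'
#' Keeps regions with `eccentricity <= ecc_max` and `area >= area_min`
#' (both thresholds inclusive); the rest are rejected. Rounded single
#' colonies pass; elongated edge remnants and undersized specks do not.
#'
#' @param regions Region tibble from [label_regions()].
#' @param ecc_max Maximum eccentricity (default 0.6).
#' @param area_min Minimum area in px (default 400, the value used at
#'   1024-px plate resolution; scale it with resolution).
#' @return List with tibbles `kept` and `rejected`; their union is the
#'   input.
#' @export
filter_regions <- function(regions, ecc_max = 0.6, area_min = 400) {
  stopifnot(is.finite(ecc_max), is.finite(area_min))
  keep <- regions$eccentricity <= ecc_max & regions$area >= area_min
  list(kept = regions[keep, , drop = FALSE],
       rejected = regions[!keep, , drop = FALSE])
}

#' Crop selected colony regions out of a plate image
#'
#' Each kept region's bounding box is expanded by `padding` pixels (default
#' 10% of the longer bbox side) and clipped to the image; the crop retains
#' plate and region identity for provenance.
#'
#' @param image A `plate_image` (the original centre-cropped plate).
#' @param kept Tibble of kept regions from [filter_regions()].
#' @param padding Padding in px, or `NULL` for 10% of the bbox side.
#' @return List of `colony_crop` objects (possibly empty), each with fields
#'   `pixels`, `plate_id`, `region_id`, `bbox`.
#' @export
crop_colonies <- function(image, kept, padding = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  pid <- plate_id_of(image)
  lapply(seq_len(nrow(kept)), function(i) {
    rg <- kept[i, ]
    pad <- padding %||% round(0.1 * max(rg$row_max - rg$row_min,
                                        rg$col_max - rg$col_min))
    r0 <- max(0L, rg$row_min - pad); r1 <- min(h, rg$row_max + pad)
    c0 <- max(0L, rg$col_min - pad); c1 <- min(w, rg$col_max + pad)
    new_colony_crop(
      pixels = unclass(image)[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE],
      plate_id = if (nzchar(pid)) pid else rg$plate_id,
      region_id = rg$region_id,
      bbox = c(row_min = r0, col_min = c0, row_max = r1, col_max = c1)
    )
  })
}

new_colony_crop <- function(pixels, plate_id, region_id, bbox) {
  stopifnot(dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  structure(
    list(pixels = pixels, plate_id = plate_id, region_id = region_id,
         bbox = bbox),
    class = "colony_crop"
  )
}

#' @export
print.colony_crop <- function(x, ...) {
  cat(sprintf("<colony_crop %s__%s> %dx%d px\n", x$plate_id, x$region_id,
              dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

crop_filename <- function(crop) sprintf("%s__%s.jpg", crop$plate_id, crop$region_id)
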