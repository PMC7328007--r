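# Images are numeric arrays dim (H, W, 3) in [0, 1], row 1 = top of the image;
# masks are logical (H, W) matrices. EBImage stores (x, y, c), so I/O
# transposes at the boundary and nowhere else.

#' Read an RGB plate image
#'
#' @param path Path to a JPEG or PNG image.
#' @param plate_id Plate identifier; defaults to the file stem.
#' @return A `plate_image`: numeric array `(H, W, 3)` in `[0, 1]` with
#'   attributes `plate_id` and `source_path`.
#' @export
read_plate_image <- function(path, plate_id = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a <- aperm(a, c(2L, 1L, 3L))
  new_plate_image(a, plate_id %||% strip_ext(basename(path)), path)
}

new_plate_image <- function(pixels, plate_id, source_path = "") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(pixels,
    plate_id = plate_id, source_path = source_path,
    class = c("plate_image", "array")
  )
}

plate_id_of <- function(x) attr(x, "plate_id") %||% ""

strip_ext <- function(x) sub("\\.[A-Za-z]+$", "", x)

#' Write an RGB image to disk (JPEG or PNG by extension)
#' @param img Numeric array `(H, W, 3)` in `[0, 1]`.
#' @param path Output path.
#' @param quality JPEG quality (ignored for PNG).
#' @export
write_plate_image <- function(img, path, quality = 95) {
  a <- aperm(clamp01(unclass(img)), c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path,
    quality = quality
  )
  invisible(path)
}

#' Read a binary mask from a single-channel PNG (0 = background)
#' @param path PNG path.
#' @return Logical `(H, W)` matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a >= 0.5
}

#' Write a binary mask as a single-channel PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Resample a (H, W[, C]) array to out_h x out_w. Pixel-centre convention:
# source coordinate of output pixel i is (i - 0.5) * in/out + 0.5, so a 2x
# nearest-neighbour upscale of one pixel is an exact 2x2 block.
resize_array <- function(x, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  in_h <- d[1]; in_w <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  if (in_h == out_h && in_w == out_w) return(x)
  sr <- (seq_len(out_h) - 0.5) * in_h / out_h + 0.5
  sc <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5
  xm <- if (length(d) == 3L) x else array(x, c(d, 1L))
  if (method == "nearest") {
    ri <- pmin(pmax(round(sr), 1L), in_h)
    ci <- pmin(pmax(round(sc), 1L), in_w)
    out <- xm[ri, ci, , drop = FALSE]
  } else {
    ri <- pmin(pmax(sr, 1), in_h)
    ci <- pmin(pmax(sc, 1), in_w)
    i0 <- pmax(pmin(floor(ri), in_h - 1), 1); i1 <- pmin(i0 + 1, in_h)
    j0 <- pmax(pmin(floor(ci), in_w - 1), 1); j1 <- pmin(j0 + 1, in_w)
    fr <- ri - i0
    fc <- ci - j0
    out <- array(0, c(out_h, out_w, nc))
    wfr <- matrix(fr, out_h, out_w); wfc <- matrix(fc, out_h, out_w, byrow = TRUE)
    for (ch in seq_len(nc)) {
      p00 <- xm[i0, j0, ch]; p01 <- xm[i0, j1, ch]
      p10 <- xm[i1, j0, ch]; p11 <- xm[i1, j1, ch]
      top <- p00 * (1 - wfc) + p01 * wfc
      bot <- p10 * (1 - wfc) + p11 * wfc
      out[, , ch] <- top * (1 - wfr) + bot * wfr
    }
  }
  if (length(d) == 3L) out else out[, , 1L]
}

#' Centre-crop an image to a square and resize it
#'
#' Takes the centred square of side `min(H, W)` and resamples it to
#' `target_size` x `target_size` (bilinear), mirroring the preprocessing the
#' prediction pipeline applies before segmentation.
#'
#' @param image A `plate_image` or `(H, W, 3)` array.
#' @param target_size Output side length in pixels (> 0).
#' @return A `plate_image` of dimension `(target_size, target_size, 3)`.
#' @export
center_crop_resize <- function(image, target_size) {
  if (!is.numeric(target_size) || length(target_size) != 1L || target_size <= 0) {
    stop("`target_size` must be a positive number")
  }
  target_size <- as.integer(target_size)
  sq <- center_crop_square(image)
  out <- resize_array(unclass(sq), target_size, target_size, "bilinear")
  new_plate_image(clamp01(out), plate_id_of(image), attr(image, "source_path") %||% "")
}

center_crop_square <- function(image) {
  d <- dim(image)
  side <- min(d[1], d[2])
  r0 <- (d[1] - side) %/% 2L
  c0 <- (d[2] - side) %/% 2L
  out <- unclass(image)[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  new_plate_image(out, plate_id_of(image), attr(image, "source_path") %||% "")
}

#' Resize a binary mask to given dimensions (nearest neighbour)
#'
#' Used to map a mask predicted at network resolution back onto the original
#' centre-cropped image before region analysis.
#'
#' @param mask Logical matrix.
#' @param original_dims Integer `(rows, cols)` of the target.
#' @return Logical matrix of the requested dimensions.
#' @export
resize_mask_to_original <- function(mask, original_dims) {
  stopifnot(length(original_dims) >= 2L, all(original_dims[1:2] >= 1))
  out <- resize_array(
    matrix(as.numeric(mask), nrow(mask), ncol(mask)),
    as.integer(original_dims[1]), as.integer(original_dims[2]), "nearest"
  )
  out >= 0.5
}

# Affine warp about the image centre: rotate by `angle` degrees, scale by
# `zoom` (>1 enlarges content), optional horizontal flip. Bilinear for
# images, nearest for masks; out-of-frame samples take `fill`.
warp_affine <- function(x, angle = 0, zoom = 1, flip_h = FALSE,
                        method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(x)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  xm <- if (length(d) == 3L) x else array(x, c(h, w, 1L))
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h) - cy, h, w)
  cc <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  if (flip_h) cc <- -cc
  # inverse map: source = R(-th) * p / zoom
  sr <- (cos(th) * rr + sin(th) * cc) / zoom + cy
  sc <- (-sin(th) * rr + cos(th) * cc) / zoom + cx
  out <- array(fill, c(h, w, nc))
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    idx <- cbind(ri[ok], ci[ok])
    for (ch in seq_len(nc)) {
      plane <- matrix(fill, h, w)
      plane[which(ok)] <- xm[, , ch][idx]
      out[, , ch] <- plane
    }
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    for (ch in seq_len(nc)) {
      plane <- xm[, , ch]
      g <- function(ri, ci) {
        ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
        v <- matrix(fill, h, w)
        v[which(ok)] <- plane[cbind(ri[ok], ci[ok])]
        v
      }
      out[, , ch] <- g(r0, c0) * (1 - fr) * (1 - fc) +
        g(r0, c0 + 1) * (1 - fr) * fc +
        g(r0 + 1, c0) * fr * (1 - fc) +
        g(r0 + 1, c0 + 1) * fr * fc
    }
  }
  if (length(d) == 3L) out else out[, , 1L]
}

# Exact dihedral-8 transforms (no resampling). k in 0:7; 0:3 are rotations by
# 90k degrees, 4:7 the same after a horizontal flip.
dihedral8 <- function(x, k) {
  stopifnot(k %in% 0:7)
  d <- dim(x)
  xm <- if (length(d) == 3L) x else array(x, c(d, 1L))
  if (k >= 4L) xm <- xm[, rev(seq_len(dim(xm)[2])), , drop = FALSE]
  r <- k %% 4L
  for (i in seq_len(r)) {
    # rotate 90 deg counter-clockwise
    xm <- aperm(xm, c(2L, 1L, 3L))[rev(seq_len(dim(xm)[2])), , , drop = FALSE]
  }
  if (length(d) == 3L) xm else xm[, , 1L]
}

# brightness delta and contrast factor about 0.5, image only
photometric_jitter <- function(img, brightness = 0, contrast = 1) {
  clamp01((unclass(img) - 0.5) * contrast + 0.5 + brightness)
}
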