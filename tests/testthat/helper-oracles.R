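# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written in the most literal way possible (per-pixel scans,
# explicit set arithmetic), sharing no code with the package internals.

# region properties from an explicit pixel list: loops over every member
# pixel, accumulates raw moments, then the moments-ellipse eccentricity
oracle_region_props <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  rs <- px[, 1] - 1  # 0-based
  cs <- px[, 2] - 1
  sr <- 0; sc <- 0
  for (i in seq_len(n)) { sr <- sr + rs[i]; sc <- sc + cs[i] }
  mr <- sr / n; mc <- sc / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (i in seq_len(n)) {
    m20 <- m20 + (rs[i] - mr)^2
    m02 <- m02 + (cs[i] - mc)^2
    m11 <- m11 + (rs[i] - mr) * (cs[i] - mc)
  }
  m20 <- m20 / n; m02 <- m02 / n; m11 <- m11 / n
  tr2 <- (m20 + m02) / 2
  det <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- tr2 + det; l2 <- tr2 - det
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(
    area = n,
    row_min = min(rs), row_max = max(rs) + 1,
    col_min = min(cs), col_max = max(cs) + 1,
    centroid_row = mr, centroid_col = mc,
    eccentricity = ecc
  )
}

disk_offsets_oracle <- function(r) {
  off <- NULL
  for (di in -r:r) for (dj in -r:r) {
    if (di * di + dj * dj <= r * r) off <- rbind(off, c(di, dj))
  }
  off
}

# per-pixel scan erosion: pixel survives iff every offset lands inside the
# image on a foreground pixel
oracle_erode <- function(m, r) {
  off <- disk_offsets_oracle(r)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      if (ii < 1 || ii > h || jj < 1 || jj > w || !m[ii, jj]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# set dilation: union of the translated foreground set, clipped to the image
oracle_dilate <- function(m, r) {
  off <- disk_offsets_oracle(r)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  px <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    ii <- px[, 1] + off[k, 1]; jj <- px[, 2] + off[k, 2]
    keep <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    out[cbind(ii[keep], jj[keep])] <- TRUE
  }
  out
}

oracle_open <- function(m, r) oracle_dilate(oracle_erode(m, r), r)

# flood-fill border clearing with explicit 8-neighbour queue
oracle_clear_border <- function(m) {
  h <- nrow(m); w <- ncol(m)
  kill <- matrix(FALSE, h, w)
  queue <- which(m & (row(m) %in% c(1, h) | col(m) %in% c(1, w)))
  kill[queue] <- TRUE
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    i <- (p - 1) %% h + 1; j <- (p - 1) %/% h + 1
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          m[ii, jj] && !kill[ii, jj]) {
        kill[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * h + ii)
      }
    }
  }
  m & !kill
}

# draw a filled shape on a blank canvas from a centre predicate
shape_mask <- function(h, w, fn) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) m[i, j] <- fn(i, j)
  m
}
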