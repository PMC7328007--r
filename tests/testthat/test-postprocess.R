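test_that("center crop takes the centred square and resizes to target", {
  img <- new_img <- array(runif(36 * 52 * 3), c(36, 52, 3))
  pi1 <- platepheno:::new_plate_image(img, "p")
  # square input at its own side is the identity
  sq <- platepheno:::new_plate_image(array(runif(40 * 40 * 3), c(40, 40, 3)), "q")
  expect_equal(unclass(center_crop_resize(sq, 40)), unclass(sq))
  # non-square input crops the centred 36x36 before resizing
  out <- center_crop_resize(pi1, 36)
  expect_equal(unclass(out), img[, 9:44, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # contract: always square of the requested size
  out2 <- center_crop_resize(pi1, 20)
  expect_equal(dim(out2), c(20, 20, 3))
  expect_error(center_crop_resize(pi1, 0), "positive")
})

test_that("mask resizing is nearest-neighbour and boolean", {
  m <- matrix(FALSE, 4, 4); m[2, 3] <- TRUE
  expect_identical(resize_mask_to_original(m, c(4, 4)), m)
  up <- resize_mask_to_original(m, c(8, 8))
  expect_equal(sum(up), 4)  # one pixel becomes an exact 2x2 block
  expect_true(all(up[3:4, 5:6]))
  # down-then-up keeps large blobs countable
  big <- shape_mask(64, 64, function(i, j) {
    (i - 20)^2 + (j - 20)^2 <= 12^2 || (i - 48)^2 + (j - 44)^2 <= 11^2
  })
  rt <- resize_mask_to_original(resize_mask_to_original(big, c(32, 32)), c(64, 64))
  expect_equal(nrow(label_regions(rt)), nrow(label_regions(big)))
})

test_that("border clearing removes exactly the edge-touching components", {
  m <- matrix(FALSE, 20, 20)
  m[1:3, 5:7] <- TRUE       # touches top
  m[9:12, 9:12] <- TRUE     # interior
  m[15:20, 1:2] <- TRUE     # touches bottom-left
  out <- clear_border(m)
  expect_false(any(out[1:3, 5:7]))
  expect_false(any(out[15:20, 1:2]))
  expect_true(all(out[9:12, 9:12]))
  # full-frame foreground vanishes
  expect_false(any(clear_border(matrix(TRUE, 8, 8))))
  # agrees with a flood-fill oracle on random masks
  set.seed(21)
  for (i in 1:10) {
    r <- matrix(runif(24 * 24) < 0.4, 24, 24)
    expect_identical(clear_border(r), oracle_clear_border(r))
  }
})

test_that("morphological opening removes speckle, keeps blobs, and is idempotent", {
  m <- matrix(FALSE, 30, 30); m[15, 15] <- TRUE
  expect_false(any(morphological_open(m, 1)))

  disk <- shape_mask(64, 64, function(i, j) (i - 32)^2 + (j - 32)^2 <= 20^2)
  opened <- morphological_open(disk, 2)
  expect_lt(abs(sum(opened) - sum(disk)) / sum(disk), 0.05)

  set.seed(31)
  r <- matrix(runif(40 * 40) < 0.45, 40, 40)
  o1 <- morphological_open(r, 2)
  expect_identical(morphological_open(o1, 2), o1)
})

test_that("region labelling uses 8-connectivity and conserves pixels", {
  # two diagonal pixels form one region
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(label_regions(m)), 1)

  disk <- shape_mask(60, 60, function(i, j) (i - 30)^2 + (j - 30)^2 <= 18^2)
  reg <- label_regions(disk)
  expect_equal(nrow(reg), 1)
  expect_lt(reg$eccentricity, 0.05)
  expect_equal(reg$area, sum(disk))

  two <- disk
  two[5:10, 5:10] <- TRUE
  reg2 <- label_regions(two, plate_id = "p9")
  expect_equal(nrow(reg2), 2)
  expect_equal(sum(reg2$area), sum(two))
  expect_true(all(reg2$plate_id == "p9"))
})

test_that("an axis-aligned 2:1 ellipse has eccentricity ~ sqrt(3)/2", {
  b <- 9
  ell <- shape_mask(60, 60, function(i, j) {
    ((i - 30) / b)^2 + ((j - 30) / (2 * b))^2 <= 1
  })
  reg <- label_regions(ell)
  expect_equal(reg$eccentricity, sqrt(3) / 2, tolerance = 0.01)
})

test_that("region properties agree with the brute-force moments oracle", {
  set.seed(41)
  checked <- 0
  while (checked < 120) {
    # random blob: union of 1-3 random disks/ellipses, possibly rotated
    m <- matrix(FALSE, 48, 48)
    for (k in seq_len(sample(1:3, 1))) {
      ci <- runif(1, 12, 36); cj <- runif(1, 12, 36)
      a <- runif(1, 2, 9); b <- runif(1, 2, 9); th <- runif(1, 0, pi)
      m <- m | shape_mask(48, 48, function(i, j) {
        u <- cos(th) * (i - ci) + sin(th) * (j - cj)
        v <- -sin(th) * (i - ci) + cos(th) * (j - cj)
        (u / a)^2 + (v / b)^2 <= 1
      })
    }
    regs <- label_regions(m)
    lab <- platepheno:::label8(m)
    for (rid in seq_len(nrow(regs))) {
      part <- lab == rid
      o <- oracle_region_props(part)
      r <- regs[regs$region_id == rid, ]
      expect_equal(r$area, o$area)
      expect_equal(r$row_min, o$row_min); expect_equal(r$row_max, o$row_max)
      expect_equal(r$col_min, o$col_min); expect_equal(r$col_max, o$col_max)
      expect_equal(r$centroid_row, o$centroid_row, tolerance = 1e-9)
      expect_equal(r$eccentricity, o$eccentricity, tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 100)
})

test_that("region filtering applies inclusive thresholds and partitions", {
  regs <- tibble::tibble(
    plate_id = "p", region_id = 1:5,
    row_min = 0L, col_min = 0L, row_max = 10L, col_max = 10L,
    area = c(1000L, 1000L, 400L, 399L, 400L),
    eccentricity = c(0.0, 0.61, 0.60, 0.1, 0.600001),
    centroid_row = 5, centroid_col = 5
  )
  fl <- filter_regions(regs)
  expect_equal(fl$kept$region_id, c(1L, 3L))
  expect_equal(fl$rejected$region_id, c(2L, 4L, 5L))
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), nrow(regs))
  # re-filtering the kept set is a no-op
  fl2 <- filter_regions(fl$kept)
  expect_identical(fl2$kept, fl$kept)
  expect_equal(nrow(fl2$rejected), 0)
})

test_that("colony crops respect bbox arithmetic, clipping and provenance", {
  img <- platepheno:::new_plate_image(array(runif(64 * 64 * 3), c(64, 64, 3)), "pl7")
  kept <- tibble::tibble(
    plate_id = "pl7", region_id = c(1L, 2L),
    row_min = c(10L, 0L), col_min = c(10L, 60L),
    row_max = c(30L, 4L), col_max = c(30L, 64L),
    area = c(400L, 16L), eccentricity = 0,
    centroid_row = 0, centroid_col = 0
  )
  crops <- crop_colonies(img, kept, padding = 0)
  expect_length(crops, 2)
  expect_equal(dim(crops[[1]]$pixels), c(20, 20, 3))
  expect_equal(unclass(crops[[1]]$pixels), unclass(img)[11:30, 11:30, ])
  # padding clipped at the image corner
  crops5 <- crop_colonies(img, kept, padding = 5)
  expect_equal(dim(crops5[[2]]$pixels)[1:2], c(9, 9))
  # file names encode plate and region identity
  expect_equal(platepheno:::crop_filename(crops[[1]]), "pl7__1.jpg")
  expect_length(crop_colonies(img, kept[0, ]), 0)
})
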