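test_that("dice coefficient follows its set formula and conventions", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE           # |A| = 4
  b <- matrix(FALSE, 8, 8); b[2:5, 2:3] <- TRUE           # |B| = 8, overlap 4
  expect_equal(dice_coefficient(a, b), 2 * 4 / (4 + 8))
  expect_equal(dice_coefficient(a, a), 1)
  d <- matrix(FALSE, 8, 8); d[6:7, 6:7] <- TRUE
  expect_equal(dice_coefficient(a, d), 0)
  # symmetry and the both-empty convention
  expect_equal(dice_coefficient(b, a), dice_coefficient(a, b))
  expect_equal(dice_coefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(FALSE, 4, 4)), "8x8.*4x4")
})

test_that("binarize is inclusive at the threshold and monotone", {
  p <- matrix(c(0, 0.2, 0.5, 0.9), 2, 2)
  expect_identical(binarize(matrix(0, 3, 3)), matrix(FALSE, 3, 3))
  expect_true(binarize(p)[1, 2])          # exactly 0.5 -> foreground
  expect_equal(sum(binarize(p, 0.9)), 1)
  expect_lte(sum(binarize(p, 0.9)), sum(binarize(p, 0.1)))
  expect_error(binarize(p, 0), "between 0 and 1")
  expect_error(binarize(p, 1), "between 0 and 1")
})

test_that("pair augmentation keeps image and mask geometrically aligned", {
  cfg <- seg_config("desk")
  spec <- tiny_plate_spec(size = 64, n_colonies = 4, seed = 2)
  r <- render_plate(spec, seed = 2)
  img <- unclass(r$image); msk <- r$ground_truth$mask

  # photometric-only config: mask must come back untouched
  cfg_photo <- seg_config("desk", augmentation = list(
    max_rotation = 0, horizontal_flip = FALSE, brightness = 0.2, contrast = 0.2))
  set.seed(1)
  out <- augment_seg_pair(img, msk, cfg_photo)
  expect_identical(out$mask, msk)
  expect_false(identical(out$image, img))

  # same RNG state gives identical outputs; mask stays boolean
  set.seed(9); a <- augment_seg_pair(img, msk, cfg)
  set.seed(9); b <- augment_seg_pair(img, msk, cfg)
  expect_identical(a, b)
  expect_type(a$mask, "logical")
  # a geometric draw moves image and mask together: foreground pixel counts
  # stay within resampling error of each other
  expect_lt(abs(sum(a$mask) - sum(msk)) / sum(msk), 0.15)
})

test_that("a short training run improves validation dice over the untrained model", {
  ds <- tiny_plate_dataset(seed = 5)
  cfg <- tiny_seg_config(seed = 42L)
  fit <- train_segmenter(ds$manifest, cfg, base_dir = ds$dir)

  # history bookkeeping: one row per scheduled epoch
  total_epochs <- sum(vapply(cfg$stages,
                             function(s) round(s$schedule$total_epochs), 1))
  expect_equal(nrow(fit$history), total_epochs)

  untrained <- build_segmenter(cfg)
  vman <- ds$manifest[ds$manifest$split == "valid", ]
  dice_of <- function(f) {
    mean(vapply(seq_len(nrow(vman)), function(i) {
      img <- center_crop_resize(
        read_plate_image(file.path(ds$dir, vman$image_path[i])), f$input_size)
      truth <- resize_mask_to_original(
        read_mask(file.path(ds$dir, vman$mask_path[i])),
        c(f$input_size, f$input_size))
      dice_coefficient(binarize(predict_mask(f, img)), truth)
    }, numeric(1)))
  }
  expect_gt(dice_of(fit), dice_of(untrained))
  expect_gt(max(fit$history$val_dice), 0.3)
})

test_that("training errors on empty splits and broken manifests", {
  ds <- tiny_plate_dataset(seed = 5)
  man <- ds$manifest
  man$split <- "train"
  expect_error(train_segmenter(man, tiny_seg_config(), base_dir = ds$dir),
               "validation split")
  man$split <- "valid"
  expect_error(train_segmenter(man, tiny_seg_config(), base_dir = ds$dir),
               "training split")
})

test_that("mask prediction is bounded, deterministic and size-checked", {
  ds <- tiny_plate_dataset(seed = 5)
  cfg <- tiny_seg_config()
  fit <- build_segmenter(cfg)  # untrained weights are fine for the contract
  img <- center_crop_resize(
    read_plate_image(file.path(ds$dir, ds$manifest$image_path[1])), 64)
  p1 <- predict_mask(fit, img)
  p2 <- predict_mask(fit, img)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)
  expect_error(predict_mask(fit, center_crop_resize(img, 32)), "trained at")
})

test_that("the paper-profile config carries the published stage parameters", {
  cfg <- seg_config("paper")
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$weight_decay, 1e-7)
  s1 <- cfg$stages[[1]]
  expect_true(s1$last_layer_only)
  expect_equal(s1$image_size, 512L)
  expect_equal(s1$schedule$max_lr, 4e-2)
  expect_equal(s1$schedule$min_lr, 8e-3)
  expect_equal(s1$schedule$epochs_up + s1$schedule$epochs_down, 8)
  s2 <- cfg$stages[[2]]
  expect_equal(s2$schedule$max_lr, c(1e-4, 1e-3, 1e-2))
  expect_equal(s2$schedule$min_lr, c(1e-4, 1e-3, 1e-2) / 20)
  s4 <- cfg$stages[[4]]
  expect_equal(s4$image_size, 1024L)
  expect_equal(s4$schedule$cycles, 20L)
  expect_equal(s4$schedule$epochs_up + s4$schedule$epochs_down, 20)
  expect_equal(s4$schedule$max_lr, c(4e-5, 2e-4, 4e-3))
})
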