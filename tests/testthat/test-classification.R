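all_off_aug <- list(max_rotation = 0, dihedral = FALSE, brightness = 0,
                    contrast = 0, max_zoom = 1)

test_that("crop augmentation respects its bounds and determinism", {
  spec <- tiny_plate_spec(size = 96, seed = 1)
  crop <- platepheno:::render_crop_impl("red", spec)
  sq <- unclass(center_crop_resize(crop, 24))

  # all transforms at identity leave the crop unchanged
  cfg0 <- clf_config("desk", augmentation = all_off_aug)
  set.seed(3)
  expect_equal(augment_crop(sq, cfg0), sq, tolerance = 1e-12)

  cfg <- clf_config("desk")
  set.seed(4); a <- augment_crop(sq, cfg)
  set.seed(4); b <- augment_crop(sq, cfg)
  expect_identical(a, b)
  expect_equal(dim(a), dim(sq))

  # zoom-only config: content is magnified, never shrunk
  cfgz <- clf_config("desk", augmentation = list(
    max_rotation = 0, dihedral = FALSE, brightness = 0, contrast = 0,
    max_zoom = 1.1))
  set.seed(5)
  z <- augment_crop(sq, cfgz)
  expect_equal(dim(z), dim(sq))
})

test_that("training refuses a split that lacks a phenotype class", {
  t1 <- t1_fixture()
  man <- t1$manifest[t1$manifest$label != "pink", ]
  expect_error(
    train_classifier(man, clf_config("desk"), base_dir = t1$dir),
    "pink"
  )
})

test_that("TTA averages probability vectors on the simplex", {
  t1 <- t1_fixture()
  crop_path <- file.path(t1$dir, t1$manifest$crop_path[1])
  crop <- unclass(read_plate_image(crop_path))

  plain <- predict_with_tta(t1$fit, crop, n_augments = 0)
  expect_s3_class(plain, "class_probabilities")
  expect_equal(sum(plain$probs), 1, tolerance = 1e-9)

  # identity-only augmentations: TTA equals the plain prediction exactly
  fit0 <- t1$fit
  fit0$config$augmentation <- all_off_aug
  tta0 <- predict_with_tta(fit0, crop, n_augments = 4, seed = 1)
  expect_equal(tta0$probs, plain$probs, tolerance = 1e-12)

  # default TTA averages the original plus four augmented copies
  tta <- predict_with_tta(t1$fit, crop, n_augments = 4, seed = 1)
  expect_equal(sum(tta$probs), 1, tolerance = 1e-9)
  expect_equal(tta$argmax_label,
               colony_phenotypes()[which.max(tta$probs)])
  expect_error(predict_with_tta(t1$fit, crop, n_augments = -1), ">= 0")
})

test_that("classify_crops conserves rows and flags unreadable files", {
  t1 <- t1_fixture()
  paths <- file.path(t1$dir, t1$manifest$crop_path[1:5])
  broken <- file.path(tempdir(), "not_an_image.jpg")
  writeLines("this is not a JPEG", broken)

  out <- classify_crops(t1$fit, c(as.list(paths), broken), tta = FALSE)
  expect_equal(nrow(out), 6)
  expect_true(all(out$status[1:5] == "ok"))
  expect_match(out$status[6], "error")
  expect_true(is.na(out$label[6]))

  # tta toggling changes probabilities, never the row count
  on <- classify_crops(t1$fit, as.list(paths), tta = TRUE, seed = 2)
  off <- classify_crops(t1$fit, as.list(paths), tta = FALSE, seed = 2)
  expect_equal(nrow(on), nrow(off))
  probs <- as.matrix(on[, c("p_white", "p_red", "p_pink", "p_variegating", "p_bad")])
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-9)

  # determinism under a seed
  again <- classify_crops(t1$fit, as.list(paths), tta = TRUE, seed = 2)
  expect_identical(on, again)
})

test_that("the trained model reads saturated red and white crops correctly", {
  t1 <- t1_fixture()
  spec <- synth_plate_spec(seed = 99, noise_sd = 0.005)
  red <- with_seed_test(1, platepheno:::render_crop_impl("red", spec))
  white <- with_seed_test(2, platepheno:::render_crop_impl("white", spec))
  pr <- predict_with_tta(t1$fit, unclass(red), n_augments = 0)
  pw <- predict_with_tta(t1$fit, unclass(white), n_augments = 0)
  expect_equal(pr$argmax_label, "red")
  expect_equal(pw$argmax_label, "white")
})

test_that("the model learns signal, not leakage: permuted labels drop to chance", {
  spec <- tiny_plate_spec(size = 96, seed = 13)
  d <- fixture_dir("perm_crops")
  man <- generate_crop_dataset(spec, 300, c(2, 1, 1, 1, 0.3), d, seed = 13)
  cfg <- tiny_clf_config(seed = 7L)

  fit <- train_classifier(file.path(d, "labels.csv"), cfg)
  acc_signal <- max(fit$history$val_accuracy)

  man_perm <- man
  tr <- man_perm$split == "train"
  man_perm$label[tr] <- with_seed_test(99, sample(man_perm$label[tr]))
  fit_perm <- train_classifier(man_perm, cfg, base_dir = d)
  acc_perm <- tail(fit_perm$history$val_accuracy, 1)

  majority <- max(table(man$label[man$split == "valid"])) /
    sum(man$split == "valid")
  expect_gt(acc_signal, 0.7)
  expect_lt(acc_perm, majority + 0.15)
  expect_gt(acc_signal - acc_perm, 0.25)
})

test_that("the paper-profile classifier config matches the published protocol", {
  cfg <- clf_config("paper")
  expect_equal(cfg$input_size, 50L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$warmup_lr, 1e-2)
  expect_equal(cfg$main_schedule$max_lr, c(1.1e-4, 3.3e-4, 1e-3))
  cyc <- schedule_cycles(cfg$main_schedule)
  expect_equal(nrow(cyc), 51)
  expect_equal(sum(cyc$epochs), 119)
  expect_equal(cfg$augmentation$max_rotation, 10)
  expect_equal(cfg$augmentation$max_zoom, 1.1)
  expect_true(cfg$augmentation$dihedral)
})
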