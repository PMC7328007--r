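# Encoder-decoder segmentation of colonies: per-pixel foreground logits
# trained with binary cross-entropy and SGDR-style circular learning rates,
# evaluated by dice coefficient.

#' Segmentation training configuration
#'
#' Two profiles are provided. `"desk"` trains a small random-init
#' encoder-decoder on 128-px synthetic plates in minutes on one CPU. In
#' `"paper"` the staged schedule mirrors the published protocol for the
#' GPU-scale model this package's family of pipelines uses (512-px last-layer
#' warmup of 1 rising + 7 falling epochs at 8e-3..4e-2; all-layer cycle of
#' 2 + 18 epochs with per-third max rates 1e-4/1e-3/1e-2 and minima at 1/20th;
#' then 1024-px stages: 0.5 + 1.5 warmup and 20 cycles of 2.5 + 17.5 with max
#' rates 4e-5/2e-4/4e-3; batch 4, weight decay 1e-7).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... Overrides for any field (encoder, image_size, batch_size,
#'   weight_decay, stages, augmentation, pos_weight, threshold, seed).
#'   `pos_weight` scales the foreground term of the BCE-with-logits loss
#'   (desk default 3): colonies cover a small minority of plate pixels and
#'   an unweighted loss lets the recall of small dark colonies collapse.
#' @return A `seg_config` object.
#' @export
seg_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(
      profile = profile,
      encoder = "micro",
      image_size = 128L,
      batch_size = 4L,
      weight_decay = 1e-7,
      stages = list(
        list(image_size = 128L, last_layer_only = TRUE,
             schedule = lr_schedule("circular", max_lr = 4e-2, min_lr = 8e-3,
                                    epochs_up = 0.5, epochs_down = 0.5)),
        list(image_size = 128L, last_layer_only = FALSE,
             schedule = lr_schedule("circular",
                                    max_lr = c(0.08, 0.08, 0.08),
                                    min_lr = c(0.08, 0.08, 0.08) / 20,
                                    epochs_up = 1, epochs_down = 8))
      ),
      augmentation = list(max_rotation = 4, horizontal_flip = TRUE,
                          brightness = 0.1, contrast = 0.1),
      pos_weight = 3,
      threshold = 0.5,
      seed = 0L
    )
  } else {
    list(
      profile = profile,
      encoder = "resnet_tiny",
      image_size = 512L,
      batch_size = 4L,
      weight_decay = 1e-7,
      stages = list(
        list(image_size = 512L, last_layer_only = TRUE,
             schedule = lr_schedule("circular", max_lr = 4e-2, min_lr = 8e-3,
                                    epochs_up = 1, epochs_down = 7)),
        list(image_size = 512L, last_layer_only = FALSE,
             schedule = lr_schedule("circular",
                                    max_lr = c(1e-4, 1e-3, 1e-2),
                                    min_lr = c(1e-4, 1e-3, 1e-2) / 20,
                                    epochs_up = 2, epochs_down = 18)),
        list(image_size = 1024L, last_layer_only = TRUE,
             schedule = lr_schedule("circular", max_lr = 4e-2, min_lr = 8e-3,
                                    epochs_up = 0.5, epochs_down = 1.5)),
        list(image_size = 1024L, last_layer_only = FALSE,
             schedule = lr_schedule("circular",
                                    max_lr = c(4e-5, 2e-4, 4e-3),
                                    min_lr = c(4e-5, 2e-4, 4e-3) / 20,
                                    epochs_up = 2.5, epochs_down = 17.5,
                                    cycles = 20))
      ),
      augmentation = list(max_rotation = 4, horizontal_flip = TRUE,
                          brightness = 0.1, contrast = 0.1),
      pos_weight = 1,
      threshold = 0.5,
      seed = 0L
    )
  }
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "seg_config")
}

supported_encoders <- c("micro", "resnet_tiny")

build_seg_graph <- function(encoder, image_size) {
  g <- nn_graph(c(image_size, image_size, 3L))
  if (encoder == "micro") {
    r1 <- nn_relu(g, nn_conv(g, 1L, 8L))
    p1 <- nn_pool(g, r1)
    r2 <- nn_relu(g, nn_conv(g, p1, 16L))
    p2 <- nn_pool(g, r2)
    r3 <- nn_relu(g, nn_conv(g, p2, 16L))
    d2 <- nn_relu(g, nn_conv(g, nn_concat(g, nn_up(g, r3), r2), 8L))
    d1 <- nn_relu(g, nn_conv(g, nn_concat(g, nn_up(g, d2), r1), 8L))
    nn_conv(g, d1, 1L, k = 1L)
  } else if (encoder == "resnet_tiny") {
    s1 <- nn_relu(g, nn_conv(g, 1L, 8L))
    b1 <- nn_relu(g, nn_add(g, nn_conv(g, nn_relu(g, nn_conv(g, s1, 8L)), 8L), s1))
    p1 <- nn_pool(g, b1)
    s2 <- nn_relu(g, nn_conv(g, p1, 16L))
    b2 <- nn_relu(g, nn_add(g, nn_conv(g, nn_relu(g, nn_conv(g, s2, 16L)), 16L), s2))
    p2 <- nn_pool(g, b2)
    bo <- nn_relu(g, nn_conv(g, p2, 32L))
    d2 <- nn_relu(g, nn_conv(g, nn_concat(g, nn_up(g, bo), b2), 16L))
    d1 <- nn_relu(g, nn_conv(g, nn_concat(g, nn_up(g, d2), b1), 8L))
    nn_conv(g, d1, 1L, k = 1L)
  } else {
    stop(sprintf("unknown encoder '%s'; supported: %s", encoder,
                 paste(supported_encoders, collapse = ", ")))
  }
  g
}

#' Build an untrained segmentation model
#'
#' Maps an `image_size` x `image_size` RGB input to a single-channel logit
#' map of the same size. Supported encoders: `"micro"` (plain
#' encoder-decoder with skip connections) and `"resnet_tiny"` (residual
#' blocks in the encoder). Weights are He-initialized deterministically from
#' `config$seed`. Trainable layers are partitioned into thirds for
#' differential learning rates.
#'
#' @param config A [seg_config()].
#' @return A `segmenter` handle (untrained `seg_fit`).
#' @export
build_segmenter <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  g <- build_seg_graph(config$encoder, config$stages[[1]]$image_size)
  model <- nn_finalize(g, paste0("segmenter_", config$encoder), config$seed)
  # colonies cover a small fraction of a plate; starting the output bias at
  # the logit of a rare-foreground prior avoids wasting early epochs on the
  # collapse-to-background phase
  out_id <- nn_last_layer_id(model)
  model$nodes[[out_id]]$b[] <- -2.2
  structure(
    list(model = model, config = config,
         input_size = config$stages[[1]]$image_size,
         threshold = config$threshold,
         norm = c(mean = 0.5, sd = 0.25),
         history = NULL),
    class = c("segmenter", "seg_fit")
  )
}

# rebuild the graph at a new input size, carrying weights over (all layers
# are convolutional, so weights are size-independent)
reshape_segmenter <- function(fit, image_size) {
  g <- build_seg_graph(fit$config$encoder, image_size)
  m2 <- nn_finalize(g, fit$model$name, fit$config$seed)
  for (i in seq_along(m2$nodes)) {
    if (!is.null(fit$model$nodes[[i]]$W)) {
      m2$nodes[[i]]$W <- fit$model$nodes[[i]]$W
      m2$nodes[[i]]$b <- fit$model$nodes[[i]]$b
    }
  }
  fit$model <- m2
  fit$input_size <- image_size
  fit
}

#' Dice coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; by convention 1 when both masks are
#' empty. Symmetric, 1 iff the masks are identical.
#'
#' @param pred,truth Logical matrices of equal dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop(sprintf("mask dimensions differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(truth), collapse = "x")))
  }
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred & truth) / (a + b)
}

#' Jointly augment an image/mask pair
#'
#' Draws one geometric transform (rotation up to
#' `config$augmentation$max_rotation` degrees, optional horizontal flip) and
#' applies it to both image and mask (nearest-neighbour for the mask, which
#' stays boolean); brightness/contrast jitter is applied to the image only.
#' Uses the current RNG stream: identical states give identical outputs.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask Logical matrix aligned with `image`.
#' @param config A [seg_config()].
#' @return List with elements `image` and `mask`.
#' @export
augment_seg_pair <- function(image, mask, config) {
  au <- config$augmentation
  angle <- runif(1, -au$max_rotation, au$max_rotation)
  flip <- isTRUE(au$horizontal_flip) && runif(1) < 0.5
  bright <- runif(1, -au$brightness, au$brightness)
  contr <- runif(1, 1 - au$contrast, 1 + au$contrast)
  img <- unclass(image)
  if (angle != 0 || flip) {
    img <- warp_affine(img, angle = angle, flip_h = flip, method = "bilinear")
    mask <- warp_affine(matrix(as.numeric(mask), nrow(mask)), angle = angle,
                        flip_h = flip, method = "nearest") >= 0.5
  }
  img <- photometric_jitter(img, bright, contr)
  list(image = img, mask = mask)
}

# binary cross-entropy with logits; `pos_weight` scales the foreground term
# (softplus(-z) = -log sigmoid(z), softplus(z) = -log(1 - sigmoid(z)))
bce_with_logits <- function(z, y, pos_weight = 1) {
  softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  mean(pos_weight * y * softplus(-z) + (1 - y) * softplus(z))
}

bce_grad <- function(z, y, pos_weight = 1) {
  s <- sigmoid(z)
  (s * (1 - y) - pos_weight * y * (1 - s)) / length(z)
}

load_seg_data <- function(manifest, base_dir, image_size) {
  n <- nrow(manifest)
  x <- array(0, c(image_size, image_size, 3L, n))
  y <- array(0, c(image_size, image_size, 1L, n))
  for (i in seq_len(n)) {
    img <- read_plate_image(file.path(base_dir, manifest$image_path[i]))
    msk <- read_mask(file.path(base_dir, manifest$mask_path[i]))
    x[, , , i] <- resize_array(unclass(img), image_size, image_size, "bilinear")
    y[, , 1L, i] <- resize_array(matrix(as.numeric(msk), nrow(msk)),
                                 image_size, image_size, "nearest")
  }
  list(x = x, y = y)
}

resolve_manifest <- function(manifest, base_dir) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  list(manifest = tibble::as_tibble(manifest), base_dir = base_dir)
}

#' Train the colony segmenter
#'
#' Runs the configured stages in order: typically a last-layer-only warmup,
#' then all layers with differential per-third learning rates under a
#' circular (SGDR-style) schedule; stages with a larger image size continue
#' from the previous stage's weights. Loss is binary cross-entropy with
#' logits (mean over pixels and batch); validation dice is logged per epoch
#' and the weights with the best validation dice are kept.
#'
#' @param manifest Plate manifest tibble or CSV path (columns image_path,
#'   mask_path, split).
#' @param config A [seg_config()].
#' @param base_dir Directory paths in the manifest are relative to; defaults
#'   to the manifest's directory when a path is given.
#' @param momentum SGD momentum (0.9, matching the classifier's optimizer).
#' @param quiet Suppress per-epoch messages.
#' @return A `seg_fit` with elements `model` (best weights), `final_model`,
#'   `history` (tibble: stage, epoch, train_loss, val_loss, val_dice, lr),
#'   `config`, `input_size`, `threshold`.
#' @export
train_segmenter <- function(manifest, config, base_dir = NULL, momentum = 0.9,
                            quiet = TRUE) {
  stopifnot(inherits(config, "seg_config"))
  rm <- resolve_manifest(manifest, base_dir)
  manifest <- rm$manifest; base_dir <- rm$base_dir
  tr <- manifest[manifest$split == "train", ]
  va <- manifest[manifest$split == "valid", ]
  if (nrow(tr) == 0) stop("training split is empty")
  if (nrow(va) == 0) stop("validation split is empty")

  fit <- build_segmenter(config)
  history <- list()
  best <- list(dice = -Inf, model = fit$model)
  epoch_global <- 0L

  with_seed(config$seed + 1L, {
    for (si in seq_along(config$stages)) {
      stage <- config$stages[[si]]
      if (fit$input_size != stage$image_size) {
        fit <- reshape_segmenter(fit, stage$image_size)
      }
      dat <- load_seg_data(tr, base_dir, stage$image_size)
      vdat <- load_seg_data(va, base_dir, stage$image_size)
      n <- dim(dat$x)[4]
      bs <- min(config$batch_size, n)
      steps_per_epoch <- ceiling(n / bs)
      sched <- stage$schedule
      n_epochs <- round(sched$total_epochs)
      state <- nn_opt_state(fit$model)
      subset <- if (isTRUE(stage$last_layer_only)) nn_last_layer_id(fit$model) else NULL
      step <- 0L
      for (ep in seq_len(n_epochs)) {
        ord <- sample.int(n)
        tl <- 0
        for (bi in seq_len(steps_per_epoch)) {
          idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
          B <- length(idx)
          xb <- array(0, c(stage$image_size, stage$image_size, 3L, B))
          yb <- array(0, c(stage$image_size, stage$image_size, 1L, B))
          for (j in seq_len(B)) {
            aug <- augment_seg_pair(dat$x[, , , idx[j]],
                                    dat$y[, , 1L, idx[j]] >= 0.5, config)
            xb[, , , j] <- aug$image
            yb[, , 1L, j] <- aug$mask
          }
          xb <- (xb - fit$norm["mean"]) / fit$norm["sd"]
          outs <- nn_forward(fit$model, xb)
          z <- outs[[fit$model$out_id]]
          pw <- config$pos_weight %||% 1
          loss <- bce_with_logits(z, yb, pw)
          if (!is.finite(loss)) {
            stop(sprintf("non-finite loss at stage %d epoch %d step %d", si, ep, step))
          }
          tl <- tl + loss
          dz <- bce_grad(z, yb, pw)
          grads <- nn_backward(fit$model, outs, dz)
          lrs <- rep_len(scheduled_lr(step, sched, steps_per_epoch), 3L)
          upd <- nn_sgd_step(fit$model, grads, state, lrs, momentum,
                             config$weight_decay, subset)
          fit$model <- upd$model; state <- upd$state
          step <- step + 1L
        }
        ev <- eval_segmenter(fit, vdat)
        epoch_global <- epoch_global + 1L
        history[[length(history) + 1L]] <- tibble::tibble(
          stage = si, epoch = epoch_global,
          train_loss = tl / steps_per_epoch,
          val_loss = ev$loss, val_dice = ev$dice,
          lr = rep_len(scheduled_lr(step, sched, steps_per_epoch), 3L)[3]
        )
        if (!quiet) {
          message(sprintf("stage %d epoch %d: train %.4f val %.4f dice %.4f",
                          si, epoch_global, tl / steps_per_epoch, ev$loss, ev$dice))
        }
        if (ev$dice > best$dice) best <- list(dice = ev$dice, model = fit$model)
      }
    }
  })
  fit$final_model <- fit$model
  fit$model <- best$model
  fit$history <- dplyr::bind_rows(history)
  fit$val_dice <- best$dice
  class(fit) <- c("segmenter", "seg_fit")
  fit
}

eval_segmenter <- function(fit, vdat, batch = 8L) {
  pw <- fit$config$pos_weight %||% 1
  n <- dim(vdat$x)[4]
  loss <- 0; dices <- numeric(n)
  done <- 0L
  while (done < n) {
    idx <- (done + 1L):min(done + batch, n)
    xb <- (vdat$x[, , , idx, drop = FALSE] - fit$norm["mean"]) / fit$norm["sd"]
    z <- nn_forward(fit$model, xb)[[fit$model$out_id]]
    yb <- vdat$y[, , , idx, drop = FALSE]
    loss <- loss + bce_with_logits(z, yb, pw) * length(idx)
    p <- sigmoid(z)
    for (j in seq_along(idx)) {
      dices[idx[j]] <- dice_coefficient(p[, , 1L, j] >= 0.5, yb[, , 1L, j] >= 0.5)
    }
    done <- done + length(idx)
  }
  list(loss = loss / n, dice = mean(dices))
}

#' Predict a per-pixel foreground probability mask
#'
#' @param fit A trained `seg_fit`.
#' @param image A `plate_image` whose side equals the model's input size
#'   (use [center_crop_resize()] first).
#' @return Numeric `(H, W)` matrix of probabilities in `[0, 1]` with the
#'   image's `plate_id` attribute.
#' @export
predict_mask <- function(fit, image) {
  s <- fit$input_size
  d <- dim(image)
  if (d[1] != s || d[2] != s) {
    stop(sprintf("image is %dx%d but the model was trained at %dx%d",
                 d[1], d[2], s, s))
  }
  x <- array((unclass(image) - fit$norm["mean"]) / fit$norm["sd"], c(s, s, 3L, 1L))
  z <- nn_forward(fit$model, x)[[fit$model$out_id]]
  p <- sigmoid(z[, , 1L, 1L])
  attr(p, "plate_id") <- plate_id_of(image)
  p
}

#' Threshold a probability mask into a binary mask
#'
#' A pixel is foreground iff its probability is `>= threshold` (inclusive).
#'
#' @param prob Numeric matrix in `[0, 1]`.
#' @param threshold Scalar strictly between 0 and 1 (default 0.5).
#' @return Logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single number strictly between 0 and 1")
  }
  prob >= threshold
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit %s> input %dpx", x$config$encoder, x$input_size))
  if (!is.null(x$history)) {
    cat(sprintf(", %d epochs, best val dice %.3f",
                nrow(x$history), max(x$history$val_dice)))
  } else {
    cat(" (untrained)")
  }
  cat("\n")
  invisible(x)
}
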