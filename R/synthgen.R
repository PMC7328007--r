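# Synthetic agar plates: round colonies of five phenotypes drawn on a plate
# disk, with pixel-exact masks and per-colony labels. The renderer is the
# package's source of training and evaluation data.

#' The five colony phenotype classes
#'
#' Fixed class order used everywhere (tie-breaking, confusion matrices,
#' manifests): white, red, pink, variegating, bad_segmentation. The fifth
#' class denotes merged/overlapping colony clusters that cannot be counted as
#' single colonies, not a colour.
#'
#' @return Character vector of the five labels.
#' @export
colony_phenotypes <- function() {
  c("white", "red", "pink", "variegating", "bad_segmentation")
}

#' Default per-class colour models
#'
#' Mean RGB (0-1 scale) and a multiplicative jitter SD per class. White
#' colonies are warm off-white, red colonies carry the vacuolar pigment of
#' adenine auxotrophs, pink is intermediate; variegating colonies alternate
#' white/red sectors, and bad-segmentation clusters borrow the single-colony
#' colours. Chosen to be separable yet confusable under pixel noise.
#'
#' @param jitter Multiplicative colour jitter SD.
#' @return Named list of colour models.
#' @export
synth_color_models <- function(jitter = 0.05) {
  list(
    white = list(mean = c(230, 225, 210) / 255, jitter = jitter),
    red = list(mean = c(170, 40, 40) / 255, jitter = jitter),
    pink = list(mean = c(220, 140, 150) / 255, jitter = jitter)
  )
}

#' Specification of a synthetic plate
#'
#' Parameterizes the generator: geometry, how many colonies, the class
#' mixture, colour models, noise and illumination, and whether a bright rim
#' ring is painted at the plate edge (an imaging artifact that exercises
#' border clearing downstream).
#'
#' @param image_size Square image side in px (default 512, desk scale;
#'   configurable up to full resolution).
#' @param plate_radius Plate disk radius in px; default `0.46 * image_size`;
#'   must be `< image_size / 2`.
#' @param n_colonies Number of colonies to place.
#' @param class_mixture Five nonnegative weights in class order (normalized
#'   internally).
#' @param color_models Per-class colour models, see [synth_color_models()].
#' @param colony_radius_frac Range of colony radii as fractions of
#'   `image_size`.
#' @param overlap_probability Probability that a colony may be placed without
#'   the usual separation margin.
#' @param noise_sd Additive Gaussian pixel noise SD (0-1 scale).
#' @param illumination_amplitude Relative amplitude of a linear illumination
#'   gradient across the plate.
#' @param edge_artifact Paint a bright rim ring at the plate edge (image
#'   only, never in the mask).
#' @param ring_probability Probability that a white colony shows the aged
#'   ring-like morphology (pinkish annulus around a white centre).
#' @param seed Default seed used by generators that take this spec.
#' @return A `synth_plate_spec` object.
#' @export
synth_plate_spec <- function(image_size = 512,
                             plate_radius = NULL,
                             n_colonies = 30,
                             class_mixture = c(white = 0.5, red = 0.2, pink = 0.15,
                                               variegating = 0.12, bad_segmentation = 0.03),
                             color_models = synth_color_models(),
                             colony_radius_frac = c(0.032, 0.05),
                             overlap_probability = 0,
                             noise_sd = 0.02,
                             illumination_amplitude = 0.06,
                             edge_artifact = TRUE,
                             ring_probability = 0.08,
                             seed = 0L) {
  image_size <- as.integer(image_size)
  plate_radius <- plate_radius %||% (0.46 * image_size)
  if (plate_radius >= image_size / 2) stop("`plate_radius` must be < image_size / 2")
  if (length(class_mixture) != 5L) stop("`class_mixture` needs five weights")
  if (any(class_mixture < 0) || sum(class_mixture) <= 0) {
    stop("`class_mixture` must be nonnegative with a positive sum")
  }
  class_mixture <- setNames(class_mixture / sum(class_mixture), colony_phenotypes())
  structure(
    list(
      image_size = image_size, plate_radius = plate_radius,
      n_colonies = n_colonies, class_mixture = class_mixture,
      color_models = color_models, colony_radius_frac = colony_radius_frac,
      overlap_probability = overlap_probability, noise_sd = noise_sd,
      illumination_amplitude = illumination_amplitude,
      edge_artifact = edge_artifact, ring_probability = ring_probability,
      agar_color = c(150, 125, 95) / 255,
      background_color = c(45, 45, 50) / 255,
      rim_color = c(235, 230, 220) / 255,
      seed = as.integer(seed)
    ),
    class = "synth_plate_spec"
  )
}

jitter_color <- function(mean, sd) clamp01(mean * exp(rnorm(3, 0, sd)))

#' Sample the appearance of one colony
#'
#' Draws a colony consistent with its phenotype: a single disk for white,
#' red and pink (white may carry a ring-like aged morphology); a disk with
#' at least two alternating white/red angular sectors for variegating; a
#' connected cluster of 2-4 overlapping disks for bad_segmentation.
#'
#' @param phenotype One of [colony_phenotypes()].
#' @param spec A [synth_plate_spec()].
#' @param seed Optional seed; when given the draw is reproducible in
#'   isolation, otherwise the current RNG stream is used.
#' @return A `colony_appearance` object (center, radius, base colour, sector
#'   pattern, ring morphology, sub-disks for clusters).
#' @export
sample_colony <- function(phenotype, spec, seed = NULL) {
  if (!phenotype %in% colony_phenotypes()) {
    stop(sprintf("unknown phenotype '%s'", phenotype))
  }
  draw <- function() sample_colony_impl(phenotype, spec)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

sample_colony_impl <- function(phenotype, spec) {
  cm <- spec$color_models
  radius <- runif(1, spec$colony_radius_frac[1], spec$colony_radius_frac[2]) *
    spec$image_size
  # uniform position inside the plate, clear of the rim
  rmax <- max(spec$plate_radius - radius - 2, 1)
  rho <- sqrt(runif(1)) * rmax
  ang <- runif(1, 0, 2 * pi)
  ctr <- (spec$image_size + 1) / 2 + rho * c(sin(ang), cos(ang))
  app <- list(
    center = ctr, radius = radius, phenotype = phenotype,
    base_color = NULL, sector_pattern = NULL,
    ring = list(flag = FALSE, color = NULL), subdisks = NULL
  )
  if (phenotype %in% c("white", "red", "pink")) {
    app$base_color <- jitter_color(cm[[phenotype]]$mean, cm[[phenotype]]$jitter)
    if (phenotype == "white" && runif(1) < spec$ring_probability) {
      app$ring <- list(
        flag = TRUE,
        color = jitter_color((cm$white$mean + cm$pink$mean) / 2, cm$white$jitter)
      )
    }
  } else if (phenotype == "variegating") {
    n_sec <- sample(3:6, 1)
    # a variegating colony by definition shows visible sectoring in both
    # colours: redraw until every sector subtends >= 0.35 rad and the two
    # alternating colours each hold 25-75% of the circumference
    bounds <- NULL
    first <- sample(c("white", "red"), 1)
    for (try in 1:100) {
      cand <- sort(runif(n_sec, 0, 2 * pi))
      gaps <- diff(c(cand, cand[1] + 2 * pi))
      share1 <- sum(gaps[seq(1, n_sec, 2)]) / (2 * pi)
      if (min(gaps) >= 0.35 && share1 >= 0.25 && share1 <= 0.75) {
        bounds <- cand
        break
      }
    }
    if (is.null(bounds)) {
      bounds <- sort((seq_len(n_sec) - 1) * 2 * pi / n_sec +
                       runif(1, 0, 2 * pi / n_sec)) %% (2 * pi)
      bounds <- sort(bounds)
    }
    cols <- matrix(0, n_sec, 3)
    pal <- if (first == "white") c("white", "red") else c("red", "white")
    for (i in seq_len(n_sec)) {
      who <- pal[(i - 1) %% 2 + 1]
      cols[i, ] <- jitter_color(cm[[who]]$mean, cm[[who]]$jitter)
    }
    app$base_color <- cols[1, ]
    app$sector_pattern <- tibble::tibble(
      start = bounds,
      end = c(bounds[-1], bounds[1] + 2 * pi),
      R = cols[, 1], G = cols[, 2], B = cols[, 3]
    )
  } else { # bad_segmentation: connected cluster of small overlapping disks
    n_sub <- sample(2:4, 1)
    subs <- vector("list", n_sub)
    r1 <- radius * runif(1, 0.45, 0.65)
    who <- sample(c("white", "red", "pink"), n_sub, replace = TRUE)
    subs[[1]] <- list(center = ctr, radius = r1,
                      color = jitter_color(cm[[who[1]]]$mean, cm[[who[1]]]$jitter))
    for (j in seq_len(n_sub)[-1]) {
      base <- subs[[sample(j - 1L, 1)]]
      rj <- radius * runif(1, 0.4, 0.6)
      d <- runif(1, 0.55, 0.85) * (base$radius + rj)
      a <- runif(1, 0, 2 * pi)
      cj <- base$center + d * c(sin(a), cos(a))
      subs[[j]] <- list(center = cj, radius = rj,
                        color = jitter_color(cm[[who[j]]]$mean, cm[[who[j]]]$jitter))
    }
    app$base_color <- subs[[1]]$color
    app$subdisks <- subs
  }
  structure(app, class = "colony_appearance")
}

# full extent of a colony from its center (covers sub-disks)
colony_extent <- function(app) {
  if (is.null(app$subdisks)) return(app$radius)
  max(vapply(app$subdisks, function(s) {
    sqrt(sum((s$center - app$center)^2)) + s$radius
  }, numeric(1)))
}

# paint one colony onto the image; returns the updated image and the linear
# pixel indices of the colony's footprint
paint_colony <- function(img, app) {
  h <- dim(img)[1]; w <- dim(img)[2]
  disks <- app$subdisks %||% list(list(center = app$center, radius = app$radius,
                                       color = app$base_color))
  hit_all <- integer(0)
  for (dsk in disks) {
    r0 <- max(1L, floor(dsk$center[1] - dsk$radius))
    r1 <- min(h, ceiling(dsk$center[1] + dsk$radius))
    c0 <- max(1L, floor(dsk$center[2] - dsk$radius))
    c1 <- min(w, ceiling(dsk$center[2] + dsk$radius))
    if (r0 > r1 || c0 > c1) next
    rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L) - dsk$center[1]
    cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE) - dsk$center[2]
    d2 <- rr^2 + cc^2
    inside <- d2 <= dsk$radius^2
    if (!any(inside)) next
    lin <- (rep(c0:c1 - 1L, each = r1 - r0 + 1L)) * h + rep(r0:r1, c1 - c0 + 1L)
    lin <- lin[inside]
    if (!is.null(app$sector_pattern)) {
      a <- (atan2(rr, cc) %% (2 * pi))[inside]
      sp <- app$sector_pattern
      # map angle into [start_1, start_1 + 2pi) then locate its sector
      a2 <- sp$start[1] + (a - sp$start[1]) %% (2 * pi)
      si <- findInterval(a2, sp$start)
      for (ch in 1:3) {
        img[lin + (ch - 1L) * h * w] <- c(sp$R, sp$G, sp$B)[(ch - 1L) * nrow(sp) + si]
      }
    } else if (isTRUE(app$ring$flag)) {
      ring <- d2[inside] > (0.62 * dsk$radius)^2
      for (ch in 1:3) {
        img[lin + (ch - 1L) * h * w] <-
          ifelse(ring, app$ring$color[ch], dsk$color[ch])
      }
    } else {
      for (ch in 1:3) img[lin + (ch - 1L) * h * w] <- dsk$color[ch]
    }
    hit_all <- c(hit_all, lin)
  }
  list(img = img, footprint = unique(hit_all))
}

#' Render a synthetic plate with ground truth
#'
#' Places `spec$n_colonies` colonies (phenotypes drawn from the class
#' mixture) inside the plate disk, paints them over an agar-coloured plate on
#' a dark background, applies an illumination gradient and pixel noise, and
#' optionally a bright rim ring at the plate edge. Colonies are separated
#' unless `overlap_probability` allows contact; placement errors out after
#' bounded retries when the plate is too crowded.
#'
#' @param spec A [synth_plate_spec()].
#' @param seed Seed for this plate (default `spec$seed`).
#' @param plate_id Identifier stored on the image.
#' @return A list with `image` (a `plate_image`) and `ground_truth`: the
#'   pixel-exact logical `mask`, a `colonies` tibble (one row per colony with
#'   phenotype and geometry), and `true_nonwhite_pct` = 100 x (red + pink +
#'   variegating) / (colonies excluding bad_segmentation), `NA` with
#'   `undefined = TRUE` when no properly-countable colony exists.
#' @export
render_plate <- function(spec, seed = spec$seed, plate_id = "synthetic_plate") {
  stopifnot(inherits(spec, "synth_plate_spec"))
  with_seed(seed, render_plate_impl(spec, plate_id))
}

render_plate_impl <- function(spec, plate_id) {
  n <- spec$n_colonies
  size <- spec$image_size
  img <- array(rep(spec$background_color, each = size * size), c(size, size, 3))
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size) - ctr
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  d2 <- rr^2 + cc^2
  plate_px <- d2 <= spec$plate_radius^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[plate_px] <- spec$agar_color[ch]
    img[, , ch] <- plane
  }

  phenos <- if (n > 0) {
    sample(colony_phenotypes(), n, replace = TRUE, prob = spec$class_mixture)
  } else {
    character(0)
  }
  # sequential placement can jam on a crowded plate even when a valid layout
  # exists, so a failed colony triggers a bounded restart of the whole layout
  apps <- NULL
  for (attempt in seq_len(25L)) {
    apps <- vector("list", n)
    placed_ctr <- matrix(0, 0, 2)
    placed_ext <- numeric(0)
    jammed_at <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        cand <- sample_colony_impl(phenos[i], spec)
        ext <- colony_extent(cand)
        allow_overlap <- runif(1) < spec$overlap_probability
        if (nrow(placed_ctr) == 0 || allow_overlap) { ok <- TRUE } else {
          dd <- sqrt((placed_ctr[, 1] - cand$center[1])^2 +
                       (placed_ctr[, 2] - cand$center[2])^2)
          ok <- all(dd >= placed_ext + ext + 2)
        }
        if (ok) break
      }
      if (!ok) { jammed_at <- i; break }
      apps[[i]] <- cand
      placed_ctr <- rbind(placed_ctr, cand$center)
      placed_ext <- c(placed_ext, ext)
    }
    if (jammed_at == 0L) break
    apps <- NULL
  }
  if (is.null(apps) && n > 0) {
    stop(sprintf(
      "could not place %d colonies within the overlap budget (200 retries per colony, 25 layout restarts)",
      n
    ))
  }
  if (n == 0) apps <- list()

  mask <- matrix(FALSE, size, size)
  for (i in seq_len(n)) {
    p <- paint_colony(img, apps[[i]])
    img <- p$img
    mask[p$footprint] <- TRUE
  }

  if (isTRUE(spec$edge_artifact)) {
    rim <- d2 > (spec$plate_radius - 1.5)^2 & d2 <= (spec$plate_radius + 1.5)^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[rim] <- spec$rim_color[ch]
      img[, , ch] <- plane
    }
  }

  phi <- runif(1, 0, 2 * pi)
  grad <- 1 + spec$illumination_amplitude * (cos(phi) * cc + sin(phi) * rr) / size
  for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  img <- clamp01(img)

  colonies <- tibble::tibble(
    colony_id = seq_len(n),
    phenotype = phenos,
    center_row = vapply(apps, function(a) a$center[1], numeric(1)),
    center_col = vapply(apps, function(a) a$center[2], numeric(1)),
    radius = vapply(apps, function(a) a$radius, numeric(1))
  )
  list(
    image = new_plate_image(img, plate_id),
    ground_truth = new_ground_truth(mask, colonies)
  )
}

new_ground_truth <- function(mask, colonies) {
  cnt <- table(factor(colonies$phenotype, levels = colony_phenotypes()))
  denom <- sum(cnt) - cnt[["bad_segmentation"]]
  num <- cnt[["red"]] + cnt[["pink"]] + cnt[["variegating"]]
  structure(
    list(
      mask = mask, colonies = colonies,
      class_counts = as.integer(cnt),
      true_nonwhite_pct = if (denom > 0) 100 * num / denom else NA_real_,
      undefined = denom == 0
    ),
    class = "ground_truth"
  )
}

# Largest-remainder apportionment of `total` into counts proportional to
# `weights`; ties broken in class order. Reproduces stratified splits that
# preserve class proportions exactly.
largest_remainder <- function(weights, total) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- quota - base
  add <- total - sum(base)
  if (add > 0) {
    ord <- order(-rem, seq_along(weights))
    base[ord[seq_len(add)]] <- base[ord[seq_len(add)]] + 1
  }
  as.integer(base)
}

#' Generate a dataset of synthetic plates on disk
#'
#' Writes `n_plates` JPEG plate images with pixel-aligned PNG masks plus a
#' CSV manifest (paths relative to `out_dir`); roughly 20% of plates (largest
#' remainder of 0.2) are flagged as the validation split. Each plate draws
#' its own seed from `seed` by counter, so outputs are order-independent and
#' two runs with the same arguments are byte-identical.
#'
#' @param spec A [synth_plate_spec()].
#' @param n_plates Number of plates.
#' @param out_dir Writable output directory (created if missing).
#' @param seed Dataset seed (default `spec$seed`).
#' @param class_mixtures Optional `n_plates` x 5 matrix of per-plate class
#'   mixtures overriding `spec$class_mixture`, for datasets spanning a range
#'   of true non-white percentages.
#' @return The manifest tibble (also written to `out_dir/manifest.csv`) with
#'   columns plate_id, image_path, mask_path, split, n_white, n_red, n_pink,
#'   n_variegating, n_bad, true_nonwhite_pct.
#' @export
generate_plate_dataset <- function(spec, n_plates, out_dir, seed = spec$seed,
                                   class_mixtures = NULL) {
  stopifnot(inherits(spec, "synth_plate_spec"), n_plates >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  seeds <- derive_seeds(seed, n_plates)
  n_val <- round(0.2 * n_plates)
  rows <- vector("list", n_plates)
  for (i in seq_len(n_plates)) {
    sp <- spec
    if (!is.null(class_mixtures)) {
      sp$class_mixture <- setNames(
        class_mixtures[i, ] / sum(class_mixtures[i, ]), colony_phenotypes()
      )
    }
    pid <- sprintf("plate_%04d", i)
    r <- render_plate(sp, seed = seeds[i], plate_id = pid)
    img_rel <- file.path("images", paste0(pid, ".jpg"))
    msk_rel <- file.path("masks", paste0(pid, ".png"))
    write_plate_image(r$image, file.path(out_dir, img_rel))
    write_mask(r$ground_truth$mask, file.path(out_dir, msk_rel))
    cnt <- r$ground_truth$class_counts
    rows[[i]] <- tibble::tibble(
      plate_id = pid, image_path = img_rel, mask_path = msk_rel,
      split = if (i > n_plates - n_val) "valid" else "train",
      n_white = cnt[1], n_red = cnt[2], n_pink = cnt[3],
      n_variegating = cnt[4], n_bad = cnt[5],
      true_nonwhite_pct = r$ground_truth$true_nonwhite_pct
    )
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Generate a labelled dataset of single-colony crops on disk
#'
#' Emulates the crops the prediction pipeline produces: one colony (or, for
#' bad_segmentation, an overlapping cluster) on an agar-coloured patch with
#' noise and brightness variation, saved as JPEG with a CSV label manifest.
#' Class counts follow `class_proportions` by largest remainder, and the
#' ~20% validation split is stratified so each class keeps the same
#' proportions as the full pool.
#'
#' @param spec A [synth_plate_spec()] (colour models, noise, radii reused).
#' @param n_crops Total number of crops.
#' @param class_proportions Five nonnegative weights in class order.
#' @param out_dir Writable output directory.
#' @param seed Dataset seed (default `spec$seed`).
#' @return Manifest tibble (also `out_dir/labels.csv`) with columns
#'   crop_path, label, split.
#' @export
generate_crop_dataset <- function(spec, n_crops, class_proportions, out_dir,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "synth_plate_spec"), n_crops >= 1)
  if (length(class_proportions) != 5L || any(class_proportions < 0) ||
      sum(class_proportions) <= 0) {
    stop("`class_proportions` must be five nonnegative weights, not all zero")
  }
  dir.create(file.path(out_dir, "crops"), recursive = TRUE, showWarnings = FALSE)
  counts <- largest_remainder(class_proportions, n_crops)
  dropped <- class_proportions > 0 & counts == 0
  if (any(dropped)) {
    warning(sprintf(
      "class(es) %s have positive weight but zero crops at n = %d; dropped from split stratification",
      paste(colony_phenotypes()[dropped], collapse = ", "), n_crops
    ))
  }
  labels <- rep(colony_phenotypes(), counts)
  seeds <- derive_seeds(seed, n_crops)
  # stratified validation: per-class largest-remainder share of round(0.2 n)
  n_val <- round(0.2 * n_crops)
  val_per_class <- if (n_val > 0) largest_remainder(counts, n_val) else integer(5)
  split <- character(n_crops)
  for (k in seq_len(5L)) {
    idx <- which(labels == colony_phenotypes()[k])
    split[idx] <- "train"
    if (val_per_class[k] > 0) split[tail(idx, val_per_class[k])] <- "valid"
  }
  rows <- vector("list", n_crops)
  for (i in seq_len(n_crops)) {
    crop <- with_seed(seeds[i], render_crop_impl(labels[i], spec))
    rel <- file.path("crops", sprintf("crop_%05d.jpg", i))
    write_plate_image(crop, file.path(out_dir, rel))
    rows[[i]] <- tibble::tibble(crop_path = rel, label = labels[i], split = split[i])
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "labels.csv"))
  manifest
}

# one colony on an agar patch, cropped like the pipeline crops colonies:
# footprint bbox plus ~10% padding, with noise and a brightness wobble
render_crop_impl <- function(label, spec) {
  size <- spec$image_size
  app <- sample_colony_impl(label, spec)
  ext <- colony_extent(app)
  pad <- 0.12 * 2 * ext
  side <- max(8L, ceiling(2 * ext + 2 * pad))
  # re-centre the colony in its own patch, with a small random offset
  off <- runif(2, -0.08, 0.08) * side
  shift <- (side + 1) / 2 + off - app$center
  app$center <- app$center + shift
  if (!is.null(app$subdisks)) {
    app$subdisks <- lapply(app$subdisks, function(s) {
      s$center <- s$center + shift
      s
    })
  }
  img <- array(rep(spec$agar_color, each = side * side), c(side, side, 3))
  img <- paint_colony(img, app)$img
  img <- img * runif(1, 1 - spec$illumination_amplitude, 1 + spec$illumination_amplitude)
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  new_plate_image(clamp01(img), plate_id = "synthetic_crop")
}

#' @export
print.synth_plate_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_plate_spec> %dpx plate (radius %.1f), %s colonies, mixture [%s]\n",
    x$image_size, x$plate_radius, x$n_colonies,
    paste(signif(x$class_mixture, 2), collapse = ", ")
  ))
  invisible(x)
}
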