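test_that("sampled colonies are consistent with their phenotype", {
  spec <- tiny_plate_spec(size = 128, seed = 0)

  w <- sample_colony("white", spec, seed = 0)
  expect_null(w$sector_pattern)
  expect_null(w$subdisks)
  expect_gt(w$radius, 0)
  expect_true(all(w$base_color > 0.6))  # light base colour

  v <- sample_colony("variegating", spec, seed = 0)
  expect_gte(nrow(v$sector_pattern), 2)
  cols <- unique(round(cbind(v$sector_pattern$R, v$sector_pattern$G,
                             v$sector_pattern$B), 4))
  expect_gte(nrow(cols), 2)  # at least two distinct colours

  b <- sample_colony("bad_segmentation", spec, seed = 0)
  expect_gte(length(b$subdisks), 2)

  expect_error(sample_colony("chartreuse", spec), "chartreuse")
})

test_that("colony sampling is deterministic under a seed", {
  spec <- tiny_plate_spec(seed = 0)
  for (ph in colony_phenotypes()) {
    a <- sample_colony(ph, spec, seed = 7)
    b <- sample_colony(ph, spec, seed = 7)
    expect_identical(a, b)
  }
})

test_that("rendered plates honour geometry, mixture and ground truth", {
  # empty plate
  spec0 <- synth_plate_spec(image_size = 64, n_colonies = 0, seed = 1)
  r0 <- render_plate(spec0)
  expect_false(any(r0$ground_truth$mask))
  expect_true(r0$ground_truth$undefined)
  expect_true(is.na(r0$ground_truth$true_nonwhite_pct))

  # 10 disjoint colonies -> exactly 10 connected components
  spec10 <- synth_plate_spec(image_size = 128, n_colonies = 10,
                             overlap_probability = 0, seed = 2,
                             class_mixture = c(1, 1, 1, 0, 0))
  r10 <- render_plate(spec10, seed = 2)
  regs <- label_regions(r10$ground_truth$mask)
  expect_equal(nrow(regs), 10)
  expect_equal(sum(regs$area), sum(r10$ground_truth$mask))

  # white-only mixture -> 0% non-white
  specw <- synth_plate_spec(image_size = 96, n_colonies = 8, seed = 3,
                            class_mixture = c(1, 0, 0, 0, 0))
  rw <- render_plate(specw)
  expect_equal(rw$ground_truth$true_nonwhite_pct, 0)

  # determinism
  ra <- render_plate(spec10, seed = 11)
  rb <- render_plate(spec10, seed = 11)
  expect_identical(unclass(ra$image), unclass(rb$image))
  expect_identical(ra$ground_truth$mask, rb$ground_truth$mask)

  # image contract
  expect_equal(dim(ra$image), c(128, 128, 3))
  expect_true(all(ra$image >= 0 & ra$image <= 1))
})

test_that("the rim artifact paints bright foreground-like pixels outside the mask", {
  spec <- synth_plate_spec(image_size = 96, n_colonies = 0, seed = 5,
                           edge_artifact = TRUE, noise_sd = 0)
  r <- render_plate(spec, seed = 5)
  ctr <- (96 + 1) / 2
  rim_px <- round(c(ctr, ctr + spec$plate_radius))  # a pixel on the rim ring
  expect_gt(mean(unclass(r$image)[rim_px[1], rim_px[2], ]), 0.8)
  expect_false(any(r$ground_truth$mask))  # never in the mask
})

test_that("non-white percentage matches a brute-force recount", {
  spec <- synth_plate_spec(image_size = 128, n_colonies = 25, seed = 4)
  for (s in 1:5) {
    r <- render_plate(spec, seed = s)
    ph <- r$ground_truth$colonies$phenotype
    nb <- sum(ph == "bad_segmentation")
    expected <- 100 * sum(ph %in% c("red", "pink", "variegating")) /
      (length(ph) - nb)
    expect_equal(r$ground_truth$true_nonwhite_pct, expected)
  }
})

test_that("every non-bad colony footprint is foreground in the mask", {
  spec <- synth_plate_spec(image_size = 128, n_colonies = 15, seed = 6)
  r <- render_plate(spec, seed = 6)
  cols <- r$ground_truth$colonies
  for (i in seq_len(nrow(cols))) {
    # sample the colony's central pixel and a mid-radius pixel
    rr <- round(cols$center_row[i]); cc <- round(cols$center_col[i])
    expect_true(r$ground_truth$mask[rr, cc],
                label = sprintf("colony %d centre in mask", i))
  }
})

test_that("class mixture is recovered over many sampled colonies", {
  mixture <- c(0.4, 0.25, 0.15, 0.15, 0.05)
  spec <- synth_plate_spec(image_size = 96, n_colonies = 24,
                           class_mixture = mixture, seed = 8)
  phenos <- character(0)
  for (s in 1:50) {
    r <- render_plate(spec, seed = 1000 + s)
    phenos <- c(phenos, r$ground_truth$colonies$phenotype)
  }
  n <- length(phenos)
  expect_gte(n, 1000)
  freq <- table(factor(phenos, levels = colony_phenotypes())) / n
  se <- sqrt(mixture * (1 - mixture) / n)
  expect_true(all(abs(as.numeric(freq) - mixture) <= 3 * se))
})

test_that("overcrowded plates error after bounded retries", {
  spec <- synth_plate_spec(image_size = 64, n_colonies = 500, seed = 9)
  expect_error(render_plate(spec), "retries")
})

test_that("plate datasets are deterministic with a ~20% validation split", {
  spec <- tiny_plate_spec(size = 64, n_colonies = 5, seed = 0)
  d1 <- fixture_dir("det1"); d2 <- fixture_dir("det2")
  m1 <- generate_plate_dataset(spec, 10, d1, seed = 3)
  m2 <- generate_plate_dataset(spec, 10, d2, seed = 3)
  expect_equal(sum(m1$split == "valid"), 2)
  expect_identical(m1[setdiff(names(m1), c("image_path", "mask_path"))],
                   m2[setdiff(names(m2), c("image_path", "mask_path"))])
  for (f in c(m1$image_path, m1$mask_path, "manifest.csv")) {
    expect_identical(file_md5(file.path(d1, f)), file_md5(file.path(d2, f)),
                     label = paste("byte-identical", f))
  }
  # manifest counts are a conservation of rendered colonies
  counts <- m1$n_white + m1$n_red + m1$n_pink + m1$n_variegating + m1$n_bad
  expect_true(all(counts == 5))
  # masks on disk match foreground convention (0/255 single channel)
  msk <- read_mask(file.path(d1, m1$mask_path[1]))
  expect_type(msk, "logical")
})

test_that("100-plate datasets flag 20 plates as validation", {
  spec <- synth_plate_spec(image_size = 48, n_colonies = 2, seed = 0,
                           edge_artifact = FALSE)
  man <- generate_plate_dataset(spec, 100, fixture_dir("val100"), seed = 1)
  expect_equal(sum(man$split == "valid"), 20)
})

test_that("crop datasets honour exact class counts and stratified split", {
  t1 <- t1_fixture()
  man <- t1$manifest
  counts <- table(factor(man$label, levels = colony_phenotypes()))
  expect_equal(as.integer(counts), c(537, 273, 310, 318, 38))
  expect_equal(sum(man$split == "valid"), 295)
  # split preserves class proportions as closely as integers allow
  vc <- table(factor(man$label[man$split == "valid"],
                     levels = colony_phenotypes()))
  expect_true(all(abs(as.integer(vc) - 0.2 * as.integer(counts)) <= 1))
})

test_that("single-class and degenerate crop requests behave", {
  spec <- tiny_plate_spec(size = 64, seed = 0)
  man <- generate_crop_dataset(spec, 10, c(1, 0, 0, 0, 0),
                               fixture_dir("whitecrops"), seed = 1)
  expect_equal(nrow(man), 10)
  expect_true(all(man$label == "white"))
  expect_warning(
    generate_crop_dataset(spec, 10, c(1, 0, 0, 0, 1e-4),
                          fixture_dir("dropclass"), seed = 1),
    "dropped"
  )
  expect_error(
    generate_crop_dataset(spec, 10, c(0, 0, 0, 0, 0), fixture_dir("zeroprop")),
    "nonnegative"
  )
})
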