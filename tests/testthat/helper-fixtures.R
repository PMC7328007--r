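# Shared fixtures. Heavy artifacts (trained desk models and their datasets)
# are built once per test session and cached; light fixtures are cheap
# constructors.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dir <- function(name) {
  d <- file.path(tempdir(), "platepheno-fixtures", name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# fast config for tests that only need *a* trained segmenter, not a good one
tiny_seg_config <- function(seed = 42L, epochs_down = 6) {
  seg_config(
    "desk",
    image_size = 64L, batch_size = 2L, seed = seed,
    stages = list(
      list(image_size = 64L, last_layer_only = TRUE,
           schedule = lr_schedule("circular", max_lr = 4e-2, min_lr = 8e-3,
                                  epochs_up = 0.5, epochs_down = 0.5)),
      list(image_size = 64L, last_layer_only = FALSE,
           schedule = lr_schedule("circular", max_lr = 0.08, min_lr = 0.004,
                                  epochs_up = 1, epochs_down = epochs_down))
    )
  )
}

tiny_clf_config <- function(seed = 42L) {
  clf_config(
    "desk",
    input_size = 24L, batch_size = 32L, seed = seed,
    head_schedule = lr_schedule("cosine_anneal", max_lr = 1e-2,
                                cycle_lengths = 1),
    main_schedule = lr_schedule("cosine_anneal",
                                max_lr = c(0.015, 0.015, 0.03),
                                cycle_lengths = c(1, 2))
  )
}

tiny_plate_spec <- function(size = 64L, n_colonies = 6L, seed = 0L) {
  # proportionally larger colonies: at 64 px the full-scale radius fraction
  # gives 2-px colonies, too small to exercise anything
  synth_plate_spec(image_size = size, n_colonies = n_colonies, seed = seed,
                   colony_radius_frac = c(0.055, 0.085))
}

tiny_plate_dataset <- function(n_plates = 12L, seed = 5L) {
  key <- sprintf("plates_%d_%d", n_plates, seed)
  if (!exists(key, .fixture_cache)) {
    d <- fixture_dir(key)
    man <- generate_plate_dataset(tiny_plate_spec(seed = seed), n_plates, d,
                                  seed = seed)
    assign(key, list(dir = d, manifest = man), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# --- acceptance-scale fixtures (built once, reused by several test files) ---

# classifier analog at the published class counts: 1476 crops
# (537/273/310/318/38), stratified 295-crop validation split, desk training
t1_fixture <- function() {
  if (!exists("t1", .fixture_cache)) {
    d <- fixture_dir("t1_crops")
    spec <- synth_plate_spec(seed = 0L)
    man <- generate_crop_dataset(spec, 1476L, c(537, 273, 310, 318, 38), d,
                                 seed = 0L)
    fit <- train_classifier(file.path(d, "labels.csv"), clf_config("desk", seed = 0L))
    va <- man[man$split == "valid", ]
    preds <- classify_crops(fit, as.list(file.path(d, va$crop_path)),
                            tta = FALSE, seed = 0L)
    ev <- evaluate_classifier(va$label, preds$label)
    assign("t1", list(dir = d, manifest = man, fit = fit, valid = va,
                      predictions = preds, eval = ev), .fixture_cache)
  }
  get("t1", .fixture_cache)
}

# end-to-end recovery fixture: desk segmenter + 128-px-scale classifier +
# 20 test plates spanning 0-100% true non-white
t3_fixture <- function() {
  if (!exists("t3", .fixture_cache)) {
    spec128 <- synth_plate_spec(image_size = 128L, n_colonies = 30L, seed = 1L)

    seg_dir <- fixture_dir("t3_seg_train")
    generate_plate_dataset(spec128, 60L, seg_dir, seed = 2L)
    seg <- train_segmenter(file.path(seg_dir, "manifest.csv"),
                           seg_config("desk", seed = 0L))

    clf_dir <- fixture_dir("t3_crops")
    generate_crop_dataset(spec128, 1000L, c(537, 273, 310, 318, 38), clf_dir,
                          seed = 3L)
    clf <- train_classifier(file.path(clf_dir, "labels.csv"),
                            clf_config("desk", seed = 0L))

    test_dir <- fixture_dir("t3_plates")
    f <- (seq_len(20) - 0.5) / 20
    mix <- cbind(white = 1 - f, red = f * 0.45, pink = f * 0.35,
                 variegating = f * 0.2, bad_segmentation = 0.03)
    tman <- generate_plate_dataset(spec128, 20L, test_dir, seed = 1L,
                                   class_mixtures = mix)
    res <- run_pipeline(file.path(test_dir, "images"), seg, clf,
                        tta = TRUE, seed = 0L)
    cmp <- compare_to_truth(res$report, tman)
    assign("t3", list(seg = seg, clf = clf, plates_dir = test_dir,
                      truth = tman, result = res, comparison = cmp),
           .fixture_cache)
  }
  get("t3", .fixture_cache)
}

cli_script <- function() {
  p <- system.file("cli", "platepheno.R", package = "platepheno")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli_script(), ...), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0) stop("CLI failed: ", paste(out, collapse = "\n"))
  out
}

file_md5 <- function(path) as.character(tools::md5sum(path))

with_seed_test <- function(seed, code) platepheno:::with_seed(seed, code)

`%||%` <- function(x, y) if (is.null(x)) y else x
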