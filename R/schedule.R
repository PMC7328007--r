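#' Cyclical learning-rate schedule specification
#'
#' Two kinds of schedule drive training, following common SGDR practice:
#'
#' * `"circular"`: within each cycle the rate rises piecewise-linearly from
#'   `min_lr` to `max_lr` over `epochs_up` epochs, then falls back to
#'   `min_lr` over `epochs_down` epochs; `cycles` cycles are run.
#' * `"cosine_anneal"`: each cycle starts at `max_lr` and follows a half
#'   cosine down to `min_lr`; cycle lengths in epochs are given by
#'   `cycle_lengths` (so warm restarts with growing cycles, e.g.
#'   `rep(c(1, 2, 4), 17)`, are expressed directly).
#'
#' `max_lr`/`min_lr` may be vectors (one entry per layer group) to express
#' differential learning rates; they must have equal length and satisfy
#' `min_lr <= max_lr` elementwise.
#'
#' @param kind `"circular"` or `"cosine_anneal"`.
#' @param max_lr,min_lr Numeric vectors of per-layer-group rates.
#' @param epochs_up,epochs_down Rising/falling phase lengths in epochs
#'   (circular kind; fractions allowed).
#' @param cycles Number of cycles (circular kind).
#' @param cycle_lengths Integer/numeric vector of per-cycle epoch counts
#'   (cosine kind).
#' @return An `lr_schedule` object.
#' @examples
#' sched <- lr_schedule("circular", max_lr = 4e-2, min_lr = 8e-3,
#'                      epochs_up = 1, epochs_down = 7)
#' scheduled_lr(0, sched, steps_per_epoch = 10)     # 8e-3 at cycle start
#' scheduled_lr(10, sched, steps_per_epoch = 10)    # 4e-2 at the phase boundary
#' @export
lr_schedule <- function(kind = c("circular", "cosine_anneal"),
                        max_lr, min_lr = 0,
                        epochs_up = NULL, epochs_down = NULL, cycles = 1L,
                        cycle_lengths = NULL) {
  kind <- match.arg(kind)
  max_lr <- as.numeric(max_lr)
  min_lr <- rep_len(as.numeric(min_lr), length(max_lr))
  if (any(min_lr > max_lr)) stop("`min_lr` must be <= `max_lr` elementwise")
  if (kind == "circular") {
    if (is.null(epochs_up) || is.null(epochs_down)) {
      stop("circular schedules need `epochs_up` and `epochs_down`")
    }
    if (epochs_up + epochs_down <= 0) stop("epochs_up + epochs_down must be > 0")
    total <- (epochs_up + epochs_down) * cycles
  } else {
    if (is.null(cycle_lengths)) stop("cosine_anneal schedules need `cycle_lengths`")
    if (any(cycle_lengths <= 0)) stop("cycle lengths must be positive")
    total <- sum(cycle_lengths)
  }
  structure(
    list(kind = kind, max_lr = max_lr, min_lr = min_lr,
         epochs_up = epochs_up, epochs_down = epochs_down,
         cycles = as.integer(cycles), cycle_lengths = cycle_lengths,
         total_epochs = total),
    class = "lr_schedule"
  )
}

#' Learning rates at a given training step
#'
#' Maps a 0-based global step index onto the schedule. Steps run from 0 to
#' `total_epochs * steps_per_epoch`; the endpoint itself may be queried (it
#' returns the cycle-end rate) but a step beyond it signals a bookkeeping bug
#' in the training loop and errors.
#'
#' @param step 0-based global step index.
#' @param schedule An [lr_schedule()].
#' @param steps_per_epoch Batches per epoch (> 0).
#' @return Numeric vector of learning rates, one per layer group entry of
#'   `max_lr`.
#' @export
scheduled_lr <- function(step, schedule, steps_per_epoch) {
  stopifnot(inherits(schedule, "lr_schedule"), steps_per_epoch > 0)
  total_steps <- schedule$total_epochs * steps_per_epoch
  if (step < 0 || step > total_steps + 1e-9) {
    stop(sprintf("step %s is beyond the schedule (total %s steps)",
                 format(step), format(total_steps)))
  }
  t <- step / steps_per_epoch  # epochs elapsed
  if (schedule$kind == "circular") {
    clen <- schedule$epochs_up + schedule$epochs_down
    tc <- if (t >= schedule$total_epochs) clen else t %% clen
    up <- schedule$epochs_up
    frac <- if (tc <= up) {
      if (up == 0) 1 else tc / up
    } else {
      1 - (tc - up) / schedule$epochs_down
    }
    schedule$min_lr + (schedule$max_lr - schedule$min_lr) * frac
  } else {
    ends <- cumsum(schedule$cycle_lengths)
    if (t >= schedule$total_epochs) return(schedule$min_lr)
    ci <- which(t < ends)[1]
    start <- if (ci == 1L) 0 else ends[ci - 1L]
    pos <- (t - start) / schedule$cycle_lengths[ci]
    schedule$min_lr + (schedule$max_lr - schedule$min_lr) * (1 + cos(pi * pos)) / 2
  }
}

#' Enumerate the cycles of a schedule
#'
#' @param schedule An [lr_schedule()].
#' @return A tibble with columns `cycle` and `epochs`; `sum(epochs)` is the
#'   total scheduled epoch count.
#' @export
schedule_cycles <- function(schedule) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (schedule$kind == "circular") {
    tibble::tibble(
      cycle = seq_len(schedule$cycles),
      epochs = rep(schedule$epochs_up + schedule$epochs_down, schedule$cycles)
    )
  } else {
    tibble::tibble(
      cycle = seq_along(schedule$cycle_lengths),
      epochs = as.numeric(schedule$cycle_lengths)
    )
  }
}

#' @export
print.lr_schedule <- function(x, ...) {
  cat(sprintf(
    "<lr_schedule %s> %s cycle(s), %g epochs total, max_lr [%s], min_lr [%s]\n",
    x$kind,
    if (x$kind == "circular") x$cycles else length(x$cycle_lengths),
    x$total_epochs,
    paste(signif(x$max_lr, 3), collapse = ", "),
    paste(signif(x$min_lr, 3), collapse = ", ")
  ))
  invisible(x)
}
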