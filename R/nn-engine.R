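# A small feed-forward CNN engine: static computation graph over batched
# arrays (H, W, C, B), convolutions as im2col + BLAS GEMM, exact backprop.
# Supports plain stacks, U-net style concat skips and residual adds, which is
# all the architectures in this package need. Everything is double precision
# and deterministic given the seed used at initialization.

nn_graph <- function(input_shape) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list(list(op = "input", from = integer(), shape = input_shape))
  g
}

nn_shape <- function(g, id) {
  id <- as.integer(id)  # force: `id` may be a builder call that mutates g
  g$nodes[[id]]$shape
}

nn_push <- function(g, node) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

nn_conv <- function(g, from, cout, k = 3L, stride = 1L) {
  s <- nn_shape(g, from)
  p <- (k - 1L) %/% 2L
  ho <- (s[1] + 2L * p - k) %/% stride + 1L
  wo <- (s[2] + 2L * p - k) %/% stride + 1L
  nn_push(g, list(
    op = "conv", from = from, k = as.integer(k), stride = as.integer(stride),
    cin = s[3], cout = as.integer(cout), shape = c(ho, wo, as.integer(cout))
  ))
}

nn_relu <- function(g, from) {
  nn_push(g, list(op = "relu", from = from, shape = nn_shape(g, from)))
}

nn_pool <- function(g, from) {
  s <- nn_shape(g, from)
  stopifnot(s[1] %% 2L == 0L, s[2] %% 2L == 0L)
  nn_push(g, list(op = "pool", from = from, shape = c(s[1] %/% 2L, s[2] %/% 2L, s[3])))
}

nn_up <- function(g, from) {
  s <- nn_shape(g, from)
  nn_push(g, list(op = "up", from = from, shape = c(s[1] * 2L, s[2] * 2L, s[3])))
}

nn_concat <- function(g, a, b) {
  sa <- nn_shape(g, a); sb <- nn_shape(g, b)
  stopifnot(sa[1] == sb[1], sa[2] == sb[2])
  nn_push(g, list(op = "concat", from = c(a, b), shape = c(sa[1], sa[2], sa[3] + sb[3])))
}

nn_add <- function(g, a, b) {
  stopifnot(identical(nn_shape(g, a), nn_shape(g, b)))
  nn_push(g, list(op = "add", from = c(a, b), shape = nn_shape(g, a)))
}

nn_gap <- function(g, from) {
  s <- nn_shape(g, from)
  nn_push(g, list(op = "gap", from = from, shape = s[3]))
}

nn_dense <- function(g, from, nout) {
  s <- nn_shape(g, from)
  stopifnot(length(s) == 1L)
  nn_push(g, list(op = "dense", from = from, nin = s, nout = as.integer(nout), shape = as.integer(nout)))
}

nn_finalize <- function(g, name, seed) {
  model <- structure(
    list(nodes = g$nodes, input_shape = g$nodes[[1]]$shape,
         out_id = length(g$nodes), name = name, seed = seed),
    class = "nn_model"
  )
  nn_init(model, seed)
}

# He-normal init, drawn in node order under one seed
nn_init <- function(model, seed) {
  with_seed(seed, {
    for (i in seq_along(model$nodes)) {
      nd <- model$nodes[[i]]
      if (nd$op == "conv") {
        fan_in <- nd$k * nd$k * nd$cin
        nd$W <- matrix(rnorm(fan_in * nd$cout, sd = sqrt(2 / fan_in)), fan_in, nd$cout)
        nd$b <- numeric(nd$cout)
      } else if (nd$op == "dense") {
        nd$W <- matrix(rnorm(nd$nin * nd$nout, sd = sqrt(2 / nd$nin)), nd$nin, nd$nout)
        nd$b <- numeric(nd$nout)
      }
      model$nodes[[i]] <- nd
    }
  })
  model
}

nn_trainable_ids <- function(model) {
  which(vapply(model$nodes, function(n) n$op %in% c("conv", "dense"), logical(1)))
}

#' Partition a model's trainable layers into three groups
#'
#' Differential learning rates are applied per group: the first, middle and
#' last third of parameterized layers in network order, sizes as equal as
#' possible (earlier groups take the remainder).
#' @param model An internal network handle.
#' @return List of three integer vectors of node ids; their union is all
#'   trainable layers.
#' @keywords internal
nn_layer_groups <- function(model) {
  ids <- nn_trainable_ids(model)
  n <- length(ids)
  q <- n %/% 3L; r <- n %% 3L
  sizes <- c(q + (r >= 1L), q + (r >= 2L), q)
  ends <- cumsum(sizes)
  list(
    ids[seq_len(ends[1])],
    ids[setdiff(seq_len(ends[2]), seq_len(ends[1]))],
    ids[setdiff(seq_len(ends[3]), seq_len(ends[2]))]
  )
}

nn_last_layer_id <- function(model) max(nn_trainable_ids(model))

nn_n_params <- function(model) {
  sum(vapply(model$nodes, function(n) {
    if (is.null(n$W)) 0L else length(n$W) + length(n$b)
  }, numeric(1)))
}

im2col <- function(x, k, stride) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  p <- (k - 1L) %/% 2L
  Ho <- (H + 2L * p - k) %/% stride + 1L
  Wo <- (W + 2L * p - k) %/% stride + 1L
  if (p > 0L) {
    xp <- array(0, c(H + 2L * p, W + 2L * p, C, B))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else {
    xp <- x
  }
  ri <- seq.int(1L, by = stride, length.out = Ho)
  ci <- seq.int(1L, by = stride, length.out = Wo)
  X <- matrix(0, Ho * Wo * B, k * k * C)
  col <- 0L
  for (cc in seq_len(C)) {
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        col <- col + 1L
        X[, col] <- xp[ri + (ki - 1L), ci + (kj - 1L), cc, ]
      }
    }
  }
  list(X = X, Ho = Ho, Wo = Wo, ri = ri, ci = ci, p = p)
}

conv_forward <- function(x, nd) {
  ic <- im2col(x, nd$k, nd$stride)
  B <- dim(x)[4]
  Y <- ic$X %*% nd$W
  Y <- Y + rep(nd$b, each = nrow(Y))
  aperm(array(Y, c(ic$Ho, ic$Wo, B, nd$cout)), c(1L, 2L, 4L, 3L))
}

conv_backward <- function(x, nd, dy) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  ic <- im2col(x, nd$k, nd$stride)
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ic$Ho * ic$Wo * B, nd$cout)
  dW <- crossprod(ic$X, dym)
  db <- colSums(dym)
  dXc <- tcrossprod(dym, nd$W)
  p <- ic$p
  dxp <- array(0, c(H + 2L * p, W + 2L * p, C, B))
  col <- 0L
  for (cc in seq_len(C)) {
    for (kj in seq_len(nd$k)) {
      for (ki in seq_len(nd$k)) {
        col <- col + 1L
        rr <- ic$ri + (ki - 1L); cc2 <- ic$ci + (kj - 1L)
        dxp[rr, cc2, cc, ] <- dxp[rr, cc2, cc, ] + array(dXc[, col], c(ic$Ho, ic$Wo, B))
      }
    }
  }
  dx <- if (p > 0L) dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(1L, d[2], 2L)
  (x[o1, o2, , , drop = FALSE] + x[o1 + 1L, o2, , , drop = FALSE] +
    x[o1, o2 + 1L, , , drop = FALSE] + x[o1 + 1L, o2 + 1L, , , drop = FALSE]) / 4
}

pool_backward <- function(x, dy) {
  d <- dim(x)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(1L, d[2], 2L)
  dx <- array(0, d)
  q <- dy / 4
  dx[o1, o2, , ] <- q
  dx[o1 + 1L, o2, , ] <- q
  dx[o1, o2 + 1L, , ] <- q
  dx[o1 + 1L, o2 + 1L, , ] <- q
  dx
}

up_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

up_backward <- function(dy) pool_forward(dy) * 4

gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(m), d[3], d[4]))  # (B, C)
}

gap_backward <- function(x, dy) {
  d <- dim(x)
  array(rep(as.vector(t(dy)) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

nn_forward <- function(model, x) {
  outs <- vector("list", length(model$nodes))
  outs[[1]] <- x
  for (i in seq_along(model$nodes)[-1]) {
    nd <- model$nodes[[i]]
    a <- outs[[nd$from[1]]]
    outs[[i]] <- switch(nd$op,
      conv = conv_forward(a, nd),
      relu = pmax(a, 0),
      pool = pool_forward(a),
      up = up_forward(a),
      concat = {
        b <- outs[[nd$from[2]]]
        da <- dim(a)
        out <- array(0, c(da[1], da[2], nd$shape[3], da[4]))
        out[, , seq_len(da[3]), ] <- a
        out[, , da[3] + seq_len(dim(b)[3]), ] <- b
        out
      },
      add = a + outs[[nd$from[2]]],
      gap = gap_forward(a),
      dense = {
        y <- a %*% nd$W
        y + rep(nd$b, each = nrow(y))
      },
      stop("unknown op: ", nd$op)
    )
  }
  outs
}

# dout: gradient wrt final node output. Returns list(grads) where grads[[i]]
# is list(dW, db) for parameterized nodes.
nn_backward <- function(model, outs, dout) {
  n <- length(model$nodes)
  douts <- vector("list", n)
  douts[[n]] <- dout
  grads <- vector("list", n)
  acc <- function(cur, add) if (is.null(cur)) add else cur + add
  for (i in seq.int(n, 2L)) {
    dy <- douts[[i]]
    if (is.null(dy)) next
    nd <- model$nodes[[i]]
    a_id <- nd$from[1]
    a <- outs[[a_id]]
    if (nd$op == "conv") {
      bk <- conv_backward(a, nd, dy)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      douts[[a_id]] <- acc(douts[[a_id]], bk$dx)
    } else if (nd$op == "relu") {
      douts[[a_id]] <- acc(douts[[a_id]], dy * (outs[[i]] > 0))
    } else if (nd$op == "pool") {
      douts[[a_id]] <- acc(douts[[a_id]], pool_backward(a, dy))
    } else if (nd$op == "up") {
      douts[[a_id]] <- acc(douts[[a_id]], up_backward(dy))
    } else if (nd$op == "concat") {
      b_id <- nd$from[2]
      ca <- dim(a)[3]
      douts[[a_id]] <- acc(douts[[a_id]], dy[, , seq_len(ca), , drop = FALSE])
      douts[[b_id]] <- acc(
        douts[[b_id]],
        dy[, , ca + seq_len(nd$shape[3] - ca), , drop = FALSE]
      )
    } else if (nd$op == "add") {
      b_id <- nd$from[2]
      douts[[a_id]] <- acc(douts[[a_id]], dy)
      douts[[b_id]] <- acc(douts[[b_id]], dy)
    } else if (nd$op == "gap") {
      douts[[a_id]] <- acc(douts[[a_id]], gap_backward(a, dy))
    } else if (nd$op == "dense") {
      grads[[i]] <- list(dW = crossprod(a, dy), db = colSums(dy))
      douts[[a_id]] <- acc(douts[[a_id]], tcrossprod(dy, nd$W))
    }
    douts[[i]] <- NULL  # free
  }
  grads
}

nn_opt_state <- function(model) {
  lapply(model$nodes, function(nd) {
    if (is.null(nd$W)) NULL else list(vW = nd$W * 0, vb = nd$b * 0)
  })
}

# SGD with momentum, weight decay and per-layer-group learning rates.
# `subset`: optional node ids to update (e.g. last layer only).
nn_sgd_step <- function(model, grads, state, lrs, momentum, weight_decay,
                        subset = NULL) {
  groups <- nn_layer_groups(model)
  for (g in 1:3) {
    for (i in groups[[g]]) {
      if (!is.null(subset) && !(i %in% subset)) next
      gr <- grads[[i]]
      if (is.null(gr)) next
      nd <- model$nodes[[i]]
      st <- state[[i]]
      st$vW <- momentum * st$vW - lrs[g] * (gr$dW + weight_decay * nd$W)
      st$vb <- momentum * st$vb - lrs[g] * gr$db
      nd$W <- nd$W + st$vW
      nd$b <- nd$b + st$vb
      model$nodes[[i]] <- nd
      state[[i]] <- st
    }
  }
  list(model = model, state = state)
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf(
    "<nn_model '%s'> input %s, %d nodes, %s parameters\n",
    x$name, paste(x$input_shape, collapse = "x"),
    length(x$nodes), format(nn_n_params(x), big.mark = ",")
  ))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
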