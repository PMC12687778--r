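# Minimal residual convolutional network engine.
#
# Feature maps are stored as C x (Nvox * B) matrices (spatial index fastest,
# then batch); convolutions are im2col gathers followed by BLAS GEMM, so both
# the 2D and 3D paths (a 2D image is a depth-1 volume with a depth-1 kernel)
# share one implementation. Backward passes are exact, which the test-suite
# verifies against finite differences.

conv_out_dim <- function(in_dim, k, stride, pad) {
  out <- floor((in_dim + 2 * pad - k) / stride) + 1
  if (any(out < 1)) {
    stop_salnet("input of size ", paste(in_dim, collapse = "x"),
                " is smaller than the network's total downsampling ",
                "(kernel ", paste(k, collapse = "x"), ", stride ",
                paste(stride, collapse = "x"), ")",
                class = "salnet_sizing_error")
  }
  out
}

# K x Nout integer matrix of linear input indices (NA = zero padding), rows
# ordered k1 fastest, columns o1 fastest
conv_index <- function(in_dim, k, stride, pad) {
  out_dim <- conv_out_dim(in_dim, k, stride, pad)
  ax <- function(a) {
    outer(seq_len(k[a]), (seq_len(out_dim[a]) - 1) * stride[a] - pad[a], `+`)
  }
  M1 <- ax(1); M2 <- ax(2); M3 <- ax(3)
  r1 <- rep(seq_len(k[1]), times = k[2] * k[3])
  r2 <- rep(rep(seq_len(k[2]), each = k[1]), times = k[3])
  r3 <- rep(seq_len(k[3]), each = k[1] * k[2])
  c1 <- rep(seq_len(out_dim[1]), times = out_dim[2] * out_dim[3])
  c2 <- rep(rep(seq_len(out_dim[2]), each = out_dim[1]), times = out_dim[3])
  c3 <- rep(seq_len(out_dim[3]), each = out_dim[1] * out_dim[2])
  P1 <- M1[r1, c1, drop = FALSE]
  P2 <- M2[r2, c2, drop = FALSE]
  P3 <- M3[r3, c3, drop = FALSE]
  ok <- P1 >= 1 & P1 <= in_dim[1] & P2 >= 1 & P2 <= in_dim[2] &
    P3 >= 1 & P3 <= in_dim[3]
  lin <- P1 + (P2 - 1) * in_dim[1] + (P3 - 1) * in_dim[1] * in_dim[2]
  lin[!ok] <- NA
  structure(matrix(as.integer(lin), nrow = prod(k)), out_dim = out_dim)
}

new_conv <- function(cin, cout, k, stride, pad, in_dim, init_gain = 1) {
  idx <- conv_index(in_dim, k, stride, pad)
  K <- prod(k)
  fan_in <- K * cin
  layer <- list(
    type = "conv",
    cin = cin, cout = cout, k = k, stride = stride, pad = pad,
    in_dim = in_dim, out_dim = attr(idx, "out_dim"),
    Nin = prod(in_dim), Nout = prod(attr(idx, "out_dim")), K = K,
    idx = idx,
    W = matrix(rnorm(cout * K * cin, sd = init_gain * sqrt(2 / fan_in)),
               nrow = cout),
    b = numeric(cout)
  )
  layer$cache_env <- new.env(parent = emptyenv())
  layer
}

# gather index for a whole batch (zero-padding entries point at a trailing
# zero column); cached per batch size
conv_batch_index <- function(ly, B) {
  key <- paste0("g", B)
  cached <- ly$cache_env[[key]]
  if (!is.null(cached)) return(cached)
  base <- as.vector(ly$idx)
  zero_col <- ly$Nin * B + 1L
  idxb <- rep(base, times = B) +
    rep((seq_len(B) - 1L) * ly$Nin, each = length(base))
  idxb[is.na(idxb)] <- zero_col
  ly$cache_env[[key]] <- idxb
  idxb
}

# scatter indices for the backward pass: per kernel offset, the valid output
# columns and their (collision-free) input positions, expanded to the batch
conv_scatter_index <- function(ly, B) {
  key <- paste0("s", B)
  cached <- ly$cache_env[[key]]
  if (!is.null(cached)) return(cached)
  out <- vector("list", ly$K)
  boff_in <- (seq_len(B) - 1L) * ly$Nin
  boff_out <- (seq_len(B) - 1L) * ly$Nout
  for (kk in seq_len(ly$K)) {
    row <- ly$idx[kk, ]
    vj <- which(!is.na(row))
    nv <- length(vj)
    out[[kk]] <- list(
      src = rep(vj, times = B) + rep(boff_out, each = nv),
      dst = rep(row[vj], times = B) + rep(boff_in, each = nv),
      full = nv == ly$Nout
    )
  }
  ly$cache_env[[key]] <- out
  out
}

# column layout: channel fastest, then kernel offset, so the gathered block
# reshapes to (cin * K) x (Nout * B) without a transpose; W columns follow
# the same (cin within offset) ordering
conv_im2col <- function(x, ly, B) {
  idxb <- conv_batch_index(ly, B)
  Xp <- cbind(x, 0)
  A <- Xp[, idxb, drop = FALSE]
  dim(A) <- c(ly$cin * ly$K, ly$Nout * B)
  A
}

conv_forward <- function(x, ly, B) {
  M <- conv_im2col(x, ly, B)
  list(out = ly$W %*% M + ly$b, cols = M)
}

conv_backward <- function(dY, ly, cols, B) {
  dW <- tcrossprod(dY, cols)
  db <- rowSums(dY)
  dM <- crossprod(ly$W, dY)           # (cin * K) x (Nout * B)
  sc <- conv_scatter_index(ly, B)
  cin <- ly$cin
  dX <- matrix(0, cin, ly$Nin * B)
  for (kk in seq_len(ly$K)) {
    rows <- ((kk - 1L) * cin + 1L):(kk * cin)
    slice <- dM[rows, , drop = FALSE]
    s <- sc[[kk]]
    if (s$full) {
      dX[, s$dst] <- dX[, s$dst, drop = FALSE] + slice
    } else {
      dX[, s$dst] <- dX[, s$dst, drop = FALSE] + slice[, s$src, drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# activation functions; "relu2" (squared rectifier) makes the input
# Jacobian proportional to the local response, which concentrates gradient
# saliency on the voxels that actually drive the prediction
act_f <- function(x, act) {
  if (act == "relu2") {
    x[x < 0] <- 0
    x * x
  } else if (act == "identity") {
    x
  } else {
    relu(x)
  }
}

# gradient of the activation given its *pre-activation* input
act_g <- function(pre, act) {
  if (act == "relu2") {
    2 * pre * (pre > 0)
  } else if (act == "identity") {
    1
  } else {
    (pre > 0) * 1
  }
}

gap_forward <- function(x, C, Nvox, B) {
  xx <- array(x, c(C, Nvox, B))
  out <- colSums(aperm(xx, c(2, 1, 3))) / Nvox
  matrix(out, nrow = C)
}

gap_backward <- function(dY, C, Nvox, B) {
  # dY: C x B -> C x (Nvox * B)
  big <- dY[, rep(seq_len(B), each = Nvox), drop = FALSE] / Nvox
  big
}

new_fc <- function(d_in, d_out, init_gain = 1) {
  list(type = "fc",
       W = matrix(rnorm(d_out * d_in, sd = init_gain * sqrt(2 / d_in)),
                  nrow = d_out),
       b = numeric(d_out),
       d_in = d_in, d_out = d_out)
}

# residual block (basic: two kxk convs; bottleneck: 1x1 reduce, kxk, 1x1
# expand) with an optional 1x1 projection shortcut
new_block <- function(cin, cout, stride, in_dim, nd_kernel, bottleneck,
                      mid = NULL) {
  k1 <- rep(1L, 3)
  if (bottleneck) {
    mid <- mid %||% max(1L, cout %/% 4L)
    c1 <- new_conv(cin, mid, k1, rep(1L, 3), rep(0L, 3), in_dim)
    c2 <- new_conv(mid, mid, nd_kernel, stride, nd_pad(nd_kernel), c1$out_dim)
    c3 <- new_conv(mid, cout, k1, rep(1L, 3), rep(0L, 3), c2$out_dim)
    convs <- list(c1, c2, c3)
    out_dim <- c3$out_dim
  } else {
    c1 <- new_conv(cin, cout, nd_kernel, stride, nd_pad(nd_kernel), in_dim)
    c2 <- new_conv(cout, cout, nd_kernel, rep(1L, 3), nd_pad(nd_kernel),
                   c1$out_dim)
    convs <- list(c1, c2)
    out_dim <- c2$out_dim
  }
  proj <- NULL
  if (cin != cout || any(stride != 1L)) {
    proj <- new_conv(cin, cout, k1, stride, rep(0L, 3), in_dim)
  }
  list(type = "block", convs = convs, proj = proj,
       in_dim = in_dim, out_dim = out_dim, cin = cin, cout = cout)
}

nd_pad <- function(k) as.integer(k %/% 2L)

block_forward <- function(x, ly, B, act = "relu") {
  caches <- vector("list", length(ly$convs))
  h <- x
  pre <- vector("list", length(ly$convs))
  for (i in seq_along(ly$convs)) {
    cf <- conv_forward(h, ly$convs[[i]], B)
    caches[[i]] <- cf$cols
    pre[[i]] <- cf$out
    h <- if (i < length(ly$convs)) act_f(cf$out, act) else cf$out
  }
  if (is.null(ly$proj)) {
    sc <- x
    proj_cols <- NULL
  } else {
    pf <- conv_forward(x, ly$proj, B)
    sc <- pf$out
    proj_cols <- pf$cols
  }
  s <- h + sc
  list(out = act_f(s, act),
       cache = list(x = x, pre = pre, cols = caches, sum = s,
                    proj_cols = proj_cols))
}

block_backward <- function(dY, ly, cache, B, act = "relu") {
  ds <- dY * act_g(cache$sum, act)
  nconv <- length(ly$convs)
  grads <- vector("list", nconv)
  d <- ds
  for (i in rev(seq_len(nconv))) {
    if (i < nconv) d <- d * act_g(cache$pre[[i]], act)
    cb <- conv_backward(d, ly$convs[[i]], cache$cols[[i]], B)
    grads[[i]] <- list(dW = cb$dW, db = cb$db)
    d <- cb$dX
  }
  if (is.null(ly$proj)) {
    dx <- d + ds
    proj_grad <- NULL
  } else {
    pb <- conv_backward(ds, ly$proj, cache$proj_cols, B)
    dx <- d + pb$dX
    proj_grad <- list(dW = pb$dW, db = pb$db)
  }
  list(dX = dx, convs = grads, proj = proj_grad)
}

# --- whole-network forward / backward --------------------------------------

net_forward <- function(net, x, B, keep_cache = TRUE) {
  caches <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    h <- switch(
      ly$type,
      conv = {
        cf <- conv_forward(h, ly, B)
        if (keep_cache) caches[[i]] <- cf$cols
        cf$out
      },
      relu = {
        if (keep_cache) caches[[i]] <- h
        act_f(h, ly$act %||% "relu")
      },
      block = {
        bf <- block_forward(h, ly, B, ly$act %||% "relu")
        if (keep_cache) caches[[i]] <- bf$cache
        bf$out
      },
      gap = {
        gap_forward(h, ly$C, ly$Nvox, B)
      },
      flatten = {
        matrix(h, nrow = ly$d, ncol = B)
      },
      fc = {
        if (keep_cache) caches[[i]] <- h
        ly$W %*% h + ly$b
      },
      stop("unknown layer type ", ly$type)
    )
  }
  list(out = h, caches = caches)
}

# dOut is the gradient at the network output (logits / feature layer);
# returns gradients for every parameterised layer plus the input gradient
net_backward <- function(net, dOut, caches, B) {
  grads <- vector("list", length(net$layers))
  d <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    d <- switch(
      ly$type,
      conv = {
        cb <- conv_backward(d, ly, caches[[i]], B)
        grads[[i]] <- list(dW = cb$dW, db = cb$db)
        cb$dX
      },
      relu = {
        d * act_g(caches[[i]], ly$act %||% "relu")
      },
      block = {
        bb <- block_backward(d, ly, caches[[i]], B, ly$act %||% "relu")
        grads[[i]] <- list(convs = bb$convs, proj = bb$proj)
        bb$dX
      },
      gap = {
        gap_backward(d, ly$C, ly$Nvox, B)
      },
      flatten = {
        matrix(d, nrow = 1L)
      },
      fc = {
        grads[[i]] <- list(dW = tcrossprod(d, caches[[i]]), db = rowSums(d))
        crossprod(ly$W, d)
      }
    )
  }
  list(grads = grads, dX = d)
}

# --- parameter bookkeeping --------------------------------------------------

# flatten parameterised tensors into a named list of matrices/vectors
collect_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "fc")) {
      out[[paste0("L", i, ".W")]] <- ly$W
      out[[paste0("L", i, ".b")]] <- ly$b
    } else if (ly$type == "block") {
      for (j in seq_along(ly$convs)) {
        out[[paste0("L", i, ".c", j, ".W")]] <- ly$convs[[j]]$W
        out[[paste0("L", i, ".c", j, ".b")]] <- ly$convs[[j]]$b
      }
      if (!is.null(ly$proj)) {
        out[[paste0("L", i, ".p.W")]] <- ly$proj$W
        out[[paste0("L", i, ".p.b")]] <- ly$proj$b
      }
    }
  }
  out
}

collect_grads <- function(net, grads) {
  out <- list()
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    g <- grads[[i]]
    if (ly$type %in% c("conv", "fc")) {
      out[[paste0("L", i, ".W")]] <- g$dW
      out[[paste0("L", i, ".b")]] <- g$db
    } else if (ly$type == "block") {
      for (j in seq_along(ly$convs)) {
        out[[paste0("L", i, ".c", j, ".W")]] <- g$convs[[j]]$dW
        out[[paste0("L", i, ".c", j, ".b")]] <- g$convs[[j]]$db
      }
      if (!is.null(ly$proj)) {
        out[[paste0("L", i, ".p.W")]] <- g$proj$dW
        out[[paste0("L", i, ".p.b")]] <- g$proj$db
      }
    }
  }
  out
}

assign_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "fc")) {
      net$layers[[i]]$W <- params[[paste0("L", i, ".W")]]
      net$layers[[i]]$b <- params[[paste0("L", i, ".b")]]
    } else if (ly$type == "block") {
      for (j in seq_along(ly$convs)) {
        net$layers[[i]]$convs[[j]]$W <- params[[paste0("L", i, ".c", j, ".W")]]
        net$layers[[i]]$convs[[j]]$b <- params[[paste0("L", i, ".c", j, ".b")]]
      }
      if (!is.null(ly$proj)) {
        net$layers[[i]]$proj$W <- params[[paste0("L", i, ".p.W")]]
        net$layers[[i]]$proj$b <- params[[paste0("L", i, ".p.b")]]
      }
    }
  }
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
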