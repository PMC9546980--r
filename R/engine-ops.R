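# Primitive tensor operations of the CPU network engine.
#
# Feature maps are dense arrays with the channel axis last:
#   2D: (H, W, C)   [H = Y, W = X]
#   3D: (D, H, W, C) [D = Z]
# Convolutions are expressed as im2col + BLAS matrix multiply; every op has a
# hand-derived backward so training needs no external framework. Weight
# matrices have shape (prod(kernel) * C_in, C_out) with rows grouped by kernel
# offset (lexicographic over axes), channel fastest within a group — the same
# order the im2col column blocks are laid out in. Hot paths branch explicitly
# on dimensionality instead of using generic index construction.

spatial_dims <- function(x) {
  d <- dim(x)
  d[-length(d)]
}

n_channels <- function(x) {
  d <- dim(x)
  d[length(d)]
}

# "same"-padded convolution, odd kernel k (1 or 3 here); the im2col/col2im
# core lives in src/convops.cpp
conv_fwd <- function(x, W, b, k, train = FALSE) {
  sp <- spatial_dims(x)
  n <- prod(sp)
  cin <- n_channels(x)
  cout <- ncol(W)
  if (k == 1L) {
    Xm <- x
    dim(Xm) <- c(n, cin)
    Ym <- Xm %*% W
  } else {
    p <- (k - 1L) %/% 2L
    xp <- .pad_zero_cpp(as.vector(x), sp, cin, p)
    Xm <- .im2col_cpp(xp, sp + 2L * p, sp, cin, k)
    Ym <- Xm %*% W
  }
  Ym <- Ym + rep(b, each = n)
  dim(Ym) <- c(sp, cout)
  cache <- if (train) list(Xm = Xm, k = k, sp = sp, cin = cin, xdim = dim(x)) else NULL
  list(y = Ym, cache = cache)
}

conv_bwd <- function(dy, cache, W) {
  sp <- cache$sp
  n <- prod(sp)
  cout <- n_channels(dy)
  dYm <- dy
  dim(dYm) <- c(n, cout)
  dW <- crossprod(cache$Xm, dYm)
  db <- colSums(dYm)
  dXc <- tcrossprod(dYm, W)
  if (cache$k == 1L) {
    dx <- dXc
    dim(dx) <- cache$xdim
  } else {
    p <- (cache$k - 1L) %/% 2L
    dxp <- .col2im_cpp(dXc, sp + 2L * p, sp, cache$cin, cache$k)
    dx <- .crop_pad_cpp(dxp, sp, cache$cin, p)
    dim(dx) <- cache$xdim
  }
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution, kernel = stride = `factors` (2 or 1 per axis);
# the shape-preserving mirror of 2x max pooling
convt_offsets <- function(factors) {
  offs <- expand.grid(lapply(factors, function(f) seq_len(f) - 1L))
  as.matrix(offs[do.call(order, as.data.frame(offs)), , drop = FALSE])
}

convt_fwd <- function(x, W, b, factors, train = FALSE) {
  sp <- spatial_dims(x)
  cin <- n_channels(x)
  cout <- ncol(W)
  out_sp <- sp * factors
  offs <- convt_offsets(factors)
  Xm <- x
  dim(Xm) <- c(prod(sp), cin)
  y <- array(0, c(out_sp, cout))
  nd <- length(sp)
  for (i in seq_len(nrow(offs))) {
    rows <- ((i - 1L) * cin + 1L):(i * cin)
    Po <- Xm %*% W[rows, , drop = FALSE]
    dim(Po) <- c(sp, cout)
    if (nd == 2L) {
      y[seq.int(offs[i, 1L] + 1L, out_sp[1L], by = factors[1L]),
        seq.int(offs[i, 2L] + 1L, out_sp[2L], by = factors[2L]), ] <- Po
    } else {
      y[seq.int(offs[i, 1L] + 1L, out_sp[1L], by = factors[1L]),
        seq.int(offs[i, 2L] + 1L, out_sp[2L], by = factors[2L]),
        seq.int(offs[i, 3L] + 1L, out_sp[3L], by = factors[3L]), ] <- Po
    }
  }
  y <- y + rep(b, each = prod(out_sp))
  cache <- if (train) list(Xm = Xm, sp = sp, out_sp = out_sp, factors = factors, cin = cin) else NULL
  list(y = y, cache = cache)
}

convt_bwd <- function(dy, cache, W) {
  sp <- cache$sp
  out_sp <- cache$out_sp
  cin <- cache$cin
  cout <- n_channels(dy)
  nd <- length(sp)
  offs <- convt_offsets(cache$factors)
  dW <- matrix(0, nrow(W), ncol(W))
  dXm <- matrix(0, prod(sp), cin)
  for (i in seq_len(nrow(offs))) {
    rows <- ((i - 1L) * cin + 1L):(i * cin)
    dPo <- if (nd == 2L) {
      dy[seq.int(offs[i, 1L] + 1L, out_sp[1L], by = cache$factors[1L]),
        seq.int(offs[i, 2L] + 1L, out_sp[2L], by = cache$factors[2L]), ,
        drop = FALSE
      ]
    } else {
      dy[seq.int(offs[i, 1L] + 1L, out_sp[1L], by = cache$factors[1L]),
        seq.int(offs[i, 2L] + 1L, out_sp[2L], by = cache$factors[2L]),
        seq.int(offs[i, 3L] + 1L, out_sp[3L], by = cache$factors[3L]), ,
        drop = FALSE
      ]
    }
    dim(dPo) <- c(prod(sp), cout)
    dW[rows, ] <- crossprod(cache$Xm, dPo)
    dXm <- dXm + tcrossprod(dPo, W[rows, , drop = FALSE])
  }
  dyM <- dy
  dim(dyM) <- c(prod(out_sp), cout)
  db <- colSums(dyM)
  dim(dXm) <- c(sp, cin)
  list(dx = dXm, dW = dW, db = db)
}

# max pooling by integer factors (2 or 1 per axis), non-overlapping windows
maxpool_fwd <- function(x, factors, train = FALSE) {
  sp <- spatial_dims(x)
  stopifnot(all(sp %% factors == 0L))
  out_sp <- sp %/% factors
  cc <- n_channels(x)
  nd <- length(sp)
  offs <- convt_offsets(factors)
  ncand <- nrow(offs)
  cand <- vector("list", ncand)
  for (i in seq_len(ncand)) {
    cand[[i]] <- if (nd == 2L) {
      x[seq.int(offs[i, 1L] + 1L, sp[1L], by = factors[1L]),
        seq.int(offs[i, 2L] + 1L, sp[2L], by = factors[2L]), ,
        drop = FALSE
      ]
    } else {
      x[seq.int(offs[i, 1L] + 1L, sp[1L], by = factors[1L]),
        seq.int(offs[i, 2L] + 1L, sp[2L], by = factors[2L]),
        seq.int(offs[i, 3L] + 1L, sp[3L], by = factors[3L]), ,
        drop = FALSE
      ]
    }
  }
  y <- cand[[1L]]
  amax <- array(1L, dim(y))
  if (ncand > 1L) {
    for (i in 2L:ncand) {
      better <- cand[[i]] > y
      y[better] <- cand[[i]][better]
      amax[better] <- i
    }
  }
  cache <- if (train) list(amax = amax, sp = sp, factors = factors, offs = offs) else NULL
  list(y = y, cache = cache)
}

maxpool_bwd <- function(dy, cache) {
  sp <- cache$sp
  nd <- length(sp)
  cc <- n_channels(dy)
  dx <- array(0, c(sp, cc))
  offs <- cache$offs
  for (i in seq_len(nrow(offs))) {
    contrib <- dy * (cache$amax == i)
    if (nd == 2L) {
      ry <- seq.int(offs[i, 1L] + 1L, sp[1L], by = cache$factors[1L])
      rx <- seq.int(offs[i, 2L] + 1L, sp[2L], by = cache$factors[2L])
      dx[ry, rx, ] <- dx[ry, rx, , drop = FALSE] + contrib
    } else {
      rz <- seq.int(offs[i, 1L] + 1L, sp[1L], by = cache$factors[1L])
      ry <- seq.int(offs[i, 2L] + 1L, sp[2L], by = cache$factors[2L])
      rx <- seq.int(offs[i, 3L] + 1L, sp[3L], by = cache$factors[3L])
      dx[rz, ry, rx, ] <- dx[rz, ry, rx, , drop = FALSE] + contrib
    }
  }
  dx
}

act_fwd <- function(x, kind) {
  if (kind == "relu") {
    y <- x
    y[y < 0] <- 0
  } else if (kind == "elu") {
    y <- .elu_fwd_cpp(x)
    dim(y) <- dim(x)
  } else if (kind == "sigmoid") {
    y <- 1 / (1 + exp(-x))
  } else {
    stop("unknown activation: ", kind)
  }
  if (is.null(dim(y))) dim(y) <- dim(x)
  y
}

# derivative expressed through the activation output (monotone, f(0)=0)
act_bwd <- function(dy, y, kind) {
  if (kind == "relu") {
    d <- dy
    d[y <= 0] <- 0
  } else if (kind == "elu") {
    d <- .elu_bwd_cpp(dy, y)
    dim(d) <- dim(dy)
  } else if (kind == "sigmoid") {
    d <- dy * y * (1 - y)
  } else {
    stop("unknown activation: ", kind)
  }
  d
}

dropout_fwd <- function(x, rate, train = FALSE) {
  if (!train || rate <= 0) {
    return(list(y = x, cache = NULL))
  }
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  y <- x * keep
  dim(y) <- dim(x)
  list(y = y, cache = list(keep = keep))
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) {
    return(dy)
  }
  dx <- dy * cache$keep
  dim(dx) <- dim(dy)
  dx
}

concat_fwd <- function(a, b) {
  spa <- spatial_dims(a)
  stopifnot(identical(spa, spatial_dims(b)))
  ca <- n_channels(a)
  cb <- n_channels(b)
  y <- c(a, b) # channel axis is last: plain concatenation of the vectors
  dim(y) <- c(spa, ca + cb)
  y
}

concat_bwd <- function(dy, ca) {
  sp <- spatial_dims(dy)
  n <- prod(sp)
  cc <- n_channels(dy)
  da <- dy[seq_len(n * ca)]
  db <- dy[(n * ca + 1L):(n * cc)]
  dim(da) <- c(sp, ca)
  dim(db) <- c(sp, cc - ca)
  list(da = da, db = db)
}

# x * m with m carrying a single channel broadcast across the channels of x
# (attention-gate coefficient map)
mulmap_fwd <- function(x, m) {
  y <- x * as.vector(m)
  dim(y) <- dim(x)
  y
}

mulmap_bwd <- function(dy, x, m) {
  sp <- spatial_dims(x)
  cc <- n_channels(x)
  n <- prod(sp)
  dx <- dy * as.vector(m)
  dim(dx) <- dim(x)
  dm <- dy * x
  dim(dm) <- c(n, cc)
  dm <- rowSums(dm)
  dim(dm) <- c(sp, 1L)
  list(dx = dx, dm = dm)
}

# x * s with s a per-channel scalar vector (squeeze-and-excitation rescale)
scalech_fwd <- function(x, s) {
  n <- prod(spatial_dims(x))
  y <- x * rep(s, each = n)
  dim(y) <- dim(x)
  y
}

scalech_bwd <- function(dy, x, s) {
  sp <- spatial_dims(x)
  cc <- n_channels(x)
  n <- prod(sp)
  dx <- dy * rep(s, each = n)
  dim(dx) <- dim(x)
  prod_ <- dy * x
  dim(prod_) <- c(n, cc)
  list(dx = dx, ds = colSums(prod_))
}

# global average pool: (spatial..., C) -> length-C vector
gmean_fwd <- function(x) {
  n <- prod(spatial_dims(x))
  xm <- x
  dim(xm) <- c(n, n_channels(x))
  colMeans(xm)
}

gmean_bwd <- function(dy, xdim) {
  n <- prod(xdim[-length(xdim)])
  dx <- rep(dy / n, each = n)
  dim(dx) <- xdim
  dx
}

dense_fwd <- function(v, W, b) {
  drop(v %*% W) + b
}

dense_bwd <- function(dy, v, W) {
  list(dv = drop(W %*% dy), dW = outer(v, dy), db = dy)
}

# per-channel normalisation using the statistics of the current patch during
# training (single-sample batches) and running averages at inference
bnorm_fwd <- function(x, gamma, beta, run_mean, run_var, train = FALSE,
                      momentum = 0.9, eps = 1e-5) {
  sp <- spatial_dims(x)
  cc <- n_channels(x)
  n <- prod(sp)
  xm <- x
  dim(xm) <- c(n, cc)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu, `-`)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean
    va <- run_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, `-`), 2L, istd, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(ym) <- c(sp, cc)
  list(
    y = ym,
    cache = if (train) list(xhat = xhat, istd = istd, sp = sp, cc = cc) else NULL,
    run_mean = run_mean, run_var = run_var
  )
}

bnorm_bwd <- function(dy, cache, gamma) {
  n <- prod(cache$sp)
  dym <- dy
  dim(dym) <- c(n, cache$cc)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2L, colMeans(dym), `-`)
  t2 <- sweep(xhat, 2L, colMeans(dym * xhat), `*`)
  dxm <- sweep(t1 - t2, 2L, gamma * cache$istd, `*`)
  dim(dxm) <- c(cache$sp, cache$cc)
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}
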