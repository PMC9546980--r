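# Builds the encoder-decoder graph described by a network_spec and runs it.
#
# The graph is a flat list of nodes in topological order. Composite blocks
# (attention gates, squeeze-and-excitation) are single nodes with their own
# forward/backward; everything else is one primitive op per node.

.add_node <- function(st, op, inputs = integer(), ...) {
  id <- length(st$nodes) + 1L
  st$nodes[[id]] <- c(list(op = op, inputs = as.integer(inputs)), list(...))
  st$last <- id
  st
}

.init_weight <- function(dims, fan_in, fan_out, init) {
  n <- prod(dims)
  w <- switch(init,
    he_normal = rnorm(n, 0, sqrt(2 / fan_in)),
    glorot_uniform = runif(n, -sqrt(6 / (fan_in + fan_out)), sqrt(6 / (fan_in + fan_out))),
    stop("unknown kernel_init: ", init)
  )
  array(w, dims)
}

.new_conv_par <- function(st, tag, k, nd, cin, cout, init) {
  wn <- paste0(tag, ".W")
  bn <- paste0(tag, ".b")
  st$params[[wn]] <- .init_weight(c(k^nd * cin, cout), k^nd * cin, k^nd * cout, init)
  st$params[[bn]] <- numeric(cout)
  list(st = st, W = wn, b = bn)
}

.new_convt_par <- function(st, tag, factors, cin, cout, init) {
  noff <- prod(factors)
  wn <- paste0(tag, ".W")
  bn <- paste0(tag, ".b")
  st$params[[wn]] <- .init_weight(c(noff * cin, cout), noff * cin, noff * cout, init)
  st$params[[bn]] <- numeric(cout)
  list(st = st, W = wn, b = bn)
}

# two 3x3(x3) convolutions, each followed by (optional BN,) activation and
# dropout -- or the full pre-activation residual version of the same
.add_block <- function(st, x_id, cin, cout, rate, spec, tag) {
  nd <- spec$ndim
  act <- tolower(spec$activation)
  add_conv <- function(st, in_id, ci, co, k, sub) {
    p <- .new_conv_par(st, paste0(tag, ".", sub), k, nd, ci, co, spec$kernel_init)
    .add_node(p$st, "conv", in_id, W = p$W, b = p$b, k = k)
  }
  add_bn <- function(st, in_id, cc, sub) {
    if (!spec$batch_norm) {
      st$last <- in_id
      return(st)
    }
    gn <- paste0(tag, ".", sub, ".gamma")
    bn <- paste0(tag, ".", sub, ".beta")
    st$params[[gn]] <- rep(1, cc)
    st$params[[bn]] <- numeric(cc)
    st$state[[paste0(tag, ".", sub, ".mean")]] <- numeric(cc)
    st$state[[paste0(tag, ".", sub, ".var")]] <- rep(1, cc)
    .add_node(st, "bnorm", in_id, gamma = gn, beta = bn, stat = paste0(tag, ".", sub))
  }
  if (spec$block_kind == "conv") {
    st <- add_conv(st, x_id, cin, cout, 3L, "conv1")
    st <- add_bn(st, st$last, cout, "bn1")
    st <- .add_node(st, "act", st$last, kind = act)
    st <- .add_node(st, "dropout", st$last, rate = rate)
    st <- add_conv(st, st$last, cout, cout, 3L, "conv2")
    st <- add_bn(st, st$last, cout, "bn2")
    st <- .add_node(st, "act", st$last, kind = act)
    st <- .add_node(st, "dropout", st$last, rate = rate)
  } else { # full pre-activation residual block
    st <- add_bn(st, x_id, cin, "bn1")
    st <- .add_node(st, "act", st$last, kind = act)
    st <- add_conv(st, st$last, cin, cout, 3L, "conv1")
    st <- .add_node(st, "dropout", st$last, rate = rate)
    st <- add_bn(st, st$last, cout, "bn2")
    st <- .add_node(st, "act", st$last, kind = act)
    st <- add_conv(st, st$last, cout, cout, 3L, "conv2")
    st <- .add_node(st, "dropout", st$last, rate = rate)
    body_id <- st$last
    if (cin != cout) {
      st <- add_conv(st, x_id, cin, cout, 1L, "proj")
      short_id <- st$last
    } else {
      short_id <- x_id
    }
    st <- .add_node(st, "add", c(body_id, short_id))
  }
  st
}

.add_se <- function(st, x_id, cc, ratio, tag) {
  cmid <- max(1L, cc %/% ratio)
  w1 <- paste0(tag, ".se.W1")
  b1 <- paste0(tag, ".se.b1")
  w2 <- paste0(tag, ".se.W2")
  b2 <- paste0(tag, ".se.b2")
  st$params[[w1]] <- .init_weight(c(cc, cmid), cc, cmid, "he_normal")
  st$params[[b1]] <- numeric(cmid)
  st$params[[w2]] <- .init_weight(c(cmid, cc), cmid, cc, "glorot_uniform")
  st$params[[b2]] <- numeric(cc)
  .add_node(st, "se", x_id, W1 = w1, b1 = b1, W2 = w2, b2 = b2)
}

# additive attention gate: 1x1 projections of skip (x) and gating signal (g),
# add, ReLU, 1x1 to one channel, sigmoid, multiply onto the skip features.
# Internal width = skip channel count; gate signal = decoder features after
# upsampling at the same level (so c_g = c_x here).
.add_attn <- function(st, x_id, g_id, cx, cg, tag) {
  nd <- st$spec$ndim
  fint <- cx
  px <- .new_conv_par(st, paste0(tag, ".att.x"), 1L, nd, cx, fint, st$spec$kernel_init)
  st <- px$st
  pg <- .new_conv_par(st, paste0(tag, ".att.g"), 1L, nd, cg, fint, st$spec$kernel_init)
  st <- pg$st
  pp <- .new_conv_par(st, paste0(tag, ".att.psi"), 1L, nd, fint, 1L, st$spec$kernel_init)
  st <- pp$st
  .add_node(st, "attn", c(x_id, g_id),
    Wx = px$W, bx = px$b, Wg = pg$W, bg = pg$b, Wp = pp$W, bp = pp$b
  )
}

#' Build a trainable network from a spec
#'
#' Constructs the encoder-decoder graph: `length(filters) - 1` encoder levels
#' (processing block then 2x max pooling, Z pooled only where `z_down` says
#' so), a bottleneck block, and a mirrored decoder using 2x transposed
#' convolutions, skip-connection concatenation (through an attention gate when
#' enabled) and a processing block per level, ending in a 1x1 convolution and
#' a sigmoid. Weights are drawn with the spec's initialiser under the given
#' seed: the same spec and seed always produce bit-identical models.
#'
#' @param spec A [network_spec()] or preset name string.
#' @param seed Integer initialisation seed.
#' @return An object of class `em_network` mapping an image patch (values in
#'   `[0, 1]`, spatial dims divisible by the network's total downsampling
#'   factor) to a probability map of identical spatial shape.
#' @export
#' @examples
#' net <- build_network(network_spec(2, c(4, 8)), seed = 1)
#' p <- predict_patch(net, matrix(runif(64 * 64), 64, 64))
#' range(p) # probabilities
build_network <- function(spec, seed = 42L) {
  if (is.character(spec)) spec <- preset_spec(spec)
  stopifnot(inherits(spec, "network_spec"))
  nd <- spec$ndim
  f <- spec$filters
  L <- length(f) - 1L
  drop_enc <- spec$dropout
  se_on <- spec$se_mode != "none"

  build <- function() {
    st <- list(nodes = list(), params = list(), state = list(), last = 0L, spec = spec)
    st <- .add_node(st, "input")
    x_id <- st$last
    cin <- 1L
    skips <- integer(L)
    skip_ch <- integer(L)
    pool_factors <- vector("list", L)
    for (l in seq_len(L)) {
      st <- .add_block(st, x_id, cin, f[l], drop_enc[l], spec, sprintf("enc%d", l))
      if (se_on) st <- .add_se(st, st$last, f[l], spec$se_ratio, sprintf("enc%d", l))
      skips[l] <- st$last
      skip_ch[l] <- f[l]
      pf <- if (nd == 2L) c(2L, 2L) else c(if (spec$z_down[l]) 2L else 1L, 2L, 2L)
      pool_factors[[l]] <- pf
      st <- .add_node(st, "pool", st$last, factors = pf)
      x_id <- st$last
      cin <- f[l]
    }
    st <- .add_block(st, x_id, cin, f[L + 1L], drop_enc[L + 1L], spec, "bottleneck")
    if (spec$se_mode == "every_conv") {
      st <- .add_se(st, st$last, f[L + 1L], spec$se_ratio, "bottleneck")
    }
    cur <- st$last
    ccur <- f[L + 1L]
    for (l in rev(seq_len(L))) {
      tag <- sprintf("dec%d", l)
      pt <- .new_convt_par(st, paste0(tag, ".up"), pool_factors[[l]], ccur, f[l], spec$kernel_init)
      st <- pt$st
      st <- .add_node(st, "convt", cur, W = pt$W, b = pt$b, factors = pool_factors[[l]])
      up_id <- st$last
      skip_id <- skips[l]
      if (spec$attention_gates) {
        st <- .add_attn(st, skip_id, up_id, skip_ch[l], f[l], tag)
        skip_id <- st$last
      }
      st <- .add_node(st, "concat", c(skip_id, up_id), ca = skip_ch[l])
      st <- .add_block(st, st$last, skip_ch[l] + f[l], f[l], drop_enc[l], spec, tag)
      if (se_on) st <- .add_se(st, st$last, f[l], spec$se_ratio, tag)
      cur <- st$last
      ccur <- f[l]
    }
    ph <- .new_conv_par(st, "head", 1L, nd, f[1L], spec$out_channels, spec$kernel_init)
    st <- ph$st
    st <- .add_node(st, "conv", cur, W = ph$W, b = ph$b, k = 1L)
    logit_id <- st$last
    st <- .add_node(st, "act", logit_id, kind = "sigmoid")
    st$logit_id <- logit_id
    st$out_id <- st$last
    st
  }
  st <- withr::with_seed(as.integer(seed), build())

  down <- rep(1L, nd)
  for (l in seq_len(L)) {
    pf <- if (nd == 2L) c(2L, 2L) else c(if (spec$z_down[l]) 2L else 1L, 2L, 2L)
    down <- down * pf
  }
  structure(
    list(
      spec = spec, seed = as.integer(seed), nodes = st$nodes,
      params = st$params, state = st$state,
      logit_id = st$logit_id, out_id = st$out_id, down_factor = down
    ),
    class = "em_network"
  )
}

#' @export
print.em_network <- function(x, ...) {
  cat(sprintf(
    "<em_network> %dD %s, filters %s, %s trainable parameters (seed %d)\n",
    x$spec$ndim,
    if (x$spec$attention_gates) "attention U-Net" else paste0(x$spec$block_kind, " U-Net"),
    paste(x$spec$filters, collapse = "-"),
    format(sum(vapply(x$params, length, 1L)), big.mark = ","), x$seed
  ))
  invisible(x)
}

.check_patch <- function(model, x) {
  nd <- model$spec$ndim
  if (length(dim(x) %||% c(nrow(x), ncol(x))) < nd) stop("patch dimensionality mismatch")
  sp <- dim(x)[seq_len(nd)]
  bad <- sp %% model$down_factor != 0
  if (any(bad)) {
    stop(sprintf(
      "patch shape (%s) must be divisible by the network's downsampling factor (%s) along each axis",
      paste(sp, collapse = "x"), paste(model$down_factor, collapse = "x")
    ))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Runs the graph. x: spatial array without channel axis. train=TRUE keeps the
# caches needed by backward_network and samples dropout from the current RNG.
forward_network <- function(model, x, train = FALSE) {
  x <- as.array(x)
  .check_patch(model, x)
  dim(x) <- c(dim(x), 1L)
  P <- model$params
  vals <- vector("list", length(model$nodes))
  caches <- if (train) vector("list", length(model$nodes)) else NULL
  for (id in seq_along(model$nodes)) {
    nd <- model$nodes[[id]]
    inp <- nd$inputs
    vals[[id]] <- switch(nd$op,
      input = x,
      conv = {
        r <- conv_fwd(vals[[inp]], P[[nd$W]], P[[nd$b]], nd$k, train)
        if (train) caches[[id]] <- r$cache
        r$y
      },
      convt = {
        r <- convt_fwd(vals[[inp]], P[[nd$W]], P[[nd$b]], nd$factors, train)
        if (train) caches[[id]] <- r$cache
        r$y
      },
      pool = {
        r <- maxpool_fwd(vals[[inp]], nd$factors, train)
        if (train) caches[[id]] <- r$cache
        r$y
      },
      act = act_fwd(vals[[inp]], nd$kind),
      dropout = {
        r <- dropout_fwd(vals[[inp]], nd$rate, train)
        if (train) caches[[id]] <- r$cache
        r$y
      },
      concat = concat_fwd(vals[[inp[1L]]], vals[[inp[2L]]]),
      add = vals[[inp[1L]]] + vals[[inp[2L]]],
      bnorm = {
        sn <- nd$stat
        r <- bnorm_fwd(
          vals[[inp]], P[[nd$gamma]], P[[nd$beta]],
          model$state[[paste0(sn, ".mean")]], model$state[[paste0(sn, ".var")]],
          train
        )
        if (train) {
          caches[[id]] <- r$cache
          model$state[[paste0(sn, ".mean")]] <- r$run_mean
          model$state[[paste0(sn, ".var")]] <- r$run_var
        }
        r$y
      },
      se = {
        xin <- vals[[inp]]
        g <- gmean_fwd(xin)
        h1 <- dense_fwd(g, P[[nd$W1]], P[[nd$b1]])
        h <- pmax(h1, 0)
        s1 <- dense_fwd(h, P[[nd$W2]], P[[nd$b2]])
        s <- 1 / (1 + exp(-s1))
        if (train) caches[[id]] <- list(g = g, h = h, s = s, xdim = dim(xin))
        scalech_fwd(xin, s)
      },
      attn = {
        xin <- vals[[inp[1L]]]
        gin <- vals[[inp[2L]]]
        rx <- conv_fwd(xin, P[[nd$Wx]], P[[nd$bx]], 1L, train)
        rg <- conv_fwd(gin, P[[nd$Wg]], P[[nd$bg]], 1L, train)
        a <- rx$y + rg$y
        r <- pmax(a, 0)
        rp <- conv_fwd(r, P[[nd$Wp]], P[[nd$bp]], 1L, train)
        m <- 1 / (1 + exp(-rp$y))
        if (train) {
          caches[[id]] <- list(cx = rx$cache, cg = rg$cache, cp = rp$cache, r = r, m = m)
        }
        mulmap_fwd(xin, m)
      },
      stop("unknown op: ", nd$op)
    )
  }
  list(vals = vals, caches = caches, out = vals[[model$out_id]], logit = vals[[model$logit_id]], model = model)
}

#' Apply a network to a single patch
#'
#' @param model An `em_network` from [build_network()], or any function taking
#'   a patch and returning a probability array of the same shape (useful as a
#'   stub in tests and pipelines).
#' @param patch Numeric array (2D or 3D, no channel axis), values in `[0, 1]`.
#' @return Probability array of the same spatial shape.
#' @export
predict_patch <- function(model, patch) {
  if (is.function(model)) {
    return(model(patch))
  }
  stopifnot(inherits(model, "em_network"))
  out <- forward_network(model, patch, train = FALSE)$out
  d <- dim(out)
  if (d[length(d)] == 1L) dim(out) <- d[-length(d)]
  out
}

# Backward pass. dlogit: gradient of the loss w.r.t. the pre-sigmoid output
# (same dims as the head conv output). Returns named gradient list matching
# model$params.
backward_network <- function(fwd, dlogit) {
  model <- fwd$model
  P <- model$params
  grads <- lapply(P, function(p) array(0, dim(p) %||% length(p)))
  dvals <- vector("list", length(model$nodes))
  dvals[[model$logit_id]] <- dlogit
  acc <- function(nm, g) {
    gg <- grads[[nm]]
    grads[[nm]] <<- gg + array(as.vector(g), dim(gg) %||% length(gg))
  }
  push <- function(id, g) {
    if (is.null(dvals[[id]])) dvals[[id]] <<- g else dvals[[id]] <<- dvals[[id]] + g
  }
  for (id in rev(seq_len(model$logit_id))) {
    dy <- dvals[[id]]
    if (is.null(dy)) next
    nd <- model$nodes[[id]]
    inp <- nd$inputs
    switch(nd$op,
      input = NULL,
      conv = {
        g <- conv_bwd(dy, fwd$caches[[id]], P[[nd$W]])
        acc(nd$W, g$dW)
        acc(nd$b, g$db)
        push(inp, g$dx)
      },
      convt = {
        g <- convt_bwd(dy, fwd$caches[[id]], P[[nd$W]])
        acc(nd$W, g$dW)
        acc(nd$b, g$db)
        push(inp, g$dx)
      },
      pool = push(inp, maxpool_bwd(dy, fwd$caches[[id]])),
      act = push(inp, act_bwd(dy, fwd$vals[[id]], nd$kind)),
      dropout = push(inp, dropout_bwd(dy, fwd$caches[[id]])),
      concat = {
        g <- concat_bwd(dy, nd$ca)
        push(inp[1L], g$da)
        push(inp[2L], g$db)
      },
      add = {
        push(inp[1L], dy)
        push(inp[2L], dy)
      },
      bnorm = {
        g <- bnorm_bwd(dy, fwd$caches[[id]], P[[nd$gamma]])
        acc(nd$gamma, g$dgamma)
        acc(nd$beta, g$dbeta)
        push(inp, g$dx)
      },
      se = {
        ch <- fwd$caches[[id]]
        xin <- fwd$vals[[inp]]
        g1 <- scalech_bwd(dy, xin, ch$s)
        ds1 <- g1$ds * ch$s * (1 - ch$s)
        g2 <- dense_bwd(ds1, ch$h, P[[nd$W2]])
        acc(nd$W2, g2$dW)
        acc(nd$b2, g2$db)
        dh <- g2$dv * (ch$h > 0)
        g3 <- dense_bwd(dh, ch$g, P[[nd$W1]])
        acc(nd$W1, g3$dW)
        acc(nd$b1, g3$db)
        push(inp, g1$dx + gmean_bwd(g3$dv, ch$xdim))
      },
      attn = {
        ch <- fwd$caches[[id]]
        xin <- fwd$vals[[inp[1L]]]
        g1 <- mulmap_bwd(dy, xin, ch$m)
        dp <- g1$dm * ch$m * (1 - ch$m)
        gp <- conv_bwd(dp, ch$cp, P[[nd$Wp]])
        acc(nd$Wp, gp$dW)
        acc(nd$bp, gp$db)
        da <- gp$dx * (ch$r > 0)
        gx <- conv_bwd(da, ch$cx, P[[nd$Wx]])
        acc(nd$Wx, gx$dW)
        acc(nd$bx, gx$db)
        gg <- conv_bwd(da, ch$cg, P[[nd$Wg]])
        acc(nd$Wg, gg$dW)
        acc(nd$bg, gg$db)
        push(inp[1L], g1$dx + gx$dx)
        push(inp[2L], gg$dx)
      },
      stop("unknown op in backward: ", nd$op)
    )
  }
  grads
}
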