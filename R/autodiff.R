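# Minimal reverse-mode tape over channel-first (C, H, W, N) arrays.
#
# A forward pass builds a tape of primitive nodes (define-by-run); backward
# walks the tape in reverse and accumulates gradients for every named
# parameter.  Parameters live in an environment keyed by hierarchical names
# ("enc.s2.b1.conv1.W"); when a context is created with init = TRUE, missing
# parameters are created on first use, so one dummy forward pass initializes
# the whole network.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_ctx <- function(params = new.env(parent = emptyenv()),
                    bn_state = new.env(parent = emptyenv()),
                    training = FALSE, init = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- list()
  ctx$params <- params
  ctx$bn_state <- bn_state
  ctx$training <- training
  ctx$init <- init
  ctx
}

node_val <- function(ctx, id) {
  force(id)  # promises may append nodes; force before reading the tape
  ctx$nodes[[id]]$value
}

add_node <- function(ctx, op, value, inputs = integer(), pnames = character(),
                     cache = NULL) {
  id <- length(ctx$nodes) + 1L
  ctx$nodes[[id]] <- list(op = op, value = value, inputs = inputs,
                          pnames = pnames, cache = cache)
  id
}

need_param <- function(ctx, name, init_fn) {
  if (!exists(name, envir = ctx$params, inherits = FALSE)) {
    if (!isTRUE(ctx$init)) stop("unknown parameter: ", name)
    assign(name, init_fn(), envir = ctx$params)
  }
  get(name, envir = ctx$params, inherits = FALSE)
}

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays")
  if (length(d) == 2L) x <- array(x, c(1L, d))        # H x W -> 1 x H x W x 1
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d, 1L))        # C x H x W -> + batch
  if (length(dim(x)) != 4L) stop("expected (C, H, W, N) array")
  x
}

op_input <- function(ctx, x) add_node(ctx, "input", as_batch(x))

op_conv <- function(ctx, xid, name, cout, k = 3L, stride = 1L,
                    pad = (k - 1L) %/% 2L) {
  x <- node_val(ctx, xid)
  cin <- dim(x)[1]
  W <- need_param(ctx, paste0(name, ".W"), function() {
    matrix(he_uniform(cout * cin * k * k, cin * k * k), cout, cin * k * k)
  })
  b <- need_param(ctx, paste0(name, ".b"), function() numeric(cout))
  if (ncol(W) != cin * k * k)
    stop(name, ": channel mismatch (input has ", cin, " channels)")
  y <- .conv2d_fwd(x, W, b, as.integer(k), as.integer(stride), as.integer(pad))
  add_node(ctx, "conv", y, xid, paste0(name, c(".W", ".b")),
           cache = list(k = k, stride = stride, pad = pad))
}

op_convt <- function(ctx, xid, name, cout, k = 3L, stride = 2L, pad = 1L) {
  x <- node_val(ctx, xid)
  cin <- dim(x)[1]
  W <- need_param(ctx, paste0(name, ".W"), function() {
    matrix(he_uniform(cin * cout * k * k, cin * k * k), cin, cout * k * k)
  })
  b <- need_param(ctx, paste0(name, ".b"), function() numeric(cout))
  y <- .convt2d_fwd(x, W, b, as.integer(k), as.integer(stride), as.integer(pad))
  add_node(ctx, "convt", y, xid, paste0(name, c(".W", ".b")),
           cache = list(k = k, stride = stride, pad = pad))
}

op_bn <- function(ctx, xid, name) {
  x <- node_val(ctx, xid)
  C <- dim(x)[1]
  gamma <- need_param(ctx, paste0(name, ".gamma"), function() rep(1, C))
  beta <- need_param(ctx, paste0(name, ".beta"), function() numeric(C))
  if (!exists(name, envir = ctx$bn_state, inherits = FALSE))
    assign(name, list(mean = numeric(C), var = rep(1, C)), envir = ctx$bn_state)
  rs <- get(name, envir = ctx$bn_state, inherits = FALSE)
  xm <- matrix(x, nrow = C)
  m <- ncol(xm)
  if (isTRUE(ctx$training)) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    ub <- if (m > 1) v * m / (m - 1) else v
    assign(name, list(mean = (1 - BN_MOMENTUM) * rs$mean + BN_MOMENTUM * mu,
                      var = (1 - BN_MOMENTUM) * rs$var + BN_MOMENTUM * ub),
           envir = ctx$bn_state)
  } else {
    mu <- rs$mean
    v <- rs$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * inv
  y <- array(gamma * xhat + beta, dim(x))
  add_node(ctx, "bn", y, xid, paste0(name, c(".gamma", ".beta")),
           cache = list(xhat = xhat, inv = inv, m = m,
                        training = isTRUE(ctx$training)))
}

op_relu <- function(ctx, xid) {
  x <- node_val(ctx, xid)
  add_node(ctx, "relu", x * (x > 0), xid)
}

op_sigmoid <- function(ctx, xid) {
  x <- node_val(ctx, xid)
  add_node(ctx, "sigmoid", 1 / (1 + exp(-x)), xid)
}

# Global average pooling: (C, H, W, N) -> (C, N).
op_gap <- function(ctx, xid) {
  x <- node_val(ctx, xid)
  d <- dim(x)
  a <- array(x, c(d[1], d[2] * d[3], d[4]))
  y <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) y[, n] <- rowMeans(matrix(a[, , n], nrow = d[1]))
  add_node(ctx, "gap", y, xid, cache = list(dims = d))
}

op_dense <- function(ctx, vid, name, cout) {
  v <- node_val(ctx, vid)
  cin <- nrow(v)
  W <- need_param(ctx, paste0(name, ".W"), function() {
    matrix(he_uniform(cout * cin, cin), cout, cin)
  })
  b <- need_param(ctx, paste0(name, ".b"), function() numeric(cout))
  add_node(ctx, "dense", W %*% v + b, vid, paste0(name, c(".W", ".b")))
}

# Channel-wise recalibration: x (C,H,W,N) scaled by gate s (C,N).
op_scale_ch <- function(ctx, xid, sid) {
  x <- node_val(ctx, xid)
  s <- node_val(ctx, sid)
  d <- dim(x)
  y <- x
  for (n in seq_len(d[4])) y[, , , n] <- x[, , , n] * s[, n]
  add_node(ctx, "scale_ch", y, c(xid, sid))
}

op_add <- function(ctx, aid, bid) {
  a <- node_val(ctx, aid)
  b <- node_val(ctx, bid)
  if (!identical(dim(a), dim(b))) stop("add: shape mismatch")
  add_node(ctx, "add", a + b, c(aid, bid))
}

op_concat <- function(ctx, aid, bid) {
  a <- node_val(ctx, aid)
  b <- node_val(ctx, bid)
  da <- dim(a); db <- dim(b)
  if (!identical(da[-1], db[-1])) stop("concat: spatial/batch mismatch")
  y <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  y[seq_len(da[1]), , , ] <- a
  y[da[1] + seq_len(db[1]), , , ] <- b
  add_node(ctx, "concat", y, c(aid, bid), cache = list(c1 = da[1]))
}

op_dropout <- function(ctx, xid, rate) {
  x <- node_val(ctx, xid)
  if (!isTRUE(ctx$training) || rate <= 0)
    return(add_node(ctx, "dropout", x, xid, cache = list(mask = NULL)))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  add_node(ctx, "dropout", x * mask, xid, cache = list(mask = mask))
}

# Backward pass from node `out` seeded with dL/d(out).  Returns an
# environment of parameter gradients; node gradients for requested leaf ids
# are attached as attribute "wrt".
tape_backward <- function(ctx, out, seed, wrt = integer()) {
  n <- length(ctx$nodes)
  g <- vector("list", n)
  g[[out]] <- seed
  pg <- new.env(parent = emptyenv())
  padd <- function(name, val) {
    cur <- if (exists(name, envir = pg, inherits = FALSE))
      get(name, envir = pg, inherits = FALSE) else 0
    assign(name, cur + val, envir = pg)
  }
  gadd <- function(id, val) {
    g[[id]] <<- if (is.null(g[[id]])) val else g[[id]] + val
  }
  for (id in rev(seq_len(n))) {
    dy <- g[[id]]
    if (is.null(dy)) next
    nd <- ctx$nodes[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        x <- node_val(ctx, nd$inputs[1])
        W <- get(nd$pnames[1], envir = ctx$params)
        cc <- nd$cache
        r <- .conv2d_bwd(x, W, dy, as.integer(cc$k), as.integer(cc$stride),
                         as.integer(cc$pad))
        gadd(nd$inputs[1], r$dx)
        padd(nd$pnames[1], r$dW)
        padd(nd$pnames[2], r$db)
      },
      convt = {
        x <- node_val(ctx, nd$inputs[1])
        W <- get(nd$pnames[1], envir = ctx$params)
        cc <- nd$cache
        r <- .convt2d_bwd(x, W, dy, as.integer(cc$k), as.integer(cc$stride),
                          as.integer(cc$pad))
        gadd(nd$inputs[1], r$dx)
        padd(nd$pnames[1], r$dW)
        padd(nd$pnames[2], r$db)
      },
      bn = {
        cc <- nd$cache
        C <- nrow(cc$xhat)
        gamma <- get(nd$pnames[1], envir = ctx$params)
        dym <- matrix(dy, nrow = C)
        dgamma <- rowSums(dym * cc$xhat)
        dbeta <- rowSums(dym)
        dx <- if (cc$training) {
          (gamma * cc$inv / cc$m) *
            (cc$m * dym - dbeta - cc$xhat * dgamma)
        } else {
          dym * (gamma * cc$inv)
        }
        x <- node_val(ctx, nd$inputs[1])
        gadd(nd$inputs[1], array(dx, dim(x)))
        padd(nd$pnames[1], dgamma)
        padd(nd$pnames[2], dbeta)
      },
      relu = {
        x <- node_val(ctx, nd$inputs[1])
        gadd(nd$inputs[1], dy * (x > 0))
      },
      sigmoid = {
        y <- nd$value
        gadd(nd$inputs[1], dy * y * (1 - y))
      },
      gap = {
        d <- nd$cache$dims
        hw <- d[2] * d[3]
        dx <- array(0, d)
        for (nn in seq_len(d[4]))
          dx[, , , nn] <- array(rep(dy[, nn] / hw, hw), d[1:3])
        gadd(nd$inputs[1], dx)
      },
      dense = {
        v <- node_val(ctx, nd$inputs[1])
        W <- get(nd$pnames[1], envir = ctx$params)
        gadd(nd$inputs[1], crossprod(W, dy))
        padd(nd$pnames[1], tcrossprod(dy, v))
        padd(nd$pnames[2], rowSums(dy))
      },
      scale_ch = {
        x <- node_val(ctx, nd$inputs[1])
        s <- node_val(ctx, nd$inputs[2])
        d <- dim(x)
        dx <- x
        ds <- matrix(0, d[1], d[4])
        for (nn in seq_len(d[4])) {
          dx[, , , nn] <- dy[, , , nn] * s[, nn]
          ds[, nn] <- rowSums(matrix(dy[, , , nn] * x[, , , nn], nrow = d[1]))
        }
        gadd(nd$inputs[1], dx)
        gadd(nd$inputs[2], ds)
      },
      add = {
        gadd(nd$inputs[1], dy)
        gadd(nd$inputs[2], dy)
      },
      concat = {
        c1 <- nd$cache$c1
        d <- dim(nd$value)
        gadd(nd$inputs[1], dy[seq_len(c1), , , , drop = FALSE])
        gadd(nd$inputs[2], dy[c1 + seq_len(d[1] - c1), , , , drop = FALSE])
      },
      dropout = {
        mask <- nd$cache$mask
        gadd(nd$inputs[1], if (is.null(mask)) dy else dy * mask)
      },
      stop("no backward rule for op ", nd$op)
    )
  }
  attr(pg, "wrt") <- g[wrt]
  pg
}
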