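# Computational-graph engine for the residual-attention U-Net.
#
# A model is a static DAG of typed nodes over 5D tensors (D, H, W, C, N).
# 2D networks are the same machinery with a singleton slice axis and
# (1, k, k) kernels, so one conv/pool/upconv implementation serves both the
# slice-wise liver model and the 3D patch models. Forward in training mode
# retains every node output so the reverse sweep can compute exact gradients.

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

add_node <- function(g, op, inputs = integer(0), params = character(0),
                     cfg = list()) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(id = id, op = op, inputs = as.integer(inputs),
                        params = params, cfg = cfg)
  id
}

# parameter initialisers ------------------------------------------------------

init_conv_w <- function(kernel, cin, cout) {
  fan_in <- prod(kernel) * cin
  array(rnorm(prod(kernel) * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kernel, cin, cout))
}

# graph-construction helpers used by build_network ----------------------------

gadd_conv <- function(g, params, input, kernel, cin, cout, name) {
  params[[paste0(name, ".w")]] <- init_conv_w(kernel, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  id <- add_node(g, "conv", input,
                 params = c(paste0(name, ".w"), paste0(name, ".b")),
                 cfg = list(kernel = kernel, cin = cin, cout = cout))
  list(id = id, params = params)
}

gadd_upconv <- function(g, params, input, factor, cin, cout, name) {
  fan_in <- cin
  params[[paste0(name, ".w")]] <-
    array(rnorm(prod(factor) * cin * cout, sd = sqrt(2 / fan_in)),
          dim = c(factor, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  id <- add_node(g, "upconv", input,
                 params = c(paste0(name, ".w"), paste0(name, ".b")),
                 cfg = list(factor = factor, cin = cin, cout = cout))
  list(id = id, params = params)
}

gadd_bn <- function(g, params, state, input, c, name) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- numeric(c)
  state[[paste0(name, ".rm")]] <- numeric(c)
  state[[paste0(name, ".rv")]] <- rep(1, c)
  id <- add_node(g, "bn", input,
                 params = c(paste0(name, ".gamma"), paste0(name, ".beta")),
                 cfg = list(c = c, state = name, momentum = 0.1, eps = 1e-5))
  list(id = id, params = params, state = state)
}

# Pre-activation bottleneck residual block: three stacks of
# batchnorm -> ReLU -> convolution (kernel pattern 1, k, 1; internal width
# cout / bottleneck_factor) plus an identity skip, with a 1x1 projection on
# the skip when the channel count changes.
gadd_residual_block <- function(g, params, state, input, cin, cout, kernel,
                                bottleneck, name) {
  m <- max(1L, as.integer(round(cout / bottleneck)))
  one <- rep(1L, 3)
  r <- gadd_bn(g, params, state, input, cin, paste0(name, ".bn1"))
  params <- r$params; state <- r$state
  a1 <- add_node(g, "relu", r$id)
  r <- gadd_conv(g, params, a1, one, cin, m, paste0(name, ".conv1"))
  params <- r$params
  r2 <- gadd_bn(g, params, state, r$id, m, paste0(name, ".bn2"))
  params <- r2$params; state <- r2$state
  a2 <- add_node(g, "relu", r2$id)
  r <- gadd_conv(g, params, a2, kernel, m, m, paste0(name, ".conv2"))
  params <- r$params
  r3 <- gadd_bn(g, params, state, r$id, m, paste0(name, ".bn3"))
  params <- r3$params; state <- r3$state
  a3 <- add_node(g, "relu", r3$id)
  r <- gadd_conv(g, params, a3, one, m, cout, paste0(name, ".conv3"))
  params <- r$params
  main <- r$id
  if (cin == cout) {
    skip <- input
  } else {
    r <- gadd_conv(g, params, input, one, cin, cout, paste0(name, ".proj"))
    params <- r$params
    skip <- r$id
  }
  out <- add_node(g, "add", c(main, skip))
  list(id = out, params = params, state = state)
}

# Attention block on a skip connection: a trunk branch (one residual block)
# is gated by a soft mask branch that pools the feature map, processes it
# with its own residual block, restores resolution with a learned transposed
# convolution and squashes to (0, 1); the output is (1 + mask) * trunk.
gadd_attention_block <- function(g, params, state, input, c, kernel, pool,
                                 bottleneck, name) {
  r <- gadd_residual_block(g, params, state, input, c, c, kernel, bottleneck,
                           paste0(name, ".trunk"))
  params <- r$params; state <- r$state
  trunk <- r$id
  p <- add_node(g, "maxpool", input, cfg = list(factor = pool))
  r <- gadd_residual_block(g, params, state, p, c, c, kernel, bottleneck,
                           paste0(name, ".mask"))
  params <- r$params; state <- r$state
  r <- gadd_upconv(g, params, r$id, pool, c, c, paste0(name, ".maskup"))
  params <- r$params
  r <- gadd_conv(g, params, r$id, rep(1L, 3), c, c, paste0(name, ".maskconv"))
  params <- r$params
  m <- add_node(g, "sigmoid", r$id)
  out <- add_node(g, "attn", c(trunk, m))
  list(id = out, params = params, state = state)
}

# forward / backward ----------------------------------------------------------

bn_forward <- function(x, gamma, beta, rm, rv, eps, training) {
  if (training) {
    st <- cpp_channel_stats(x)
    mu <- st$mu
    va <- st$va
  } else {
    mu <- rm
    va <- rv
  }
  invstd <- 1 / sqrt(va + eps)
  r <- cpp_bn_apply(x, mu, invstd, gamma, beta)
  list(out = r$out, xhat = r$xhat, invstd = invstd, mu = mu, va = va)
}

bn_backward <- function(dy, xhat, invstd, gamma) {
  cpp_bn_bw(dy, xhat, gamma, invstd)
}

forward_graph <- function(model, x, training = FALSE, keep = FALSE) {
  nodes <- model$nodes
  params <- model$params
  state <- model$state
  vals <- vector("list", length(nodes))
  extras <- vector("list", length(nodes))
  # inference does not need retained activations: free each node's output
  # as soon as its last consumer has run, keeping peak memory near the
  # widest single layer instead of the whole graph
  last_use <- NULL
  if (!keep) {
    last_use <- integer(length(nodes))
    for (nd in nodes)
      for (j in nd$inputs) last_use[j] <- max(last_use[j], nd$id)
    last_use[model$output_id] <- length(nodes) + 1L
  }
  for (nd in nodes) {
    v <- switch(nd$op,
      input = x,
      conv = cpp_conv3d_fw(vals[[nd$inputs]], params[[nd$params[1]]],
                           params[[nd$params[2]]]),
      upconv = cpp_upconv_fw(vals[[nd$inputs]], params[[nd$params[1]]],
                             params[[nd$params[2]]]),
      bn = {
        nm <- nd$cfg$state
        r <- bn_forward(vals[[nd$inputs]], params[[nd$params[1]]],
                        params[[nd$params[2]]],
                        state[[paste0(nm, ".rm")]],
                        state[[paste0(nm, ".rv")]],
                        nd$cfg$eps, training)
        if (training) {
          mom <- nd$cfg$momentum
          state[[paste0(nm, ".rm")]] <-
            (1 - mom) * state[[paste0(nm, ".rm")]] + mom * r$mu
          state[[paste0(nm, ".rv")]] <-
            (1 - mom) * state[[paste0(nm, ".rv")]] + mom * r$va
        }
        extras[[nd$id]] <- r[c("xhat", "invstd")]
        r$out
      },
      relu = {
        v <- vals[[nd$inputs]]
        v[v < 0] <- 0
        v
      },
      sigmoid = 1 / (1 + exp(-vals[[nd$inputs]])),
      maxpool = {
        r <- cpp_maxpool_fw(vals[[nd$inputs]], as.integer(nd$cfg$factor))
        extras[[nd$id]] <- list(idx = r$idx, xdim = dim(vals[[nd$inputs]]))
        r$out
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      concat = {
        a <- vals[[nd$inputs[1]]]; b <- vals[[nd$inputs[2]]]
        da <- dim(a); db <- dim(b)
        out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
        pa <- prod(da[1:3])
        for (n in seq_len(da[5])) {
          off <- (n - 1) * pa * (da[4] + db[4])
          out[off + seq_len(pa * da[4])] <-
            a[(n - 1) * pa * da[4] + seq_len(pa * da[4])]
          out[off + pa * da[4] + seq_len(pa * db[4])] <-
            b[(n - 1) * pa * db[4] + seq_len(pa * db[4])]
        }
        out
      },
      attn = vals[[nd$inputs[1]]] * (1 + vals[[nd$inputs[2]]]),
      stop_raunet(paste("unknown op", nd$op), "raunet_internal")
    )
    vals[[nd$id]] <- v
    if (!keep) {
      extras[nd$id] <- list(NULL)
      for (j in nd$inputs)
        if (last_use[j] <= nd$id) vals[j] <- list(NULL)
    }
  }
  out <- vals[[model$output_id]]
  if (!keep) vals <- NULL
  list(out = out, vals = vals, extras = extras, state = state)
}

backward_graph <- function(model, fwd, dout) {
  nodes <- model$nodes
  params <- model$params
  vals <- fwd$vals
  extras <- fwd$extras
  grads_node <- vector("list", length(nodes))
  grads_par <- list()
  grads_node[[model$output_id]] <- dout

  acc <- function(slot, g) {
    if (is.null(grads_node[[slot]])) g else grads_node[[slot]] + g
  }

  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- grads_node[[i]]
    if (is.null(dy)) next
    switch(nd$op,
      input = NULL,
      conv = {
        r <- cpp_conv3d_bw(vals[[nd$inputs]], params[[nd$params[1]]], dy)
        grads_par[[nd$params[1]]] <-
          (grads_par[[nd$params[1]]] %||% 0) + r$dw
        grads_par[[nd$params[2]]] <-
          (grads_par[[nd$params[2]]] %||% 0) + r$db
        grads_node[[nd$inputs]] <- acc(nd$inputs, r$dx)
      },
      upconv = {
        r <- cpp_upconv_bw(vals[[nd$inputs]], params[[nd$params[1]]], dy)
        grads_par[[nd$params[1]]] <-
          (grads_par[[nd$params[1]]] %||% 0) + r$dw
        grads_par[[nd$params[2]]] <-
          (grads_par[[nd$params[2]]] %||% 0) + r$db
        grads_node[[nd$inputs]] <- acc(nd$inputs, r$dx)
      },
      bn = {
        e <- extras[[i]]
        r <- bn_backward(dy, e$xhat, e$invstd, params[[nd$params[1]]])
        grads_par[[nd$params[1]]] <-
          (grads_par[[nd$params[1]]] %||% 0) + r$dgamma
        grads_par[[nd$params[2]]] <-
          (grads_par[[nd$params[2]]] %||% 0) + r$dbeta
        grads_node[[nd$inputs]] <- acc(nd$inputs, r$dx)
      },
      relu = {
        g <- dy
        g[vals[[nd$inputs]] <= 0] <- 0
        grads_node[[nd$inputs]] <- acc(nd$inputs, g)
      },
      sigmoid = {
        s <- vals[[i]]
        grads_node[[nd$inputs]] <- acc(nd$inputs, dy * s * (1 - s))
      },
      maxpool = {
        e <- extras[[i]]
        grads_node[[nd$inputs]] <-
          acc(nd$inputs, cpp_maxpool_bw(e$idx, dy, as.integer(e$xdim)))
      },
      add = {
        grads_node[[nd$inputs[1]]] <- acc(nd$inputs[1], dy)
        grads_node[[nd$inputs[2]]] <- acc(nd$inputs[2], dy)
      },
      concat = {
        da <- dim(vals[[nd$inputs[1]]])
        db <- dim(vals[[nd$inputs[2]]])
        pa <- prod(da[1:3])
        ga <- array(0, da)
        gb <- array(0, db)
        for (n in seq_len(da[5])) {
          off <- (n - 1) * pa * (da[4] + db[4])
          ga[(n - 1) * pa * da[4] + seq_len(pa * da[4])] <-
            dy[off + seq_len(pa * da[4])]
          gb[(n - 1) * pa * db[4] + seq_len(pa * db[4])] <-
            dy[off + pa * da[4] + seq_len(pa * db[4])]
        }
        grads_node[[nd$inputs[1]]] <- acc(nd$inputs[1], ga)
        grads_node[[nd$inputs[2]]] <- acc(nd$inputs[2], gb)
      },
      attn = {
        trunk <- vals[[nd$inputs[1]]]
        mask <- vals[[nd$inputs[2]]]
        grads_node[[nd$inputs[1]]] <- acc(nd$inputs[1], dy * (1 + mask))
        grads_node[[nd$inputs[2]]] <- acc(nd$inputs[2], dy * trunk)
      }
    )
    grads_node[i] <- list(NULL) # free as we go (keep list length intact)
  }
  grads_par
}
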