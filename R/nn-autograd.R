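# Minimal reverse-mode automatic differentiation on numeric arrays.
#
# A computation graph node is an environment holding `value` (numeric
# array/matrix/vector), `parents` (list of nodes), `backfn` (maps the
# node's gradient to a list of parent gradients, positionally aligned) and
# an accumulated `grad`. Graphs are rebuilt every forward pass; parameter
# nodes persist across passes and collect gradients until zeroed.
# Tensors use channel-major layout: (C, L, N) = channels x positions x batch.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

.ag_next_id <- function() {
  .ag_env$counter <- .ag_env$counter + 1L
  .ag_env$counter
}

ag_node <- function(value, parents = list(), backfn = NULL, param = FALSE,
                    name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$param <- param
  e$name <- name
  e$id <- .ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_param <- function(value, name = NULL) ag_node(value, param = TRUE, name = name)
ag_const <- function(value) ag_node(value)

ag_is_node <- function(x) inherits(x, "ag_node")
ag_value <- function(x) if (ag_is_node(x)) x$value else x

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# reverse-accumulation from a scalar loss node
ag_backward <- function(loss) {
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- vector("list", 256L)
  stack[[1L]] <- list(n = loss, done = FALSE)
  n_stack <- 1L
  while (n_stack > 0L) {
    top <- stack[[n_stack]]
    n_stack <- n_stack - 1L
    if (top$done) {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- top$n
      next
    }
    key <- as.character(top$n$id)
    if (!is.null(visited[[key]])) next
    visited[[key]] <- TRUE
    n_stack <- n_stack + 1L
    if (n_stack > length(stack)) stack <- c(stack, vector("list", length(stack)))
    stack[[n_stack]] <- list(n = top$n, done = TRUE)
    for (p in top$n$parents) {
      if (is.null(visited[[as.character(p$id)]])) {
        n_stack <- n_stack + 1L
        if (n_stack > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[n_stack]] <- list(n = p, done = FALSE)
      }
    }
  }
  loss$grad <- if (length(loss$value) == 1) 1 else array(1, dim = dim(loss$value))
  for (i in rev(seq_len(n_topo))) {
    n <- topo[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

## ---- elementwise and linear-algebra primitives -------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(g) list(g * k))
}

ag_const_add <- function(a, k) {
  ag_node(a$value + k, list(a), function(g) list(g))
}

# W %*% x + b, x a matrix (columns = batch), b a vector
ag_affine <- function(W, x, b) {
  Wv <- W$value; xv <- x$value
  ag_node(Wv %*% xv + b$value, list(W, x, b), function(g) {
    list(g %*% t(xv), crossprod(Wv, g), rowSums(g))
  })
}

ag_rowbind <- function(a, b) {
  na <- nrow(a$value)
  ag_node(rbind(a$value, b$value), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[-seq_len(na), , drop = FALSE])
  })
}

ag_rows <- function(x, idx) {
  dims <- dim(x$value)
  ag_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, dims[1], dims[2])
    out[idx, ] <- g
    list(out)
  })
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_tanh <- function(x) {
  y <- tanh(x$value)
  ag_node(y, list(x), function(g) list(g * (1 - y^2)))
}

ag_leaky_relu <- function(x, slope = 0.01) {
  xv <- x$value
  y <- ifelse(xv > 0, xv, slope * xv)
  ag_node(y, list(x), function(g) list(g * ifelse(xv > 0, 1, slope)))
}

# softmax along the first dimension, independently for each remaining index;
# works on matrices (per column) and (C, L, N) arrays (per position/sample)
ag_softmax_dim1 <- function(x) {
  xv <- x$value
  dims <- dim(xv)
  m <- matrix(xv, nrow = dims[1])
  m <- m - rep(apply(m, 2, max), each = dims[1])
  e <- exp(m)
  y <- e / rep(colSums(e), each = dims[1])
  yv <- array(y, dim = dims)
  ag_node(yv, list(x), function(g) {
    gm <- matrix(g, nrow = dims[1])
    dot <- colSums(gm * y)
    dx <- y * (gm - rep(dot, each = dims[1]))
    list(array(dx, dim = dims))
  })
}

## ---- tensor primitives (C, L, N) ---------------------------------------

# broadcast an (L, N) mask over channels of an (C, L, N) tensor
.bmask <- function(mask, C) {
  array(rep(as.numeric(mask), each = C), dim = c(C, dim(mask)))
}

# zero out padded positions
ag_mask <- function(x, mask) {
  C <- dim(x$value)[1]
  mb <- .bmask(mask, C)
  ag_node(x$value * mb, list(x), function(g) list(g * mb))
}

# 1-D convolution: x (C_in, L, N), W (C_out, C_in, K), b (C_out).
# Symmetric zero padding for odd K (output length = input length), or
# causal (left-only) padding so position t sees inputs <= t.
ag_conv1d <- function(x, W, b, dilation = 1L, causal = FALSE) {
  xv <- x$value; Wv <- W$value
  dims <- dim(xv)
  C_in <- dims[1]; L <- dims[2]; N <- dims[3]
  K <- dim(Wv)[3]; C_out <- dim(Wv)[1]
  if (dim(Wv)[2] != C_in) {
    stop(sprintf("conv1d channel mismatch: input has %d channels, filter expects %d",
                 C_in, dim(Wv)[2]), call. = FALSE)
  }
  span <- dilation * (K - 1L)
  if (causal) {
    padL <- span; padR <- 0L
  } else {
    if (K %% 2L == 0L) stop("non-causal conv1d requires an odd kernel size", call. = FALSE)
    padL <- span %/% 2L; padR <- span - padL
  }
  Lp <- L + padL + padR
  xp <- array(0, dim = c(C_in, Lp, N))
  xp[, padL + seq_len(L), ] <- xv
  ym <- matrix(0, C_out, L * N)
  for (k in seq_len(K)) {
    off <- (k - 1L) * dilation
    xs <- xp[, off + seq_len(L), , drop = FALSE]
    ym <- ym + matrix(Wv[, , k], C_out, C_in) %*% matrix(xs, C_in, L * N)
  }
  yv <- array(ym + b$value, dim = c(C_out, L, N))
  ag_node(yv, list(x, W, b), function(g) {
    gm <- matrix(g, C_out, L * N)
    dW <- array(0, dim = dim(Wv))
    dxp <- array(0, dim = c(C_in, Lp, N))
    for (k in seq_len(K)) {
      off <- (k - 1L) * dilation
      xs <- matrix(xp[, off + seq_len(L), , drop = FALSE], C_in, L * N)
      dW[, , k] <- gm %*% t(xs)
      dxp[, off + seq_len(L), ] <- dxp[, off + seq_len(L), , drop = FALSE] +
        array(crossprod(matrix(Wv[, , k], C_out, C_in), gm), c(C_in, L, N))
    }
    db <- rowSums(gm)
    dx <- dxp[, padL + seq_len(L), , drop = FALSE]
    list(dx, dW, db)
  })
}

# masked batch normalization over (C, L, N); statistics use valid positions
# only. `layer` is an environment with running_mean / running_var, updated
# in training mode.
ag_batchnorm <- function(x, gamma, beta, mask, layer, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  C <- dim(xv)[1]
  mb <- .bmask(mask, C)
  Nv <- sum(mask)
  if (training) {
    xm <- xv * mb
    mu <- rowSums(matrix(xm, C)) / Nv
    cen <- xv - mu
    vr <- rowSums(matrix((cen^2) * mb, C)) / Nv
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * vr
  } else {
    mu <- layer$running_mean
    vr <- layer$running_var
    cen <- xv - mu
  }
  std <- sqrt(vr + eps)
  xhat <- cen / std
  yv <- gamma$value * xhat + beta$value
  ag_node(yv, list(x, gamma, beta), function(g) {
    dgamma <- rowSums(matrix(g * xhat * mb, C))
    dbeta <- rowSums(matrix(g * mb, C))
    if (training) {
      gm <- g * mb
      sum_g <- rowSums(matrix(gm, C))
      sum_gx <- rowSums(matrix(gm * xhat, C))
      dx <- (gamma$value / std) *
        (gm - (sum_g + xhat * sum_gx) / Nv) * mb
      # note: broadcasting of per-channel vectors over (C, L, N) relies on
      # channel-major layout (first dimension recycles fastest)
    } else {
      dx <- (gamma$value / std) * g * mb
    }
    list(dx, dgamma, dbeta)
  })
}

# masked global average pooling over positions: (C, L, N) -> (C, N)
ag_gap <- function(x, mask) {
  xv <- x$value
  C <- dim(xv)[1]; N <- dim(xv)[3]
  Lv <- pmax(colSums(mask), 1)
  y <- matrix(0, C, N)
  for (n in seq_len(N)) y[, n] <- (xv[, , n] %*% mask[, n]) / Lv[n]
  ag_node(y, list(x), function(g) {
    dx <- array(0, dim = dim(xv))
    for (n in seq_len(N)) dx[, , n] <- outer(g[, n], mask[, n] / Lv[n])
    list(dx)
  })
}

# multiply each sample's (C, L) slab by a per-sample scalar; s has length N
ag_sample_scale <- function(x, s) {
  xv <- x$value; sv <- s$value
  dims <- dim(xv)
  sb <- array(rep(sv, each = dims[1] * dims[2]), dim = dims)
  ag_node(xv * sb, list(x, s), function(g) {
    ds <- colSums(matrix(g * xv, dims[1] * dims[2], dims[3]))
    list(g * sb, ds)
  })
}

# extract row i of a matrix as a plain vector node
ag_row_of <- function(m, i) {
  dims <- dim(m$value)
  ag_node(as.numeric(m$value[i, ]), list(m), function(g) {
    out <- matrix(0, dims[1], dims[2])
    out[i, ] <- g
    list(out)
  })
}

# extract slice i of the first dimension of (E, L, N) as an (L, N) matrix
ag_slice_dim1 <- function(x, i) {
  dims <- dim(x$value)
  ag_node(array(x$value[i, , ], dim = dims[-1]), list(x), function(g) {
    out <- array(0, dim = dims)
    out[i, , ] <- g
    list(out)
  })
}

# multiply an (C, L, N) tensor by positionwise weights (L, N), broadcast
# down the channel rows
ag_pos_scale <- function(x, w) {
  xv <- x$value; C <- dim(xv)[1]
  wb <- .bmask(w$value, C)
  ag_node(xv * wb, list(x, w), function(g) {
    dw <- matrix(colSums(matrix(g * xv, C)), dim(xv)[2], dim(xv)[3])
    list(g * wb, dw)
  })
}

# concatenate tensors along the channel (first) dimension
ag_concat_c <- function(nodes) {
  vals <- lapply(nodes, `[[`, "value")
  Cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  rest <- dim(vals[[1]])[-1]
  out <- array(0, dim = c(sum(Cs), rest))
  at <- 0L
  for (v in vals) {
    out[at + seq_len(dim(v)[1]), , ] <- v
    at <- at + dim(v)[1]
  }
  ag_node(out, nodes, function(g) {
    pos <- 0L
    lapply(Cs, function(C) {
      sl <- g[pos + seq_len(C), , , drop = FALSE]
      pos <<- pos + C
      sl
    })
  })
}

# time slice t of (C, L, N) -> (C, N)
ag_time_slice <- function(x, t) {
  dims <- dim(x$value)
  ag_node(matrix(x$value[, t, ], dims[1], dims[3]), list(x), function(g) {
    out <- array(0, dim = dims)
    out[, t, ] <- g
    list(out)
  })
}

# stack L matrices (C, N) into (C, L, N)
ag_stack_time <- function(nodes) {
  L <- length(nodes)
  C <- nrow(nodes[[1]]$value); N <- ncol(nodes[[1]]$value)
  out <- array(0, dim = c(C, L, N))
  for (t in seq_len(L)) out[, t, ] <- nodes[[t]]$value
  ag_node(out, nodes, function(g) {
    lapply(seq_len(L), function(t) matrix(g[, t, ], C, N))
  })
}

# reverse each sample along the position axis within its own valid length
# (pack-style); padded positions map to zero. lengths: integer vector (N).
ag_reverse_time <- function(x, lengths) {
  xv <- x$value
  dims <- dim(xv)
  L <- dims[2]; N <- dims[3]
  src <- integer(L * N)
  for (n in seq_len(N)) {
    base <- (n - 1L) * L
    Ln <- lengths[n]
    if (Ln > 0) src[base + seq_len(Ln)] <- base + rev(seq_len(Ln))
  }
  sel <- src > 0L
  rev_one <- function(v) {
    m <- matrix(v, dims[1])
    out <- matrix(0, dims[1], L * N)
    out[, sel] <- m[, src[sel], drop = FALSE]
    array(out, dims)
  }
  ag_node(rev_one(xv), list(x), function(g) list(rev_one(g)))
}

# masked softmax cross-entropy: logits (K, L, N), target (L, N) 1-based
# class indices (any value at padded positions), mask (L, N) validity.
ag_ce_loss <- function(logits, target, mask) {
  lv <- logits$value
  K <- dim(lv)[1]; L <- dim(lv)[2]; N <- dim(lv)[3]
  m <- matrix(lv, K)
  m <- m - rep(apply(m, 2, max), each = K)
  e <- exp(m)
  p <- e / rep(colSums(e), each = K)
  tgt <- as.integer(target)
  valid <- as.numeric(mask) > 0
  nvalid <- sum(valid)
  cols <- which(valid)
  picked <- p[cbind(tgt[cols], cols)]
  loss <- -sum(log(pmax(picked, 1e-12))) / nvalid
  ag_node(loss, list(logits), function(g) {
    d <- p
    d[cbind(tgt[cols], cols)] <- d[cbind(tgt[cols], cols)] - 1
    d[, !valid] <- 0
    list(array(d * (g / nvalid), dim = c(K, L, N)))
  })
}
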