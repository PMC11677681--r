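# Layer constructors. A layer is a list (or, for batch norm, an environment
# carrying running statistics) of parameter nodes plus static config;
# forward functions build the autograd graph. Initialization uses the
# session RNG so model construction is reproducible under set.seed().

.init_mat <- function(nr, nc, fan_in = nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

nn_conv1d <- function(C_in, C_out, K, dilation = 1L, causal = FALSE,
                      name = "conv") {
  W <- array(stats::rnorm(C_out * C_in * K, sd = sqrt(2 / (C_in * K))),
             dim = c(C_out, C_in, K))
  list(type = "conv1d",
       W = ag_param(W, paste0(name, ".W")),
       b = ag_param(numeric(C_out), paste0(name, ".b")),
       dilation = as.integer(dilation), causal = causal)
}

conv1d_fwd <- function(layer, x) {
  ag_conv1d(x, layer$W, layer$b, dilation = layer$dilation,
            causal = layer$causal)
}

nn_bn <- function(C, name = "bn") {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$gamma <- ag_param(rep(1, C), paste0(name, ".gamma"))
  e$beta <- ag_param(numeric(C), paste0(name, ".beta"))
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  e
}

bn_fwd <- function(layer, x, mask, training) {
  ag_batchnorm(x, layer$gamma, layer$beta, mask, layer, training = training)
}

# Residual dynamic 1-D convolution block: per-sample attention over B
# candidate filters (softmax of a kernel-1 convolution of the globally
# average-pooled input), convolution with the weighted filter combination,
# batch norm, plus a 1x1-projected batch-normalized residual path, then
# LeakyReLU. The weighted filter combination is applied through the
# linearity conv(x, sum_b w_b F_b) = sum_b w_b conv(x, F_b).
nn_dyconv_block <- function(C_in, C_out, K = 3L, B = 3L, leaky_slope = 0.01,
                            name = "dyconv") {
  list(
    type = "dyconv",
    att_W = ag_param(.init_mat(B, C_in), paste0(name, ".att_W")),
    att_b = ag_param(numeric(B), paste0(name, ".att_b")),
    filters = lapply(seq_len(B), function(b) {
      nn_conv1d(C_in, C_out, K, name = sprintf("%s.flt%d", name, b))
    }),
    bn_main = nn_bn(C_out, paste0(name, ".bn_main")),
    res_conv = nn_conv1d(C_in, C_out, 1L, name = paste0(name, ".res")),
    bn_res = nn_bn(C_out, paste0(name, ".bn_res")),
    B = as.integer(B), slope = leaky_slope
  )
}

# returns list(out =, weights = per-sample attention weight matrix (B, N))
dyconv_block_fwd <- function(block, x, mask, training = TRUE) {
  pooled <- ag_gap(x, mask)
  omega <- ag_softmax_dim1(ag_affine(block$att_W, pooled, block$att_b))
  comb <- NULL
  for (b in seq_len(block$B)) {
    cb <- ag_sample_scale(conv1d_fwd(block$filters[[b]], x),
                          ag_row_of(omega, b))
    comb <- if (is.null(comb)) cb else ag_add(comb, cb)
  }
  main <- bn_fwd(block$bn_main, comb, mask, training)
  res <- bn_fwd(block$bn_res, conv1d_fwd(block$res_conv, x), mask, training)
  out <- ag_mask(ag_leaky_relu(ag_add(main, res), block$slope), mask)
  list(out = out, weights = omega)
}

# single-direction recurrent layer; type "lstm" (gates f, i, o, candidate)
# or "gru" (gates r, z, candidate)
nn_rnn_cell <- function(type = c("lstm", "gru"), C_in, H, name = "rnn") {
  type <- match.arg(type)
  n_gates <- if (type == "lstm") 4L else 3L
  list(type = type, H = as.integer(H), C_in = as.integer(C_in),
       W = ag_param(.init_mat(n_gates * H, H + C_in), paste0(name, ".W")),
       b = ag_param(numeric(n_gates * H), paste0(name, ".b")))
}

# run a cell over (C, L, N); returns hidden states (H, L, N)
rnn_fwd <- function(cell, x) {
  dims <- dim(x$value)
  L <- dims[2]; N <- dims[3]; H <- cell$H
  h <- ag_const(matrix(0, H, N))
  Cst <- ag_const(matrix(0, H, N))
  outs <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- ag_time_slice(x, t)
    if (cell$type == "lstm") {
      z <- ag_affine(cell$W, ag_rowbind(h, xt), cell$b)
      f <- ag_sigmoid(ag_rows(z, seq_len(H)))
      i <- ag_sigmoid(ag_rows(z, H + seq_len(H)))
      o <- ag_sigmoid(ag_rows(z, 2L * H + seq_len(H)))
      cand <- ag_tanh(ag_rows(z, 3L * H + seq_len(H)))
      Cst <- ag_add(ag_mul(f, Cst), ag_mul(i, cand))
      h <- ag_mul(o, ag_tanh(Cst))
    } else {
      z <- ag_affine(cell$W, ag_rowbind(h, xt), cell$b)
      r <- ag_sigmoid(ag_rows(z, seq_len(H)))
      u <- ag_sigmoid(ag_rows(z, H + seq_len(H)))
      pre <- ag_rows(z, 2L * H + seq_len(H))
      # candidate uses the reset-gated recurrent contribution: recompute the
      # recurrent part of the candidate with r applied to h_{t-1}
      Wh <- ag_rows_cols(cell$W, 2L * H + seq_len(H), seq_len(H))
      rec <- ag_matmul(Wh, h)
      cand <- ag_tanh(ag_add(ag_sub(pre, rec), ag_matmul(Wh, ag_mul(r, h))))
      h <- ag_add(ag_mul(u, h), ag_mul(ag_const_add(ag_scale(u, -1), 1), cand))
    }
    outs[[t]] <- h
  }
  ag_stack_time(outs)
}

# matrix product of two matrix nodes
ag_matmul <- function(A, B) {
  Av <- A$value; Bv <- B$value
  ag_node(Av %*% Bv, list(A, B), function(g) {
    list(g %*% t(Bv), crossprod(Av, g))
  })
}

# submatrix (rows, cols) of a matrix node
ag_rows_cols <- function(x, ri, ci) {
  dims <- dim(x$value)
  ag_node(x$value[ri, ci, drop = FALSE], list(x), function(g) {
    out <- matrix(0, dims[1], dims[2])
    out[ri, ci] <- g
    list(out)
  })
}

nn_birnn <- function(type, C_in, H, name = "birnn") {
  list(type = paste0("bi", type),
       fwd = nn_rnn_cell(type, C_in, H, paste0(name, ".fwd")),
       bwd = nn_rnn_cell(type, C_in, H, paste0(name, ".bwd")))
}

# bidirectional pass with pack-style per-sample reversal; lengths from mask
birnn_fwd <- function(layer, x, mask) {
  lengths <- as.integer(colSums(mask))
  hf <- rnn_fwd(layer$fwd, x)
  xr <- ag_reverse_time(x, lengths)
  hb <- ag_reverse_time(rnn_fwd(layer$bwd, xr), lengths)
  ag_mask(ag_concat_c(list(hf, hb)), mask)
}

# collect all parameter nodes reachable from a (possibly nested) model
collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (ag_is_node(o)) {
      if (isTRUE(o$param)) out[[length(out) + 1L]] <<- o
    } else if (is.environment(o)) {
      for (nm in c("gamma", "beta")) {
        if (!is.null(o[[nm]])) walk(o[[nm]])
      }
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

n_params <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}
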