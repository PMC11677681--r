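#' Configuration of the multi-task secondary-structure predictor
#'
#' The network concatenates the enabled per-residue feature channels
#' (one-hot, PSSM, HMM, physicochemical, autoencoder encoding), extracts
#' multi-scale local features with residual convolutions at the configured
#' scales, concatenates any language-model embedding channels, shares
#' parameters between the secondary-structure task and the binary
#' solvent-accessibility auxiliary task through a multi-gate
#' mixture-of-experts block, and runs one combined time-series tower
#' (temporal convolutional network followed by a BiGRU) plus a softmax head
#' per task.
#'
#' @param n_classes_ss 8 (fine-grained) or 3 (coarse) structure states.
#' @param features Character vector of enabled input channels, a subset of
#'   `c("one_hot", "pssm", "hmm", "physchem", "hta")`; channels can be
#'   toggled individually for ablations.
#' @param use_embedding Concatenate an embedding feature after the
#'   multi-scale module (requires an `embedding` list-column on the corpus).
#' @param embedding_dim Embedding width D (default 1280).
#' @param scales Odd kernel sizes of the multi-scale module (default 1, 5, 9).
#' @param scale_channels Output channels per scale (default 32).
#' @param E Number of expert networks (default 3).
#' @param beta Conv+BN pairs per expert (default 2).
#' @param CH Channel width of experts and fused features (default 64).
#' @param M TCN residual blocks; block `i` uses dilation `2^(i-1)`.
#' @param tcn_kernel TCN kernel size (default 3).
#' @param bigru_layers,bigru_hidden BiGRU depth and per-direction width.
#' @param leaky_slope LeakyReLU negative slope.
#' @param rsa_threshold Buried/exposed threshold for the auxiliary task.
#' @return A list of class `mtl_config`.
#' @export
mtl_config <- function(n_classes_ss = 8L,
                       features = c("one_hot", "hta"),
                       use_embedding = FALSE, embedding_dim = 1280L,
                       scales = c(1L, 5L, 9L), scale_channels = 32L,
                       E = 3L, beta = 2L, CH = 64L, M = 3L,
                       tcn_kernel = 3L, bigru_layers = 1L,
                       bigru_hidden = 32L, leaky_slope = 0.01,
                       rsa_threshold = 0.15) {
  known <- c("one_hot", "pssm", "hmm", "physchem", "hta")
  bad <- setdiff(features, known)
  if (length(bad) > 0) {
    stop(sprintf("unknown feature channel(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(n_classes_ss %in% c(3L, 8L), length(features) >= 1,
            all(scales %% 2 == 1), E >= 1, beta >= 1, M >= 1)
  widths <- c(one_hot = 21L, pssm = 20L, hmm = 30L, physchem = 7L, hta = 4L)
  structure(list(
    n_classes_ss = as.integer(n_classes_ss),
    features = features,
    input_channels = sum(widths[features]),
    use_embedding = isTRUE(use_embedding),
    embedding_dim = as.integer(embedding_dim),
    scales = as.integer(scales), scale_channels = as.integer(scale_channels),
    E = as.integer(E), beta = as.integer(beta), CH = as.integer(CH),
    M = as.integer(M), tcn_kernel = as.integer(tcn_kernel),
    bigru_layers = as.integer(bigru_layers),
    bigru_hidden = as.integer(bigru_hidden),
    leaky_slope = leaky_slope, rsa_threshold = rsa_threshold,
    n_tasks = 2L
  ), class = "mtl_config")
}

# build the parameterized network (uses the session RNG)
mtl_new <- function(config = mtl_config()) {
  C_in <- config$input_channels
  SC <- config$scale_channels
  ms <- lapply(seq_along(config$scales), function(i) {
    s <- config$scales[i]
    list(conv = nn_conv1d(C_in, SC, s, name = sprintf("ms%d.conv", i)),
         bn = nn_bn(SC, sprintf("ms%d.bn", i)),
         res = nn_conv1d(C_in, SC, 1L, name = sprintf("ms%d.res", i)),
         bn_res = nn_bn(SC, sprintf("ms%d.bn_res", i)))
  })
  C_cat <- SC * length(config$scales) +
    if (config$use_embedding) config$embedding_dim else 0L
  CH <- config$CH
  tasks <- c("ss", "rsa")
  residuals <- lapply(tasks, function(tk) {
    list(conv = nn_conv1d(C_cat, CH, 1L, name = sprintf("mmoe.res.%s", tk)),
         bn = nn_bn(CH, sprintf("mmoe.res_bn.%s", tk)))
  })
  gates <- lapply(tasks, function(tk) {
    list(conv = nn_conv1d(C_cat, config$E, 1L, name = sprintf("mmoe.gate.%s", tk)),
         bn = nn_bn(config$E, sprintf("mmoe.gate_bn.%s", tk)))
  })
  experts <- lapply(seq_len(config$E), function(k) {
    lapply(seq_len(config$beta), function(b) {
      cin <- if (b == 1) C_cat else CH
      list(conv = nn_conv1d(cin, CH, 3L, name = sprintf("mmoe.ex%d.conv%d", k, b)),
           bn = nn_bn(CH, sprintf("mmoe.ex%d.bn%d", k, b)))
    })
  })
  towers <- lapply(tasks, function(tk) {
    tcn <- lapply(seq_len(config$M), function(i) {
      list(conv1 = nn_conv1d(CH, CH, config$tcn_kernel, dilation = 2L^(i - 1L),
                             causal = TRUE, name = sprintf("tcn.%s%d.c1", tk, i)),
           bn1 = nn_bn(CH, sprintf("tcn.%s%d.bn1", tk, i)),
           conv2 = nn_conv1d(CH, CH, config$tcn_kernel, dilation = 2L^(i - 1L),
                             causal = TRUE, name = sprintf("tcn.%s%d.c2", tk, i)),
           bn2 = nn_bn(CH, sprintf("tcn.%s%d.bn2", tk, i)))
    })
    gru_in <- CH
    grus <- lapply(seq_len(config$bigru_layers), function(l) {
      g <- nn_birnn("gru", gru_in, config$bigru_hidden,
                    name = sprintf("bigru.%s%d", tk, l))
      gru_in <<- 2L * config$bigru_hidden
      g
    })
    n_out <- if (tk == "ss") config$n_classes_ss else 2L
    head <- nn_conv1d(2L * config$bigru_hidden, n_out, 1L,
                      name = sprintf("head.%s", tk))
    list(tcn = tcn, grus = grus, head = head)
  })
  names(residuals) <- names(gates) <- names(towers) <- tasks
  structure(list(config = config, multiscale = ms, residuals = residuals,
                 gates = gates, experts = experts, towers = towers),
            class = "pssp_mtl")
}

# multi-scale residual convolution + embedding concatenation
.mtl_multiscale <- function(model, x, embed, mask, training) {
  cfg <- model$config
  outs <- lapply(model$multiscale, function(m) {
    f <- bn_fwd(m$bn, conv1d_fwd(m$conv, x), mask, training)
    r <- bn_fwd(m$bn_res, conv1d_fwd(m$res, x), mask, training)
    ag_mask(ag_leaky_relu(ag_add(r, f), cfg$leaky_slope), mask)
  })
  if (!is.null(embed)) outs <- c(outs, list(embed))
  ag_concat_c(outs)
}

# MMoE parameter-sharing block; returns per-task fused features and the
# per-task gate weight tensors (E, L, N)
.mtl_mmoe <- function(model, fc, mask, training) {
  cfg <- model$config
  ex_out <- lapply(model$experts, function(ex) {
    h <- fc
    for (pair in ex) {
      h <- ag_mask(ag_leaky_relu(
        bn_fwd(pair$bn, conv1d_fwd(pair$conv, h), mask, training),
        cfg$leaky_slope), mask)
    }
    h
  })
  out <- list(); gates <- list()
  for (tk in c("ss", "rsa")) {
    res <- bn_fwd(model$residuals[[tk]]$bn,
                  conv1d_fwd(model$residuals[[tk]]$conv, fc), mask, training)
    g_lin <- ag_leaky_relu(
      bn_fwd(model$gates[[tk]]$bn,
             conv1d_fwd(model$gates[[tk]]$conv, fc), mask, training),
      cfg$leaky_slope)
    omega <- ag_softmax_dim1(g_lin)
    mix <- NULL
    for (k in seq_len(cfg$E)) {
      term <- ag_pos_scale(ex_out[[k]], ag_slice_dim1(omega, k))
      mix <- if (is.null(mix)) term else ag_add(mix, term)
    }
    fused <- ag_mask(ag_leaky_relu(ag_add(res, mix), cfg$leaky_slope), mask)
    out[[tk]] <- fused
    gates[[tk]] <- omega
  }
  list(out = out, gates = gates)
}

# one TCN residual block: two causal dilated convolutions with BN and
# LeakyReLU, plus identity residual
.tcn_block <- function(block, x, mask, training, slope) {
  h <- ag_mask(ag_leaky_relu(
    bn_fwd(block$bn1, conv1d_fwd(block$conv1, x), mask, training), slope), mask)
  h <- bn_fwd(block$bn2, conv1d_fwd(block$conv2, h), mask, training)
  ag_mask(ag_leaky_relu(ag_add(h, x), slope), mask)
}

.mtl_tower <- function(model, tk, x, mask, training) {
  cfg <- model$config
  tower <- model$towers[[tk]]
  h <- x
  for (block in tower$tcn) h <- .tcn_block(block, h, mask, training, cfg$leaky_slope)
  for (g in tower$grus) h <- birnn_fwd(g, h, mask)
  conv1d_fwd(tower$head, h)
}

# full forward pass; returns logits nodes plus gate tensors
.mtl_forward_nodes <- function(model, feats, mask, training) {
  x <- ag_const(feats$x)
  embed <- if (!is.null(feats$embed)) ag_const(feats$embed) else NULL
  fc <- .mtl_multiscale(model, x, embed, mask, training)
  mm <- .mtl_mmoe(model, fc, mask, training)
  list(ss = .mtl_tower(model, "ss", mm$out$ss, mask, training),
       rsa = .mtl_tower(model, "rsa", mm$out$rsa, mask, training),
       gates = mm$gates)
}

# assemble the hybrid feature tensor for a batch. Optional channels come
# from corpus list-columns `pssm`, `hmm`, `embedding`, `hta`.
mtl_batch_features <- function(records, idx, config, b,
                               physchem = NULL) {
  chans <- list()
  if ("one_hot" %in% config$features) chans$one_hot <- NULL # from b$x
  need_col <- function(col) {
    if (!(col %in% names(records)) ||
        any(vapply(records[[col]][idx], is.null, logical(1)))) {
      stop(sprintf(
        "feature channel '%s' is enabled but records carry no '%s' matrices",
        col, col), call. = FALSE)
    }
  }
  widths <- c(one_hot = 21L, pssm = 20L, hmm = 30L, physchem = 7L, hta = 4L)
  C <- config$input_channels
  x <- array(0, dim = c(C, b$Lmax, b$N))
  at <- 0L
  for (f in config$features) {
    w <- widths[[f]]
    rows <- at + seq_len(w)
    if (f == "one_hot") {
      x[rows, , ] <- b$x
    } else if (f == "physchem") {
      if (is.null(physchem)) physchem <- physchem_table()
      for (n in seq_len(b$N)) {
        m <- physchem_encode(records$sequence[idx[n]], physchem)
        x[rows, seq_len(b$lengths[n]), n] <- t(m)
      }
    } else {
      need_col(if (f == "hta") "hta" else f)
      for (n in seq_len(b$N)) {
        m <- records[[if (f == "hta") "hta" else f]][[idx[n]]]
        if (nrow(m) != b$lengths[n] || ncol(m) != w) {
          stop(sprintf("record '%s': feature '%s' must be %d x %d",
                       records$id[idx[n]], f, b$lengths[n], w), call. = FALSE)
        }
        x[rows, seq_len(b$lengths[n]), n] <- t(m)
      }
    }
    at <- at + w
  }
  embed <- NULL
  if (config$use_embedding) {
    need_col("embedding")
    embed <- array(0, dim = c(config$embedding_dim, b$Lmax, b$N))
    for (n in seq_len(b$N)) {
      m <- records$embedding[[idx[n]]]
      if (nrow(m) != b$lengths[n] || ncol(m) != config$embedding_dim) {
        stop(sprintf("record '%s': embedding must be %d x %d",
                     records$id[idx[n]], b$lengths[n], config$embedding_dim),
             call. = FALSE)
      }
      embed[, seq_len(b$lengths[n]), n] <- t(m)
    }
  }
  list(x = x, embed = embed)
}

#' Train the multi-task predictor
#'
#' Joint training of the secondary-structure and buried/exposed tasks with
#' the weighted cross-entropy `w_ss * CE(ss) + w_rsa * CE(rsa)` (AdamW,
#' stepwise learning-rate halving, early stopping on validation Q accuracy
#' of the structure task).
#'
#' @param records Corpus tibble with `ss8` and `rsa` tracks (plus any
#'   feature list-columns the configuration enables).
#' @param config An [mtl_config()].
#' @param train A [train_config()].
#' @param val_fraction Held-out fraction for early stopping (default 0.15).
#' @param verbose Print per-epoch progress.
#' @return An object of class `mtl_fit` with `model`, `history` (per-epoch
#'   losses, learning rate, validation Q) and `best_epoch`.
#' @export
train_mtl <- function(records, config = mtl_config(), train = train_config(),
                      val_fraction = 0.15, verbose = FALSE) {
  .assert_ss8(records)
  if (any(vapply(records$rsa, is.null, logical(1)))) {
    stop("the auxiliary task needs per-residue RSA on every record", call. = FALSE)
  }
  set.seed(train$seed)
  model <- mtl_new(config)
  params <- collect_params(model)
  opt <- adamw_new(params)
  n <- nrow(records)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  w <- train$loss_weights
  history <- list()
  best <- NULL
  for (epoch in seq_len(train$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, train)
    loss_ss <- c(); loss_rsa <- c()
    for (bi in make_batches(length(tr_idx), train$batch_size)) {
      b <- padded_batch(records, tr_idx[bi], config$rsa_threshold)
      feats <- mtl_batch_features(records, tr_idx[bi], config, b)
      nodes <- .mtl_forward_nodes(model, feats, b$mask, training = TRUE)
      ss_target <- if (config$n_classes_ss == 8L) b$ss_idx else {
        matrix(match(.ss8_to_ss3_map[ss8_states()[b$ss_idx]], ss3_states()),
               b$Lmax, b$N)
      }
      ce_ss <- ag_ce_loss(nodes$ss, ss_target, b$mask)
      ce_rsa <- ag_ce_loss(nodes$rsa, b$rsa_idx, b$mask)
      loss <- ag_add(ag_scale(ce_ss, w[["ss"]]), ag_scale(ce_rsa, w[["rsa"]]))
      ag_zero_grad(params)
      ag_backward(loss)
      adamw_step(opt, params, lr, train$weight_decay)
      loss_ss <- c(loss_ss, ce_ss$value)
      loss_rsa <- c(loss_rsa, ce_rsa$value)
    }
    val <- .mtl_validate(model, records, val_idx, train$batch_size)
    history[[length(history) + 1L]] <- tibble::tibble(
      epoch = epoch + 1L, lr = lr,
      loss_ss = mean(loss_ss), loss_rsa = mean(loss_rsa),
      loss = w[["ss"]] * mean(loss_ss) + w[["rsa"]] * mean(loss_rsa),
      val_q = val)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f (ss %.4f, rsa %.4f), val Q %.2f%%",
                      epoch + 1L, history[[length(history)]]$loss,
                      mean(loss_ss), mean(loss_rsa), val))
    }
    hist_v <- vapply(history, function(h) h$val_q, numeric(1))
    es <- early_stopper(hist_v, train$patience)
    if (es$best_epoch == length(hist_v)) best <- .clone_state(model)
    if (es$stop) break
  }
  hist_v <- vapply(history, function(h) h$val_q, numeric(1))
  .restore_state(model, best)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = early_stopper(hist_v, train$patience)$best_epoch,
                 config = config, train = train),
            class = "mtl_fit")
}

.mtl_validate <- function(model, records, idx, batch_size) {
  pred <- .mtl_predict_strings(model, records, idx, batch_size)
  obs <- records$ss8[idx]
  if (model$config$n_classes_ss == 3L) obs <- map_ss8_to_ss3(obs)
  states <- if (model$config$n_classes_ss == 8L) ss8_states() else ss3_states()
  q_accuracy(pred$ss, obs, states)
}

.mtl_predict_strings <- function(model, records, idx, batch_size = 32L) {
  cfg <- model$config
  states <- if (cfg$n_classes_ss == 8L) ss8_states() else ss3_states()
  ss_out <- character(length(idx)); rsa_out <- vector("list", length(idx))
  ss_probs <- vector("list", length(idx)); rsa_probs <- vector("list", length(idx))
  for (bi in make_batches(length(idx), batch_size, shuffle = FALSE)) {
    b <- padded_batch(records, idx[bi], cfg$rsa_threshold)
    feats <- mtl_batch_features(records, idx[bi], cfg, b)
    nodes <- .mtl_forward_nodes(model, feats, b$mask, training = FALSE)
    ssl <- nodes$ss$value; rsl <- nodes$rsa$value
    for (n in seq_len(b$N)) {
      Lr <- b$lengths[n]
      pm <- .softmax_cols(matrix(ssl[, seq_len(Lr), n], cfg$n_classes_ss))
      rm <- .softmax_cols(matrix(rsl[, seq_len(Lr), n], 2L))
      ss_out[bi[n]] <- paste(states[max.col(t(pm))], collapse = "")
      rsa_out[[bi[n]]] <- c("buried", "exposed")[max.col(t(rm))]
      ss_probs[[bi[n]]] <- t(pm)
      rsa_probs[[bi[n]]] <- t(rm)
    }
  }
  list(ss = ss_out, rsa = rsa_out, ss_probs = ss_probs, rsa_probs = rsa_probs)
}

.softmax_cols <- function(m) {
  m <- m - rep(apply(m, 2, max), each = nrow(m))
  e <- exp(m)
  e / rep(colSums(e), each = nrow(m))
}

#' Predict secondary structure and solvent accessibility
#'
#' Evaluation-mode forward pass over a corpus.
#'
#' @param object A fitted `mtl_fit`.
#' @param records Corpus tibble (feature list-columns as required by the
#'   model's configuration).
#' @param batch_size Sequences per padded batch.
#' @param ... Unused.
#' @return A tibble with columns `id`, `pred_ss` (predicted label string),
#'   `pred_rsa` (list of per-residue buried/exposed calls), `ss_probs` and
#'   `rsa_probs` (list-columns of per-residue class probability matrices,
#'   rows summing to 1).
#' @export
predict.mtl_fit <- function(object, records, batch_size = 32L, ...) {
  .assert_corpus(records)
  p <- .mtl_predict_strings(object$model, records, seq_len(nrow(records)),
                            batch_size)
  tibble::tibble(id = records$id, pred_ss = p$ss, pred_rsa = p$rsa,
                 ss_probs = p$ss_probs, rsa_probs = p$rsa_probs)
}

#' @export
print.mtl_fit <- function(x, ...) {
  cat(sprintf(
    "Multi-task predictor: %d-state head, %d experts, %d parameters\n",
    x$config$n_classes_ss, x$config$E, n_params(x$model)))
  cat(sprintf("  trained %d epoch(s); best epoch %d (val Q %.2f%%)\n",
              nrow(x$history), x$best_epoch, x$history$val_q[x$best_epoch]))
  invisible(x)
}
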