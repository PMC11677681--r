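#' Configuration of the highly targeted autoencoder
#'
#' The autoencoder maps one-hot residue features to a low-dimensional
#' per-residue encoding. The encoder chains `A` residual dynamic-convolution
#' blocks (per-sample attention over `B` candidate filters) down to
#' `encoding_channels` channels; the decoder is a BiLSTM that reconstructs
#' the 21-way residue identity at every position. Training masks one
#' randomly chosen single-category secondary-structure segment per sequence.
#'
#' @param A Number of residual dynamic-convolution blocks (>= 1).
#' @param encoding_channels Width of the encoding (default 4).
#' @param hidden_channels Channel width of the intermediate blocks.
#' @param kernel Odd convolution kernel size.
#' @param B Number of candidate filters per block (default 3).
#' @param decoder_layers,decoder_hidden BiLSTM depth and per-direction
#'   hidden units (defaults 2 and 20).
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param mask_mode `"zero"` replaces masked one-hot rows by all-zero rows;
#'   `"token"` appends a dedicated 22nd mask channel.
#' @param loss_scope `"all"` reconstructs every non-padded position
#'   (default); `"masked"` restricts the loss to masked positions.
#' @return A list of class `hta_config`.
#' @export
hta_config <- function(A = 2L, encoding_channels = 4L, hidden_channels = 16L,
                       kernel = 3L, B = 3L, decoder_layers = 2L,
                       decoder_hidden = 20L, leaky_slope = 0.01,
                       mask_mode = c("zero", "token"),
                       loss_scope = c("all", "masked")) {
  mask_mode <- match.arg(mask_mode)
  loss_scope <- match.arg(loss_scope)
  stopifnot(A >= 1, B >= 1, encoding_channels >= 1, kernel %% 2 == 1)
  structure(list(A = as.integer(A),
                 encoding_channels = as.integer(encoding_channels),
                 hidden_channels = as.integer(hidden_channels),
                 kernel = as.integer(kernel), B = as.integer(B),
                 decoder_layers = as.integer(decoder_layers),
                 decoder_hidden = as.integer(decoder_hidden),
                 leaky_slope = leaky_slope, mask_mode = mask_mode,
                 loss_scope = loss_scope,
                 input_channels = if (mask_mode == "token") 22L else 21L),
            class = "hta_config")
}

# build the parameterized model (uses the session RNG)
hta_new <- function(config = hta_config()) {
  C_in <- config$input_channels
  widths <- c(C_in,
              rep(config$hidden_channels, max(config$A - 1L, 0L)),
              config$encoding_channels)
  blocks <- lapply(seq_len(config$A), function(a) {
    nn_dyconv_block(widths[a], widths[a + 1L], K = config$kernel,
                    B = config$B, leaky_slope = config$leaky_slope,
                    name = sprintf("enc.block%d", a))
  })
  dec_in <- config$encoding_channels
  decoder <- list()
  for (l in seq_len(config$decoder_layers)) {
    decoder[[l]] <- nn_birnn("lstm", dec_in, config$decoder_hidden,
                             name = sprintf("dec.bilstm%d", l))
    dec_in <- 2L * config$decoder_hidden
  }
  out <- nn_conv1d(dec_in, 21L, 1L, name = "dec.out")
  structure(list(config = config, blocks = blocks, decoder = decoder,
                 out = out), class = "pssp_hta")
}

#' Mask one secondary-structure segment of a record
#'
#' Chooses one maximal single-category segment uniformly at random and
#' replaces its one-hot rows according to the mask mode (`"zero"`: all-zero
#' rows; `"token"`: a dedicated 22nd mask channel). Label tracks are never
#' altered; the mask acts on input features only.
#'
#' @param sequence Residue string.
#' @param ss8 8-state label string of the same length.
#' @param mask_mode See [hta_config()].
#' @return A list with `one_hot` (the masked L x 21 or L x 22 matrix),
#'   `positions` (masked residue positions) and `segment` (the chosen
#'   segment row).
#' @export
mask_segment <- function(sequence, ss8, mask_mode = c("zero", "token")) {
  mask_mode <- match.arg(mask_mode)
  if (is.na(ss8) || !nzchar(ss8)) {
    stop("mask_segment needs 8-state labels to locate segments", call. = FALSE)
  }
  segs <- extract_segments(ss8)
  pick <- segs[sample.int(nrow(segs), 1L), ]
  oh <- one_hot_encode(sequence)
  if (mask_mode == "token") {
    oh <- cbind(oh, MASK = 0L)
  }
  pos <- seq.int(pick$start, pick$end)
  oh[pos, ] <- 0L
  if (mask_mode == "token") oh[pos, 22L] <- 1L
  list(one_hot = oh, positions = pos, segment = pick)
}

# encoder forward on a prepared input tensor (C_in, Lmax, N)
.hta_encode_tensor <- function(model, x_arr, mask, training = FALSE) {
  x <- ag_const(x_arr)
  weights <- vector("list", length(model$blocks))
  for (a in seq_along(model$blocks)) {
    r <- dyconv_block_fwd(model$blocks[[a]], x, mask, training = training)
    x <- r$out
    weights[[a]] <- r$weights
  }
  list(encoding = x, weights = weights)
}

.hta_decode_node <- function(model, enc, mask) {
  h <- enc
  for (layer in model$decoder) h <- birnn_fwd(layer, h, mask)
  conv1d_fwd(model$out, h)
}

#' Encode records with a trained autoencoder
#'
#' Runs the encoder (evaluation mode, non-masked input: at inference no
#' residue is hidden, so the encoding covers every position) and returns one
#' L x 4 encoding matrix per record.
#'
#' @param model A fitted autoencoder (`hta_fit$model` or the fit itself).
#' @param records Corpus tibble.
#' @param batch_size Sequences per padded batch.
#' @return A list of L x `encoding_channels` matrices, named by record id.
#' @export
hta_encode <- function(model, records, batch_size = 32L) {
  if (inherits(model, "hta_fit")) model <- model$model
  stopifnot(inherits(model, "pssp_hta"))
  .assert_corpus(records)
  out <- vector("list", nrow(records))
  batches <- make_batches(nrow(records), batch_size, shuffle = FALSE)
  for (bi in batches) {
    b <- padded_batch(records, bi)
    x_arr <- b$x
    if (model$config$mask_mode == "token") {
      x_arr <- .with_mask_channel(x_arr, b$mask)
    }
    enc <- .hta_encode_tensor(model, x_arr, b$mask, training = FALSE)$encoding
    for (n in seq_len(b$N)) {
      out[[bi[n]]] <- t(matrix(enc$value[, seq_len(b$lengths[n]), n],
                               model$config$encoding_channels))
    }
  }
  names(out) <- records$id
  out
}

# append an all-zero mask channel to (21, L, N)
.with_mask_channel <- function(x_arr, mask) {
  d <- dim(x_arr)
  out <- array(0, dim = c(d[1] + 1L, d[2], d[3]))
  out[seq_len(d[1]), , ] <- x_arr
  out
}

#' Decode encodings back to residue logits
#'
#' Runs the BiLSTM decoder plus the position-wise output layer on an
#' encoding tensor; mainly useful for inspecting reconstruction quality.
#'
#' @param model A fitted autoencoder or `pssp_hta` model.
#' @param encoding An L x `encoding_channels` matrix as produced by
#'   [hta_encode()].
#' @return An L x 21 matrix of residue logits.
#' @export
hta_decode <- function(model, encoding) {
  if (inherits(model, "hta_fit")) model <- model$model
  stopifnot(inherits(model, "pssp_hta"), is.matrix(encoding))
  L <- nrow(encoding)
  enc <- ag_const(array(t(encoding), dim = c(ncol(encoding), L, 1L)))
  mask <- matrix(1, L, 1)
  logits <- .hta_decode_node(model, enc, mask)
  t(matrix(logits$value, 21L, L))
}

#' Train the highly targeted autoencoder
#'
#' Each epoch draws a fresh random single-category segment mask per
#' sequence, encodes the masked input, decodes with the BiLSTM and minimizes
#' the 21-way cross-entropy between decoder logits and the true residue
#' identities over non-padded positions (AdamW, stepwise learning-rate
#' halving, early stopping on validation reconstruction accuracy).
#'
#' @param records Corpus tibble with `ss8` labels (needed for masking).
#' @param config An [hta_config()].
#' @param train A [train_config()].
#' @param val_fraction Fraction of records held out to monitor early
#'   stopping (default 0.1; at least one record).
#' @param verbose Print per-epoch progress.
#' @return An object of class `hta_fit` with elements `model`, `history`
#'   (per-epoch tibble of loss, learning rate and validation accuracy) and
#'   `best_epoch`. Supports [generics::tidy()] and [generics::glance()].
#' @export
train_hta <- function(records, config = hta_config(), train = train_config(),
                      val_fraction = 0.1, verbose = FALSE) {
  .assert_ss8(records)
  if (nrow(records) < 2) stop("need at least two records to train", call. = FALSE)
  set.seed(train$seed)
  model <- hta_new(config)
  params <- collect_params(model)
  opt <- adamw_new(params)
  n <- nrow(records)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  history <- list()
  best <- NULL
  for (epoch in seq_len(train$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, train)
    losses <- c()
    for (bi in make_batches(length(tr_idx), train$batch_size)) {
      b <- padded_batch(records, tr_idx[bi])
      xin <- .hta_masked_input(records, tr_idx[bi], b, config)
      enc <- .hta_encode_tensor(model, xin$x, b$mask, training = TRUE)
      logits <- .hta_decode_node(model, enc$encoding, b$mask)
      loss_mask <- if (config$loss_scope == "masked") xin$mask_pos else b$mask
      loss <- ag_ce_loss(logits, b$aa_idx, loss_mask)
      ag_zero_grad(params)
      ag_backward(loss)
      adamw_step(opt, params, lr, train$weight_decay)
      losses <- c(losses, loss$value)
    }
    val_acc <- .hta_eval_accuracy(model, records, val_idx, train$batch_size)
    history[[length(history) + 1L]] <- tibble::tibble(
      epoch = epoch + 1L, lr = lr, train_loss = mean(losses),
      val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val recon acc %.2f%%",
                      epoch + 1L, mean(losses), val_acc))
    }
    hist_v <- vapply(history, function(h) h$val_accuracy, numeric(1))
    es <- early_stopper(hist_v, train$patience)
    if (es$best_epoch == length(hist_v)) best <- .clone_state(model)
    if (es$stop) break
  }
  hist_v <- vapply(history, function(h) h$val_accuracy, numeric(1))
  best_epoch <- early_stopper(hist_v, train$patience)$best_epoch
  .restore_state(model, best)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, config = config, train = train),
            class = "hta_fit")
}

# draw fresh masks for a batch; returns masked input tensor and the matrix
# of masked positions
.hta_masked_input <- function(records, idx, b, config) {
  x <- if (config$mask_mode == "token") {
    .with_mask_channel(b$x, b$mask)
  } else {
    b$x
  }
  mask_pos <- matrix(0, b$Lmax, b$N)
  for (n in seq_len(b$N)) {
    ms <- mask_segment(records$sequence[idx[n]], records$ss8[idx[n]],
                       config$mask_mode)
    x[, seq_len(b$lengths[n]), n] <- t(ms$one_hot)
    mask_pos[ms$positions, n] <- 1
  }
  list(x = x, mask_pos = mask_pos)
}

# masked-position reconstruction accuracy in evaluation mode
.hta_eval_accuracy <- function(model, records, idx, batch_size) {
  correct <- 0L; total <- 0L
  for (bi in make_batches(length(idx), batch_size, shuffle = FALSE)) {
    b <- padded_batch(records, idx[bi])
    xin <- .hta_masked_input(records, idx[bi], b, model$config)
    enc <- .hta_encode_tensor(model, xin$x, b$mask, training = FALSE)
    logits <- .hta_decode_node(model, enc$encoding, b$mask)$value
    pred <- apply(logits, c(2, 3), which.max)
    sel <- xin$mask_pos > 0
    correct <- correct + sum((pred == b$aa_idx)[sel])
    total <- total + sum(sel)
  }
  100 * correct / total
}

#' Masked-position reconstruction accuracy of a fitted autoencoder
#'
#' Masks one random single-category segment per sequence (fresh draws under
#' the given seed), reconstructs and reports the accuracy on the masked
#' positions, together with the residue-frequency baseline (the accuracy of
#' always guessing the corpus's most frequent residue).
#'
#' @param fit An `hta_fit` (or `pssp_hta` model).
#' @param records Corpus tibble with `ss8` labels.
#' @param seed Seed for the mask draws.
#' @return A list with `accuracy` and `baseline`, both percentages.
#' @export
hta_reconstruction_accuracy <- function(fit, records, seed = 1L) {
  model <- if (inherits(fit, "hta_fit")) fit$model else fit
  .assert_ss8(records)
  set.seed(seed)
  acc <- .hta_eval_accuracy(model, records, seq_len(nrow(records)), 32L)
  freq <- table(unlist(lapply(records$sequence, .chars)))
  baseline <- 100 * max(freq) / sum(freq)
  list(accuracy = acc, baseline = baseline)
}

#' @export
print.hta_fit <- function(x, ...) {
  cat(sprintf(
    "Highly targeted autoencoder: %d blocks, %d-channel encoding, %d parameters\n",
    x$config$A, x$config$encoding_channels, n_params(x$model)))
  cat(sprintf("  trained %d epoch(s); best epoch %d (val recon acc %.2f%%)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_accuracy[x$best_epoch]))
  invisible(x)
}

## ---- state snapshots ---------------------------------------------------

.clone_state <- function(model) {
  params <- collect_params(model)
  vals <- lapply(params, function(p) p$value)
  names(vals) <- vapply(params, function(p) p$name %||% "", character(1))
  list(params = vals, bn = .collect_bn_state(model))
}

.restore_state <- function(model, state) {
  if (is.null(state)) return(invisible(model))
  params <- collect_params(model)
  for (i in seq_along(params)) params[[i]]$value <- state$params[[i]]
  .restore_bn_state(model, state$bn)
  invisible(model)
}

.collect_bn_state <- function(x) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o) && identical(o$type, "bn")) {
      out[[length(out) + 1L]] <<- list(mean = o$running_mean,
                                       var = o$running_var)
    } else if (is.list(o) && !ag_is_node(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

.restore_bn_state <- function(x, st) {
  i <- 0L
  walk <- function(o) {
    if (is.environment(o) && identical(o$type, "bn")) {
      i <<- i + 1L
      o$running_mean <- st[[i]]$mean
      o$running_var <- st[[i]]$var
    } else if (is.list(o) && !ag_is_node(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  invisible(x)
}
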