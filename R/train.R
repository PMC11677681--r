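#' Training configuration
#'
#' Optimization protocol shared by the autoencoder and the multi-task
#' predictor: AdamW with weight decay 0.05, batch size 32, initial learning
#' rate 5e-4 halved every five epochs, early stopping with patience 3 on
#' the validation metric, and task loss weights 0.8 (secondary structure)
#' to 0.2 (solvent accessibility).
#'
#' @param batch_size Sequences per batch (padded to the batch maximum).
#' @param initial_lr Initial learning rate.
#' @param lr_halving_period Epochs between learning-rate halvings.
#' @param weight_decay AdamW decoupled weight decay.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param loss_weights Named vector `c(ss = , rsa = )`, summing to 1.
#' @param seed RNG seed used for initialization, shuffling and masking.
#' @param max_epochs Upper bound on training epochs.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, initial_lr = 5e-4,
                         lr_halving_period = 5L, weight_decay = 0.05,
                         patience = 3L, loss_weights = c(ss = 0.8, rsa = 0.2),
                         seed = 42L, max_epochs = 100L) {
  stopifnot(abs(sum(loss_weights) - 1) < 1e-8, patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 weight_decay = weight_decay,
                 patience = as.integer(patience),
                 loss_weights = loss_weights,
                 seed = as.integer(seed),
                 max_epochs = as.integer(max_epochs)),
            class = "train_config")
}

#' Stepwise learning-rate schedule
#'
#' `lr = initial_lr * 0.5 ^ floor(epoch / period)` with `epoch` counted from
#' zero.
#'
#' @param epoch Zero-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(0, train_config())   # 5e-4
#' lr_schedule(5, train_config())   # 2.5e-4
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  config$initial_lr * 0.5^(epoch %/% config$lr_halving_period)
}

#' Early-stopping decision from a validation history
#'
#' Monitors a higher-is-better validation quantity; training stops once
#' `patience` consecutive epochs have failed to improve on the best value
#' seen so far.
#'
#' @param history Numeric vector of per-epoch validation values (higher is
#'   better), in epoch order.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return A list with `stop` (logical), `best_epoch` (1-based index of the
#'   best value) and `wait` (epochs since the best value).
#' @export
early_stopper <- function(history, patience = 3L) {
  stopifnot(length(history) >= 1, patience >= 1)
  best_epoch <- which.max(history)
  wait <- length(history) - best_epoch
  list(stop = wait >= patience, best_epoch = best_epoch, wait = wait)
}

#' Shuffle a corpus into batches
#'
#' @param n_records Number of records (or a corpus data frame).
#' @param batch_size Records per batch; the final batch may be smaller.
#' @param shuffle Shuffle record order (uses the session RNG).
#' @return A list of integer index vectors.
#' @export
make_batches <- function(n_records, batch_size = 32L, shuffle = TRUE) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  stopifnot(n_records >= 1)
  idx <- if (shuffle) sample.int(n_records) else seq_len(n_records)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Weighted multi-task cross-entropy
#'
#' `w_ss * CE(ss) + w_rsa * CE(rsa)`, each cross-entropy averaged over
#' non-padded positions. This is the numeric (evaluation) form used to
#' report losses; training uses the differentiable equivalent internally.
#'
#' @param ss_probs,rsa_probs Arrays of per-residue class probabilities,
#'   shaped (classes, L, N).
#' @param ss_target,rsa_target Integer matrices (L, N) of 1-based class
#'   indices.
#' @param mask Validity matrix (L, N); padded positions are excluded.
#' @param weights Named vector `c(ss = , rsa = )` summing to 1.
#' @return The scalar weighted loss.
#' @export
multitask_loss <- function(ss_probs, rsa_probs, ss_target, rsa_target, mask,
                           weights = c(ss = 0.8, rsa = 0.2)) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  ce <- function(p, tgt) {
    K <- dim(p)[1]
    pm <- matrix(p, K)
    cols <- which(as.numeric(mask) > 0)
    picked <- pm[cbind(as.integer(tgt)[cols], cols)]
    -mean(log(pmax(picked, 1e-12)))
  }
  unname(weights["ss"] * ce(ss_probs, ss_target) +
           weights["rsa"] * ce(rsa_probs, rsa_target))
}

## ---- AdamW -------------------------------------------------------------

adamw_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  opt$v <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(opt, params, lr, weight_decay = 0.05) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    newv <- p$value - lr * (mhat / (sqrt(vhat) + opt$eps) +
                              weight_decay * p$value)
    if (is.null(dim(p$value))) newv <- as.numeric(newv) else dim(newv) <- dim(p$value)
    p$value <- newv
  }
  invisible(opt)
}

## ---- batch assembly ----------------------------------------------------

# Pad a set of records into channel-major tensors. Returns one-hot input
# (21, Lmax, N), validity mask (Lmax, N), residue class indices, and, when
# labels are present, 8-state and buried/exposed targets.
padded_batch <- function(records, idx, rsa_threshold = 0.15) {
  seqs <- records$sequence[idx]
  L <- nchar(seqs)
  Lmax <- max(L)
  N <- length(idx)
  x <- array(0, dim = c(21L, Lmax, N))
  mask <- matrix(0, Lmax, N)
  aa_idx <- matrix(1L, Lmax, N)
  for (n in seq_len(N)) {
    oh <- one_hot_encode(seqs[n])
    x[, seq_len(L[n]), n] <- t(oh)
    mask[seq_len(L[n]), n] <- 1
    aa_idx[seq_len(L[n]), n] <- max.col(oh)
  }
  out <- list(idx = idx, lengths = L, x = x, mask = mask, aa_idx = aa_idx,
              Lmax = Lmax, N = N)
  if ("ss8" %in% names(records) && !anyNA(records$ss8[idx])) {
    ss_idx <- matrix(1L, Lmax, N)
    for (n in seq_len(N)) {
      ss_idx[seq_len(L[n]), n] <- match(.chars(records$ss8[idx[n]]), ss8_states())
    }
    out$ss_idx <- ss_idx
  }
  if ("rsa" %in% names(records) &&
      !any(vapply(records$rsa[idx], is.null, logical(1)))) {
    rsa_idx <- matrix(1L, Lmax, N)
    for (n in seq_len(N)) {
      rsa_idx[seq_len(L[n]), n] <-
        ifelse(records$rsa[[idx[n]]] <= rsa_threshold, 1L, 2L)
    }
    out$rsa_idx <- rsa_idx
  }
  out
}
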