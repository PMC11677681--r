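# Independent oracles and fixture builders used across the suite.

# Brute-force segment-overlap score: literal position-set transcription of
# the segment-overlap definition, kept independent of the package's
# interval-arithmetic implementation.
oracle_segments <- function(labels) {
  chars <- strsplit(labels, "")[[1]]
  segs <- list()
  start <- 1
  for (i in seq_along(chars)) {
    if (i == length(chars) || chars[i + 1] != chars[i]) {
      segs[[length(segs) + 1]] <- list(cat = chars[i], pos = start:i)
      start <- i + 1
    }
  }
  segs
}

oracle_sov <- function(pred, obs, states) {
  so <- oracle_segments(obs)
  sp <- oracle_segments(pred)
  total <- 0
  N <- 0
  for (cat in states) {
    s1s <- Filter(function(s) s$cat == cat, so)
    s2s <- Filter(function(s) s$cat == cat, sp)
    for (s1 in s1s) {
      ovs <- vapply(s2s, function(s2) length(intersect(s1$pos, s2$pos)),
                    numeric(1))
      if (length(s2s) == 0 || all(ovs == 0)) {
        N <- N + length(s1$pos)
      } else {
        for (j in which(ovs > 0)) {
          s2 <- s2s[[j]]
          minov <- length(intersect(s1$pos, s2$pos))
          maxov <- length(union(s1$pos, s2$pos))
          delta <- min(maxov - minov, minov,
                       floor(length(s1$pos) / 2), floor(length(s2$pos) / 2))
          total <- total + (minov + delta) / maxov * length(s1$pos)
          N <- N + length(s1$pos)
        }
      }
    }
  }
  100 * total / N
}

# random label string over given states
random_labels <- function(L, states) {
  paste(sample(states, L, replace = TRUE), collapse = "")
}

# plain straight-loop 1-D convolution oracle (same padding, odd kernel):
# x (C_in, L), W (C_out, C_in, K), b (C_out)
oracle_conv1d <- function(x, W, b, dilation = 1, causal = FALSE) {
  C_in <- nrow(x); L <- ncol(x)
  C_out <- dim(W)[1]; K <- dim(W)[3]
  span <- dilation * (K - 1)
  padL <- if (causal) span else span %/% 2
  y <- matrix(0, C_out, L)
  for (t in 1:L) {
    for (k in 1:K) {
      src <- t - padL + (k - 1) * dilation
      if (src >= 1 && src <= L) {
        y[, t] <- y[, t] + matrix(W[, , k], C_out, C_in) %*% x[, src]
      }
    }
    y[, t] <- y[, t] + b
  }
  y
}

# masked batch-norm oracle over a list of (C, L) slabs with (L) masks
oracle_bn <- function(slabs, masks, gamma, beta, eps = 1e-5) {
  C <- nrow(slabs[[1]])
  allv <- do.call(cbind, lapply(seq_along(slabs), function(i) {
    slabs[[i]][, masks[[i]] > 0, drop = FALSE]
  }))
  mu <- rowMeans(allv)
  vr <- rowSums((allv - mu)^2) / ncol(allv)
  lapply(slabs, function(s) {
    gamma * (s - mu) / sqrt(vr + eps) + beta
  })
}

# deterministic-emission generator config: residue identity encodes the
# secondary structure category (H->A, E->V, others->G), the regime used for
# the learnability checks
det_emission_config <- function(n_sequences, length_range = c(30L, 50L),
                                seed = 42L) {
  cats <- psspkit::ss8_states()
  em <- matrix(0, 8, 21, dimnames = list(cats, psspkit::aa_alphabet()))
  em[, "G"] <- 1
  em["H", ] <- 0; em["H", "A"] <- 1
  em["E", ] <- 0; em["E", "V"] <- 1
  em["T", ] <- 0; em["T", "P"] <- 1
  em["S", ] <- 0; em["S", "S"] <- 1
  psspkit::generator_config(n_sequences = n_sequences,
                            length_range = length_range,
                            emission = em, seed = seed)
}

# small labelled corpus for metric tests
tiny_corpus <- function(n = 12, seed = 99) {
  syn <- psspkit::generate_corpus(
    psspkit::generator_config(n_sequences = n, length_range = c(15L, 30L),
                              seed = seed))
  syn$records
}

ns <- asNamespace("psspkit")
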