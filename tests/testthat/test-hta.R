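test_that("segment masking chooses one segment uniformly and leaves labels alone", {
  # single segment: always chosen
  set.seed(1)
  ms <- mask_segment("AAAA", "HHHH")
  expect_equal(ms$positions, 1:4)
  expect_equal(rowSums(ms$one_hot), rep(0, 4))
  # three segments: empirical pick frequencies are uniform
  set.seed(2)
  picks <- replicate(3000, mask_segment("AAAAAA", "HHEELL")$segment$category)
  freq <- table(picks) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  # token mode marks a dedicated 22nd channel
  set.seed(3)
  mt <- mask_segment("AAAA", "HHEE", mask_mode = "token")
  expect_equal(ncol(mt$one_hot), 22L)
  expect_equal(mt$one_hot[mt$positions, 22], rep(1L, length(mt$positions)))
  expect_error(mask_segment("AAAA", NA_character_), "labels")
})

test_that("encoding has the contracted shape and is deterministic in eval mode", {
  set.seed(11)
  model <- ns$hta_new(hta_config(A = 2L, hidden_channels = 6L,
                                 decoder_hidden = 5L, decoder_layers = 1L))
  rec <- tiny_corpus(5)
  e1 <- hta_encode(model, rec)
  e2 <- hta_encode(model, rec)
  expect_equal(length(e1), 5L)
  for (i in 1:5) {
    expect_equal(dim(e1[[i]]), c(nchar(rec$sequence[i]), 4L))
    expect_identical(e1[[i]], e2[[i]])
  }
  # encoding channel count is exactly 4 under the default config
  expect_equal(hta_config()$encoding_channels, 4L)
})

test_that("evaluation-mode encodings are padding invariant", {
  set.seed(13)
  model <- ns$hta_new(hta_config(A = 2L, hidden_channels = 6L,
                                 decoder_hidden = 5L, decoder_layers = 1L))
  rec <- tiny_corpus(6)
  solo <- hta_encode(model, rec[1, ], batch_size = 1L)
  batched <- hta_encode(model, rec, batch_size = 6L)
  expect_equal(solo[[1]], batched[[1]], tolerance = 1e-10)
})

test_that("decoder logits have the right shape and respond to the encoding", {
  set.seed(17)
  model <- ns$hta_new(hta_config(A = 1L, decoder_hidden = 5L,
                                 decoder_layers = 1L))
  enc <- matrix(rnorm(8 * 4), 8, 4)
  logits <- hta_decode(model, enc)
  expect_equal(dim(logits), c(8L, 21L))
  logits2 <- hta_decode(model, enc * 2)
  expect_false(isTRUE(all.equal(logits, logits2)))
})

test_that("autoencoder training lifts reconstruction above the frequency baseline", {
  # masked-loss toy run on a corpus whose residues encode the segment
  # category, so masked segments are inferable from their flanks
  syn <- generate_corpus(det_emission_config(200, c(20L, 40L), seed = 5))
  cfg <- hta_config(A = 2L, hidden_channels = 8L, decoder_hidden = 12L,
                    decoder_layers = 1L, loss_scope = "masked")
  tc <- train_config(batch_size = 32L, initial_lr = 2e-3,
                     lr_halving_period = 10L, max_epochs = 25L,
                     patience = 25L, seed = 42L)
  fit <- train_hta(syn$records, cfg, tc)
  expect_true(all(is.finite(fit$history$train_loss)))
  # loss decreases over training
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  ra <- hta_reconstruction_accuracy(fit, syn$records, seed = 9)
  expect_gt(ra$accuracy, ra$baseline)
  # fixed seed reproduces the loss history bit for bit
  fit2 <- train_hta(syn$records, cfg,
                    train_config(batch_size = 32L, initial_lr = 2e-3,
                                 lr_halving_period = 10L, max_epochs = 2L,
                                 patience = 18L, seed = 42L))
  expect_identical(fit2$history$train_loss, fit$history$train_loss[1:2])
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(glance(fit)$epochs, nrow(fit$history))
})

test_that("checkpoints round-trip the autoencoder exactly", {
  syn <- generate_corpus(generator_config(n_sequences = 10,
                                          length_range = c(12L, 20L), seed = 6))
  fit <- train_hta(syn$records,
                   hta_config(A = 1L, decoder_hidden = 4L, decoder_layers = 1L),
                   train_config(batch_size = 8L, max_epochs = 1L))
  f <- withr::local_tempfile(fileext = ".json")
  model_save(fit, f)
  back <- model_load(f)
  e1 <- hta_encode(fit, syn$records)
  e2 <- hta_encode(back, syn$records)
  for (i in seq_along(e1)) expect_equal(e1[[i]], e2[[i]], tolerance = 1e-12)
})
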