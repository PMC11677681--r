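test_that("multiscale concatenation has the configured channel arithmetic", {
  set.seed(21)
  cfg <- mtl_config(features = "one_hot", scales = c(1L, 5L, 9L),
                    scale_channels = 6L, E = 2L, CH = 8L, M = 1L,
                    bigru_hidden = 4L)
  model <- ns$mtl_new(cfg)
  L <- 11; N <- 2
  mask <- matrix(1, L, N)
  x <- ns$ag_const(array(rnorm(21 * L * N), dim = c(21, L, N)))
  fc <- ns$.mtl_multiscale(model, x, NULL, mask, TRUE)
  expect_equal(dim(fc$value), c(3L * 6L, L, N))   # sum over scales
  # with an embedding tensor the width grows by D
  emb <- ns$ag_const(array(rnorm(5 * L * N), dim = c(5, L, N)))
  cfg2 <- mtl_config(features = "one_hot", use_embedding = TRUE,
                     embedding_dim = 5L, scales = c(1L, 5L, 9L),
                     scale_channels = 6L, E = 2L, CH = 8L, M = 1L,
                     bigru_hidden = 4L)
  m2 <- ns$mtl_new(cfg2)
  fc2 <- ns$.mtl_multiscale(m2, x, emb, mask, TRUE)
  expect_equal(dim(fc2$value)[1], 3L * 6L + 5L)
  # output length equals input length at every scale
  expect_equal(dim(fc2$value)[2], L)
})

test_that("predictions are probability rows for both heads", {
  set.seed(23)
  syn <- generate_corpus(det_emission_config(10, c(12L, 20L), seed = 8))
  cfg <- mtl_config(features = "one_hot", scales = c(1L, 3L),
                    scale_channels = 4L, E = 2L, CH = 8L, M = 1L,
                    bigru_hidden = 4L)
  fit <- train_mtl(syn$records, cfg,
                   train_config(batch_size = 8L, max_epochs = 1L))
  pred <- predict(fit, syn$records)
  expect_equal(nrow(pred), 10L)
  for (i in 1:10) {
    L <- nchar(syn$records$sequence[i])
    expect_equal(nchar(pred$pred_ss[i]), L)
    expect_equal(dim(pred$ss_probs[[i]]), c(L, 8L))
    expect_equal(rowSums(pred$ss_probs[[i]]), rep(1, L), tolerance = 1e-9)
    expect_equal(rowSums(pred$rsa_probs[[i]]), rep(1, L), tolerance = 1e-9)
  }
})

test_that("feature channels are individually toggleable (ablation mode)", {
  set.seed(29)
  syn <- generate_corpus(det_emission_config(8, c(10L, 16L), seed = 9))
  rec <- syn$records
  # attach a fake encoding channel and physchem; widths must line up
  rec$hta <- lapply(nchar(rec$sequence), function(L) matrix(0.1, L, 4))
  cfg_a <- mtl_config(features = c("one_hot", "physchem", "hta"),
                      scales = 3L, scale_channels = 4L, E = 1L, CH = 6L,
                      M = 1L, bigru_hidden = 3L)
  expect_equal(cfg_a$input_channels, 21L + 7L + 4L)
  cfg_b <- mtl_config(features = "one_hot", scales = 3L, scale_channels = 4L,
                      E = 1L, CH = 6L, M = 1L, bigru_hidden = 3L)
  expect_equal(cfg_b$input_channels, 21L)
  fit <- train_mtl(rec, cfg_a, train_config(batch_size = 8L, max_epochs = 1L))
  expect_s3_class(fit, "mtl_fit")
  # an enabled channel without matrices is a labeled input error
  cfg_c <- mtl_config(features = c("one_hot", "pssm"), scales = 3L,
                      scale_channels = 4L, E = 1L, CH = 6L, M = 1L,
                      bigru_hidden = 3L)
  expect_error(train_mtl(rec, cfg_c, train_config(max_epochs = 1L)),
               "pssm")
})

test_that("evaluation-mode outputs are padding invariant", {
  set.seed(31)
  syn <- generate_corpus(generator_config(n_sequences = 6,
                                          length_range = c(10L, 25L),
                                          seed = 10))
  rec <- syn$records
  cfg <- mtl_config(features = "one_hot", scales = c(1L, 3L),
                    scale_channels = 4L, E = 2L, CH = 8L, M = 2L,
                    bigru_hidden = 4L)
  fit <- train_mtl(rec, cfg, train_config(batch_size = 6L, max_epochs = 1L))
  solo <- predict(fit, rec[2, ], batch_size = 1L)
  grouped <- predict(fit, rec, batch_size = 6L)
  expect_equal(solo$ss_probs[[1]], grouped$ss_probs[[2]], tolerance = 1e-8)
  expect_equal(solo$pred_ss, grouped$pred_ss[2])
})

test_that("both task losses decrease under the 0.8/0.2 weighting", {
  syn <- generate_corpus(det_emission_config(40, c(15L, 30L), seed = 12))
  cfg <- mtl_config(features = "one_hot", scales = c(1L, 3L),
                    scale_channels = 6L, E = 2L, CH = 12L, M = 1L,
                    bigru_hidden = 6L)
  fit <- train_mtl(syn$records, cfg,
                   train_config(batch_size = 16L, max_epochs = 5L, seed = 42L))
  h <- fit$history
  expect_lt(h$loss_ss[nrow(h)], h$loss_ss[1])
  expect_lt(h$loss_rsa[nrow(h)], h$loss_rsa[1])
})

test_that("a 3-state head trains and predicts over the coarse alphabet", {
  syn <- generate_corpus(det_emission_config(10, c(10L, 16L), seed = 14))
  cfg <- mtl_config(n_classes_ss = 3L, features = "one_hot", scales = 3L,
                    scale_channels = 4L, E = 1L, CH = 6L, M = 1L,
                    bigru_hidden = 3L)
  fit <- train_mtl(syn$records, cfg,
                   train_config(batch_size = 8L, max_epochs = 1L))
  pred <- predict(fit, syn$records)
  chars <- unique(unlist(strsplit(pred$pred_ss, "")))
  expect_true(all(chars %in% ss3_states()))
})

test_that("checkpoints round-trip the predictor exactly", {
  syn <- generate_corpus(det_emission_config(8, c(10L, 16L), seed = 15))
  cfg <- mtl_config(features = "one_hot", scales = c(1L, 3L),
                    scale_channels = 4L, E = 2L, CH = 6L, M = 1L,
                    bigru_hidden = 3L)
  fit <- train_mtl(syn$records, cfg,
                   train_config(batch_size = 8L, max_epochs = 1L))
  f <- withr::local_tempfile(fileext = ".json")
  model_save(fit, f)
  back <- model_load(f)
  p1 <- predict(fit, syn$records)
  p2 <- predict(back, syn$records)
  expect_equal(p1$pred_ss, p2$pred_ss)
  expect_equal(p1$ss_probs[[1]], p2$ss_probs[[1]], tolerance = 1e-12)
})
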