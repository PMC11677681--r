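# Self-describing JSON checkpoints: the configuration needed to rebuild the
# architecture, every parameter array (with dimensions), and the batch-norm
# running statistics.

.state_to_json <- function(state, config, class, extra = list()) {
  ser_param <- function(v) list(dim = dim(v) %||% length(v), data = as.numeric(v))
  list(
    class = class,
    config = unclass(config),
    params = lapply(state$params, ser_param),
    param_names = names(state$params),
    bn = state$bn,
    extra = extra
  )
}

#' Save or load a fitted model checkpoint
#'
#' Checkpoints are plain JSON holding the model configuration, all parameter
#' arrays and batch-norm running statistics; [model_load()] rebuilds the
#' architecture from the embedded configuration and restores the weights.
#'
#' @param fit An `hta_fit` or `mtl_fit`.
#' @param path Output/input file path.
#' @return `model_load()` returns the restored fit object (history omitted
#'   unless stored).
#' @export
model_save <- function(fit, path) {
  stopifnot(inherits(fit, c("hta_fit", "mtl_fit")))
  state <- .clone_state(fit$model)
  obj <- .state_to_json(state, fit$config, class(fit),
                        extra = list(best_epoch = fit$best_epoch))
  obj$history <- as.list(fit$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  is_hta <- "hta_fit" %in% obj$class
  # RNG-independent rebuild: values are overwritten immediately after
  if (is_hta) {
    config <- do.call(hta_config, cfg[c("A", "encoding_channels",
                                        "hidden_channels", "kernel", "B",
                                        "decoder_layers", "decoder_hidden",
                                        "leaky_slope", "mask_mode",
                                        "loss_scope")])
    model <- hta_new(config)
  } else {
    config <- do.call(mtl_config, cfg[c("n_classes_ss", "features",
                                        "use_embedding", "embedding_dim",
                                        "scales", "scale_channels", "E",
                                        "beta", "CH", "M", "tcn_kernel",
                                        "bigru_layers", "bigru_hidden",
                                        "leaky_slope", "rsa_threshold")])
    model <- mtl_new(config)
  }
  vals <- lapply(obj$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1) array(p$data, dim = d) else as.numeric(p$data)
  })
  bn <- if (is.data.frame(obj$bn)) {
    lapply(seq_len(nrow(obj$bn)), function(i) {
      list(mean = as.numeric(obj$bn$mean[[i]]), var = as.numeric(obj$bn$var[[i]]))
    })
  } else {
    obj$bn
  }
  .restore_state(model, list(params = vals, bn = bn))
  history <- if (!is.null(obj$history)) tibble::as_tibble(obj$history) else NULL
  structure(list(model = model, history = history,
                 best_epoch = obj$extra$best_epoch, config = config,
                 train = NULL),
            class = if (is_hta) "hta_fit" else "mtl_fit")
}
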