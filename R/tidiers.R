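#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation into one row per metric
#'
#' @param x A `pssp_evaluation` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble with `metric` and `value` columns.
#' @exportS3Method generics::tidy
tidy.pssp_evaluation <- function(x, ...) x$summary

#' @rdname tidy.pssp_evaluation
#' @exportS3Method generics::glance
glance.pssp_evaluation <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric", values_from = "value")
}

#' Tidy an association analysis into one row per table cell
#'
#' @param x A `pssp_association` from [ss_rsa_association()].
#' @param ... Unused.
#' @return A tibble with `rsa_bin`, `ss8`, `observed` and `expected`.
#' @exportS3Method generics::tidy
tidy.pssp_association <- function(x, ...) {
  O <- unclass(as.matrix(x$counts))
  tibble::tibble(
    rsa_bin = rep(rownames(O), times = ncol(O)),
    ss8 = rep(colnames(O), each = nrow(O)),
    observed = as.numeric(O),
    expected = as.numeric(x$expected)
  )
}

#' @rdname tidy.pssp_association
#' @exportS3Method generics::glance
glance.pssp_association <- function(x, ...) {
  tibble::tibble(cramers_v = x$v, n = x$margins$grand,
                 threshold = x$threshold)
}

#' Tidy a training history into one row per epoch
#'
#' @param x An `hta_fit` or `mtl_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @exportS3Method generics::tidy
tidy.mtl_fit <- function(x, ...) x$history

#' @rdname tidy.mtl_fit
#' @exportS3Method generics::tidy
tidy.hta_fit <- function(x, ...) x$history

#' @rdname tidy.mtl_fit
#' @exportS3Method generics::glance
glance.mtl_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_q = x$history$val_q[x$best_epoch],
                 n_params = n_params(x$model))
}

#' @rdname tidy.mtl_fit
#' @exportS3Method generics::glance
glance.hta_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_accuracy = x$history$val_accuracy[x$best_epoch],
                 n_params = n_params(x$model))
}
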