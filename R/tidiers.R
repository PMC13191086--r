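#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted localization model
#'
#' One row per training epoch with train/test accuracy and loss.
#'
#' @param x A `loc_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_accuracy`, `test_accuracy`,
#'   `train_loss`, `test_loss`.
#' @export
tidy.loc_model <- function(x, ...) {
  x$curves
}

#' @rdname tidy.loc_model
#' @return `glance`: one-row tibble with the final-epoch metrics, the
#'   encoding mode and the data sizes.
#' @export
glance.loc_model <- function(x, ...) {
  last <- tail(x$curves, 1L)
  tibble(
    mode = x$encoder$mode, m = x$encoder$m,
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    epochs = last$epoch,
    n_train = length(x$data$idx_train %||% integer()),
    n_test = length(x$data$idx_test %||% integer()),
    train_accuracy = last$train_accuracy,
    test_accuracy = last$test_accuracy,
    train_loss = last$train_loss,
    test_loss = last$test_loss
  )
}

#' Tidy an evaluation object
#'
#' @param x A `loc_eval`.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return The requested curve as a tibble.
#' @export
tidy.loc_eval <- function(x, curve = c("roc", "pr"), ...) {
  x[[match.arg(curve)]]
}

#' @rdname tidy.loc_eval
#' @export
glance.loc_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, auroc = x$auroc, auprc = x$auprc)
}
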