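#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation results of an end classifier
#'
#' @param x An `end_classifier`.
#' @param ... Unused.
#' @return A tibble of grid-search rounds, hyperparameter combinations and
#'   cross-validated accuracies.
#' @method tidy end_classifier
#' @export
tidy.end_classifier <- function(x, ...) {
  dplyr::mutate(x$cv_results, algorithm = x$algorithm,
                .before = 1L)
}

#' One-row summary of a fitted end classifier
#'
#' @param x An `end_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, chosen hyperparameters (as a
#'   packed string), cross-validated accuracy, and held-out confusion
#'   counts and accuracy when available.
#' @method glance end_classifier
#' @export
glance.end_classifier <- function(x, ...) {
  out <- tibble(
    algorithm = x$algorithm,
    hyperparameters = paste(names(x$hyperparameters),
                            signif(unlist(x$hyperparameters), 4),
                            sep = "=", collapse = ", "),
    cv_acc = x$cv_acc
  )
  if (!is.null(x$metrics)) out <- dplyr::bind_cols(out, x$metrics)
  out
}

#' @rdname glance.end_classifier
#' @method glance end_classifier_set
#' @export
glance.end_classifier_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance.end_classifier))
}

#' @rdname tidy.end_classifier
#' @method tidy end_classifier_set
#' @export
tidy.end_classifier_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy.end_classifier))
}
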