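#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding report
#'
#' One row per cross-validation fold, for both the real model and (if
#' computed) the shuffled-label null.
#'
#' @param x A `decoding_report`.
#' @param ... Unused.
#' @return A tibble: `model`, `rep`, `fold`, `auc`.
#' @export
tidy.decoding_report <- function(x, ...) {
  out <- dplyr::mutate(x$fold_aucs, model = "real", .before = 1)
  if (!is.null(x$null)) {
    out <- dplyr::bind_rows(out,
      dplyr::mutate(x$null$null_fold_aucs, model = "null", .before = 1))
  }
  out
}

#' @rdname tidy.decoding_report
#' @return `glance()`: a one-row tibble with `mean_auc`, `n_folds`,
#'   `null_mean_auc`, `p_value`, and the main CV parameters.
#' @export
glance.decoding_report <- function(x, ...) {
  tibble::tibble(
    mean_auc = x$mean_auc,
    n_folds = nrow(x$fold_aucs),
    null_mean_auc = if (is.null(x$null)) NA_real_ else x$null$null_mean_auc,
    p_value = if (is.null(x$null)) NA_real_ else x$null$p_value,
    k = x$params$k, repeats = x$params$repeats,
    nrounds = x$params$nrounds, max_depth = x$params$max_depth,
    seed = x$seed
  )
}
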