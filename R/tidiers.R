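#' Tidy a gradient embedding
#'
#' One row per unit and component, with the component score.
#'
#' @param x A `gradient_embedding` or `aligned_gradients`.
#' @param ... Unused.
#' @return A tibble (unit, component, score).
#' @exportS3Method generics::tidy
tidy.gradient_embedding <- function(x, ...) {
  m <- x$components
  tibble(unit = rep(rownames(m) %||% as.character(seq_len(nrow(m))), ncol(m)),
         component = rep(colnames(m), each = nrow(m)),
         score = as.vector(m))
}

#' @rdname tidy.gradient_embedding
#' @exportS3Method generics::tidy
tidy.aligned_gradients <- tidy.gradient_embedding

#' Glance at a gradient embedding
#'
#' @param x A `gradient_embedding`.
#' @param ... Unused.
#' @return One-row tibble: n_units, n_components, lambda_1, var_explained_1.
#' @exportS3Method generics::glance
glance.gradient_embedding <- function(x, ...) {
  tibble(n_units = nrow(x$components), n_components = ncol(x$components),
         lambda_1 = x$eigenvalues[1],
         var_explained_1 = x$variance_explained[1])
}

#' Tidy a state model
#'
#' One row per state with its size and within-cluster SSE share.
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return A tibble (state, n_windows, occupancy).
#' @exportS3Method generics::tidy
tidy.state_model <- function(x, ...) {
  tibble(state = seq_len(x$k), n_windows = x$sizes,
         occupancy = x$sizes / sum(x$sizes))
}

#' Glance at a state model
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return One-row tibble: k, n_windows, sse, n_restarts, seed.
#' @exportS3Method generics::glance
glance.state_model <- function(x, ...) {
  tibble(k = x$k, n_windows = length(x$cluster), sse = x$sse,
         n_restarts = x$n_restarts, seed = x$seed)
}

#' Tidy a state quality scan
#'
#' @param x A `state_quality_scan`.
#' @param ... Unused.
#' @return The per-k scan tibble with the chosen k flagged.
#' @exportS3Method generics::tidy
tidy.state_quality_scan <- function(x, ...) {
  out <- x$scan
  out$chosen <- out$k == x$chosen_k
  out
}

#' Tidy a state contrast
#'
#' @param x A `state_contrast`.
#' @param ... Unused.
#' @return The per-edge tibble (edge/feature, t, df, p, q).
#' @exportS3Method generics::tidy
tidy.state_contrast <- function(x, ...) x$edges

#' Glance at an LOOCV classification report
#'
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @return One-row tibble of the confusion metrics plus fold count.
#' @exportS3Method generics::glance
glance.loocv_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble(folds = x$folds, cost = x$cost))
}

#' Tidy an LOOCV classification report
#'
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @return The feature-ranking tibble.
#' @exportS3Method generics::tidy
tidy.loocv_report <- function(x, ...) x$feature_ranking

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
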