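#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a neutral-model fit
#'
#' @param x An `ncm_fit`.
#' @param ... Unused.
#' @return The per-taxon tibble (`taxon`, `p`, `freq_obs`, `freq_pred`,
#'   `lower`, `upper`, `partition`).
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @rdname tidy.ncm_fit
#' @return For `glance`, a one-row tibble with `Nm`, its CI, `r_squared`,
#'   `detection_limit`, `n_samples`, `n_taxa`.
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(Nm = x$Nm, Nm_lower = x$Nm_lower, Nm_upper = x$Nm_upper,
                 r_squared = x$r_squared, detection_limit = x$detection_limit,
                 n_samples = x$n_samples, n_taxa = nrow(x$taxa))
}

#' Tidy a null-model result
#'
#' @param x A `null_model_result`.
#' @param ... Unused.
#' @return `tidy`: the per-pair tibble; `glance`: the per-group summary.
#' @export
tidy.null_model_result <- function(x, ...) x$pairs

#' @rdname tidy.null_model_result
#' @export
glance.null_model_result <- function(x, ...) x$summary

#' Tidy a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return `tidy`: the retained importance ranking; `glance`: a one-row
#'   tibble of accuracies and split sizes.
#' @export
tidy.classifier_report <- function(x, ...) x$importance

#' @rdname tidy.classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(train_accuracy = x$train_accuracy,
                 test_accuracy = x$test_accuracy,
                 top_k = x$top_k, n_train = x$n_train, n_test = x$n_test)
}

#' Tidy a discrimination report
#'
#' @param x A `discrimination_report`.
#' @param ... Unused.
#' @return `tidy`: the per-individual unique-species tibble; `glance`: a
#'   one-row summary.
#' @export
tidy.discrimination_report <- function(x, ...) x$unique_species

#' @rdname tidy.discrimination_report
#' @export
glance.discrimination_report <- function(x, ...) {
  tibble::tibble(fraction = x$fraction, n_individuals = x$n_individuals,
                 n_core = length(x$core), rank_threshold = x$rank_threshold,
                 habitat = x$habitat)
}
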