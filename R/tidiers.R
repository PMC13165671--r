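# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained SENN: per-epoch training history
#' @param x A `senn_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (learning rate, loss components,
#'   accuracies, validation AUCs).
#' @export
tidy.senn_model <- function(x, ...) x$history

#' One-row summary of a trained SENN
#' @param x A `senn_model`.
#' @param ... Unused.
#' @return Tibble with epoch counts, best smoothed epoch, best validation
#'   AUC, parameter count and seed.
#' @export
glance.senn_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_auc = max(x$history$val_auc),
    n_parameters = sum(vapply(x$params, length, 0L)),
    seed = x$seed)
}

#' Tidy an experiment run: the subject-level metric row
#' @param x A `senn_run`.
#' @param ... Unused.
#' @return One-row tibble of test metrics (sensitivity, specificity,
#'   accuracy, F1, ROC-AUC, average precision, Brier, ECE, tau,
#'   temperature).
#' @export
tidy.senn_run <- function(x, ...) dplyr::mutate(x$metrics, seed = x$seed)

#' One-row summary of an experiment run
#' @param x A `senn_run`.
#' @param ... Unused.
#' @return Tibble with seed, subjects evaluated, AUC and operating point.
#' @export
glance.senn_run <- function(x, ...) {
  tibble::tibble(seed = x$seed,
                 n_test_subjects = length(x$subject_probs),
                 roc_auc = x$metrics$roc_auc, tau = x$metrics$tau,
                 temperature = x$metrics$temperature)
}

#' Tidy a concept report: per-concept statistics
#' @param x A `concept_report`.
#' @param ... Unused.
#' @return Tibble ordered by the discriminative ranking (class gap
#'   descending).
#' @export
tidy.concept_report <- function(x, ...) x$stats[x$ranking, ]
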