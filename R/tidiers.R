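#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model selection table
#'
#' One row per candidate model with its AIC ranking statistics.
#'
#' @param x a `model_table` from [exhaustive_logistic()].
#' @param ... unused.
#' @return A tibble: `model`, `k`, `logLik`, `aic`, `delta_aic`, `weight`,
#'   `supported`, `converged`.
#' @export
tidy.model_table <- function(x, ...) {
  tibble::as_tibble(x)[c("model", "k", "logLik", "aic", "delta_aic",
                         "weight", "supported", "converged")]
}

#' Glance at a model selection table
#'
#' @param x a `model_table` from [exhaustive_logistic()].
#' @param ... unused.
#' @return A one-row tibble: `n_models`, `best_model`, `best_aic`,
#'   `n_supported` (models within 2 AIC of the best), `weight_best`.
#' @export
glance.model_table <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    best_model = x$model[1],
    best_aic = x$aic[1],
    n_supported = sum(x$supported),
    weight_best = x$weight[1]
  )
}

#' Tidy a validation report
#'
#' @param x a `validation_report` from [validate_hotspots()].
#' @param ... unused.
#' @return A tibble with the raw and length-corrected distance contrasts.
#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$comparison, correction = "none", .before = 1),
    dplyr::mutate(x$comparison_corrected, correction = "half_mean_length",
                  .before = 1)
  )
}

#' Glance at a validation report
#'
#' @param x a `validation_report` from [validate_hotspots()].
#' @param ... unused.
#' @return A one-row tibble of the headline validation numbers.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_hotspots = length(x$hotspot_distances),
    n_intersecting_lcp = x$n_hotspots_intersecting_lcp,
    median_ratio = x$comparison$ratio,
    p = x$comparison$p,
    record_fraction = x$fractions$record_fraction,
    length_fraction = x$fractions$length_fraction
  )
}
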