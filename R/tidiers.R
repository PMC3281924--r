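#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated contrast
#'
#' @param x A `moderated_contrast` from [moderate()].
#' @param ... Unused.
#' @return A plain tibble of per-gene statistics.
#' @export
tidy.moderated_contrast <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a moderated contrast
#'
#' Reports the estimated variance-prior hyperparameters (`d0`, `s0sq`), the
#' gene count and the number of genes at q < 0.05.
#'
#' @inheritParams tidy.moderated_contrast
#' @export
glance.moderated_contrast <- function(x, ...) {
  tibble::tibble(
    d0 = attr(x, "d0"),
    s0sq = attr(x, "s0sq"),
    n_genes = nrow(x),
    n_q05 = sum(x$q < 0.05)
  )
}

#' Tidy a time-course fit
#' @param x A `timecourse_fit` from [anova_timecourse()].
#' @param ... Unused.
#' @export
tidy.timecourse_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a time-course fit
#' @inheritParams tidy.timecourse_fit
#' @export
glance.timecourse_fit <- function(x, ...) {
  tibble::tibble(
    tissue = attr(x, "tissue"),
    n_stages = length(attr(x, "stages")),
    n_genes = nrow(x),
    n_p001 = sum(x$p < 1e-3)
  )
}

#' Tidy an enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}
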