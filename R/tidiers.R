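#' @importFrom generics tidy glance
NULL

#' Tidy a fitted flow model
#'
#' Returns the global codon dwell times and normalised rates, one row per
#' sense codon present in the data.
#'
#' @param x A `flow_fit` object.
#' @param ... Unused.
#' @return Tibble `codon`, `mu`, `rate` (min-normalised).
#' @export
tidy.flow_fit <- function(x, ...) {
  dplyr::left_join(x$dwell_global, codon_rates(x), by = "codon")
}

#' One-row summary of a fitted flow model
#'
#' @param x A `flow_fit` object.
#' @param ... Unused.
#' @return Tibble with fit dimensions, configuration and final objective.
#' @export
glance.flow_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$flows),
    n_codons = nrow(x$dwell_global),
    C = x$config$C,
    mode = x$config$mode,
    loss = x$config$loss,
    n_sweeps = x$config$n_sweeps,
    objective = utils::tail(x$trace, 1)
  )
}

#' Tidy a Kozak TE-regression fit
#'
#' @param x A `kozak_fit` object.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` of averaged feature weights (including
#'   the Kozak feature weight).
#' @export
tidy.kozak_fit <- function(x, ...) {
  tibble::tibble(term = names(x$w), estimate = unname(x$w))
}

#' One-row summary of a Kozak TE-regression fit
#'
#' @param x A `kozak_fit` object.
#' @param ... Unused.
#' @return Tibble with chosen penalties, mean test and null errors.
#' @export
glance.kozak_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = x$config$n,
    n_splits = x$config$n_splits,
    test_size = x$config$test_size,
    lambda1 = x$lambda1,
    lambda2 = x$lambda2,
    test_error = x$test_error,
    null_error = x$null_error
  )
}
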