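#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy variance components
#'
#' @param x a `variance_components` fit from [heritability()].
#' @param ... ignored.
#' @return A tibble with one row per variance component.
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(
    component = c("additive", "residual"),
    estimate = c(x$sigma_a2, x$sigma_e2)
  )
}

#' One-row summary of a heritability fit
#'
#' @param x a `variance_components` fit.
#' @param ... ignored.
#' @return A one-row tibble (`h2`, `loglik`, `converged`, `n`).
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(h2 = x$h2, loglik = x$loglik,
                 converged = x$converged, n = x$n)
}

#' Tidy per-SNP Fst
#'
#' @param x an `fst_result` from [wc_fst()].
#' @param ... ignored.
#' @return The per-SNP tibble.
#' @export
tidy.fst_result <- function(x, ...) x$per_snp

#' One-row summary of an Fst computation
#'
#' @param x an `fst_result`.
#' @param ... ignored.
#' @return A one-row tibble with the genome-wide ratio-of-sums estimate.
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(comparison = paste(x$labels, collapse = "-"),
                 fst = x$overall,
                 n_snps = sum(is.finite(x$per_snp$fst)))
}

#' Tidy a Pst estimate
#'
#' @param x a `pst_result` from [pst()].
#' @param ... ignored.
#' @return A one-row tibble with estimate and bootstrap interval.
#' @export
tidy.pst_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$ci[1],
                 conf.high = x$ci[2], fst_mean = x$fst_mean %||% NA_real_)
}
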