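#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rose histogram into a plain tibble
#'
#' @param x A [rose_histogram()].
#' @param ... Unused.
#' @return A tibble with `bin`, `bin_start`, `bin_end`, `weight`,
#'   `proportion` and `n_cells`.
#' @export
tidy.rose_histogram <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_cells <- attr(x, "n_cells") %||% NA_integer_
  class(out) <- class(tibble::tibble())
  out
}

#' Tidy a position distribution into a plain tibble
#'
#' @param x A [position_distribution()].
#' @param ... Unused.
#' @return A tibble with `bin_start`, `bin_end`, `count`, `frequency` and
#'   `n_cells`.
#' @export
tidy.position_distribution <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_cells <- attr(x, "n_cells") %||% NA_integer_
  class(out) <- class(tibble::tibble())
  out
}
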