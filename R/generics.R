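#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.cr_classification <- function(x, ...) {
  tibble::as_tibble(x$typed)
}

#' @export
glance.cr_classification <- function(x, ...) {
  tibble::tibble(
    n_type1 = unname(x$counts[["1"]]),
    n_type2 = unname(x$counts[["2"]]),
    n_type3 = unname(x$counts[["3"]]),
    n_type4 = unname(x$counts[["4"]]),
    n_typed = nrow(x$typed),
    n_unclassified = nrow(x$unclassified))
}
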