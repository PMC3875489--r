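#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
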