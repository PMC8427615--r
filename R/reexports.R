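# Generics re-exported so users can call tidy()/glance()/autoplot()/
# as_tibble() without attaching the generics packages themselves.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
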