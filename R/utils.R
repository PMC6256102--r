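#' @importFrom rlang .data
#' @importFrom stats predict
NULL

#' @export
`[.dtc_corpus` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "classes") <- attr(x, "classes")
    if (!inherits(out, "dtc_corpus")) class(out) <- c("dtc_corpus", class(out))
  }
  out
}
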