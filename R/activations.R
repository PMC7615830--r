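# Elementwise activation functions and their derivatives.
# All operate on numeric vectors/matrices and preserve shape.

.activations <- list(
  linear = list(
    f = function(x) x,
    fprime = function(x) array(1, dim = dim(x) %||% length(x))
  ),
  sigmoid = list(
    f = function(x) 1 / (1 + exp(-x)),
    fprime = function(x) {
      s <- 1 / (1 + exp(-x))
      s * (1 - s)
    }
  ),
  leaky_relu = list(
    f = function(x) ifelse(x > 0, x, 0.01 * x),
    fprime = function(x) ifelse(x > 0, 1, 0.01)
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

.get_activation <- function(name) {
  act <- .activations[[name]]
  if (is.null(act)) {
    stop("unknown activation '", name, "'; supported: ",
         paste(names(.activations), collapse = ", "), call. = FALSE)
  }
  act
}
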