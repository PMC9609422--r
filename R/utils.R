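#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for reported percentages and cluster scores. Base `round()` rounds half to
#' even, which would turn e.g. 81.245 into 81.24.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  # small epsilon guards binary-representation shortfalls like 2.675*100 = 267.49999
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# loop-free density of a simple undirected graph; 0 by convention for n < 2
simple_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds for independent RNG streams, kept under 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}
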