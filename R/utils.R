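# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Cubic smoothstep on [0, 1]; 0 below, 1 above.
sstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Deterministic per-pixel sub-seed
#'
#' Derives a reproducible, pixel-order-independent seed from a scene seed and
#' a (row, col) position, so that scenes can be simulated pixel by pixel in
#' any order with identical output.
#'
#' @param seed integer scene seed.
#' @param row,col 1-based pixel position.
#' @return A single integer below 2^31.
#' @keywords internal
sub_seed <- function(seed, row, col) {
  # mix with distinct large primes; modulus keeps the value a valid R seed
  as.integer((as.double(seed) * 2654435761 + row * 40503 + col * 69621) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
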