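# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Close a non-negative vector to sum 1
#'
#' @param x numeric vector, all entries >= 0.
#' @return `x / sum(x)`; errors if the sum is zero or any entry negative.
#' @keywords internal
close_composition <- function(x) {
  if (any(x < 0)) stop("composition entries must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("cannot close a zero-sum composition")
  x / s
}

# Check that a composition sums to 1 within tol.
assert_closed <- function(x, tol = 1e-9, what = "composition") {
  if (any(x < -tol)) stop(sprintf("%s has negative entries", what))
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("%s does not sum to 1 (sum = %.12g)", what, sum(x)))
  }
  invisible(TRUE)
}

# Deterministic seed derivation: keep results reproducible when a function
# needs several independent streams from one user-supplied seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647L)
}

# Stable group letters: A, B, C, ..., Z, AA, AB, ... for > 26 groups.
group_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}
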