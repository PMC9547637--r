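#' @keywords internal
"_PACKAGE"

## Ring arithmetic on Z_{2^ell} stored in doubles.
##
## All values live in [0, 2^ell) with ell <= 48 so that every intermediate of
## the limb-split multiplication below stays below 2^53 and is therefore exact
## in IEEE doubles.  The cap is enforced at config validation.

RING_MAX_BITS <- 48L
LIMB <- 2^24

ring_modulus <- function(ell) 2^ell

addmod <- function(a, b, ell) (a + b) %% 2^ell

submod <- function(a, b, ell) (a - b) %% 2^ell

#' Exact multiplication modulo 2^ell via 24-bit limbs
#' @noRd
mulmod <- function(a, b, ell) {
  if (ell <= 24) return((a * b) %% 2^ell)
  ah <- a %/% LIMB; al <- a %% LIMB
  bh <- b %/% LIMB; bl <- b %% LIMB
  # a*b = ah*bh*2^48 + (ah*bl + al*bh)*2^24 + al*bl ; first term vanishes mod
  # 2^ell for ell <= 48
  cross <- (ah * bl + al * bh) %% 2^(ell - 24L)
  (cross * LIMB + al * bl) %% 2^ell
}

#' Uniform draw on [0, 2^ell) using two 24-bit slices
#' @noRd
ring_runif <- function(n, ell) {
  if (ell <= 24) return(floor(stats::runif(n) * 2^ell))
  hi <- floor(stats::runif(n) * 2^(ell - 24L))
  lo <- floor(stats::runif(n) * LIMB)
  hi * LIMB + lo
}

## 31 fresh bits per RNG draw via intToBits (raw 0/1 output, LSB-first);
## the 2^-32 per-bit bias of the draw is far below anything the statistical
## share tests could resolve
random_bits_raw <- function(n) {
  if (n <= 0) return(raw(0))
  m <- ceiling(n / 31)
  iv <- as.integer(floor(stats::runif(m) * 2147483647))
  bits <- as.vector(matrix(intToBits(iv), 32L, m)[seq_len(31L), ,
                                                  drop = FALSE])
  length(bits) <- n
  bits
}

#' Integer (double) vector to LSB-first bit matrix
#' @noRd
int_to_bits <- function(v, width) {
  out <- matrix(raw(length(v) * width), nrow = length(v))
  x <- v
  for (j in seq_len(width)) {
    out[, j] <- as.raw(x %% 2)
    x <- x %/% 2
  }
  out
}

#' LSB-first 0/1 raw matrix to double vector
#' @noRd
bits_to_int <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, ncol = 1L)
  w <- ncol(bits)
  drop(matrix(as.numeric(bits != as.raw(0)), ncol = w) %*% 2^(seq_len(w) - 1L))
}

## Modular sums of ring elements.  Summands approach 2^48, so plain sums of
## more than 2^5 terms would leave the exactly-representable double range;
## accumulate in chunks of 16 with a reduction after each chunk.

sum_mod <- function(v, ell) {
  acc <- 0
  idx <- seq_along(v)
  for (ch in split(idx, ceiling(idx / 16))) {
    acc <- addmod(acc, sum(v[ch]), ell)
  }
  acc
}

rowsum_mod <- function(mat, ell) {
  acc <- numeric(nrow(mat))
  idx <- seq_len(ncol(mat))
  for (ch in split(idx, ceiling(idx / 16))) {
    acc <- addmod(acc, rowSums(mat[, ch, drop = FALSE]), ell)
  }
  acc
}

## -- misc ------------------------------------------------------------------

#' All permutations of seq_len(r), deterministic lexicographic order
#' @noRd
all_permutations <- function(r) {
  if (r == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(r)) {
    rest <- all_permutations(r - 1L)
    rem <- setdiff(seq_len(r), i)
    for (p in rest) out[[length(out) + 1L]] <- c(i, rem[p])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
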