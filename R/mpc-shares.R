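## Full-threshold secret sharing.
##
## Boolean shares are raw 0/1 matrices (lanes x width, one row per
## independent protocol lane); the XOR of all parties' matrices reconstructs
## the secret bits.  Arithmetic shares are numeric vectors of ring elements
## in [0, 2^ell); the sum modulo 2^ell reconstructs.  Shares travel in plain
## lists `xs[[party]]`.

as_bitmat <- function(v) {
  if (is.raw(v)) {
    if (is.null(dim(v))) matrix(v, ncol = 1L) else v
  } else {
    m <- as.matrix(v) * 1
    matrix(as.raw(m != 0), nrow = nrow(m))
  }
}

#' Split a bit vector into full-threshold XOR shares
#'
#' The first `n - 1` shares are uniform random bits; the last is the XOR of
#' all previous shares and the secret, so any proper subset of shares is
#' independent of the secret.
#'
#' @param v Secret bits: raw/logical/0-1 vector or matrix (rows = lanes).
#' @param n_parties Number of shares.
#' @param rng Optional RNG stream (see internals); default session RNG.
#' @return List of `n_parties` raw matrices.
#' @export
share_bool <- function(v, n_parties = 2L, rng = NULL) {
  stopifnot(n_parties >= 2L)
  v <- as_bitmat(v)
  nb <- length(v)
  draw <- function() {
    b <- if (is.null(rng)) random_bits_raw(nb) else {
      with_stream(rng, random_bits_raw(nb))
    }
    matrix(b, nrow = nrow(v))
  }
  shares <- lapply(seq_len(n_parties - 1L), function(i) draw())
  last <- Reduce(xor, shares, accumulate = FALSE) |> xor(v)
  c(shares, list(last))
}

#' Reconstruct a Boolean-shared secret
#' @param shares List of raw share matrices of equal dimension.
#' @return Raw 0/1 matrix.
#' @export
reconstruct_bool <- function(shares) {
  dims <- unique(lapply(shares, dim))
  if (length(dims) != 1L) stop("share width/shape mismatch", call. = FALSE)
  Reduce(xor, shares)
}

#' Split a ring element into additive arithmetic shares
#'
#' First `n - 1` shares uniform on the ring, last share
#' `v - sum(others) mod 2^ell`.
#'
#' @param v Secrets in `[0, 2^ell)` (numeric vector).
#' @param n_parties Number of shares.
#' @param ring_bits Ring width `ell`.
#' @param rng Optional RNG stream.
#' @return List of numeric share vectors.
#' @export
share_arith <- function(v, n_parties = 2L, ring_bits = 48L, rng = NULL) {
  stopifnot(n_parties >= 2L)
  if (any(v < 0 | v >= 2^ring_bits)) {
    stop("secret outside ring [0, 2^ring_bits)", call. = FALSE)
  }
  draw <- function() {
    if (is.null(rng)) ring_runif(length(v), ring_bits) else {
      with_stream(rng, ring_runif(length(v), ring_bits))
    }
  }
  shares <- lapply(seq_len(n_parties - 1L), function(i) draw())
  tot <- Reduce(function(a, b) addmod(a, b, ring_bits), shares)
  c(shares, list(submod(v, tot, ring_bits)))
}

#' Reconstruct an arithmetically shared secret
#' @param shares List of numeric share vectors.
#' @param ring_bits Ring width.
#' @return Numeric vector of secrets.
#' @export
reconstruct_arith <- function(shares, ring_bits = 48L) {
  Reduce(function(a, b) addmod(a, b, ring_bits), shares)
}

## public constants as degenerate sharings (party 1 holds the value)
const_bool <- function(bits, n) {
  bits <- as_bitmat(bits)
  c(list(bits), rep(list(matrix(raw(length(bits)), nrow = nrow(bits))),
                    n - 1L))
}

const_arith <- function(v, n) {
  c(list(as.numeric(v)), rep(list(numeric(length(v))), n - 1L))
}

## -- local gates ------------------------------------------------------------

bxor <- function(xs, ys) Map(xor, xs, ys)

bnot <- function(xs) {
  xs[[1]] <- xor(xs[[1]], rep(as.raw(1), length(xs[[1]])))
  xs
}

aadd <- function(xs, ys, ell) Map(function(a, b) addmod(a, b, ell), xs, ys)
asub <- function(xs, ys, ell) Map(function(a, b) submod(a, b, ell), xs, ys)
asmul_const <- function(xs, k, ell) lapply(xs, function(a) mulmod(a, k, ell))
aadd_const <- function(xs, k, ell) {
  xs[[1]] <- addmod(xs[[1]], k, ell)
  xs
}

#' Local share operations
#'
#' XOR of Boolean shares and addition of arithmetic shares are evaluated
#' locally by each party on its own shares, with no communication.
#'
#' @param xs,ys Lists of per-party shares (raw matrices for `xor_gate`,
#'   numeric ring vectors for `add_local`).
#' @param ring_bits Ring width for `add_local`.
#' @return List of result shares.
#' @export
xor_gate <- function(xs, ys) bxor(xs, ys)

#' @rdname xor_gate
#' @export
add_local <- function(xs, ys, ring_bits = 48L) aadd(xs, ys, ring_bits)

## -- openings and reconstructions ------------------------------------------

## internal opening of (uniformly masked) protocol values: every party sends
## its piece to every other; not an output reconstruction
open_bool <- function(ctx, xs) {
  ctx$open_count <- ctx$open_count + 1L
  broadcast_values(ctx, xs)
  reconstruct_bool(xs)
}

open_arith <- function(ctx, xs) {
  ctx$open_count <- ctx$open_count + 1L
  broadcast_values(ctx, xs)
  reconstruct_arith(xs, ctx$ring)
}

#' Reveal a shared output value to all parties
#'
#' The only operation that turns shares back into a secret by design; the
#' secure linkage audits that it runs exactly twice per protocol execution
#' (once per revealed count).
#'
#' @param ctx An [mpc_context()].
#' @param xs List of shares (raw matrices or numeric vectors).
#' @param type `"arith"` or `"bool"`.
#' @return The reconstructed public value.
#' @export
reveal <- function(ctx, xs, type = c("arith", "bool")) {
  type <- match.arg(type)
  ctx$reveal_count <- ctx$reveal_count + 1L
  if (ctx$metering) {
    return(if (type == "arith") numeric(length(xs[[1]])) else xs[[1]])
  }
  broadcast_values(ctx, xs)
  if (type == "arith") reconstruct_arith(xs, ctx$ring) else reconstruct_bool(xs)
}

## -- interactive gates ------------------------------------------------------

#' Shared AND via a Beaver triple
#'
#' Parties open `d = x XOR a`, `e = y XOR b` (uniformly masked, so the
#' transcript is independent of the inputs) and locally combine
#' `c XOR (d AND b) XOR (e AND a)`, with party 1 additionally adding
#' `d AND e`.
#'
#' @param ctx An [mpc_context()] with provisioned pools.
#' @param xs,ys Lists of Boolean share matrices of equal shape.
#' @return List of Boolean share matrices of `x AND y`.
#' @export
and_gate <- function(ctx, xs, ys) {
  dm <- dim(xs[[1]])
  nb <- length(xs[[1]])
  if (ctx$metering) {
    ctx$meter$bool_bits <- ctx$meter$bool_bits + nb
    z <- raw(nb)
    if (!is.null(dm)) dim(z) <- dm
    return(rep(list(z), ctx$n))
  }
  tr <- consume_bool_triple(ctx, nb)
  ctx$open_count <- ctx$open_count + 1L
  ds <- Map(function(x, t) xor(x, t$a), xs, tr)
  es <- Map(function(y, t) xor(y, t$b), ys, tr)
  broadcast_values(ctx, Map(list, ds, es))
  d <- Reduce(xor, ds)
  e <- Reduce(xor, es)
  zs <- Map(function(t) xor(xor(d & t$b, e & t$a), t$c), tr)
  zs[[1]] <- xor(zs[[1]], d & e)
  zs
}

#' Shared multiplication via an arithmetic Beaver triple
#'
#' @param ctx An [mpc_context()] with provisioned pools.
#' @param xs,ys Lists of arithmetic share vectors.
#' @return List of arithmetic shares of `x * y mod 2^ell`.
#' @export
mul_beaver <- function(ctx, xs, ys) {
  nl <- length(xs[[1]])
  ell <- ctx$ring
  if (ctx$metering) {
    ctx$meter$arith <- ctx$meter$arith + nl
    return(lapply(seq_len(ctx$n), function(i) numeric(nl)))
  }
  tr <- consume_arith_triple(ctx, nl)
  ctx$open_count <- ctx$open_count + 1L
  ds <- Map(function(x, t) submod(x, t$a, ell), xs, tr)
  es <- Map(function(y, t) submod(y, t$b, ell), ys, tr)
  broadcast_values(ctx, Map(list, ds, es))
  d <- Reduce(function(a, b) addmod(a, b, ell), ds)
  e <- Reduce(function(a, b) addmod(a, b, ell), es)
  zs <- Map(function(t) {
    addmod(t$c, addmod(mulmod(d, t$b, ell), mulmod(e, t$a, ell), ell), ell)
  }, tr)
  zs[[1]] <- addmod(zs[[1]], mulmod(d, e, ell), ell)
  zs
}

#' Boolean-to-arithmetic share conversion of single bits
#'
#' Consumes one dealer bit correlation per lane: a random bit `r` shared both
#' Boolean and arithmetically.  The parties open the masked bit
#' `z = x XOR r` and locally output `z + r - 2 z r` on the ring.
#'
#' @param ctx An [mpc_context()] with provisioned pools.
#' @param xs Lists of single-bit Boolean shares (lane vectors).
#' @return List of arithmetic shares reconstructing the same 0/1 value.
#' @export
b2a <- function(ctx, xs) {
  xs <- lapply(xs, function(x) as.raw(x))
  nl <- length(xs[[1]])
  ell <- ctx$ring
  if (ctx$metering) {
    ctx$meter$b2a <- ctx$meter$b2a + nl
    return(lapply(seq_len(ctx$n), function(i) numeric(nl)))
  }
  cr <- consume_b2a(ctx, nl)
  ctx$open_count <- ctx$open_count + 1L
  masked <- Map(function(x, c) xor(x, c$rb), xs, cr)
  broadcast_values(ctx, masked)
  z <- as.numeric(Reduce(xor, masked) != as.raw(0))
  # x = z XOR r = z + r - 2 z r on the ring; z is public, so share_i =
  # delta_{i,1} z + ra_i - 2 z ra_i.  (1 - 2z) * ra stays below 2^49 in
  # magnitude, so the product is exact without limb splitting.
  Map(function(c, i) {
    base <- (c$ra * (1 - 2 * z)) %% 2^ell
    if (i == 1L) addmod(base, z, ell) else base
  }, cr, seq_along(cr))
}
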