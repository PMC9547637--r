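## Share-level circuits built from XOR/AND and the arithmetic primitives.
## Bit matrices are LSB-first: column j holds bit 2^(j-1) of every lane.

col_of <- function(xs, j) lapply(xs, function(m) m[, j])
cbind_shares <- function(...) {
  args <- list(...)
  n <- length(args[[1]])
  lapply(seq_len(n), function(i) {
    do.call(cbind, lapply(args, function(a) a[[i]]))
  })
}
slice_cols <- function(xs, cols) lapply(xs, function(m) m[, cols, drop = FALSE])

zero_bool <- function(ctx, lanes, width) {
  lapply(seq_len(ctx$n), function(i) matrix(raw(lanes * width), lanes, width))
}

broadcast_bit <- function(cs, width) {
  lapply(cs, function(c) matrix(c, length(c), width))
}

## ripple-carry addition of two Boolean-shared integers (lanes x width),
## one AND gate per bit; returns sum (mod 2^width) and the carry-out bit
ripple_add <- function(ctx, as, bs, carry_in = 0L) {
  lanes <- nrow(as[[1]])
  width <- ncol(as[[1]])
  carry <- const_bool(matrix(as.raw(rep(carry_in, lanes)), lanes, 1), ctx$n)
  carry <- lapply(carry, as.vector)
  sum_sh <- lapply(seq_len(ctx$n), function(i) matrix(raw(lanes * width), lanes, width))
  for (j in seq_len(width)) {
    aj <- col_of(as, j)
    bj <- col_of(bs, j)
    axc <- bxor(aj, carry)
    bxc <- bxor(bj, carry)
    sj <- bxor(axc, bj)
    t <- and_gate(ctx, axc, bxc)
    carry <- bxor(lapply(t, as.vector), carry)
    for (i in seq_len(ctx$n)) sum_sh[[i]][, j] <- sj[[i]]
  }
  list(sum = sum_sh, carry = carry)
}

## a - b via a + NOT(b) + 1; carry-out reconstructs [a >= b]
ripple_sub <- function(ctx, as, bs) {
  r <- ripple_add(ctx, as, bnot(bs), carry_in = 1L)
  list(diff = r$sum, ge = r$carry)
}

## Boolean multiplexer: selector bit s (per lane) chooses x (s=1) or y
bmux <- function(ctx, cs, xs, ys) {
  width <- ncol(xs[[1]])
  d <- bxor(xs, ys)
  sel <- and_gate(ctx, broadcast_bit(cs, width), d)
  bxor(ys, sel)
}

#' Arithmetic-to-Boolean share conversion
#'
#' Each party Boolean-shares its own arithmetic share truncated to `width`
#' bits; the sharings are then summed with shared ripple-carry adders,
#' yielding Boolean shares of the secret's low `width` bits.
#'
#' @param ctx An [mpc_context()].
#' @param xs Arithmetic shares (lane vectors).
#' @param width Output bit width (secret must fit if full value is needed).
#' @return Boolean shares, lanes x width, LSB first.
#' @export
a2b <- function(ctx, xs, width) {
  lanes <- length(xs[[1]])
  sharings <- lapply(seq_len(ctx$n), function(i) {
    bits <- int_to_bits(xs[[i]] %% 2^width, width)
    if (ctx$metering) {
      const_bool(matrix(raw(length(bits)), nrow(bits)), ctx$n) # shape only
    } else {
      share_bool(bits, ctx$n, rng = ctx$party_rng[[i]])
    }
  })
  acc <- sharings[[1]]
  for (i in seq_len(ctx$n)[-1]) {
    acc <- ripple_add(ctx, acc, sharings[[i]])$sum
  }
  acc
}

#' Oblivious greater-or-equal comparison
#'
#' Computes the sign bit of `u - v` on the ring via [a2b()] and negates it,
#' so the result bit reconstructs `1` iff `u >= v`.  Caller must guarantee
#' both secrets lie below `2^(ring_bits - 1)`; the configuration loader
#' enforces this bound for every circuit intermediate.
#'
#' @param ctx An [mpc_context()].
#' @param us,vs Arithmetic shares.
#' @return Single-bit Boolean shares (lane vectors).
#' @export
compare_ge <- function(ctx, us, vs) {
  d <- asub(us, vs, ctx$ring)
  bits <- a2b(ctx, d, ctx$ring)
  sign <- col_of(bits, ctx$ring)
  lapply(bnot(sign), as.vector)
}

#' Oblivious selection between two arithmetic shares
#'
#' `mux(c, x, y)` reconstructs `x` where the selector bit is 1 and `y`
#' otherwise, via `y + b2a(c) * (x - y)`.
#'
#' @param ctx An [mpc_context()].
#' @param cs Single-bit Boolean shares (selector).
#' @param xs,ys Arithmetic shares.
#' @return Arithmetic shares of the selection.
#' @export
mux <- function(ctx, cs, xs, ys) {
  ca <- b2a(ctx, cs)
  d <- asub(xs, ys, ctx$ring)
  aadd(ys, mul_beaver(ctx, ca, d), ctx$ring)
}

## two muxes sharing one converted selector (used by the tournament)
mux_pair <- function(ctx, cs, x1, y1, x2, y2) {
  ca <- b2a(ctx, cs)
  ell <- ctx$ring
  list(aadd(y1, mul_beaver(ctx, ca, asub(x1, y1, ell)), ell),
       aadd(y2, mul_beaver(ctx, ca, asub(x2, y2, ell)), ell))
}

## equality of two Boolean-shared words: XNOR then AND-tree to one bit
equality_bits <- function(ctx, as, bs) {
  x <- bnot(bxor(as, bs))
  while (ncol(x[[1]]) > 1L) {
    w <- ncol(x[[1]])
    h <- w %/% 2L
    t <- and_gate(ctx, slice_cols(x, seq_len(h)),
                  slice_cols(x, h + seq_len(h)))
    x <- if (w %% 2L == 1L) cbind_shares(t, slice_cols(x, w)) else t
  }
  lapply(x, as.vector)
}

## OR over the columns of a Boolean share matrix, as a NOT-AND-tree of the
## negated bits (one result bit per lane)
or_tree <- function(ctx, xs) {
  x <- bnot(xs)
  while (ncol(x[[1]]) > 1L) {
    w <- ncol(x[[1]])
    h <- w %/% 2L
    t <- and_gate(ctx, slice_cols(x, seq_len(h)),
                  slice_cols(x, h + seq_len(h)))
    x <- if (w %% 2L == 1L) cbind_shares(t, slice_cols(x, w)) else t
  }
  lapply(bnot(x), as.vector)
}

## single-bit OR of two lane vectors
or_bit <- function(ctx, xs, ys) {
  lapply(bnot(and_gate(ctx, bnot(xs), bnot(ys))), as.vector)
}

#' Oblivious floor division by restoring long division
#'
#' Divides Boolean-converted numerators by denominators, producing
#' arithmetic shares of the floor quotient.  `wn`/`wd` are public bit-width
#' bounds of numerator and denominator derived from the configuration.  A
#' zero denominator yields an (all-ones) garbage quotient that callers must
#' gate out — in the linkage circuit a zero denominator only occurs for
#' absent fields, whose contribution is multiplied by a zero presence bit.
#'
#' @param ctx An [mpc_context()].
#' @param nums,dens Arithmetic shares of numerator and denominator.
#' @param wn,wd Bit widths.
#' @param qw Quotient width: when the caller can bound the quotient below
#'   `2^qw` (for the Dice circuit the quotient never exceeds `2^p`), the top
#'   `wn - qw` iterations shift numerator bits into the remainder without a
#'   subtraction, since their quotient bits are structurally zero.
#' @return Arithmetic shares of `floor(num / den)`.
#' @export
divide_floor <- function(ctx, nums, dens, wn, wd, qw = wn) {
  lanes <- length(nums[[1]])
  qw <- min(qw, wn)
  numbits <- a2b(ctx, nums, wn)
  denbits <- a2b(ctx, dens, wd)
  den_ext <- cbind_shares(denbits, zero_bool(ctx, lanes, 1L))
  R <- zero_bool(ctx, lanes, wd)
  qcols <- vector("list", qw)
  for (i in rev(seq_len(wn))) {
    ncol_i <- lapply(col_of(numbits, i), function(v) matrix(v, lanes, 1))
    if (i > qw) {
      # quotient bit is 0 by the caller's bound, so the remainder stays
      # below the denominator: shift in the numerator bit locally
      R <- cbind_shares(ncol_i, slice_cols(R, seq_len(wd - 1L)))
      next
    }
    S <- cbind_shares(ncol_i, R)
    sub <- ripple_sub(ctx, S, den_ext)
    qcols[[i]] <- sub$ge
    R <- bmux(ctx, sub$ge, slice_cols(sub$diff, seq_len(wd)),
              slice_cols(S, seq_len(wd)))
  }
  # convert quotient bits and recombine: sum_j 2^(j-1) * q_j
  qmat <- lapply(seq_len(ctx$n), function(i) {
    m <- matrix(raw(lanes * qw), lanes, qw)
    for (j in seq_len(qw)) m[, j] <- qcols[[j]][[i]]
    m
  })
  qa <- b2a(ctx, lapply(qmat, as.vector))
  out <- lapply(seq_len(ctx$n), function(i) numeric(lanes))
  ell <- ctx$ring
  for (j in seq_len(qw)) {
    idx <- (j - 1L) * lanes + seq_len(lanes)
    for (i in seq_len(ctx$n)) {
      out[[i]] <- addmod(out[[i]], mulmod(qa[[i]][idx], 2^(j - 1L), ell), ell)
    }
  }
  out
}
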