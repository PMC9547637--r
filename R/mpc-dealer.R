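## Correlated-randomness dealer.
##
## Stands in for the OT-extension-based setup machinery of the original
## system: a trusted dealer generates Beaver triples (Boolean and
## arithmetic) and bit-conversion correlations ahead of time and hands each
## party its bundle.  This preserves the setup/online structure and all
## correctness properties but assumes a dealer trusted not to collude —
## a deliberately weaker trust model, prominently documented.
##
## Generation is only legal in the setup phase; the online phase can only
## consume, and exhaustion is an error rather than silent regeneration.

#' Generate correlated randomness for a protocol run
#'
#' @param ctx An [mpc_context()]; its phase must be `"setup"`.
#' @param counts List with `bool_bits` (Boolean triple bits), `arith`
#'   (arithmetic triples) and `b2a` (bit-conversion correlations).
#' @param seed Dealer seed.
#' @return `ctx`, invisibly, with provisioned pools.
#' @export
dealer_generate <- function(ctx, counts, seed = NULL) {
  if (ctx$phase == "online") {
    stop("online phase must not generate correlated randomness", call. = FALSE)
  }
  n <- ctx$n
  ell <- ctx$ring
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  nb <- ceiling(counts$bool_bits %||% 0)
  na <- ceiling(counts$arith %||% 0)
  nc <- ceiling(counts$b2a %||% 0)

  a_sh <- lapply(seq_len(n), function(i) random_bits_raw(nb))
  b_sh <- lapply(seq_len(n), function(i) random_bits_raw(nb))
  cc <- Reduce(xor, a_sh) & Reduce(xor, b_sh)
  c_sh <- lapply(seq_len(n - 1L), function(i) random_bits_raw(nb))
  c_sh <- c(c_sh, list(xor(Reduce(xor, c_sh, as.raw(raw(nb))), cc)))

  aa_sh <- lapply(seq_len(n), function(i) ring_runif(na, ell))
  ab_sh <- lapply(seq_len(n), function(i) ring_runif(na, ell))
  prod <- mulmod(Reduce(function(x, y) addmod(x, y, ell), aa_sh),
                 Reduce(function(x, y) addmod(x, y, ell), ab_sh), ell)
  ac_sh <- lapply(seq_len(n - 1L), function(i) ring_runif(na, ell))
  tot <- Reduce(function(x, y) addmod(x, y, ell), ac_sh, numeric(na))
  ac_sh <- c(ac_sh, list(submod(prod, tot, ell)))

  r_bits <- random_bits_raw(nc)
  rb_sh <- lapply(seq_len(n - 1L), function(i) random_bits_raw(nc))
  rb_sh <- c(rb_sh, list(xor(Reduce(xor, rb_sh, as.raw(raw(nc))), r_bits)))
  rv <- as.numeric(r_bits != as.raw(0))
  ra_sh <- lapply(seq_len(n - 1L), function(i) ring_runif(nc, ell))
  tot <- Reduce(function(x, y) addmod(x, y, ell), ra_sh, numeric(nc))
  ra_sh <- c(ra_sh, list(submod(rv, tot, ell)))

  pools <- new.env(parent = emptyenv())
  pools$phase_created <- "setup"
  pools$bool <- list(a = a_sh, b = b_sh, c = c_sh, size = nb, cursor = 0)
  pools$arith <- list(a = aa_sh, b = ab_sh, c = ac_sh, size = na, cursor = 0)
  pools$b2a <- list(rb = rb_sh, ra = ra_sh, size = nc, cursor = 0)
  ctx$pools <- pools
  invisible(ctx)
}

pool_take <- function(ctx, kind, nreq) {
  p <- ctx$pools
  if (is.null(p)) stop("no correlated randomness provisioned", call. = FALSE)
  slot <- p[[kind]]
  if (slot$cursor + nreq > slot$size) {
    stop("correlated randomness exhausted (", kind, "): requested ", nreq,
         " beyond pool of ", slot$size, call. = FALSE)
  }
  idx <- slot$cursor + seq_len(nreq)
  p[[kind]]$cursor <- slot$cursor + nreq
  idx
}

consume_bool_triple <- function(ctx, nbits) {
  idx <- pool_take(ctx, "bool", nbits)
  p <- ctx$pools$bool
  lapply(seq_len(ctx$n), function(i) {
    list(a = p$a[[i]][idx], b = p$b[[i]][idx], c = p$c[[i]][idx])
  })
}

consume_arith_triple <- function(ctx, nl) {
  idx <- pool_take(ctx, "arith", nl)
  p <- ctx$pools$arith
  lapply(seq_len(ctx$n), function(i) {
    list(a = p$a[[i]][idx], b = p$b[[i]][idx], c = p$c[[i]][idx])
  })
}

consume_b2a <- function(ctx, nl) {
  idx <- pool_take(ctx, "b2a", nl)
  p <- ctx$pools$b2a
  lapply(seq_len(ctx$n), function(i) {
    list(rb = p$rb[[i]][idx], ra = p$ra[[i]][idx])
  })
}

#' Consumable accounting of a context
#'
#' @param ctx An [mpc_context()].
#' @return Tibble with one row per consumable kind: provisioned and consumed
#'   amounts.
#' @export
pool_status <- function(ctx) {
  p <- ctx$pools
  if (is.null(p)) {
    return(tibble::tibble(kind = character(), provisioned = numeric(),
                          consumed = numeric()))
  }
  tibble::tibble(
    kind = c("bool_triple_bits", "arith_triples", "b2a_correlations"),
    provisioned = c(p$bool$size, p$arith$size, p$b2a$size),
    consumed = c(p$bool$cursor, p$arith$cursor, p$b2a$cursor)
  )
}

## Metering: run the (data-independent) circuit once with zeroed shares and
## no communication, tallying exact consumable needs.  Because every gate's
## shape depends only on input dimensions and configuration, the tally is
## exact for the subsequent live run.
meter_reset <- function(ctx) {
  ctx$metering <- TRUE
  ctx$meter <- list(bool_bits = 0, arith = 0, b2a = 0)
  invisible(ctx)
}

meter_stop <- function(ctx) {
  ctx$metering <- FALSE
  counts <- ctx$meter
  list(bool_bits = counts$bool_bits, arith = counts$arith, b2a = counts$b2a)
}
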