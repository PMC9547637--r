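## Protocol context: parties, channel, correlated-randomness pools, phase
## bookkeeping and the reconstruction audit counters.  Both (all) parties run
## lock-step in one process; every transmitted value still passes through the
## channel object so transcripts and communication volumes are real.

#' Create an MPC protocol context
#'
#' @param n_parties Number of computation parties (sharing primitives are
#'   general; the linkage circuits are orchestrated for two).
#' @param ring_bits Ring width for arithmetic sharing (`<= 48`).
#' @param seed Integer seed for the per-party local randomness streams used
#'   to share inputs.  `NULL` draws from the session RNG.
#' @param record_transcript Keep every transmitted payload (needed by the
#'   transcript-indistinguishability checks; costs memory on large runs).
#' @return An environment of class `mpc_context`.
#' @export
mpc_context <- function(n_parties = 2L, ring_bits = 48L, seed = NULL,
                        record_transcript = FALSE) {
  stopifnot(n_parties >= 2L, ring_bits <= RING_MAX_BITS)
  ctx <- new.env(parent = emptyenv())
  ctx$n <- as.integer(n_parties)
  ctx$ring <- as.integer(ring_bits)
  ctx$phase <- "setup"
  ctx$metering <- FALSE
  ctx$meter <- list(bool_bits = 0, arith = 0, b2a = 0)
  ctx$reveal_count <- 0L
  ctx$open_count <- 0L
  ctx$record_transcript <- isTRUE(record_transcript)
  ctx$transcript <- list()
  ctx$bytes_sent <- 0
  ctx$pools <- NULL
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ctx$party_rng <- lapply(seq_len(n_parties), function(i) {
    rng_stream(seed + 7919L * i)
  })
  class(ctx) <- "mpc_context"
  ctx
}

#' @export
print.mpc_context <- function(x, ...) {
  cat("<mpc_context> ", x$n, " parties, ring 2^", x$ring, ", phase ", x$phase,
      ", reveals ", x$reveal_count, "\n", sep = "")
  invisible(x)
}

## -- independent seeded RNG streams (state swapping) ------------------------

rng_stream <- function(seed) {
  st <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed %% .Machine$integer.max)
  st$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  st
}

with_stream <- function(st, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", st$state, globalenv())
  on.exit({
    st$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

## -- channel ----------------------------------------------------------------

payload_bytes <- function(x) {
  if (is.list(x)) return(sum(vapply(x, payload_bytes, numeric(1))))
  if (is.raw(x)) length(x) / 8 else 8 * length(x) # packed-bit accounting
}

chan_send <- function(ctx, from, to, payload) {
  ctx$bytes_sent <- ctx$bytes_sent + payload_bytes(payload)
  if (ctx$record_transcript) {
    ctx$transcript[[length(ctx$transcript) + 1L]] <-
      list(from = from, to = to, payload = payload)
  }
  invisible(NULL)
}

## With lock-step in-process execution the receiving side reads the same
## object the sender queued; chan_send records it for the transcript and
## accounting, and `broadcast_values` returns the delivered copies.
broadcast_values <- function(ctx, values) {
  for (i in seq_len(ctx$n)) {
    for (j in seq_len(ctx$n)[-i]) chan_send(ctx, i, j, values[[i]])
  }
  values
}
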