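## The oblivious EpiLink circuit.
##
## Reuses the plaintext engine's fixed-point formulation gate by gate:
## per-field Dice similarity as AND of shared Bloom filters + bit conversion
## + a restoring-division quotient, exact-match fields as shared equality of
## salted token hashes, the exchange-group permutation tournament with
## cross-multiplied comparisons, division-free threshold classification, and
## an OR-tree per left-hand record.  Only the two counts (matches, tentative
## matches) are ever reconstructed.

.profile_cache <- new.env(parent = emptyenv())

secure_widths <- function(spec, p) {
  wd <- ceiling(log2(2 * spec$bloom_len + 1))
  wn <- ceiling(log2(2 * spec$bloom_len * 2^p + 1))
  list(wn = as.integer(wn), wd = as.integer(wd))
}

TOKEN_HASH_BITS <- 32L

## Boolean/arithmetic input sharing of one party's encoded records.  The
## owning party's local RNG stream provides the masks; in metering mode the
## shapes are produced without randomness.
share_encoded_inputs <- function(ctx, enc, owner, config) {
  n <- enc$n
  zshare_bool <- function(v) {
    v <- as_bitmat(v)
    if (ctx$metering) const_bool(matrix(raw(length(v)), nrow(v)), ctx$n)
    else share_bool(v, ctx$n, rng = ctx$party_rng[[owner]])
  }
  zshare_arith <- function(v) {
    if (ctx$metering) const_arith(numeric(length(v)), ctx$n)
    else share_arith(v, ctx$n, config$ring_bits, rng = ctx$party_rng[[owner]])
  }
  out <- list()
  for (fn in names(config$fields)) {
    f <- enc$fields[[fn]]
    spec <- config$fields[[fn]]
    entry <- list(presence = zshare_bool(as.raw(f$presence)))
    if (spec$comparator == "dice") {
      entry$bits <- zshare_bool(f$bits)
      entry$hw <- zshare_arith(f$hw)
    } else {
      th <- f$token_hash
      th[is.na(th)] <- 0
      entry$hash_bits <- zshare_bool(int_to_bits(th, TOKEN_HASH_BITS))
    }
    out[[fn]] <- entry
  }
  out
}

## row-expand shared record-level matrices to pair lanes
lane_rows <- function(shares, idx) {
  lapply(shares, function(m) {
    if (is.null(dim(m))) m[idx] else m[idx, , drop = FALSE]
  })
}

#' Oblivious per-field similarity (fixed-point)
#'
#' Dice fields: bitwise AND of the two shared Bloom filters, bit-converted
#' and summed into a shared intersection Hamming weight, then a restoring
#' long-division quotient of `2 * Hw * 2^p` by `Hw(x) + Hw(y)`.  Binary
#' fields: shared equality of the salted token hashes scaled to `2^p`.
#' Returns the similarity share already gated by the pair-presence bit,
#' together with the presence bit's arithmetic conversion (the field's
#' contribution to the weight mass).
#'
#' @param ctx An [mpc_context()].
#' @param xa,xb Lane-expanded shared field entries of the two parties.
#' @param spec The governing [field_spec()].
#' @param config The [linkage_config()].
#' @return List `s` (arithmetic shares of `floor(2^p * s)`, 0 when either
#'   side absent) and `pres` (arithmetic shares of the both-present bit).
#' @export
secure_field_similarity <- function(ctx, xa, xb, spec, config) {
  p <- config$fixedpoint_bits
  pres_bit <- and_gate(ctx, lapply(xa$presence, as.vector),
                       lapply(xb$presence, as.vector))
  pres_a <- b2a(ctx, pres_bit)
  if (spec$comparator == "dice") {
    lanes <- nrow(xa$bits[[1]])
    w <- secure_widths(spec, p)
    xw <- and_gate(ctx, xa$bits, xb$bits)
    conv <- b2a(ctx, lapply(xw, as.vector))
    hw_and <- lapply(conv, function(v) {
      rowsum_mod(matrix(v, nrow = lanes), config$ring_bits)
    })
    num <- asmul_const(hw_and, 2^(p + 1), config$ring_bits)
    den <- aadd(xa$hw, xb$hw, config$ring_bits)
    q <- divide_floor(ctx, num, den, w$wn, w$wd, qw = p + 1L)
    s <- mul_beaver(ctx, q, pres_a)
  } else {
    eq <- equality_bits(ctx, xa$hash_bits, xb$hash_bits)
    eqp <- and_gate(ctx, eq, pres_bit)
    s <- asmul_const(b2a(ctx, eqp), 2^p, config$ring_bits)
  }
  list(s = s, pres = pres_a)
}

#' Oblivious record score (numerator and weight mass)
#'
#' Accumulates `N = sum w_i * s_i` and `M = sum w_i * present_i` over the
#' per-field outputs, evaluates every exchange-group permutation combination
#' as a candidate `(N, M)` pair, canonicalizes all-absent candidates to
#' `(0, 1)`, and selects the maximum-score candidate by a pairwise
#' tournament using cross-multiplied comparisons (`N_a M_b` vs `N_b M_a`) —
#' identical, value for value, to the plaintext fixed-point engine.
#'
#' @param ctx An [mpc_context()].
#' @param field_sims Named list of [secure_field_similarity()] outputs, one
#'   per field combination (`"a|b"` keys for exchange-group cross pairs).
#' @param config The [linkage_config()].
#' @param plan The linkage plan (internal; computed from `config`).
#' @return List of arithmetic share lists `N` and `M`.
#' @export
secure_record_score <- function(ctx, field_sims, config,
                                plan = linkage_plan(config)) {
  ell <- config$ring_bits
  w <- config$weights_scaled
  lanes <- length(field_sims[[1]]$s[[1]])
  zero <- const_arith(numeric(lanes), ctx$n)
  Nb <- zero
  Mb <- zero
  for (f in plan$base) {
    fs <- field_sims[[f]]
    Nb <- aadd(Nb, asmul_const(fs$s, w[f], ell), ell)
    Mb <- aadd(Mb, asmul_const(fs$pres, w[f], ell), ell)
  }
  group_parts <- lapply(plan$groups, function(g) {
    r <- length(g$members)
    lapply(g$perms, function(perm) {
      Ng <- zero
      Mg <- zero
      for (i in seq_len(r)) {
        key <- paste0(g$members[i], "|", g$members[perm[i]])
        fs <- field_sims[[key]]
        Ng <- aadd(Ng, asmul_const(fs$s, w[g$members[i]], ell), ell)
        Mg <- aadd(Mg, asmul_const(fs$pres, w[g$members[i]], ell), ell)
      }
      list(N = Ng, M = Mg)
    })
  })
  cands <- vector("list", nrow(plan$cand_idx))
  for (ci in seq_len(nrow(plan$cand_idx))) {
    N <- Nb
    M <- Mb
    if (length(plan$groups)) {
      for (gi in seq_along(plan$groups)) {
        part <- group_parts[[gi]][[plan$cand_idx[ci, gi]]]
        N <- aadd(N, part$N, ell)
        M <- aadd(M, part$M, ell)
      }
    }
    cands[[ci]] <- list(N = N, M = M)
  }
  one <- const_arith(rep(1, lanes), ctx$n)
  cands <- lapply(cands, function(cd) {
    v <- compare_ge(ctx, cd$M, one)          # any field present?
    va <- b2a(ctx, v)
    N2 <- mul_beaver(ctx, va, cd$N)
    M2 <- aadd(one, mul_beaver(ctx, va, asub(cd$M, one, ell)), ell)
    list(N = N2, M = M2)
  })
  best <- cands[[1]]
  for (cd in cands[-1]) {
    cross_ch <- mul_beaver(ctx, cd$N, best$M)
    cross_in <- mul_beaver(ctx, best$N, cd$M)
    keep_inc <- compare_ge(ctx, cross_in, cross_ch) # ties keep the earlier
    take <- bnot(keep_inc)
    sel <- mux_pair(ctx, take, cd$N, best$N, cd$M, best$M)
    best <- list(N = sel[[1]], M = sel[[2]])
  }
  best
}

#' Oblivious two-threshold classification
#'
#' Division-free: `score >= t` is tested as
#' `N * t_den >= t_num * M * 2^p` (both sides public-scaled shares), ties
#' upward, exactly as in the plaintext fixed-point engine.
#'
#' @param ctx An [mpc_context()].
#' @param score Output of [secure_record_score()].
#' @param config The [linkage_config()].
#' @return List of single-bit Boolean share lists `is_match` and
#'   `is_tentative_or_match`.
#' @export
secure_classify <- function(ctx, score, config) {
  ell <- config$ring_bits
  p2 <- 2^config$fixedpoint_bits
  is_match <- compare_ge(ctx,
                         asmul_const(score$N, config$tm_den, ell),
                         asmul_const(score$M, config$tm_num * p2, ell))
  is_tm <- compare_ge(ctx,
                      asmul_const(score$N, config$tt_den, ell),
                      asmul_const(score$M, config$tt_num * p2, ell))
  list(is_match = is_match, is_tentative_or_match = is_tm)
}

## field-combination keys needed by the circuit
circuit_combos <- function(plan) {
  combos <- lapply(plan$base, function(f) list(key = f, a = f, b = f))
  for (g in plan$groups) {
    r <- length(g$members)
    for (i in seq_len(r)) {
      for (j in seq_len(r)) {
        combos[[length(combos) + 1L]] <-
          list(key = paste0(g$members[i], "|", g$members[j]),
               a = g$members[i], b = g$members[j])
      }
    }
  }
  combos
}

## One full pass of the linkage circuit; used identically for the metering
## (setup profiling) pass and the live online pass.
run_linkage_circuit <- function(ctx, encA, encB, config, block_size) {
  plan <- linkage_plan(config)
  combos <- circuit_combos(plan)
  nA <- encA$n
  nB <- encB$n
  inA <- share_encoded_inputs(ctx, encA, 1L, config)
  inB <- share_encoded_inputs(ctx, encB, 2L, config)
  any_match <- NULL
  any_tm <- NULL
  blocks <- split(seq_len(nB), ceiling(seq_len(nB) / block_size))
  blocks <- blocks[order(as.numeric(names(blocks)))]
  for (blk in blocks) {
    bl <- length(blk)
    idxA <- rep(seq_len(nA), times = bl)
    idxB <- rep(blk, each = nA)
    field_sims <- list()
    for (cb in combos) {
      xa <- lapply(inA[[cb$a]], lane_rows, idx = idxA)
      names(xa) <- names(inA[[cb$a]])
      xb <- lapply(inB[[cb$b]], lane_rows, idx = idxB)
      names(xb) <- names(inB[[cb$b]])
      field_sims[[cb$key]] <-
        secure_field_similarity(ctx, xa, xb, config$fields[[cb$a]], config)
    }
    score <- secure_record_score(ctx, field_sims, config, plan)
    cls <- secure_classify(ctx, score, config)
    # per-A-record OR over this block's columns
    m_mat <- lapply(cls$is_match, function(v) matrix(v, nrow = nA))
    t_mat <- lapply(cls$is_tentative_or_match, function(v) matrix(v, nrow = nA))
    blk_m <- if (bl > 1L) or_tree(ctx, m_mat) else lapply(m_mat, as.vector)
    blk_t <- if (bl > 1L) or_tree(ctx, t_mat) else lapply(t_mat, as.vector)
    any_match <- if (is.null(any_match)) blk_m else or_bit(ctx, any_match, blk_m)
    any_tm <- if (is.null(any_tm)) blk_t else or_bit(ctx, any_tm, blk_t)
  }
  ell <- config$ring_bits
  ma <- b2a(ctx, any_match)
  ta <- b2a(ctx, any_tm)
  list(match_sum = lapply(ma, function(v) sum_mod(v, ell)),
       tm_sum = lapply(ta, function(v) sum_mod(v, ell)))
}

#' Secure intersection cardinality of two patient datasets
#'
#' Runs the full oblivious linkage between party 1's dataset `A` and party
#' 2's dataset `B` and reveals only two numbers: how many `A` records have a
#' match in `B`, and how many have at best a tentative match.  Per-pair
#' similarities, classifications and match bits remain secret-shared
#' throughout; the reconstruction audit in the returned statistics shows
#' exactly two reveal operations.
#'
#' The run has two strictly separated phases.  The setup phase is
#' input-independent: a profiling pass over the (data-oblivious) circuit
#' establishes the exact consumable counts, and the dealer generates that
#' much correlated randomness.  The online phase executes the circuit on the
#' shared inputs and can only consume.
#'
#' @param A Party 1's records (data frame or [encode_records()] result).
#' @param B Party 2's records.
#' @param config The shared [linkage_config()]; its fingerprint is compared
#'   in clear before any input is shared.
#' @param seed Seed for dealer and input-masking randomness.
#' @param config_b Party 2's configuration (defaults to `config`; supplying
#'   a different one demonstrates the abort-on-mismatch contract).
#' @param block_size `B` rows per circuit block (memory knob).
#' @param record_transcript Keep all transmitted payloads.
#' @return An `epilink_intersection` with `protocol = "secure"` and a
#'   `stats` list (phase timings, consumable accounting, reveal audit,
#'   bytes sent).
#' @export
secure_intersection_cardinality <- function(A, B, config, seed = NULL,
                                            config_b = NULL,
                                            block_size = 64L,
                                            record_transcript = FALSE) {
  stopifnot(inherits(config, "linkage_config"))
  cfg_b <- config_b %||% config
  if (config_hash(config) != config_hash(cfg_b)) {
    stop(errorCondition(
      "configuration fingerprints differ between parties; aborting before any input is shared",
      class = c("epilinkr_protocol_error", "error", "condition")))
  }
  encA <- as_encoded(A, config)
  encB <- as_encoded(B, config)
  stopifnot(encA$n >= 1L, encB$n >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ctx <- mpc_context(2L, config$ring_bits, seed = seed,
                     record_transcript = record_transcript)

  ctx$phase <- "setup"
  t0 <- proc.time()[["elapsed"]]
  # circuit profiling: consumable counts depend only on the circuit shape,
  # so identical shapes reuse the cached profile
  shape_key <- paste(config_hash(config), encA$n, encB$n, block_size,
                     sep = "/")
  counts <- .profile_cache[[shape_key]]
  if (is.null(counts)) {
    meter_reset(ctx)
    run_linkage_circuit(ctx, encA, encB, config, block_size)
    counts <- meter_stop(ctx)
    ctx$reveal_count <- 0L
    ctx$open_count <- 0L
    .profile_cache[[shape_key]] <- counts
  }
  dealer_generate(ctx, counts, seed = seed + 104729L)
  t1 <- proc.time()[["elapsed"]]

  ctx$phase <- "online"
  sums <- run_linkage_circuit(ctx, encA, encB, config, block_size)
  tentative_sh <- Map(function(t, m) submod(t, m, config$ring_bits),
                      sums$tm_sum, sums$match_sum)
  match_count <- reveal(ctx, sums$match_sum, "arith")
  tentative_count <- reveal(ctx, tentative_sh, "arith")
  t2 <- proc.time()[["elapsed"]]

  status <- pool_status(ctx)
  if (!all(status$provisioned == status$consumed)) {
    stop("consumable accounting mismatch between setup profiling and online run",
         call. = FALSE)
  }
  new_intersection(
    match_count = match_count, tentative_count = tentative_count,
    n_left = encA$n, n_right = encB$n, mode = "fixedpoint",
    protocol = "secure",
    stats = list(setup_seconds = t1 - t0, online_seconds = t2 - t1,
                 consumables = status, reveals = ctx$reveal_count,
                 openings = ctx$open_count, bytes_sent = ctx$bytes_sent,
                 seed = seed))
}
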