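#' Similarity of a single field pair
#'
#' Binary comparator: 1 if the normalized tokens agree, else 0.  Dice
#' comparator: Bloom-filter Dice similarity of the two values.  If either
#' side is absent the comparison is undefined and `NA` is returned; the
#' record-level score then drops this field from both the numerator and the
#' denominator of the weighted sum.
#'
#' @param a,b Field values (raw strings; normalized internally) or `NA`.
#' @param spec The [field_spec()] governing both values.
#' @param salt,padded Encoding parameters, as in the configuration.
#' @return Similarity in `[0,1]`, or `NA` if undefined.
#' @export
field_similarity <- function(a, b, spec, salt = "epilinkr/v1", padded = FALSE) {
  a <- normalize_value(a)
  b <- normalize_value(b)
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (spec$comparator == "binary") {
    return(as.numeric(a == b))
  }
  dice(bloom_encode(a, spec, salt, padded), bloom_encode(b, spec, salt, padded))
}

#' Classify a similarity score against the two thresholds
#'
#' Scores below the tentative threshold are non-matches, scores at or above
#' the match threshold are matches, everything in between is a tentative
#' match.  Ties resolve upward.
#'
#' @param score Numeric vector of scores in `[0,1]`.
#' @param config A [linkage_config()].
#' @return Factor with levels `non_match`, `tentative_match`, `match`.
#' @export
classify <- function(score, config) {
  stopifnot(inherits(config, "linkage_config"))
  cls <- ifelse(score >= config$threshold_match, "match",
                ifelse(score >= config$threshold_tentative,
                       "tentative_match", "non_match"))
  factor(cls, levels = c("non_match", "tentative_match", "match"))
}

## ---------------------------------------------------------------------------
## internal vectorized pair engine
##
## Everything pairwise is computed on nA x nB matrices, blocked over B.  The
## fixed-point mode mirrors the secure circuit operation for operation
## (floor-divided Dice, integer weights, candidate canonicalization, strict
## challenger tournament, cross-multiplied threshold tests) so that the MPC
## path can be checked for exact agreement.

linkage_plan <- function(config) {
  grouped <- unlist(config$exchange_groups)
  base <- setdiff(names(config$fields), grouped)
  groups <- lapply(config$exchange_groups, function(g) {
    list(members = g, perms = all_permutations(length(g)))
  })
  n_cand <- prod(c(1, vapply(groups, function(g) length(g$perms), numeric(1))))
  if (n_cand > 64) {
    stop("exchange-group permutation space too large (", n_cand,
         " candidates)", call. = FALSE)
  }
  # candidate index -> one permutation choice per group (cartesian product,
  # first group varies fastest); shared verbatim by the secure circuit
  cand_idx <- if (length(groups)) {
    do.call(expand.grid, lapply(groups, function(g) seq_along(g$perms)))
  } else {
    data.frame(row.names = 1)
  }
  list(base = base, groups = groups, cand_idx = cand_idx)
}

as_encoded <- function(x, config) {
  if (inherits(x, "encoded_records")) {
    if (x$config_hash != config_hash(config)) {
      stop("encoded records were produced under a different configuration",
           call. = FALSE)
    }
    return(x)
  }
  encode_records(x, config)
}

## numeric 0/1 matrix view of a dice field's bits
dice_num_matrix <- function(enc, field) {
  b <- enc$fields[[field]]$bits
  matrix(as.numeric(b != as.raw(0)), nrow = nrow(b))
}

## Similarity and presence matrices for one (fieldA, fieldB) combo over a
## block of B rows.  `mode` "exact" gives real Dice / 0-1 equality; mode
## "fixedpoint" gives floor(2^p * s).
combo_matrices <- function(fa, fb, encA, encB, blk, config, mode, cacheA) {
  sa <- config$fields[[fa]]
  p2 <- 2^config$fixedpoint_bits
  A <- encA$fields[[fa]]
  B <- encB$fields[[fb]]
  P <- outer(A$presence, B$presence[blk], "&") * 1
  if (sa$comparator == "dice") {
    XA <- cacheA[[fa]]
    XB <- matrix(as.numeric(B$bits[blk, , drop = FALSE] != as.raw(0)),
                 nrow = length(blk))
    ip <- tcrossprod(XA, XB)
    den <- outer(A$hw, B$hw[blk], "+")
    pos <- den > 0
    S <- matrix(0, nrow(ip), ncol(ip))
    if (mode == "exact") {
      S[pos] <- 2 * ip[pos] / den[pos]
    } else {
      S[pos] <- floor((2 * p2) * ip[pos] / den[pos])
      # floor of an exact rational: numerator < 2^(p + log2(2m)) is exact in
      # doubles, but guard against FP division landing a hair under an
      # integer quotient
      exact <- ((2 * p2) * ip[pos]) %% den[pos] == 0
      S[pos][exact] <- (2 * p2) * ip[pos][exact] / den[pos][exact]
    }
  } else {
    EQ <- outer(A$token, B$token[blk], "==")
    EQ[is.na(EQ)] <- FALSE
    S <- EQ * (if (mode == "exact") 1 else p2)
  }
  S <- S * P
  list(S = S, P = P)
}

## (N, M) candidate matrices for a block: base contribution plus one entry
## per exchange-group permutation combination.
block_candidates <- function(encA, encB, blk, config, mode, plan, cacheA) {
  w <- if (mode == "exact") config$weights else config$weights_scaled
  nA <- encA$n
  bl <- length(blk)
  Nb <- matrix(0, nA, bl)
  Mb <- matrix(0, nA, bl)
  for (f in plan$base) {
    cm <- combo_matrices(f, f, encA, encB, blk, config, mode, cacheA)
    Nb <- Nb + w[f] * cm$S
    Mb <- Mb + w[f] * cm$P
  }
  group_parts <- lapply(plan$groups, function(g) {
    r <- length(g$members)
    combos <- vector("list", r * r)
    dim(combos) <- c(r, r)
    for (i in seq_len(r)) {
      for (j in seq_len(r)) {
        combos[[i, j]] <- combo_matrices(g$members[i], g$members[j],
                                         encA, encB, blk, config, mode, cacheA)
      }
    }
    lapply(g$perms, function(perm) {
      Ng <- matrix(0, nA, bl)
      Mg <- matrix(0, nA, bl)
      for (i in seq_len(r)) {
        cm <- combos[[i, perm[i]]]
        Ng <- Ng + w[g$members[i]] * cm$S
        Mg <- Mg + w[g$members[i]] * cm$P
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
        N <- N + part$N
        M <- M + part$M
      }
    }
    cands[[ci]] <- list(N = N, M = M)
  }
  cands
}

## Reduce candidates to the best (N, M) per pair.  Fixed-point mode follows
## the circuit exactly: canonicalize all-absent candidates (M = 0) to (0, 1),
## then a sequential tournament where a challenger replaces the incumbent
## only on a strictly larger cross-multiplied score.
best_candidate <- function(cands, mode) {
  canon <- lapply(cands, function(cd) {
    z <- cd$M == 0
    cd$N[z] <- 0
    cd$M[z] <- 1
    cd
  })
  best <- canon[[1]]
  for (cd in canon[-1]) {
    if (mode == "exact") {
      take <- cd$N / cd$M > best$N / best$M
    } else {
      take <- mulx(cd$N, best$M) > mulx(best$N, cd$M)
    }
    best$N[take] <- cd$N[take]
    best$M[take] <- cd$M[take]
  }
  best
}

## products here stay < 2^53 by the config ring-bound validation
mulx <- function(a, b) a * b

## One pass over all pairs.  Returns per-A-row accumulators: any-match /
## any-tentative flags and the best-scoring B row (ties to the lowest index).
pairwise_scan <- function(encA, encB, config, mode, block_size = 1024L,
                          want_best = TRUE) {
  plan <- linkage_plan(config)
  p2 <- 2^config$fixedpoint_bits
  nA <- encA$n
  nB <- encB$n
  dice_fields <- names(config$fields)[vapply(config$fields, function(f) {
    f$comparator == "dice"
  }, logical(1))]
  cacheA <- stats::setNames(
    lapply(dice_fields, function(f) dice_num_matrix(encA, f)), dice_fields)

  anyM <- rep(FALSE, nA)
  anyT <- rep(FALSE, nA)
  bestIdx <- rep(NA_integer_, nA)
  bestS <- rep(-1, nA)
  bestN <- rep(0, nA)
  bestM <- rep(1, nA)

  blocks <- split(seq_len(nB), ceiling(seq_len(nB) / block_size))
  blocks <- blocks[order(as.numeric(names(blocks)))]
  for (blk in blocks) {
    cands <- block_candidates(encA, encB, blk, config, mode, plan, cacheA)
    best <- best_candidate(cands, mode)
    if (mode == "exact") {
      SC <- best$N / best$M
      isM <- SC >= config$threshold_match
      isT <- SC >= config$threshold_tentative
    } else {
      isM <- mulx(best$N, config$tm_den) >= mulx(config$tm_num * p2, best$M)
      isT <- mulx(best$N, config$tt_den) >= mulx(config$tt_num * p2, best$M)
    }
    anyM <- anyM | rowSums(isM) > 0
    anyT <- anyT | rowSums(isT) > 0
    if (want_best) {
      for (j in seq_along(blk)) {
        if (mode == "exact") {
          upd <- SC[, j] > bestS | is.na(bestIdx)
          bestS[upd] <- SC[upd, j]
        } else {
          upd <- mulx(best$N[, j], bestM) > mulx(bestN, best$M[, j]) |
            is.na(bestIdx)
          bestN[upd] <- best$N[upd, j]
          bestM[upd] <- best$M[upd, j]
        }
        bestIdx[upd] <- blk[j]
      }
    }
  }
  score <- if (!want_best) {
    NULL
  } else if (mode == "exact") {
    pmax(bestS, 0)
  } else {
    bestN / (bestM * p2)
  }
  list(any_match = anyM, any_tentative = anyT,
       best = bestIdx, score = score,
       best_nm = if (want_best && mode == "fixedpoint") {
         list(N = bestN, M = bestM)
       })
}

## ---------------------------------------------------------------------------

#' Record-level EpiLink similarity of two records
#'
#' Normalized weighted sum of the per-field similarities over the fields
#' defined on both sides, with exchange-group values assigned to slots by
#' the score-maximizing permutation.
#'
#' @param x,y Single-row data frames (or one-row slices) of patient fields.
#' @param config A [linkage_config()].
#' @return A `similarity_score`: list with `value` (exact score in `[0,1]`)
#'   and `fixedpoint` (the integer `floor(2^p * score)` computed by the
#'   fixed-point engine that the secure circuit replicates).
#' @export
record_similarity <- function(x, y, config) {
  encX <- as_encoded(tibble::as_tibble(x)[1, ], config)
  encY <- as_encoded(tibble::as_tibble(y)[1, ], config)
  ex <- pairwise_scan(encX, encY, config, "exact", want_best = TRUE)
  fp <- pairwise_scan(encX, encY, config, "fixedpoint", want_best = TRUE)
  structure(list(value = ex$score,
                 fixedpoint = floor(fp$best_nm$N / fp$best_nm$M)),
            class = "similarity_score")
}

#' Link every record of one dataset against another
#'
#' For each record of `A`, finds the record of `B` maximizing the EpiLink
#' similarity (ties broken by the lowest `B` index) and classifies the best
#' score against the configured thresholds.
#'
#' @param A,B Patient data frames (or pre-encoded [encode_records()]
#'   results).
#' @param config A [linkage_config()].
#' @param mode `"exact"` for real-valued scores, `"fixedpoint"` for the
#'   integer arithmetic mirrored by the secure circuit.
#' @param block_size Number of `B` rows processed per block (memory knob).
#' @return An `epilink_linkage` tibble with columns `row_a`, `best_b`,
#'   `score`, `match_class`.
#' @export
link_pair <- function(A, B, config, mode = c("exact", "fixedpoint"),
                      block_size = 1024L) {
  mode <- match.arg(mode)
  encA <- as_encoded(A, config)
  encB <- as_encoded(B, config)
  stopifnot(encA$n >= 1L, encB$n >= 1L)
  res <- pairwise_scan(encA, encB, config, mode, block_size, want_best = TRUE)
  cls <- if (mode == "exact") {
    classify(res$score, config)
  } else {
    p2 <- 2^config$fixedpoint_bits
    nm <- res$best_nm
    lv <- c("non_match", "tentative_match", "match")
    isM <- mulx(nm$N, config$tm_den) >= mulx(config$tm_num * p2, nm$M)
    isT <- mulx(nm$N, config$tt_den) >= mulx(config$tt_num * p2, nm$M)
    factor(ifelse(isM, "match", ifelse(isT, "tentative_match", "non_match")),
           levels = lv)
  }
  out <- tibble::tibble(row_a = seq_len(encA$n), best_b = res$best,
                        score = res$score, match_class = cls)
  class(out) <- c("epilink_linkage", class(out))
  attr(out, "config_thresholds") <- c(config$threshold_tentative,
                                      config$threshold_match)
  attr(out, "mode") <- mode
  out
}

#' Number of common patients between two datasets (plaintext)
#'
#' Counts the records of `A` that have at least one `B` record classified
#' `match` (and, separately, those whose best classification is
#' `tentative_match`).  With `mode = "fixedpoint"` the counts use exactly the
#' integer arithmetic of the secure circuit, making this function the
#' plaintext oracle for [secure_intersection_cardinality()].
#'
#' @inheritParams link_pair
#' @param one_to_one Count under a one-to-one assignment instead of the
#'   default any-match semantics: each `A` record's best match is assigned
#'   greedily in descending score order and every `B` record is used at
#'   most once, so `k` copies of one patient on the left meeting a single
#'   copy on the right count once, not `k` times.
#' @return An `epilink_intersection` object.
#' @export
intersection_cardinality_plain <- function(A, B, config,
                                           mode = c("exact", "fixedpoint"),
                                           block_size = 1024L,
                                           one_to_one = FALSE) {
  mode <- match.arg(mode)
  encA <- as_encoded(A, config)
  encB <- as_encoded(B, config)
  stopifnot(encA$n >= 1L, encB$n >= 1L)
  if (one_to_one) {
    lk <- link_pair(encA, encB, config, mode, block_size)
    ord <- order(-lk$score, lk$row_a)
    taken <- logical(encB$n)
    cls <- character(0)
    for (i in ord) {
      if (lk$match_class[i] == "non_match" || taken[lk$best_b[i]]) next
      taken[lk$best_b[i]] <- TRUE
      cls <- c(cls, as.character(lk$match_class[i]))
    }
    return(new_intersection(match_count = sum(cls == "match"),
                            tentative_count = sum(cls == "tentative_match"),
                            n_left = encA$n, n_right = encB$n,
                            mode = mode, protocol = "plaintext"))
  }
  res <- pairwise_scan(encA, encB, config, mode, block_size, want_best = FALSE)
  new_intersection(match_count = sum(res$any_match),
                   tentative_count = sum(res$any_tentative & !res$any_match),
                   n_left = encA$n, n_right = encB$n,
                   mode = mode, protocol = "plaintext")
}

new_intersection <- function(match_count, tentative_count, n_left, n_right,
                             mode, protocol, stats = NULL) {
  structure(list(match_count = as.integer(match_count),
                 tentative_count = as.integer(tentative_count),
                 n_left = as.integer(n_left), n_right = as.integer(n_right),
                 mode = mode, protocol = protocol, stats = stats),
            class = "epilink_intersection")
}

#' @export
print.epilink_intersection <- function(x, ...) {
  cat("<epilink_intersection> [", x$protocol, "/", x$mode, "] ",
      x$n_left, " x ", x$n_right, " records: ",
      x$match_count, " matches, ", x$tentative_count,
      " tentative\n", sep = "")
  invisible(x)
}

#' Three-way overlap via composed pairwise linkages
#'
#' Counts the records of `A` that have a `match` both in `B` and in `C`.
#' Composition of two pairwise linkages is used because a direct multi-party
#' similarity is not defined for this (non-transitive) score.
#'
#' @param A,B,C Patient data frames or encoded records.
#' @inheritParams link_pair
#' @return An `epilink_multiway` object: `count` plus a per-`A`-row `flags`
#'   tibble with `match_in_b`, `match_in_c`.
#' @export
multiway_overlap <- function(A, B, C, config, mode = c("exact", "fixedpoint"),
                             block_size = 1024L) {
  mode <- match.arg(mode)
  encA <- as_encoded(A, config)
  rb <- pairwise_scan(encA, as_encoded(B, config), config, mode, block_size,
                      want_best = FALSE)
  rc <- pairwise_scan(encA, as_encoded(C, config), config, mode, block_size,
                      want_best = FALSE)
  structure(list(count = sum(rb$any_match & rc$any_match),
                 flags = tibble::tibble(row_a = seq_len(encA$n),
                                        match_in_b = rb$any_match,
                                        match_in_c = rc$any_match)),
            class = "epilink_multiway")
}

#' @export
print.epilink_multiway <- function(x, ...) {
  cat("<epilink_multiway> ", x$count, " records matched in both partner ",
      "datasets\n", sep = "")
  invisible(x)
}
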