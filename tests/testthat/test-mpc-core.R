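test_that("boolean sharing reconstructs and fixed example holds", {
  # XOR of shares (1,0,0) is the secret 1
  sh <- list(matrix(as.raw(1)), matrix(as.raw(0)), matrix(as.raw(0)))
  expect_equal(as.integer(reconstruct_bool(sh)), 1L)
  # exhaustive 8-bit sweep round-trip, two and three parties
  set.seed(1)
  for (v in 0:255) {
    bits <- epilinkr:::int_to_bits(v, 8L)
    for (np in 2:3) {
      expect_equal(as.vector(reconstruct_bool(share_bool(bits, np))),
                   as.vector(bits))
    }
  }
  expect_error(reconstruct_bool(list(matrix(raw(2)), matrix(raw(3)))),
               "mismatch")
})

test_that("arithmetic sharing reconstructs on the ring", {
  expect_equal(reconstruct_arith(list(200, 56, 5), 8L), 5)
  set.seed(2)
  v <- floor(runif(1000) * 2^48)
  expect_equal(reconstruct_arith(share_arith(v, 2, 48), 48), v)
  expect_equal(reconstruct_arith(share_arith(v, 3, 48), 48), v)
  z <- share_arith(rep(0, 50), 2, 48)
  expect_true(all((z[[1]] + z[[2]]) %% 2^48 == 0))
  expect_error(share_arith(2^48, 2, 48), "outside ring")
})

test_that("share marginals are uniform (chi-squared on seeded runs)", {
  set.seed(42)
  first_bits <- replicate(10000, as.integer(share_bool(as.raw(1), 2)[[1]]))
  p <- stats::chisq.test(table(first_bits))$p.value
  expect_gt(p, 1e-3)
  # arithmetic first share: bucket the ring into 16 cells
  v <- share_arith(rep(7, 5000), 2, 48)[[1]]
  p2 <- stats::chisq.test(table(floor(v / 2^44)))$p.value
  expect_gt(p2, 1e-3)
})

test_that("xor gate is local and matches plaintext exhaustively", {
  ctx <- test_ctx(seed = 3)
  b0 <- ctx$bytes_sent
  for (x in 0:3) for (y in 0:3) {
    xb <- epilinkr:::int_to_bits(x, 2L)
    yb <- epilinkr:::int_to_bits(y, 2L)
    z <- epilinkr:::bxor(share_bool(xb, 2), share_bool(yb, 2))
    expect_equal(epilinkr:::bits_to_int(reconstruct_bool(z)),
                 bitwXor(x, y))
  }
  expect_equal(ctx$bytes_sent, b0) # no communication
})

test_that("beaver AND matches plaintext and consumes triples", {
  ctx <- test_ctx(seed = 4)
  for (x in 0:1) for (y in 0:1) {
    z <- and_gate(ctx, share_bool(as.raw(x), 2), share_bool(as.raw(y), 2))
    expect_equal(as.integer(reconstruct_bool(z)), bitwAnd(x, y))
  }
  # randomized wide vectors
  set.seed(9)
  for (i in 1:5) {
    x <- as.raw(sample(0:1, 500, TRUE))
    y <- as.raw(sample(0:1, 500, TRUE))
    z <- and_gate(ctx, share_bool(x, 2), share_bool(y, 2))
    expect_identical(as.vector(reconstruct_bool(z)), as.vector(x & y))
  }
  used <- pool_status(ctx)$consumed[1]
  expect_equal(used, 4 + 5 * 500)
})

test_that("pool exhaustion is an error, not silent regeneration", {
  ctx <- mpc_context(2, 48, seed = 5)
  dealer_generate(ctx, list(bool_bits = 4, arith = 0, b2a = 0), seed = 6)
  x <- share_bool(as.raw(c(1, 1, 0)), 2)
  and_gate(ctx, x, x) # consumes 3
  expect_error(and_gate(ctx, x, x), "exhausted")
})

test_that("the online phase cannot generate correlated randomness", {
  ctx <- mpc_context(2, 48, seed = 7)
  ctx$phase <- "online"
  expect_error(dealer_generate(ctx, list(bool_bits = 8), seed = 1),
               "online phase")
  ctx$phase <- "setup"
  expect_silent(dealer_generate(ctx, list(bool_bits = 8, arith = 0,
                                          b2a = 0), seed = 1))
})

test_that("dealer output satisfies the beaver defining relations", {
  ctx <- test_ctx(bool_bits = 2000, arith = 500, b2a = 500, seed = 8)
  tb <- epilinkr:::consume_bool_triple(ctx, 2000)
  a <- reconstruct_bool(lapply(tb, function(t) matrix(t$a)))
  b <- reconstruct_bool(lapply(tb, function(t) matrix(t$b)))
  cc <- reconstruct_bool(lapply(tb, function(t) matrix(t$c)))
  expect_identical(as.vector(cc), as.vector(a & b))
  ta <- epilinkr:::consume_arith_triple(ctx, 500)
  av <- reconstruct_arith(lapply(ta, `[[`, "a"), 48)
  bv <- reconstruct_arith(lapply(ta, `[[`, "b"), 48)
  cv <- reconstruct_arith(lapply(ta, `[[`, "c"), 48)
  expect_equal(cv, epilinkr:::mulmod(av, bv, 48))
  cr <- epilinkr:::consume_b2a(ctx, 500)
  rbit <- reconstruct_bool(lapply(cr, function(c) matrix(c$rb)))
  rval <- reconstruct_arith(lapply(cr, `[[`, "ra"), 48)
  expect_equal(rval, as.numeric(rbit != as.raw(0)))
  # bundle sizes match the request exactly
  st <- pool_status(ctx)
  expect_equal(st$consumed, c(2000, 500, 500))
})

test_that("beaver multiplication matches ring products", {
  ctx <- test_ctx(arith = 5000, seed = 10)
  set.seed(10)
  x <- floor(runif(1000) * 2^16)
  y <- floor(runif(1000) * 2^16)
  z <- mul_beaver(ctx, share_arith(x, 2, 48), share_arith(y, 2, 48))
  expect_equal(reconstruct_arith(z, 48), (x * y) %% 2^48)
  # full-width operands through the limb multiplier
  xw <- floor(runif(200) * 2^24) * 2^24 + floor(runif(200) * 2^24)
  yw <- floor(runif(200) * 2^24) * 2^24 + floor(runif(200) * 2^24)
  zw <- mul_beaver(ctx, share_arith(xw, 2, 48), share_arith(yw, 2, 48))
  expect_equal(reconstruct_arith(zw, 48),
               epilinkr:::mulmod(xw, yw, 48))
  # identities
  one <- share_arith(rep(1, 10), 2, 48)
  zero <- share_arith(rep(0, 10), 2, 48)
  v <- share_arith(1:10, 2, 48)
  expect_equal(reconstruct_arith(mul_beaver(ctx, v, one), 48), as.numeric(1:10))
  expect_equal(reconstruct_arith(mul_beaver(ctx, v, zero), 48), rep(0, 10))
})

test_that("share conversions round-trip both directions", {
  ctx <- test_ctx(bool_bits = 3e5, b2a = 2e4, seed = 12)
  # b2a: exhaustive bits plus randomized vectors
  for (b in 0:1) {
    z <- b2a(ctx, share_bool(as.raw(b), 2))
    expect_equal(reconstruct_arith(z, 48), b)
  }
  set.seed(12)
  bits <- as.raw(sample(0:1, 2000, TRUE))
  z <- b2a(ctx, lapply(share_bool(bits, 2), as.vector))
  expect_equal(reconstruct_arith(z, 48), as.numeric(bits != as.raw(0)))
  # a2b: boundary values and 1000 randomized round trips
  for (v in c(0, 2^48 - 1)) {
    bb <- a2b(ctx, share_arith(v, 2, 48), 48L)
    expect_equal(epilinkr:::bits_to_int(reconstruct_bool(bb)), v)
  }
  v <- floor(runif(1000) * 2^20)
  bb <- a2b(ctx, share_arith(v, 2, 48), 20L)
  expect_equal(epilinkr:::bits_to_int(reconstruct_bool(bb)), v)
})

test_that("comparison and mux match plaintext on bounded operands", {
  ctx <- test_ctx(bool_bits = 5e5, arith = 1e4, b2a = 1e4, seed = 13)
  set.seed(13)
  u <- floor(runif(300) * 2^40)
  v <- floor(runif(300) * 2^40)
  u[1] <- v[1] # tie reconstructs 1 (>= semantics)
  ge <- compare_ge(ctx, share_arith(u, 2, 48), share_arith(v, 2, 48))
  expect_equal(as.integer(reconstruct_bool(ge)), as.integer(u >= v))
  sel <- mux(ctx, ge, share_arith(u, 2, 48), share_arith(v, 2, 48))
  expect_equal(reconstruct_arith(sel, 48), pmax(u, v))
  # c = 1 selects x, c = 0 selects y
  x <- share_arith(5, 2, 48)
  y <- share_arith(9, 2, 48)
  expect_equal(reconstruct_arith(mux(ctx, share_bool(as.raw(1), 2), x, y), 48), 5)
  expect_equal(reconstruct_arith(mux(ctx, share_bool(as.raw(0), 2), x, y), 48), 9)
})

test_that("restoring division floors exactly, with and without the quotient bound", {
  ctx <- test_ctx(bool_bits = 4e6, b2a = 1e6, seed = 14)
  set.seed(14)
  num <- floor(runif(200) * 2^20)
  den <- 1 + floor(runif(200) * 1000)
  q <- divide_floor(ctx, share_arith(num, 2, 48), share_arith(den, 2, 48),
                    20L, 10L)
  expect_equal(reconstruct_arith(q, 48), num %/% den)
  # bounded-quotient mode as used by the dice circuit
  hw <- sample(0:500, 100, TRUE)
  hx <- pmax(hw, sample(0:500, 100, TRUE))
  hy <- pmax(hw, sample(0:500, 100, TRUE))
  num <- 2 * hw * 2^16
  den <- hx + hy
  den[den == 0] <- 1
  q2 <- divide_floor(ctx, share_arith(num, 2, 48), share_arith(den, 2, 48),
                     27L, 10L, qw = 17L)
  expect_equal(reconstruct_arith(q2, 48), num %/% den)
})

test_that("transcript of beaver openings is input-independent", {
  # one party's received openings over repeated fresh-randomness runs are
  # indistinguishable between two different secret inputs (homogeneity
  # chi-squared); a sanity check of the masking, not a security proof
  collect <- function(x, y, runs, seed) {
    ctx <- mpc_context(2, 48, seed = seed, record_transcript = TRUE)
    dealer_generate(ctx, list(bool_bits = runs, arith = 0, b2a = 0),
                    seed = seed)
    vapply(seq_len(runs), function(i) {
      and_gate(ctx, share_bool(as.raw(x), 2), share_bool(as.raw(y), 2))
      msg <- ctx$transcript[[length(ctx$transcript)]] # party 2 -> party 1
      as.integer(msg$payload[[1]]) # d-share opening
    }, integer(1))
  }
  set.seed(77)
  d0 <- collect(0, 0, 400, seed = 101)
  d1 <- collect(1, 1, 400, seed = 202)
  tab <- rbind(table(factor(d0, 0:1)), table(factor(d1, 0:1)))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("channel transcripts capture every transmitted payload", {
  ctx <- mpc_context(2, 48, seed = 15, record_transcript = TRUE)
  dealer_generate(ctx, list(bool_bits = 64, arith = 0, b2a = 0), seed = 16)
  x <- share_bool(as.raw(sample(0:1, 64, TRUE)), 2)
  and_gate(ctx, x, x)
  expect_length(ctx$transcript, 2L) # one broadcast per party
  expect_setequal(vapply(ctx$transcript, `[[`, numeric(1), "from"), c(1, 2))
  expect_gt(ctx$bytes_sent, 0)
})
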