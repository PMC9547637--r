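# Shared fixtures: a small, fast configuration (short Bloom filters), tiny
# record tables and independent oracles.

tiny_config <- function(...) {
  linkage_config(
    fields = list(
      field_spec("first_name", "dice", weight = 8, bloom_len = 64L,
                 num_hashes = 3L),
      field_spec("surname", "dice", weight = 9, bloom_len = 64L,
                 num_hashes = 3L),
      field_spec("year_of_birth", "binary", weight = 6),
      field_spec("zip_code", "binary", weight = 7)
    ),
    exchange_groups = list(c("first_name", "surname")),
    ...
  )
}

tiny_records <- function(first, sur, yob, zip) {
  tibble::tibble(first_name = first, surname = sur,
                 year_of_birth = as.character(yob),
                 zip_code = as.character(zip))
}

# Brute-force record-similarity oracle: weighted mean over present fields,
# maximized over all exchange-group permutations, built directly from
# field_similarity() without the engine's tournament machinery.
oracle_record_similarity <- function(x, y, config) {
  x <- normalize_records(x, config)
  y <- normalize_records(y, config)
  plan_groups <- config$exchange_groups
  grouped <- unlist(plan_groups)
  base <- setdiff(names(config$fields), grouped)
  score_for <- function(assignments) {
    num <- 0
    den <- 0
    for (a in assignments) {
      s <- field_similarity(x[[a$fa]][1], y[[a$fb]][1],
                            config$fields[[a$fa]], config$salt, config$padded)
      if (!is.na(s)) {
        num <- num + config$weights[[a$fa]] * s
        den <- den + config$weights[[a$fa]]
      }
    }
    if (den == 0) 0 else num / den
  }
  base_assign <- lapply(base, function(f) list(fa = f, fb = f))
  perm_sets <- lapply(plan_groups, function(g) {
    perms <- epilinkr:::all_permutations(length(g))
    lapply(perms, function(p) {
      lapply(seq_along(g), function(i) list(fa = g[i], fb = g[p[i]]))
    })
  })
  combos <- Reduce(function(acc, ps) {
    unlist(lapply(acc, function(a) lapply(ps, function(p) c(a, p))),
           recursive = FALSE)
  }, perm_sets, init = list(base_assign))
  max(vapply(combos, score_for, numeric(1)))
}

# fresh context with a generously provisioned dealer pool
test_ctx <- function(bool_bits = 2e5, arith = 2e4, b2a = 2e5, seed = 1,
                     record_transcript = FALSE) {
  ctx <- mpc_context(2L, 48L, seed = seed,
                     record_transcript = record_transcript)
  dealer_generate(ctx, list(bool_bits = bool_bits, arith = arith, b2a = b2a),
                  seed = seed + 1L)
  ctx
}
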