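#' Split a normalized string into n-grams
#'
#' Contiguous substrings of length `n` in order, duplicates retained.  No
#' padding sentinels are added by default; with `padded = TRUE` the string is
#' wrapped in `n - 1` underscores on each side.  A string shorter than `n`
#' yields itself as the single token.
#'
#' @param s Character vector of normalized, non-absent strings.
#' @param n n-gram length.
#' @param padded Add sentinel padding.
#' @return For length-1 input a character vector of tokens; otherwise a list
#'   of such vectors.
#' @export
#' @examples
#' ngrams("MEIER", 2) # "ME" "EI" "IE" "ER"
ngrams <- function(s, n = 2L, padded = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 1L, !anyNA(s))
  one <- function(x) {
    if (padded && n > 1L) {
      pad <- strrep("_", n - 1L)
      x <- paste0(pad, x, pad)
    }
    L <- nchar(x)
    if (L < n) return(x)
    substring(x, 1:(L - n + 1L), n:L)
  }
  if (length(s) == 1L) one(s) else lapply(s, one)
}

## Two independent hash values per token via double hashing: h1, h2 are the
## first two 48-bit slices of SHA-256(salt | token), exact in doubles.
## Results are memoized per (salt, token).
.hash_cache <- new.env(parent = emptyenv())

token_hash_halves <- function(tokens, salt) {
  keys <- paste0(salt, "\x01", tokens)
  miss <- !vapply(keys, exists, logical(1), envir = .hash_cache)
  if (any(miss)) {
    hx <- as.character(openssl::sha256(keys[miss]))
    h1 <- strtoi(substr(hx, 1, 6), 16L) * 2^24 + strtoi(substr(hx, 7, 12), 16L)
    h2 <- strtoi(substr(hx, 13, 18), 16L) * 2^24 + strtoi(substr(hx, 19, 24), 16L)
    for (i in seq_along(hx)) {
      assign(keys[miss][i], c(h1[i], h2[i]), envir = .hash_cache)
    }
  }
  out <- vapply(keys, get, numeric(2), envir = .hash_cache)
  list(h1 = out[1, ], h2 = out[2, ])
}

#' Encode a normalized string as a Bloom filter
#'
#' Every n-gram is hashed with `k` nominally independent hash functions whose
#' outputs are reduced modulo the filter length `m`; the addressed bits are
#' set.  The `k` functions are realized by double hashing,
#' \eqn{g_j = (h_1 + j h_2) \bmod m}, with \eqn{h_1, h_2} the first two
#' 48-bit slices of `SHA-256(salt || 0x01 || ngram)` (the `0x01` byte
#' domain-separates the Bloom hash from the token hash), which makes the
#' encoding a deterministic
#' function of `(value, m, k, n, salt)` and therefore bit-identical across
#' parties.  The filter is a plain similarity data structure here, not a
#' privacy mechanism.
#'
#' @param s One normalized, non-absent string.
#' @param spec A [field_spec()] with comparator `"dice"`.
#' @param salt Public salt string.
#' @param padded Sentinel padding for n-grams.
#' @return A `bloom_filter`: list with `bits` (raw 0/1 vector of length `m`),
#'   `m`, `k`.
#' @export
bloom_encode <- function(s, spec, salt = "epilinkr/v1", padded = FALSE) {
  stopifnot(length(s) == 1L, !is.na(s))
  bits <- bloom_bits_for(s, spec$bloom_len, spec$num_hashes, spec$ngram_len,
                         salt, padded)
  structure(list(bits = bits, m = spec$bloom_len, k = spec$num_hashes),
            class = "bloom_filter")
}

bloom_bits_for <- function(s, m, k, n, salt, padded) {
  grams <- ngrams(s, n, padded)
  h <- token_hash_halves(grams, salt)
  h1 <- h$h1 %% m
  h2 <- h$h2 %% m
  idx <- (rep(h1, times = k) + rep(0:(k - 1L), each = length(h1)) *
            rep(h2, times = k)) %% m
  bits <- raw(m)
  bits[unique(idx) + 1L] <- as.raw(1L)
  bits
}

#' Hamming weight (population count) of a bit vector
#'
#' @param bits Raw or logical/integer 0/1 vector, or a `bloom_filter`.
#' @return Number of set bits.
#' @export
hamming_weight <- function(bits) {
  if (inherits(bits, "bloom_filter")) bits <- bits$bits
  if (is.raw(bits)) sum(bits != as.raw(0)) else sum(bits != 0)
}

#' Dice similarity of two Bloom filters
#'
#' \deqn{S = \frac{2\,\mathrm{Hw}(x \wedge y)}{\mathrm{Hw}(x) + \mathrm{Hw}(y)}}
#' computed exactly before any rounding.  Two all-zero filters (which cannot
#' arise from a present value) score 0 with a warning.
#'
#' @param x,y `bloom_filter` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
dice <- function(x, y) {
  stopifnot(inherits(x, "bloom_filter"), inherits(y, "bloom_filter"))
  if (x$m != y$m) stop("bloom filters have different lengths", call. = FALSE)
  hx <- hamming_weight(x$bits)
  hy <- hamming_weight(y$bits)
  if (hx + hy == 0L) {
    warning("dice of two empty filters defined as 0", call. = FALSE)
    return(0)
  }
  2 * sum((x$bits & y$bits) != as.raw(0)) / (hx + hy)
}

## 32-bit salted token hash for exact-comparator fields inside the secure
## circuit (collision probability 2^-32 per comparison).
binary_token_hash <- function(values, salt) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (any(ok)) {
    hx <- as.character(openssl::sha256(paste0(salt, "\x02", values[ok])))
    out[ok] <- strtoi(substr(hx, 1, 4), 16L) * 2^16 +
      strtoi(substr(hx, 5, 8), 16L)
  }
  out
}

#' Precompute per-record encodings
#'
#' Dice fields become Bloom filters with stored Hamming weights; binary
#' fields keep their normalized token plus a 32-bit salted token hash (used
#' by the secure equality circuit).  A presence bit per field marks absent
#' values, which carry no payload.
#'
#' @param records Patient data frame (normalized or raw; normalization is
#'   applied).
#' @param config A [linkage_config()].
#' @return An `encoded_records` object.
#' @export
encode_records <- function(records, config) {
  stopifnot(inherits(config, "linkage_config"))
  rec <- normalize_records(records, config)
  n <- nrow(rec)
  fields <- lapply(config$fields, function(f) {
    v <- rec[[f$name]]
    presence <- !is.na(v)
    if (f$comparator == "dice") {
      bits <- matrix(raw(n * f$bloom_len), nrow = n)
      vals <- unique(v[presence])
      for (val in vals) {
        b <- bloom_bits_for(val, f$bloom_len, f$num_hashes, f$ngram_len,
                            config$salt, config$padded)
        bits[which(v == val), ] <- matrix(b, nrow = sum(v == val, na.rm = TRUE),
                                          ncol = f$bloom_len, byrow = TRUE)
      }
      hw <- as.numeric(rowSums(matrix(bits != as.raw(0), nrow = n)))
      list(type = "dice", bits = bits, hw = hw, presence = presence)
    } else {
      list(type = "binary", token = v,
           token_hash = binary_token_hash(v, config$salt),
           presence = presence)
    }
  })
  structure(list(n = n, fields = fields, config_hash = config_hash(config)),
            class = "encoded_records")
}

#' @export
print.encoded_records <- function(x, ...) {
  cat("<encoded_records> ", x$n, " records, ", length(x$fields),
      " fields\n", sep = "")
  invisible(x)
}

## little-endian-within-byte hex packing, for debug dumps and fixtures
pack_bits_hex <- function(bits01) {
  n <- length(bits01)
  pad <- (8 - n %% 8) %% 8
  v <- c(as.integer(bits01 != as.raw(0)), rep(0L, pad))
  bytes <- colSums(matrix(v, nrow = 8) * 2^(0:7))
  paste(sprintf("%02x", bytes), collapse = "")
}

#' Dump encodings as JSON lines
#'
#' One JSON object per record: presence flags, Hamming weights, hex-packed
#' Bloom filters (little-endian bit order within bytes) and token hashes.
#' Intended for cross-implementation fixture comparison.
#'
#' @param enc An [encode_records()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dump_encodings <- function(enc, path) {
  stopifnot(inherits(enc, "encoded_records"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(enc$n)) {
    row <- lapply(enc$fields, function(f) {
      if (!f$presence[i]) return(list(present = FALSE))
      if (f$type == "dice") {
        list(present = TRUE, hw = f$hw[i], bits = pack_bits_hex(f$bits[i, ]))
      } else {
        list(present = TRUE, token = f$token[i], hash = f$token_hash[i])
      }
    })
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
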