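#' Describe one identifying field for linkage
#'
#' A field specification names an identifying attribute (e.g. `surname`),
#' selects its comparator and carries the statistical weight used in the
#' normalized weighted-sum record similarity.  The weight can either be given
#' directly or derived from the field's assumed error rate \eqn{e_i} and
#' value frequency \eqn{f_i} via [field_weight()].
#'
#' @param name Field name (column name in the patient CSV).
#' @param comparator `"dice"` for fuzzy Bloom-filter comparison of strings,
#'   `"binary"` for exact agreement (e.g. year of birth).
#' @param weight Positive field weight.  Exactly one of `weight` or the pair
#'   `error_rate`/`frequency` must be supplied.
#' @param error_rate Probability in (0,1) that the field is recorded
#'   erroneously for a true match.
#' @param frequency Average value frequency in (0,1) (probability of chance
#'   agreement between non-matching records).
#' @param bloom_len Bloom filter length `m` in bits (dice fields only).
#' @param num_hashes Number of hash functions `k` (dice fields only).
#' @param ngram_len n-gram length used when tokenizing strings (default
#'   bigrams).
#' @return A `field_spec` list.
#' @export
#' @examples
#' field_spec("surname", "dice", error_rate = 0.01, frequency = 0.004)
#' field_spec("year_of_birth", "binary", weight = 6)
field_spec <- function(name, comparator = c("dice", "binary"), weight = NULL,
                       error_rate = NULL, frequency = NULL,
                       bloom_len = 500L, num_hashes = 15L, ngram_len = 2L) {
  comparator <- match.arg(comparator)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  has_w <- !is.null(weight)
  has_ef <- !is.null(error_rate) && !is.null(frequency)
  if (has_w == has_ef) {
    stop("field '", name, "': supply exactly one of `weight` or ",
         "(`error_rate` and `frequency`)", call. = FALSE)
  }
  if (has_ef) weight <- field_weight(error_rate, frequency)
  if (!is.numeric(weight) || weight <= 0) {
    stop("field '", name, "': weight must be > 0", call. = FALSE)
  }
  bloom_len <- as.integer(bloom_len)
  num_hashes <- as.integer(num_hashes)
  ngram_len <- as.integer(ngram_len)
  if (comparator == "dice") {
    stopifnot(bloom_len >= 1L, num_hashes >= 1L, ngram_len >= 1L)
  }
  structure(
    list(name = name, comparator = comparator, weight = as.numeric(weight),
         error_rate = error_rate, frequency = frequency,
         bloom_len = bloom_len, num_hashes = num_hashes,
         ngram_len = ngram_len),
    class = "field_spec"
  )
}

#' Derive a field weight from error rate and value frequency
#'
#' The weight follows the classical log-odds convention of probabilistic
#' record linkage: \eqn{w_i = \log_2((1 - e_i)/f_i)}, where \eqn{e_i} is the
#' field error rate and \eqn{f_i} the average value frequency.  Rare, reliably
#' recorded fields thus receive large weights.
#'
#' @param error_rate,frequency Numbers in (0,1) with
#'   `(1 - error_rate)/frequency > 1`.
#' @return Positive weight (vectorized).
#' @export
#' @examples
#' field_weight(0.01, 1e-4) # ~ 13.27
field_weight <- function(error_rate, frequency) {
  if (any(error_rate <= 0 | error_rate >= 1)) {
    stop("error_rate must lie in (0,1)", call. = FALSE)
  }
  if (any(frequency <= 0 | frequency >= 1)) {
    stop("frequency must lie in (0,1)", call. = FALSE)
  }
  w <- log2((1 - error_rate) / frequency)
  if (any(w < 0)) {
    stop("(1 - error_rate)/frequency must exceed 1 (weight must be positive)",
         call. = FALSE)
  }
  w
}

## Smallest power-of-ten rational approximation used for threshold
## comparisons inside the integer circuit.
rationalize_threshold <- function(t, max_den = 1e4) {
  den <- 1
  while (den <= max_den) {
    if (abs(t * den - round(t * den)) < 1e-9) {
      return(list(num = round(t * den), den = den))
    }
    den <- den * 10
  }
  list(num = round(t * max_den), den = max_den)
}

#' Assemble and validate a linkage configuration
#'
#' Collects the field specifications, exchange groups, classification
#' thresholds and the numeric parameters shared by the plaintext fixed-point
#' engine and the secure circuit.  Validation enforces, among other checks,
#' that every intermediate of the integer circuit (weighted sums, threshold
#' cross-products and the exchange-group tournament cross-products) stays
#' below \eqn{2^{\ell-1}}, so the oblivious comparison is sound.
#'
#' @param fields List of [field_spec()] objects.
#' @param exchange_groups List of character vectors of field names; the
#'   values of a group's fields are compared under all permutations and the
#'   best-scoring assignment is used (tolerates swapped name fields).
#' @param threshold_tentative,threshold_match Classification thresholds in
#'   (0,1) with `threshold_tentative <= threshold_match`.  Scores at or above
#'   `threshold_match` classify as `match`, scores in between as
#'   `tentative_match`.
#' @param fixedpoint_bits Fractional bits `p` of the fixed-point similarity.
#' @param ring_bits Ring width `ell` of the arithmetic sharing (`<= 48`).
#' @param weight_scale Integer scale `W`; weights are rounded to
#'   `round(W * w)` for the integer circuit.
#' @param salt Public salt for the Bloom and token hashes.  Both parties must
#'   use the same salt; it is part of the configuration fingerprint.
#' @param padded Pad strings with sentinels before n-gram extraction
#'   (default off).
#' @return A validated `linkage_config` object.
#' @export
linkage_config <- function(fields, exchange_groups = list(),
                           threshold_tentative = 0.7, threshold_match = 0.9,
                           fixedpoint_bits = 16L, ring_bits = 48L,
                           weight_scale = 64L, salt = "epilinkr/v1",
                           padded = FALSE) {
  if (inherits(fields, "field_spec")) fields <- list(fields)
  stopifnot(length(fields) >= 1L)
  ok <- vapply(fields, inherits, logical(1), "field_spec")
  if (!all(ok)) stop("`fields` must be a list of field_spec objects", call. = FALSE)
  names(fields) <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(names(fields))) {
    stop("duplicate field names in configuration", call. = FALSE)
  }
  if (!(threshold_tentative > 0 && threshold_tentative < 1 &&
        threshold_match > 0 && threshold_match < 1)) {
    stop("thresholds must lie in (0,1)", call. = FALSE)
  }
  if (threshold_tentative > threshold_match) {
    stop("threshold_tentative must not exceed threshold_match", call. = FALSE)
  }
  fixedpoint_bits <- as.integer(fixedpoint_bits)
  ring_bits <- as.integer(ring_bits)
  weight_scale <- as.integer(weight_scale)
  stopifnot(fixedpoint_bits >= 1L, weight_scale >= 1L, ring_bits >= 8L)
  if (ring_bits > RING_MAX_BITS) {
    stop("ring_bits must be <= ", RING_MAX_BITS,
         " (exact double arithmetic bound)", call. = FALSE)
  }

  # exchange groups: existing, distinct members, disjoint groups, shared
  # comparator and Bloom geometry within a group
  seen <- character(0)
  for (g in exchange_groups) {
    if (length(g) < 2L) stop("exchange groups need >= 2 members", call. = FALSE)
    if (anyDuplicated(g)) stop("exchange group members must be distinct", call. = FALSE)
    missing <- setdiff(g, names(fields))
    if (length(missing)) {
      stop("exchange group references unknown field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (length(intersect(g, seen))) {
      stop("field(s) in more than one exchange group: ",
           paste(intersect(g, seen), collapse = ", "), call. = FALSE)
    }
    seen <- c(seen, g)
    cmp <- unique(vapply(fields[g], `[[`, character(1), "comparator"))
    if (length(cmp) != 1L) {
      stop("all members of an exchange group must share one comparator",
           call. = FALSE)
    }
    if (cmp == "dice") {
      geom <- unique(vapply(fields[g], function(f) {
        paste(f$bloom_len, f$num_hashes, f$ngram_len)
      }, character(1)))
      if (length(geom) != 1L) {
        stop("dice exchange-group members must share bloom_len/num_hashes/",
             "ngram_len", call. = FALSE)
      }
    }
  }

  weights <- vapply(fields, `[[`, numeric(1), "weight")
  w_scaled <- round(weight_scale * weights)
  w_scaled[w_scaled < 1] <- 1
  tt <- rationalize_threshold(threshold_tentative)
  tm <- rationalize_threshold(threshold_match)

  cfg <- structure(
    list(fields = fields, exchange_groups = exchange_groups,
         threshold_tentative = threshold_tentative,
         threshold_match = threshold_match,
         tt_num = tt$num, tt_den = tt$den, tm_num = tm$num, tm_den = tm$den,
         fixedpoint_bits = fixedpoint_bits, ring_bits = ring_bits,
         weight_scale = weight_scale, weights = weights,
         weights_scaled = w_scaled, salt = salt, padded = isTRUE(padded)),
    class = "linkage_config"
  )
  validate_ring_bounds(cfg)
  cfg
}

## No circuit intermediate may reach 2^(ell-1): the oblivious >= comparison
## extracts the sign bit of a difference.
validate_ring_bounds <- function(cfg) {
  p <- cfg$fixedpoint_bits
  ell <- cfg$ring_bits
  max_m <- sum(cfg$weights_scaled)
  max_n <- max_m * 2^p
  worst <- max(
    max_n * max(cfg$tm_den, cfg$tt_den),       # classification lhs
    max(cfg$tm_num, cfg$tt_num) * max_m * 2^p, # classification rhs
    max_n * max_m,                             # tournament cross-products
    vapply(cfg$fields, function(f) {
      if (f$comparator == "dice") 2 * f$bloom_len * 2^p else 2^p
    }, numeric(1))                             # per-field dice numerator
  )
  if (worst >= 2^(ell - 1L)) {
    stop("ring overflow risk: largest circuit intermediate needs ",
         ceiling(log2(worst)) + 1L, " bits but ring_bits = ", ell,
         "; increase ring_bits or lower fixedpoint_bits/weight_scale",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Default eight-field patient linkage configuration
#'
#' First name, surname, birth name, day/month/year of birth, ZIP code and
#' city, with the three name fields forming an exchange group.  The numeric
#' error rates and frequencies (and hence the weights) are this package's
#' documented placeholders, chosen to be plausible for German patient
#' registries; real deployments should calibrate them on their own data.
#'
#' @param ... Overrides passed on to [linkage_config()].
#' @return A `linkage_config`.
#' @export
default_linkage_config <- function(...) {
  fields <- list(
    field_spec("first_name",    "dice",   error_rate = 0.01, frequency = 0.005),
    field_spec("surname",       "dice",   error_rate = 0.01, frequency = 0.004),
    field_spec("birth_name",    "dice",   error_rate = 0.05, frequency = 0.004),
    field_spec("day_of_birth",  "binary", error_rate = 0.02, frequency = 1 / 28),
    field_spec("month_of_birth","binary", error_rate = 0.02, frequency = 1 / 12),
    field_spec("year_of_birth", "binary", error_rate = 0.02, frequency = 1 / 70),
    field_spec("zip_code",      "binary", error_rate = 0.03, frequency = 0.001),
    field_spec("city",          "dice",   error_rate = 0.02, frequency = 0.01)
  )
  linkage_config(
    fields,
    exchange_groups = list(c("first_name", "surname", "birth_name")),
    ...
  )
}

#' @export
print.linkage_config <- function(x, ...) {
  cat("<linkage_config> ", length(x$fields), " fields, thresholds ",
      x$threshold_tentative, "/", x$threshold_match,
      ", p=", x$fixedpoint_bits, ", ring=2^", x$ring_bits, "\n", sep = "")
  for (f in x$fields) {
    cat(sprintf("  %-14s %-6s w=%.3f", f$name, f$comparator, f$weight))
    if (f$comparator == "dice") {
      cat(sprintf("  m=%d k=%d n=%d", f$bloom_len, f$num_hashes, f$ngram_len))
    }
    cat("\n")
  }
  if (length(x$exchange_groups)) {
    cat("  exchange groups:",
        paste(vapply(x$exchange_groups, paste, character(1), collapse = "+"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a linkage configuration from JSON or YAML
#'
#' The schema mirrors the arguments of [linkage_config()]: a `fields` array
#' of objects (`name`, `comparator`, and either `weight` or
#' `error_rate`+`frequency`, plus optional `bloom_len`, `num_hashes`,
#' `ngram_len`), optional `exchange_groups`, thresholds and numeric
#' parameters.  An example ships at
#' `system.file("extdata/config-default.json", package = "epilinkr")`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `linkage_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(raw$fields)) stop("config lacks a `fields` array", call. = FALSE)
  fields <- lapply(raw$fields, function(f) {
    args <- f[intersect(names(f), c("name", "comparator", "weight",
                                    "error_rate", "frequency", "bloom_len",
                                    "num_hashes", "ngram_len"))]
    do.call(field_spec, args)
  })
  args <- list(fields = fields,
               exchange_groups = lapply(raw$exchange_groups %||% list(),
                                        unlist))
  for (nm in c("threshold_tentative", "threshold_match", "fixedpoint_bits",
               "ring_bits", "weight_scale", "salt", "padded")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(linkage_config, args)
}

#' Configuration fingerprint
#'
#' SHA-256 over the canonical JSON serialization of every semantically
#' relevant configuration component.  Exchanged in clear before a secure run;
#' a mismatch aborts the protocol before any input is shared.
#'
#' @param config A `linkage_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "linkage_config"))
  canon <- list(
    fields = lapply(config$fields, function(f) {
      list(name = f$name, comparator = f$comparator,
           weight = round(f$weight, 12), bloom_len = f$bloom_len,
           num_hashes = f$num_hashes, ngram_len = f$ngram_len)
    }),
    groups = config$exchange_groups,
    tt = c(config$tt_num, config$tt_den), tm = c(config$tm_num, config$tm_den),
    p = config$fixedpoint_bits, ring = config$ring_bits,
    W = config$weight_scale, salt = config$salt, padded = config$padded
  )
  as.character(openssl::sha256(jsonlite::toJSON(canon, auto_unbox = TRUE,
                                                digits = NA)))
}
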