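#' Normalize an identifying value
#'
#' Both parties must encode byte-identical strings for identical inputs, so
#' normalization is a fixed cross-party contract: Unicode compatibility
#' decomposition (NFKD), removal of combining marks, upper-casing, removal of
#' every character that is not `A-Z`, `0-9` or an internal space, and
#' whitespace collapsing.  An empty result (or missing input) becomes `NA`,
#' the package's representation of an absent field.
#'
#' The function is total, deterministic and idempotent.
#'
#' @param x Character vector (anything coercible).
#' @return Character vector; `NA` marks absent values.
#' @export
#' @examples
#' normalize_value("  Müller-Lüdenscheid ") # "MULLERLUDENSCHEID"
normalize_value <- function(x) {
  x <- as.character(x)
  out <- stringi::stri_trans_nfkd(x)
  out <- stringi::stri_replace_all_regex(out, "\\p{M}", "")
  out <- stringi::stri_trans_toupper(out, locale = "en")
  out <- stringi::stri_replace_all_regex(out, "[^A-Z0-9 ]", "")
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  out <- stringi::stri_trim_both(out)
  out[is.na(x) | !nzchar(out) | is.na(out)] <- NA_character_
  out
}

#' Normalize a patient table against a configuration
#'
#' Keeps exactly the configured fields (in configuration order) and applies
#' [normalize_value()] to each.  Idempotent; every linkage entry point calls
#' it, so callers may pass raw or pre-normalized tables interchangeably.
#'
#' @param records Data frame with one row per patient.
#' @param config A [linkage_config()].
#' @return Tibble with the configured columns, normalized, `NA` = absent.
#' @export
normalize_records <- function(records, config) {
  stopifnot(inherits(config, "linkage_config"))
  wanted <- names(config$fields)
  missing <- setdiff(wanted, names(records))
  if (length(missing)) {
    stop("records lack configured column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(records)[wanted]
  dplyr::mutate(out, dplyr::across(dplyr::everything(), normalize_value))
}

#' Read a patient CSV
#'
#' UTF-8, comma-separated, RFC-4180 quoting, header row.  Header names are
#' matched case-insensitively against the configured field names; extra
#' columns are dropped with a warning, a missing configured column is an
#' error.  Values are normalized on load and empty cells become absent
#' (`NA`).  Row order is preserved.
#'
#' @param path CSV file path.
#' @param config A [linkage_config()].
#' @return Tibble of normalized patient records.
#' @export
load_records <- function(path, config) {
  stopifnot(inherits(config, "linkage_config"))
  if (!file.exists(path)) stop("cannot read records file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  wanted <- names(config$fields)
  hit <- match(tolower(wanted), tolower(names(df)))
  if (anyNA(hit)) {
    stop("CSV ", path, " lacks configured column(s): ",
         paste(wanted[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), names(df)[hit])
  if (length(extra)) {
    warning("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- df[hit]
  names(df) <- wanted
  normalize_records(df, config)
}

#' Write patient records as an RFC-4180 CSV
#'
#' @param records Data frame of patient records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, na = "")
  invisible(path)
}
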