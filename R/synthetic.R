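## Synthetic patient-data generator.
##
## Emulates the evaluation design of institutional overlap studies: three
## datasets with a controlled pairwise-exclusive overlap, a small set of
## persons common to all three, and a corruption model applied to duplicate
## copies only, with machine-readable ground truth.  Name pools ship as
## packaged word lists; dates, ZIP codes and pool draws are uniform.

name_pool <- function(which) {
  path <- system.file("extdata", paste0(which, ".txt"), package = "epilinkr")
  readLines(path, encoding = "UTF-8")
}

#' Generate a synthetic patient population
#'
#' Draws `n` distinct synthetic persons with the default eight identifying
#' fields: names from packaged pools (the birth name usually equals the
#' surname, with a 20% married-name deviation), birth dates uniform over
#' `year_range`, five-digit ZIP codes and pool cities.  Identity tuples are
#' deduplicated by rejection, so all `n` persons are distinct.
#' Deterministic for a fixed seed.
#'
#' @param n Number of persons.
#' @param seed Integer seed.
#' @param year_range Birth-year range (inclusive).
#' @return Tibble with one row per person.
#' @export
generate_population <- function(n, seed = 1L, year_range = c(1930L, 2010L)) {
  stopifnot(n >= 1L)
  set.seed(seed)
  firsts <- name_pool("first-names")
  surs <- name_pool("surnames")
  cities <- name_pool("cities")
  days_in <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  draw <- function(k) {
    sur <- sample(surs, k, replace = TRUE)
    birth <- ifelse(stats::runif(k) < 0.2, sample(surs, k, replace = TRUE), sur)
    month <- sample.int(12L, k, replace = TRUE)
    tibble::tibble(
      first_name = sample(firsts, k, replace = TRUE),
      surname = sur,
      birth_name = birth,
      day_of_birth = vapply(month, function(m) sample.int(days_in[m], 1L),
                            integer(1)),
      month_of_birth = month,
      year_of_birth = sample(seq(year_range[1], year_range[2]), k,
                             replace = TRUE),
      zip_code = sprintf("%05d", sample.int(99999L, k, replace = TRUE)),
      city = sample(cities, k, replace = TRUE)
    )
  }
  out <- draw(n)
  key <- function(df) {
    do.call(paste, c(df[c("first_name", "surname", "day_of_birth",
                          "month_of_birth", "year_of_birth", "zip_code")],
                     sep = "\r"))
  }
  repeat {
    dup <- duplicated(key(out))
    if (!any(dup)) break
    out[dup, ] <- draw(sum(dup))
  }
  dplyr::mutate(out, dplyr::across(dplyr::everything(), as.character))
}

#' Define a record corruption model
#'
#' Per-field independent error operators applied to duplicate copies of a
#' person's record, emulating typos, data-entry drift and missingness:
#' character substitution, character deletion, swapping two exchange-group
#' fields, and field drop (to absent).  Probabilities default low, as is
#' realistic for registry identifying data.
#'
#' @param substitution,deletion,swap,drop Per-field (per-group for `swap`)
#'   probabilities in `[0, 1]`.
#' @return A `noise_model`.
#' @export
noise_model <- function(substitution = 0.03, deletion = 0.01, swap = 0.01,
                        drop = 0.02) {
  prob <- c(substitution = substitution, deletion = deletion, swap = swap,
            drop = drop)
  stopifnot(all(prob >= 0 & prob <= 1))
  structure(as.list(prob), class = "noise_model")
}

#' Noise-free corruption model
#' @return A `noise_model` with all probabilities zero.
#' @export
noise_off <- function() noise_model(0, 0, 0, 0)

substitute_char <- function(s) {
  if (is.na(s) || nchar(s) == 0L) return(s)
  i <- sample.int(nchar(s), 1L)
  paste0(substr(s, 1L, i - 1L), sample(LETTERS, 1L),
         substr(s, i + 1L, nchar(s)))
}

delete_char <- function(s) {
  if (is.na(s) || nchar(s) <= 1L) return(s)
  i <- sample.int(nchar(s), 1L)
  paste0(substr(s, 1L, i - 1L), substr(s, i + 1L, nchar(s)))
}

#' Apply a corruption model to records
#'
#' Fields are corrupted independently; the swap operator exchanges the
#' values of two randomly chosen fields of an exchange group.
#'
#' @param records Patient data frame.
#' @param model A [noise_model()].
#' @param exchange_groups List of field-name vectors eligible for swapping.
#' @return Corrupted tibble (same shape).
#' @export
corrupt_records <- function(records, model,
                            exchange_groups = list(c("first_name", "surname",
                                                     "birth_name"))) {
  stopifnot(inherits(model, "noise_model"))
  df <- tibble::as_tibble(records)
  n <- nrow(df)
  if (n == 0L) return(df)
  for (fn in names(df)) {
    hit <- stats::runif(n) < model$substitution
    if (any(hit)) df[[fn]][hit] <- vapply(df[[fn]][hit], substitute_char,
                                          character(1))
    hit <- stats::runif(n) < model$deletion
    if (any(hit)) df[[fn]][hit] <- vapply(df[[fn]][hit], delete_char,
                                          character(1))
    hit <- stats::runif(n) < model$drop
    if (any(hit)) df[[fn]][hit] <- NA_character_
  }
  for (g in exchange_groups) {
    g <- intersect(g, names(df))
    if (length(g) < 2L) next
    hit <- which(stats::runif(n) < model$swap)
    for (i in hit) {
      pick <- sample(g, 2L)
      tmp <- df[[pick[1]]][i]
      df[[pick[1]]][i] <- df[[pick[2]]][i]
      df[[pick[2]]][i] <- tmp
    }
  }
  df
}

#' Generate three overlapping datasets with ground truth
#'
#' Produces three datasets of exactly `n_per_dataset` rows.  Per unordered
#' dataset pair, exactly `pairwise_overlap` persons appear in exactly those
#' two datasets; `triple_overlap` persons appear in all three; all remaining
#' rows are unique to one dataset.  Copies of a person beyond its canonical
#' (lowest-numbered) dataset pass through [corrupt_records()]; rows are
#' shuffled within each dataset.
#'
#' @param n_per_dataset Rows per dataset.
#' @param pairwise_overlap Persons shared by exactly two datasets, per pair.
#' @param triple_overlap Persons present in all three datasets.
#' @param noise A [noise_model()] for duplicate copies.
#' @param seed Integer seed.
#' @param dir Optional directory; if given, writes `dataset-1.csv` ..
#'   `dataset-3.csv` and `ground-truth.json` there.
#' @return List with `datasets` (list of three tibbles), `ground_truth`
#'   (tibble `person_id`, `dataset`, `row`) and `composition`.
#' @export
generate_overlapping_datasets <- function(n_per_dataset = 2000L,
                                          pairwise_overlap = 200L,
                                          triple_overlap = 8L,
                                          noise = noise_off(),
                                          seed = 1L, dir = NULL) {
  n <- as.integer(n_per_dataset)
  pw <- as.integer(pairwise_overlap)
  tri <- as.integer(triple_overlap)
  if (pw < 0L || tri < 0L || n < 2L * pw + tri + 1L) {
    stop("infeasible composition: need n_per_dataset >= 2*pairwise_overlap",
         " + triple_overlap + 1", call. = FALSE)
  }
  uniq <- n - 2L * pw - tri
  total <- 3L * uniq + 3L * pw + tri
  pop <- generate_population(total, seed = seed)
  pop$person_id <- seq_len(total)

  memberships <- c(
    rep(list(1:3), tri),
    rep(list(c(1L, 2L)), pw), rep(list(c(1L, 3L)), pw),
    rep(list(c(2L, 3L)), pw),
    rep(list(1L), uniq), rep(list(2L), uniq), rep(list(3L), uniq)
  )
  set.seed(seed + 1L)
  canonical <- vapply(memberships, min, integer(1))
  datasets <- vector("list", 3L)
  gt <- list()
  for (d in 1:3) {
    ids <- which(vapply(memberships, function(m) d %in% m, logical(1)))
    df <- pop[ids, names(pop) != "person_id"]
    dup <- canonical[ids] != d
    if (any(dup)) df[dup, ] <- corrupt_records(df[dup, ], noise)
    ord <- sample.int(nrow(df))
    datasets[[d]] <- df[ord, ]
    gt[[d]] <- tibble::tibble(person_id = ids[ord], dataset = d,
                              row = seq_len(nrow(df)))
  }
  gt <- dplyr::bind_rows(gt)
  composition <- list(n_per_dataset = n, pairwise_overlap = pw,
                      triple_overlap = tri, seed = seed)
  out <- list(datasets = datasets, ground_truth = gt,
              composition = composition)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (d in 1:3) {
      write_records(datasets[[d]], file.path(dir, paste0("dataset-", d, ".csv")))
    }
    jsonlite::write_json(
      list(composition = composition,
           ground_truth = gt),
      file.path(dir, "ground-truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Overlap counts implied by a ground truth
#'
#' @param ground_truth The `ground_truth` tibble of
#'   [generate_overlapping_datasets()].
#' @return List with `pairwise_shared` (named, inclusive of triple members),
#'   `pairwise_exclusive` and `triple`.
#' @export
overlap_counts <- function(ground_truth) {
  sets <- lapply(1:3, function(d) {
    unique(ground_truth$person_id[ground_truth$dataset == d])
  })
  inter <- function(i, j) length(intersect(sets[[i]], sets[[j]]))
  triple <- length(Reduce(intersect, sets))
  shared <- c("1-2" = inter(1, 2), "1-3" = inter(1, 3), "2-3" = inter(2, 3))
  list(pairwise_shared = shared,
       pairwise_exclusive = shared - triple,
       triple = triple)
}
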