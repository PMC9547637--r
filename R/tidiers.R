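#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intersection result
#'
#' @param x An `epilink_intersection`.
#' @param ... Unused.
#' @return One-row tibble with the counts and run metadata.
#' @export
tidy.epilink_intersection <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, mode = x$mode,
                 n_left = x$n_left, n_right = x$n_right,
                 match_count = x$match_count,
                 tentative_count = x$tentative_count)
}

#' @rdname tidy.epilink_intersection
#' @export
glance.epilink_intersection <- function(x, ...) {
  out <- tidy.epilink_intersection(x)
  if (!is.null(x$stats)) {
    out$setup_seconds <- x$stats$setup_seconds
    out$online_seconds <- x$stats$online_seconds
    out$reveals <- x$stats$reveals
    out$bytes_sent <- x$stats$bytes_sent
  }
  out
}

#' Tidy a linkage table
#'
#' @param x An `epilink_linkage` tibble from [link_pair()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.epilink_linkage <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("row_a", "best_b", "score", "match_class")])
}

#' @rdname tidy.epilink_linkage
#' @export
glance.epilink_linkage <- function(x, ...) {
  tibble::tibble(n = nrow(x),
                 matches = sum(x$match_class == "match"),
                 tentative = sum(x$match_class == "tentative_match"),
                 mean_best_score = mean(x$score))
}

#' Plot the best-match score distribution of a linkage
#'
#' Histogram of each left-hand record's best similarity with the two
#' classification thresholds marked.
#'
#' @param object An `epilink_linkage` tibble.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epilink_linkage <- function(object, bins = 40, ...) {
  thr <- attr(object, "config_thresholds")
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = thr, linetype = c("dashed", "solid"),
                        colour = c("orange", "red")) +
    ggplot2::labs(x = "best-match EpiLink similarity", y = "records",
                  title = "Best-match score distribution",
                  subtitle = "dashed: tentative threshold, solid: match threshold") +
    ggplot2::theme_minimal()
}

#' Plot an intersection result
#'
#' @param object An `epilink_intersection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epilink_intersection <- function(object, ...) {
  df <- tibble::tibble(
    class = factor(c("match", "tentative_match"),
                   levels = c("match", "tentative_match")),
    count = c(object$match_count, object$tentative_count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "records",
                  title = sprintf("Common patients (%s, %s)", object$protocol,
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
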