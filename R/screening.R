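#' Screen candidate indicators by expert-panel scores
#'
#' Each expert rates every candidate indicator on a 5-point importance scale.
#' An indicator enters the preliminary set when its across-rater mean score
#' is strictly greater than `mean_threshold` and, under the `sd_max`
#' consensus rule, the across-rater standard deviation (divisor `n - 1`)
#' does not exceed `sd_max` — a Delphi-style operationalization of "the
#' experts agreed it matters".
#'
#' @param panel A data frame of rater-by-item scores: one row per rater, one
#'   numeric column per candidate indicator, every score in 1..5. A leading
#'   non-numeric rater-id column (as written by panel CSVs) is dropped
#'   automatically.
#' @param mean_threshold Retention threshold on the rater mean; strictly
#'   greater than. Default 3.5.
#' @param consensus_rule `"sd_max"` (default) or `"none"`.
#' @param sd_max Maximum allowed across-rater SD under the `sd_max` rule.
#' @return A tibble with one row per item in input order: `item`, `mean`,
#'   `sd`, `retained`. Class `screening_result`.
#' @export
#' @examples
#' panel <- data.frame(jump_height = c(5, 5, 4), shoe_color = c(2, 1, 3))
#' screen_items(panel)
screen_items <- function(panel, mean_threshold = 3.5,
                         consensus_rule = c("sd_max", "none"), sd_max = 1.0) {
  consensus_rule <- match.arg(consensus_rule)
  panel <- tibble::as_tibble(panel)
  numeric_cols <- vapply(panel, is.numeric, logical(1))
  if (!numeric_cols[1] && all(numeric_cols[-1])) {
    panel <- panel[-1]          # leading rater-id column
    numeric_cols <- numeric_cols[-1]
  }
  if (!all(numeric_cols)) {
    stop("non-numeric score column(s): ",
         paste(names(panel)[!numeric_cols], collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) < 2) {
    stop("at least 2 raters are required; got ", nrow(panel), call. = FALSE)
  }
  scores <- as.matrix(panel)
  if (anyNA(scores) || !all(scores %in% 1:5)) {
    stop("every score must be an integer in 1..5", call. = FALSE)
  }
  res <- tibble::tibble(
    item = names(panel),
    mean = unname(colMeans(scores)),
    sd = unname(apply(scores, 2L, stats::sd))
  )
  res$retained <- res$mean > mean_threshold &
    (consensus_rule == "none" | res$sd <= sd_max)
  structure(res, class = c("screening_result", class(res)),
            mean_threshold = mean_threshold,
            consensus_rule = consensus_rule, sd_max = sd_max)
}

#' Read an expert panel CSV
#'
#' Expected layout: first column a rater identifier, remaining columns one
#' integer score (1..5) per candidate indicator.
#'
#' @param path Path to the CSV file.
#' @return A tibble of scores (rater-id column preserved).
#' @export
read_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @method glance screening_result
#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x),
    n_retained = sum(x$retained),
    mean_threshold = attr(x, "mean_threshold"),
    consensus_rule = attr(x, "consensus_rule"),
    sd_max = attr(x, "sd_max")
  )
}

#' Plot expert-panel screening results
#'
#' Dot plot of rater means with the retention threshold; retained items
#' highlighted.
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$item <- factor(df$item, levels = rev(df$item))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$item,
                                   colour = .data$retained)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean - .data$sd,
                                         xmax = .data$mean + .data$sd),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = attr(object, "mean_threshold"),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey55")) +
    ggplot2::labs(x = "rater mean (points, 1-5)", y = NULL,
                  colour = "retained",
                  title = "Expert screening of candidate indicators") +
    ggplot2::theme_minimal()
}
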