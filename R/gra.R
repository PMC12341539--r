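#' Mean-normalize a sequence
#'
#' Divides every element by the sequence mean, the pre-processing step
#' applied to the standard and every inspected sequence before grey
#' relational coefficients are computed. The output has mean exactly 1 and
#' is invariant to positive rescaling of the input. Sequences with
#' non-positive mean are rejected rather than silently shifted.
#'
#' @param x Numeric vector with strictly positive mean.
#' @return `x / mean(x)`.
#' @export
#' @examples
#' mean_normalize(c(1, 2, 3)) # 0.5 1.0 1.5
mean_normalize <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    stop("mean normalization undefined: sequence mean must be strictly positive",
         call. = FALSE)
  }
  x / m
}

#' Grey relational coefficients and grades (Deng)
#'
#' Computes Deng's grey relational coefficients of `m` inspected sequences
#' against one standard sequence. All sequences are mean-normalized first;
#' with \eqn{\Delta_{0i}(k) = |x_0(k) - x_i(k)|} on the normalized data and
#' \eqn{\Delta_{min}, \Delta_{max}} the global minimum and maximum over all
#' sequences `i` and positions `k`, the coefficient is
#' \deqn{\zeta_i(k) = \frac{\Delta_{min} + p\,\Delta_{max}}
#'                         {\Delta_{0i}(k) + p\,\Delta_{max}}}
#' with distinguishing coefficient `p` (0.5 by convention). The grade of
#' sequence `i` is the mean of its coefficients over `k`. Because the
#' extrema are global, a sequence's grade depends on which other sequences
#' are in the comparison set. In the degenerate case where every inspected
#' sequence equals the standard after normalization (\eqn{\Delta_{max} = 0})
#' all coefficients are defined as 1.
#'
#' @param standard Numeric vector: the criterion (standard) sequence
#'   \eqn{x_0}.
#' @param inspected A numeric matrix or data frame with one column per
#'   inspected sequence, `length(standard)` rows.
#' @param p Distinguishing coefficient in \[0, 1\]. Default 0.5.
#' @return An object of class `gra_fit`: a list with `coefficients` and
#'   `deltas` (m x n matrices), `grades` (named length-m vector),
#'   `delta_min`, `delta_max`, `p`, `n`, and the normalized sequences.
#' @export
#' @examples
#' gra_coefficients(c(1, 2, 3), cbind(flat = c(2, 2, 2)))$coefficients
gra_coefficients <- function(standard, inspected, p = 0.5) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  X <- as.matrix(inspected)
  n <- length(standard)
  if (n < 2) stop("sequences must have length >= 2", call. = FALSE)
  if (nrow(X) != n) {
    stop("inspected sequences must have the same length as the standard",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  x0 <- mean_normalize(standard)
  Xn <- apply(X, 2L, mean_normalize)
  deltas <- t(abs(Xn - x0))                     # m x n
  d_min <- min(deltas)
  d_max <- max(deltas)
  coefs <- if (d_max == 0) {
    matrix(1, nrow(deltas), ncol(deltas), dimnames = dimnames(deltas))
  } else {
    (d_min + p * d_max) / (deltas + p * d_max)
  }
  grades <- rowMeans(coefs)
  structure(
    list(coefficients = coefs, deltas = deltas, grades = grades,
         delta_min = d_min, delta_max = d_max, p = p, n = n,
         normalized_standard = x0, normalized_inspected = Xn),
    class = "gra_fit"
  )
}

#' Grey relational grades
#'
#' The grade of each inspected sequence: the arithmetic mean of its grey
#' relational coefficients across positions. Provided as a standalone
#' accessor; [gra_coefficients()] already populates grades.
#'
#' @param fit A `gra_fit` from [gra_coefficients()].
#' @return Named numeric vector of grades in (0, 1].
#' @export
gra_grade <- function(fit) {
  stopifnot(inherits(fit, "gra_fit"))
  rowMeans(fit$coefficients)
}

#' Rank grades and classify their strength
#'
#' Orders grades descending (ties keep input order) and labels each as
#' `strong` (grade > `strong_cut`), `moderate` (`weak_cut` <= grade <=
#' `strong_cut`) or `weak` (grade < `weak_cut`). The conventional cuts are
#' 0.9 and 0.8; both boundaries classify as moderate.
#'
#' @param grades Numeric vector of grades in (0, 1], optionally named.
#' @param strong_cut,weak_cut Classification cuts. Defaults 0.9 and 0.8.
#' @return A tibble in input order with `indicator`, `grade`, `rank`,
#'   `class` (factor strong/moderate/weak).
#' @export
#' @examples
#' rank_and_classify(c(a = 0.95, b = 0.85, c = 0.7))
rank_and_classify <- function(grades, strong_cut = 0.9, weak_cut = 0.8) {
  if (weak_cut > strong_cut) stop("weak_cut must not exceed strong_cut", call. = FALSE)
  g <- as.numeric(grades)
  nms <- names(grades)
  if (is.null(nms)) nms <- paste0("x", seq_along(g))
  ord <- order(-g)                      # stable: ties keep input order
  rk <- integer(length(g))
  rk[ord] <- seq_along(g)
  cls <- ifelse(g > strong_cut, "strong", ifelse(g < weak_cut, "weak", "moderate"))
  tibble::tibble(
    indicator = nms,
    grade = g,
    rank = rk,
    class = factor(cls, levels = c("strong", "moderate", "weak"))
  )
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation and the standard two-sided t-test p-value on
#' `n - 2` degrees of freedom, with a significance flag at `alpha`.
#'
#' @param x,y Numeric vectors of equal length at least 3, each with nonzero
#'   variance.
#' @param alpha Significance level for the flag. Default 0.05.
#' @return A list with `r`, `p_value`, `significant`.
#' @export
pearson <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       significant = ct$p.value < alpha)
}

#' Grey relational analysis of a cohort against its criterion
#'
#' The full ranking analysis: every non-criterion column of the cohort is
#' treated as an inspected sequence, the criterion column as the standard
#' sequence. Grades use a single global \eqn{\Delta_{min}/\Delta_{max}}
#' across all indicators; each indicator also gets its Pearson correlation
#' with the criterion and a strong/moderate/weak class label.
#'
#' @param cohort A data frame of athletes by variables (e.g. from
#'   [generate_exact()] or [read_cohort()]).
#' @param criterion Name of the criterion column; defaults to the cohort's
#'   `criterion` attribute.
#' @param p Distinguishing coefficient. Default 0.5.
#' @param strong_cut,weak_cut Classification cuts for [rank_and_classify()].
#' @param alpha Significance level for the Pearson flag.
#' @return An object of class `gra_result` wrapping the `gra_fit` and the
#'   report table; `tidy()` returns the table (rows ordered by descending
#'   grade), `glance()` a one-row summary.
#' @export
#' @examples
#' cohort <- generate_exact(trampoline_moments(), n = 40, seed = 1)
#' res <- run_gra(cohort)
#' tidy(res)
run_gra <- function(cohort, criterion = attr(cohort, "criterion"), p = 0.5,
                    strong_cut = 0.9, weak_cut = 0.8, alpha = 0.05) {
  cohort <- validate_cohort(cohort, criterion)
  criterion <- attr(cohort, "criterion")
  indicators <- setdiff(names(cohort), criterion)
  if (length(indicators) == 0) {
    stop("cohort has no indicator columns besides the criterion", call. = FALSE)
  }
  fit <- gra_coefficients(cohort[[criterion]],
                          as.matrix(cohort[indicators]), p = p)
  ranked <- rank_and_classify(fit$grades, strong_cut = strong_cut,
                              weak_cut = weak_cut)
  pears <- purrr::map(indicators,
                      ~ pearson(cohort[[.x]], cohort[[criterion]], alpha = alpha))
  table <- ranked %>%
    dplyr::mutate(
      pearson_r = purrr::map_dbl(pears, "r"),
      pearson_p = purrr::map_dbl(pears, "p_value"),
      significant = purrr::map_lgl(pears, "significant")
    ) %>%
    dplyr::arrange(.data$rank) %>%
    dplyr::select("rank", "indicator", "pearson_r", "pearson_p",
                  "significant", "grade", "class")
  structure(
    list(table = table, fit = fit, criterion = criterion, p = p,
         strong_cut = strong_cut, weak_cut = weak_cut, n = nrow(cohort)),
    class = "gra_result"
  )
}

#' Table-style grey relational report
#'
#' Convenience wrapper around [run_gra()] returning just the ranked report
#' tibble (one row per indicator, ordered by descending grade).
#'
#' @inheritParams run_gra
#' @return A tibble with `rank`, `indicator`, `pearson_r`, `pearson_p`,
#'   `significant`, `grade`, `class`.
#' @export
run_gra_table <- function(cohort, criterion = attr(cohort, "criterion"),
                          p = 0.5, strong_cut = 0.9, weak_cut = 0.8,
                          alpha = 0.05) {
  run_gra(cohort, criterion = criterion, p = p, strong_cut = strong_cut,
          weak_cut = weak_cut, alpha = alpha)$table
}

#' @export
print.gra_result <- function(x, ...) {
  cat("<gra_result> ", nrow(x$table), " indicators vs criterion '",
      x$criterion, "' (n = ", x$n, ", p = ", x$p, ")\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @describeIn run_gra Tidy the ranked report table.
#' @param x A `gra_result`.
#' @param ... Unused.
#' @method tidy gra_result
#' @export
tidy.gra_result <- function(x, ...) {
  x$table
}

#' @describeIn run_gra One-row summary: n, p, global extrema, class counts.
#' @method glance gra_result
#' @export
glance.gra_result <- function(x, ...) {
  cls <- table(x$table$class)
  tibble::tibble(
    n = x$n,
    n_indicators = nrow(x$table),
    p = x$p,
    delta_min = x$fit$delta_min,
    delta_max = x$fit$delta_max,
    n_strong = as.integer(cls[["strong"]]),
    n_moderate = as.integer(cls[["moderate"]]),
    n_weak = as.integer(cls[["weak"]])
  )
}

#' Plot grey relational grades
#'
#' Horizontal bar chart of grades in rank order, colored by strength class,
#' with the classification cuts drawn as reference lines.
#'
#' @param object A `gra_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gra_result
#' @export
autoplot.gra_result <- function(object, ...) {
  df <- object$table
  df$indicator <- factor(df$indicator, levels = rev(df$indicator))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$indicator,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(object$weak_cut, object$strong_cut),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(strong = "#1b7837",
                                          moderate = "#fdb863",
                                          weak = "#b2182b")) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "grey relational grade", y = NULL, fill = "class",
                  title = paste0("Grey relational grades vs ", object$criterion)) +
    ggplot2::theme_minimal()
}
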