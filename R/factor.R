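#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares observed correlations with anti-image partial correlations. With
#' `q_ij` the partial correlation between variables i and j given all others
#' (obtained from the scaled inverse of the correlation matrix), the overall
#' measure is
#' \deqn{KMO = \sum_{i \ne j} r_{ij}^2 \Big/ \left(\sum_{i \ne j} r_{ij}^2 +
#'   \sum_{i \ne j} q_{ij}^2\right).}
#' Values above 0.5 are conventionally taken to license factor analysis. For
#' any 2-variable matrix with nonzero correlation the partial correlation
#' equals the simple correlation, so KMO is identically 0.5.
#'
#' @param R A symmetric correlation matrix with unit diagonal, invertible.
#' @return A list with `kmo` (overall) and `msa` (per-variable measures,
#'   named when `R` has dimnames).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  check_correlation_matrix(R)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; KMO diagnostics unavailable",
         call. = FALSE)
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)   # anti-image partial correlations (off-diagonal)
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  denom_tot <- sum(r2) + sum(q2)
  if (denom_tot == 0) {
    stop("all off-diagonal correlations are zero; KMO is undefined (0/0)",
         call. = FALSE)
  }
  msa_denom <- rowSums(r2) + rowSums(q2)
  msa <- ifelse(msa_denom == 0, NA_real_, rowSums(r2) / msa_denom)
  names(msa) <- rownames(R)
  list(kmo = sum(r2) / denom_tot, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no correlations to
#' factor). The statistic is
#' \deqn{\chi^2 = -\left(n - 1 - \frac{2p + 5}{6}\right)\,\log\det R}
#' on `p (p - 1) / 2` degrees of freedom, with `p` the number of variables
#' and `n` the sample size behind `R`.
#'
#' @param R A positive-definite correlation matrix.
#' @param n Sample size; must exceed the number of variables.
#' @return A list with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  check_correlation_matrix(R)
  p <- ncol(R)
  if (n <= p) stop("sample size must exceed the number of variables", call. = FALSE)
  detR <- det(R)
  if (detR <= 0) {
    stop("correlation matrix has non-positive determinant", call. = FALSE)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Extract principal components with eigenvalue above 1
#'
#' Principal-component extraction on the correlation matrix: eigenvalues in
#' descending order; loading column j is eigenvector j scaled by the square
#' root of its eigenvalue; columns are sign-fixed so each column's
#' largest-magnitude entry is positive. Only components whose eigenvalue is
#' strictly greater than `eigen_cut` (Kaiser criterion at the default 1) are
#' retained.
#'
#' @param R A symmetric positive-semidefinite correlation matrix.
#' @param eigen_cut Retention cut on the eigenvalue, strict. Default 1.
#' @return A list with `eigenvalues` (all, descending), `loadings`
#'   (variables x retained components) and `n_retained`.
#' @export
extract_components <- function(R, eigen_cut = 1) {
  R <- as.matrix(R)
  check_correlation_matrix(R)
  e <- eigen(R, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)   # stable; ties keep eigen() order
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  keep <- which(vals > eigen_cut)
  L <- vecs[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]), length(keep))
  L <- fix_loading_signs(L)
  rownames(L) <- rownames(R)
  if (ncol(L) > 0) colnames(L) <- paste0("PC", seq_along(keep))
  list(eigenvalues = vals, loadings = L, n_retained = length(keep))
}

fix_loading_signs <- function(L) {
  if (ncol(L) == 0) return(L)
  s <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  sweep(L, 2L, s, `*`)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (the sum over
#' components of the variance of squared loadings, after optional Kaiser row
#' normalization), driving the solution toward simple structure. Row
#' communalities are preserved exactly. A single-column loading matrix is
#' returned unchanged with an identity rotation.
#'
#' @param loadings Variables-by-components loading matrix.
#' @param kaiser_normalize Normalize rows to unit communality before
#'   rotating (the SPSS default). Default `TRUE`.
#' @param tol Convergence tolerance on the relative criterion increase.
#' @return A list with `loadings` (rotated, sign-fixed) and `rotmat`
#'   (orthogonal rotation matrix).
#' @export
rotate_varimax <- function(loadings, kaiser_normalize = TRUE, tol = 1e-9) {
  L <- as.matrix(loadings)
  if (ncol(L) < 2) {
    return(list(loadings = L, rotmat = diag(ncol(L))))
  }
  v <- stats::varimax(L, normalize = kaiser_normalize, eps = tol)
  rot <- unclass(v$loadings)
  attr(rot, "dimnames") <- dimnames(L)
  s <- apply(rot, 2L, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  list(loadings = sweep(rot, 2L, s, `*`),
       rotmat = sweep(v$rotmat, 2L, s, `*`))
}

#' Varimax criterion value of a loading matrix
#'
#' The quantity maximized by [rotate_varimax()]: the sum over components of
#' the (population) variance of the squared loadings, computed after
#' optional Kaiser row normalization. Exposed for oracle-style comparisons.
#'
#' @inheritParams rotate_varimax
#' @return A single number.
#' @export
varimax_criterion <- function(loadings, kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  L2 <- L^2
  sum(apply(L2, 2L, function(col) mean(col^2) - mean(col)^2))
}

#' Select one representative indicator per rotated component
#'
#' Every indicator is first assigned to the component on which its absolute
#' rotated loading is largest, so each indicator belongs to exactly one
#' component. Within a component, the representative is the assigned
#' indicator with the largest absolute loading, provided that loading
#' strictly exceeds `loading_threshold`; otherwise the component is flagged
#' as unrepresented. Remaining assigned indicators are reported as the
#' component's "other indicators".
#'
#' @param loadings Rotated loading matrix (variables x components).
#' @param indicator_names Names for the rows; defaults to rownames.
#' @param loading_threshold Minimum absolute loading for a representative.
#'   Default 0.4.
#' @return A tibble with one row per component: `component`,
#'   `representative` (NA when unrepresented), `loading`, `others`
#'   (list-column of character vectors), `flagged`.
#' @export
select_representatives <- function(loadings, indicator_names = rownames(loadings),
                                   loading_threshold = 0.4) {
  L <- as.matrix(loadings)
  if (ncol(L) == 0 || nrow(L) == 0) {
    stop("no components to select representatives from", call. = FALSE)
  }
  if (is.null(indicator_names)) {
    indicator_names <- paste0("v", seq_len(nrow(L)))
  }
  assigned <- apply(abs(L), 1L, which.max)
  purrr::map_dfr(seq_len(ncol(L)), function(j) {
    members <- which(assigned == j)
    if (length(members) == 0) {
      return(tibble::tibble(component = j, representative = NA_character_,
                            loading = NA_real_, others = list(character(0)),
                            flagged = TRUE))
    }
    best <- members[which.max(abs(L[members, j]))]
    best_load <- L[best, j]
    ok <- abs(best_load) > loading_threshold
    tibble::tibble(
      component = j,
      representative = if (ok) indicator_names[best] else NA_character_,
      loading = best_load,
      others = list(indicator_names[setdiff(members, if (ok) best else integer(0))]),
      flagged = !ok
    )
  })
}

#' Reduce one indicator block to its representative indicators
#'
#' The per-block reduction pipeline: correlation matrix, KMO and Bartlett
#' diagnostics, principal-component extraction under the Kaiser criterion,
#' varimax rotation, and representative selection. When the diagnostics fail
#' (KMO at or below `kmo_min`, or Bartlett p at or above `bartlett_alpha`)
#' the block is not factored: the result carries the diagnostics and a
#' `diagnostics_passed = FALSE` flag instead of silently continuing.
#'
#' @param cohort A cohort data frame (athletes x variables).
#' @param columns Character vector naming the block's indicator columns.
#' @param block_name Label for the block.
#' @param kmo_min,bartlett_alpha Diagnostic gates (defaults 0.5 and 0.05).
#' @param eigen_cut,loading_threshold Passed to [extract_components()] and
#'   [select_representatives()].
#' @param kaiser_normalize Passed to [rotate_varimax()].
#' @return An object of class `factor_solution`.
#' @export
#' @examples
#' set.seed(1)
#' f <- rnorm(200)
#' block <- tibble::tibble(a = f + rnorm(200, sd = 0.6),
#'                         b = f + rnorm(200, sd = 0.6),
#'                         c = f + rnorm(200, sd = 0.6))
#' reduce_block(block, c("a", "b", "c"), "toy")
reduce_block <- function(cohort, columns, block_name = "block",
                         kmo_min = 0.5, bartlett_alpha = 0.05,
                         eigen_cut = 1, loading_threshold = 0.4,
                         kaiser_normalize = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("block '", block_name, "' references unknown column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(columns) < 2) {
    stop("a block needs at least 2 indicators to factor", call. = FALSE)
  }
  X <- as.matrix(cohort[columns])
  n <- nrow(X)
  R <- stats::cor(X)
  out <- list(block_name = block_name, indicator_names = columns,
              correlation_matrix = R, n = n,
              kmo_min = kmo_min, bartlett_alpha = bartlett_alpha,
              eigen_cut = eigen_cut, loading_threshold = loading_threshold)

  diag_err <- NULL
  km <- tryCatch(kmo(R), error = function(e) {
    diag_err <<- conditionMessage(e)
    NULL
  })
  bt <- tryCatch(bartlett_sphericity(R, n), error = function(e) {
    diag_err <<- conditionMessage(e)
    NULL
  })
  out$kmo <- if (is.null(km)) NA_real_ else km$kmo
  out$msa <- if (is.null(km)) NULL else km$msa
  out$bartlett <- bt
  passed <- !is.null(km) && !is.null(bt) &&
    km$kmo > kmo_min && bt$p_value < bartlett_alpha
  out$diagnostics_passed <- passed
  out$diagnostics_note <- if (!is.null(diag_err)) diag_err else if (!passed) {
    sprintf("KMO = %.3f (gate > %.2f), Bartlett p = %.3g (gate < %.2f)",
            out$kmo, kmo_min,
            if (is.null(bt)) NA_real_ else bt$p_value, bartlett_alpha)
  } else NA_character_

  if (passed) {
    ex <- extract_components(R, eigen_cut = eigen_cut)
    out$eigenvalues <- ex$eigenvalues
    out$n_retained <- ex$n_retained
    out$unrotated_loadings <- ex$loadings
    rot <- rotate_varimax(ex$loadings, kaiser_normalize = kaiser_normalize)
    out$rotated_loadings <- rot$loadings
    out$rotmat <- rot$rotmat
    p <- length(columns)
    out$contributions <- 100 * colSums(rot$loadings^2) / p
    out$cumulative <- sum(out$contributions)
    out$representatives <- if (ex$n_retained > 0) {
      select_representatives(rot$loadings, columns,
                             loading_threshold = loading_threshold)
    } else {
      tibble::tibble(component = integer(0), representative = character(0),
                     loading = numeric(0), others = list(), flagged = logical(0))
    }
  }
  structure(out, class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution> block '", x$block_name, "': ",
      length(x$indicator_names), " indicators, n = ", x$n, "\n", sep = "")
  cat(sprintf("  KMO = %.3f | Bartlett chi2 = %s (df %s, p = %s)\n",
              x$kmo,
              if (is.null(x$bartlett)) "NA" else format(x$bartlett$chi2, digits = 4),
              if (is.null(x$bartlett)) "NA" else x$bartlett$df,
              if (is.null(x$bartlett)) "NA" else format.pval(x$bartlett$p_value)))
  if (!isTRUE(x$diagnostics_passed)) {
    cat("  diagnostics FAILED: ", x$diagnostics_note, "\n", sep = "")
    return(invisible(x))
  }
  cat("  components retained: ", x$n_retained,
      sprintf(" (cumulative %.2f%%)\n", x$cumulative), sep = "")
  print(x$representatives, ...)
  invisible(x)
}

#' @describeIn reduce_block Tidy the rotated loadings into a long tibble
#'   (`indicator`, `component`, `loading`, `communality`).
#' @param x A `factor_solution`.
#' @param ... Unused.
#' @method tidy factor_solution
#' @export
tidy.factor_solution <- function(x, ...) {
  if (!isTRUE(x$diagnostics_passed) || x$n_retained == 0) {
    return(tibble::tibble(indicator = character(0), component = integer(0),
                          loading = numeric(0), communality = numeric(0)))
  }
  L <- x$rotated_loadings
  comm <- rowSums(L^2)
  tibble::tibble(
    indicator = rep(rownames(L), times = ncol(L)),
    component = rep(seq_len(ncol(L)), each = nrow(L)),
    loading = as.vector(L),
    communality = rep(comm, times = ncol(L))
  )
}

#' @describeIn reduce_block One-row summary: diagnostics, components
#'   retained, cumulative contribution.
#' @method glance factor_solution
#' @export
glance.factor_solution <- function(x, ...) {
  tibble::tibble(
    block = x$block_name,
    n = x$n,
    n_indicators = length(x$indicator_names),
    kmo = x$kmo,
    bartlett_chi2 = if (is.null(x$bartlett)) NA_real_ else x$bartlett$chi2,
    bartlett_df = if (is.null(x$bartlett)) NA_real_ else x$bartlett$df,
    bartlett_p = if (is.null(x$bartlett)) NA_real_ else x$bartlett$p_value,
    diagnostics_passed = isTRUE(x$diagnostics_passed),
    n_retained = if (is.null(x$n_retained)) NA_integer_ else x$n_retained,
    cumulative_pct = if (is.null(x$cumulative)) NA_real_ else x$cumulative
  )
}

#' Plot a factor solution's rotated loadings
#'
#' Heatmap-style tile plot of the rotated loading matrix with representatives
#' marked.
#'
#' @param object A `factor_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot factor_solution
#' @export
autoplot.factor_solution <- function(object, ...) {
  df <- tidy.factor_solution(object)
  if (nrow(df) == 0) {
    stop("nothing to plot: diagnostics failed or no components retained",
         call. = FALSE)
  }
  reps <- object$representatives
  df$is_rep <- paste(df$indicator, df$component) %in%
    paste(reps$representative, reps$component)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component),
                                   y = .data$indicator,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading),
                                    fontface = ifelse(.data$is_rep, "bold", "plain")),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "rotated component", y = NULL, fill = "loading",
                  title = paste0("Varimax loadings: ", object$block_name)) +
    ggplot2::theme_minimal()
}

check_correlation_matrix <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("expected a square matrix", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("matrix does not have a unit diagonal", call. = FALSE)
  }
  invisible(TRUE)
}
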