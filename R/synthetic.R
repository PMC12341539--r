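#' Complete a target correlation matrix from criterion correlations alone
#'
#' The calibration tables print only each indicator's correlation with the
#' criterion; the indicator-indicator block is unknown. This builds the full
#' `(m + 1) x (m + 1)` correlation matrix (criterion first) under one of two
#' completion strategies and repairs it to positive definiteness if needed.
#'
#' `rank_one` fills entry `(i, j)` for indicators `i != j` with `r_i * r_j`,
#' the correlation structure implied by a single latent factor that the
#' criterion measures without error. This is always a valid correlation
#' matrix when all `|r| < 1`. `zero` leaves the indicator block diagonal,
#' which can be indefinite when the criterion correlations are strong; the
#' repair step (eigenvalues clipped at 1e-6, reconstruction, rescaling to
#' unit diagonal) then perturbs the matrix minimally.
#'
#' @param criterion_corrs Numeric vector of indicator-criterion correlations,
#'   all strictly inside (-1, 1).
#' @param fill_strategy `"rank_one"` (default) or `"zero"`.
#' @param names Optional indicator names; the criterion is labelled by
#'   `criterion_name`.
#' @param criterion_name Label for the first row/column.
#' @return A symmetric positive-definite correlation matrix with unit
#'   diagonal; row/column 1 is the criterion.
#' @export
#' @examples
#' build_target_correlation(c(0.9, 0.9))
build_target_correlation <- function(criterion_corrs,
                                     fill_strategy = c("rank_one", "zero"),
                                     names = NULL,
                                     criterion_name = "criterion") {
  fill_strategy <- match.arg(fill_strategy)
  r <- as.numeric(criterion_corrs)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("all criterion correlations must be finite with |r| < 1", call. = FALSE)
  }
  m <- length(r)
  R <- matrix(0, m + 1L, m + 1L)
  R[1L, -1L] <- r
  R[-1L, 1L] <- r
  if (fill_strategy == "rank_one" && m > 1L) {
    block <- tcrossprod(r)
    R[-1L, -1L] <- block
  }
  diag(R) <- 1
  R <- nearest_pd_correlation(R)
  labs <- c(criterion_name,
            if (is.null(names)) paste0("x", seq_len(m)) else as.character(names))
  dimnames(R) <- list(labs, labs)
  R
}

# Eigenvalue-clipping repair: clip the spectrum at `floor`, reconstruct, and
# rescale to unit diagonal. A no-op (up to symmetrization) for matrices that
# are already positive definite.
nearest_pd_correlation <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor) {
    return(R)
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Generate a cohort whose sample moments match the specification exactly
#'
#' Constructs an `n`-athlete cohort whose sample means, sample SDs (divisor
#' `n - 1`) and sample Pearson correlations between each indicator and the
#' criterion equal the moment specification to machine precision. The
#' construction draws an `n x m` standard-normal matrix, centers its columns,
#' whitens it against its own empirical covariance (so the draw has exactly
#' zero mean and identity sample covariance), re-imposes the completed target
#' correlation through its Cholesky factor, and finally rescales and shifts
#' to the target SDs and means.
#'
#' Exact whitening requires the centered draw to have full column rank, hence
#' the `n >= m + 2` requirement, with `m` counting the criterion. A cohort at
#' the original study scale (`n = 16` athletes, 17 variables) cannot support
#' exact matching; use [generate_sampled()] there.
#'
#' @param spec A [moment_spec()].
#' @param n Number of athletes; must satisfy `n >= m + 2` where `m` is the
#'   number of indicators plus one.
#' @param seed Integer random seed (mandatory; generation is a pure function
#'   of `(spec, n, seed)`).
#' @param fill_strategy Passed to [build_target_correlation()].
#' @return A tibble with `n` rows: the criterion column followed by one
#'   column per indicator, with a `criterion` attribute naming it.
#' @export
#' @examples
#' cohort <- generate_exact(trampoline_moments(), n = 40, seed = 1)
#' mean(cohort$pre_jump_height) # 3.13
#' cor(cohort$standing_long_jump, cohort$pre_jump_height) # 0.871
generate_exact <- function(spec, n, seed, fill_strategy = "rank_one") {
  stopifnot(inherits(spec, "moment_spec"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  m <- nrow(spec$indicators) + 1L
  if (n < m + 2L) {
    stop("exact moment matching needs n >= ", m + 2L,
         " (number of variables + 2); got n = ", n,
         ". Use generate_sampled() for smaller cohorts.", call. = FALSE)
  }
  R <- build_target_correlation(spec$indicators$r, fill_strategy = fill_strategy,
                                names = spec$indicators$indicator,
                                criterion_name = spec$criterion$name)
  sds <- c(spec$criterion$sd, spec$indicators$sd)
  mus <- c(spec$criterion$mean, spec$indicators$mean)

  X <- withr::with_seed(seed, {
    Y <- NULL
    for (attempt in 1:5) {
      Z <- matrix(stats::rnorm(n * m), n, m)
      Z <- scale(Z, center = TRUE, scale = FALSE)
      S <- crossprod(Z) / (n - 1)
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(ch)) {
        Y <- Z %*% backsolve(ch, diag(m))
        break
      }
    }
    if (is.null(Y)) {
      stop("centered random draw was rank-deficient after 5 attempts", call. = FALSE)
    }
    W <- Y %*% chol(R)
    W <- sweep(W, 2L, sds, `*`)
    sweep(W, 2L, mus, `+`)
  })
  colnames(X) <- colnames(R)
  out <- tibble::as_tibble(as.data.frame(X))
  attr(out, "criterion") <- spec$criterion$name
  out
}

#' Sample a cohort from the moment-matched multivariate normal
#'
#' Rows are independent draws from the multivariate normal whose mean vector
#' and covariance are implied by the moment specification and the completed
#' target correlation. Sample moments match the specification only in
#' expectation, converging as `n` grows; this is the mode for cohorts at the
#' original study scale (`n = 16`), where exact matching is rank-infeasible.
#'
#' @inheritParams generate_exact
#' @param n Number of athletes, at least 3.
#' @return A tibble as in [generate_exact()].
#' @export
#' @examples
#' generate_sampled(trampoline_moments(), n = 16, seed = 7)
generate_sampled <- function(spec, n, seed, fill_strategy = "rank_one") {
  stopifnot(inherits(spec, "moment_spec"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n < 3) stop("a cohort needs at least 3 athletes", call. = FALSE)
  R <- build_target_correlation(spec$indicators$r, fill_strategy = fill_strategy,
                                names = spec$indicators$indicator,
                                criterion_name = spec$criterion$name)
  sds <- c(spec$criterion$sd, spec$indicators$sd)
  mus <- c(spec$criterion$mean, spec$indicators$mean)
  Sigma <- R * tcrossprod(sds)
  X <- withr::with_seed(seed, MASS::mvrnorm(n, mu = mus, Sigma = Sigma))
  colnames(X) <- colnames(R)
  out <- tibble::as_tibble(as.data.frame(X))
  attr(out, "criterion") <- spec$criterion$name
  out
}

#' Validate a cohort table
#'
#' Checks the structural contract every downstream stage relies on: at least
#' 3 complete numeric rows, unique column names, and a criterion column that
#' occurs exactly once.
#'
#' @param cohort A data frame of athletes by variables.
#' @param criterion Name of the criterion column; defaults to the cohort's
#'   `criterion` attribute when present.
#' @return The cohort as a tibble (invisibly validated), with the
#'   `criterion` attribute set.
#' @export
validate_cohort <- function(cohort, criterion = attr(cohort, "criterion")) {
  cohort <- tibble::as_tibble(cohort)
  if (is.null(criterion)) {
    stop("no criterion column designated", call. = FALSE)
  }
  if (anyDuplicated(names(cohort))) {
    dup <- names(cohort)[duplicated(names(cohort))]
    stop("duplicate column name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (sum(names(cohort) == criterion) != 1L) {
    stop("criterion column '", criterion, "' must appear exactly once", call. = FALSE)
  }
  if (nrow(cohort) < 3) {
    stop("a cohort needs at least 3 athletes; got ", nrow(cohort), call. = FALSE)
  }
  not_num <- names(cohort)[!vapply(cohort, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric column(s): ", paste(not_num, collapse = ", "), call. = FALSE)
  }
  na_cells <- which(is.na(as.matrix(cohort)), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    stop("missing value at row ", na_cells[1, 1], ", column '",
         names(cohort)[na_cells[1, 2]], "'", call. = FALSE)
  }
  attr(cohort, "criterion") <- criterion
  cohort
}
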