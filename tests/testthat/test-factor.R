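equicorrelation <- function(p, r) {
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}

test_that("KMO is exactly 0.5 for any 2-variable matrix with nonzero correlation", {
  for (r in c(0.1, -0.45, 0.8, -0.99)) {
    expect_equal(kmo(equicorrelation(2, r))$kmo, 0.5)
  }
})

test_that("KMO via the inverse-matrix formula matches partial-correlation regressions", {
  expect_equal(kmo(equicorrelation(3, 0.5))$kmo,
               kmo_regression_oracle(equicorrelation(3, 0.5)),
               tolerance = 1e-10)
  withr::with_seed(21, {
    for (p in 3:5) {
      R <- random_correlation(p)
      expect_equal(kmo(R)$kmo, kmo_regression_oracle(R), tolerance = 1e-8)
    }
  })
})

test_that("degenerate KMO inputs raise informative errors", {
  expect_error(kmo(diag(3)), "undefined")
  singular <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(kmo(singular), "singular")
})

test_that("Bartlett's sphericity statistic matches its closed form", {
  id <- bartlett_sphericity(diag(4), n = 30)
  expect_equal(id$chi2, 0)
  expect_equal(id$p_value, 1)

  # 2 variables, r = 0.5, n = 20: multiplier 19 - 9/6 = 17.5, det = 0.75
  b <- bartlett_sphericity(equicorrelation(2, 0.5), n = 20)
  expect_equal(b$chi2, -17.5 * log(0.75))
  expect_equal(b$df, 1)
  expect_equal(b$p_value, pchisq(-17.5 * log(0.75), 1, lower.tail = FALSE))

  expect_error(bartlett_sphericity(equicorrelation(3, 0.5), n = 3), "sample size")
})

test_that("component extraction applies the strict Kaiser criterion", {
  expect_equal(extract_components(diag(5))$n_retained, 0)

  ex <- extract_components(equicorrelation(3, 0.5))
  expect_equal(ex$eigenvalues, c(2, 0.5, 0.5))   # 1 + (p-1)r and 1 - r
  expect_equal(ex$n_retained, 1)
  expect_equal(unname(ex$loadings[, 1]), rep(sqrt(2 / 3), 3))
})

test_that("eigenvalue sum equals the variable count on random correlation matrices", {
  withr::with_seed(33, {
    for (p in c(3, 5, 8)) {
      R <- random_correlation(p)
      expect_equal(sum(extract_components(R)$eigenvalues), p, tolerance = 1e-8)
    }
  })
})

test_that("varimax leaves perfect simple structure unchanged", {
  L <- rbind(c(1, 0), c(0, 1))
  rot <- rotate_varimax(L, kaiser_normalize = FALSE)
  expect_equal(abs(rot$loadings), L, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("varimax attains the planar grid-search optimum on 2-component problems", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      L <- matrix(rnorm(12), 6, 2)
      rot <- rotate_varimax(L, kaiser_normalize = FALSE, tol = 1e-12)
      achieved <- varimax_criterion(rot$loadings, kaiser_normalize = FALSE)
      best <- varimax_grid_oracle(L, kaiser_normalize = FALSE, step = 0.001)
      expect_equal(achieved, best, tolerance = 1e-6)
      expect_gte(achieved + 1e-12,
                 varimax_criterion(L, kaiser_normalize = FALSE))
    }
  })
})

test_that("varimax rotation is orthogonal and preserves row communalities", {
  withr::with_seed(6, L <- matrix(rnorm(30), 10, 3))
  for (kaiser in c(TRUE, FALSE)) {
    rot <- rotate_varimax(L, kaiser_normalize = kaiser)
    expect_equal(crossprod(rot$rotmat), diag(3), tolerance = 1e-10)
    expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-8)
    expect_equal(unname(L %*% rot$rotmat), unname(rot$loadings), tolerance = 1e-8)
  }
})

test_that("representatives follow the max-|loading| assignment rule", {
  L <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.6))
  reps <- select_representatives(L, c("i1", "i2", "i3"))
  expect_equal(reps$representative, c("i1", "i2"))
  expect_equal(reps$loading, c(0.9, 0.8))
  expect_equal(reps$others[[1]], character(0))
  expect_equal(reps$others[[2]], "i3")       # assigned to comp 2, not chosen
  expect_false(any(reps$flagged))
  # every indicator in exactly one component's assigned list
  all_assigned <- c(unlist(reps$others), na.omit(reps$representative))
  expect_setequal(all_assigned, c("i1", "i2", "i3"))
})

test_that("components whose best loading is below threshold get no representative", {
  reps <- select_representatives(matrix(0.3, 1, 1), "only")
  expect_true(is.na(reps$representative))
  expect_true(reps$flagged)
  expect_error(select_representatives(matrix(numeric(0), 0, 0)), "no components")
})

test_that("a strong one-factor block passes diagnostics and retains one component", {
  withr::with_seed(8, {
    f <- rnorm(200)
    block <- tibble::tibble(
      a = f + rnorm(200, sd = 0.8),
      b = f + rnorm(200, sd = 0.8),
      c = f + rnorm(200, sd = 0.8),
      d = f + rnorm(200, sd = 0.8)
    )
  })
  sol <- reduce_block(block, c("a", "b", "c", "d"), "one_factor")
  expect_true(sol$diagnostics_passed)
  expect_gt(sol$kmo, 0.5)
  expect_lt(sol$bartlett$p_value, 0.05)
  expect_equal(sol$n_retained, 1)
  expect_equal(nrow(sol$representatives), 1)
  expect_false(sol$representatives$flagged)
})

test_that("a block of independent indicators yields a diagnostic-failure result", {
  withr::with_seed(12, {
    block <- tibble::as_tibble(matrix(rnorm(200 * 4), 200, 4,
                                      dimnames = list(NULL, letters[1:4])))
  })
  sol <- reduce_block(block, letters[1:4], "null_block")
  expect_false(sol$diagnostics_passed)
  expect_null(sol$rotated_loadings)
  expect_match(sol$diagnostics_note, "KMO|Bartlett")
  expect_false(glance(sol)$diagnostics_passed)
})

test_that("k orthogonal latent factors are recovered with their top indicators", {
  withr::with_seed(77, {
    n <- 500
    factors <- matrix(rnorm(n * 3), n, 3)
    loading_sets <- list(c(0.9, 0.8, 0.75), c(0.85, 0.8, 0.7), c(0.9, 0.75, 0.7))
    cols <- list()
    for (j in 1:3) {
      for (l in seq_along(loading_sets[[j]])) {
        lam <- loading_sets[[j]][l]
        cols[[paste0("f", j, "_", l)]] <-
          lam * factors[, j] + sqrt(1 - lam^2) * rnorm(n)
      }
    }
    block <- tibble::as_tibble(cols)
  })
  sol <- reduce_block(block, names(block), "three_factor")
  expect_true(sol$diagnostics_passed)
  expect_equal(sol$n_retained, 3)
  # each latent factor's highest-loading indicator is its representative
  expect_setequal(sol$representatives$representative, c("f1_1", "f2_1", "f3_1"))
})

test_that("tidy communalities match the unrotated solution", {
  withr::with_seed(14, {
    f1 <- rnorm(300); f2 <- rnorm(300)
    block <- tibble::tibble(
      a = f1 + rnorm(300, sd = 0.5), b = f1 + rnorm(300, sd = 0.5),
      c = f1 + rnorm(300, sd = 0.5), d = f2 + rnorm(300, sd = 0.5),
      e = f2 + rnorm(300, sd = 0.5), f = f2 + rnorm(300, sd = 0.5)
    )
  })
  sol <- reduce_block(block, letters[1:6], "two_factor")
  expect_equal(sol$n_retained, 2)
  td <- tidy(sol)
  expect_equal(nrow(td), 12)
  comm_unrot <- rowSums(sol$unrotated_loadings^2)
  comm_rot <- rowSums(sol$rotated_loadings^2)
  expect_equal(unname(comm_rot), unname(comm_unrot), tolerance = 1e-8)
  expect_equal(sum(sol$contributions),
               100 * sum(comm_unrot) / 6, tolerance = 1e-8)
})
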