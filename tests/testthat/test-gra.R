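test_that("mean normalization divides by the mean and rejects non-positive means", {
  expect_equal(mean_normalize(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(mean_normalize(c(1, 2, 3)), c(0.5, 1, 1.5))
  x <- c(2, 7, 3, 8)
  expect_equal(mean_normalize(10 * x), mean_normalize(x))  # scale cancels
  expect_error(mean_normalize(c(-1, 1)), "strictly positive")
  expect_error(mean_normalize(c(-2, -3)), "strictly positive")
})

test_that("Deng coefficients match hand-computed worked examples", {
  # identical sequences: degenerate delta_max = 0, coefficients all 1
  fit0 <- gra_coefficients(c(1, 2, 3), cbind(copy = c(2, 4, 6)))
  expect_equal(unname(fit0$coefficients[1, ]), c(1, 1, 1))
  expect_equal(unname(fit0$grades), 1)

  # standard (1,2,3) vs flat (2,2,2): normalized deltas (0.5, 0, 0.5)
  fit <- gra_coefficients(c(1, 2, 3), cbind(flat = c(2, 2, 2)), p = 0.5)
  expect_equal(unname(fit$deltas[1, ]), c(0.5, 0, 0.5))
  expect_equal(fit$delta_min, 0)
  expect_equal(fit$delta_max, 0.5)
  expect_equal(unname(fit$coefficients[1, ]), c(1 / 3, 1, 1 / 3))
  expect_equal(unname(fit$grades), 5 / 9)
  expect_equal(unname(gra_grade(fit)), 5 / 9)

  # global extrema couple sequences: x1 = x0 forces delta_min = 0, and the
  # flat x2 has constant normalized delta 1/3 = delta_max
  fit2 <- gra_coefficients(c(1, 2), cbind(same = c(1, 2), flat = c(3, 3)), p = 0.5)
  expect_equal(fit2$delta_max, 1 / 3)
  expect_equal(unname(fit2$coefficients["flat", ]), c(1 / 3, 1 / 3))
  expect_equal(unname(fit2$grades["same"]), 1)
})

test_that("vectorized GRA equals the brute-force oracle on small random cohorts", {
  withr::with_seed(19, {
    for (rep in 1:12) {
      n <- sample(2:5, 1)
      m <- sample(1:5, 1)
      standard <- runif(n, 1, 10)
      inspected <- matrix(runif(n * m, 1, 10), n, m)
      p <- sample(c(0.1, 0.5, 1), 1)
      fit <- gra_coefficients(standard, inspected, p = p)
      oracle <- brute_force_gra(standard, inspected, p = p)
      expect_equal(unname(fit$coefficients), oracle$coefficients, tolerance = 1e-12)
      expect_equal(unname(fit$grades), oracle$grades, tolerance = 1e-12)
      expect_equal(fit$delta_min, oracle$d_min)
      expect_equal(fit$delta_max, oracle$d_max)
    }
  })
})

test_that("coefficients and grades respect their theoretical bounds", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      n <- sample(3:10, 1)
      m <- sample(2:6, 1)
      fit <- gra_coefficients(runif(n, 1, 5), matrix(runif(n * m, 1, 5), n, m))
      lower <- (fit$delta_min + 0.5 * fit$delta_max) /
        (fit$delta_max + 0.5 * fit$delta_max)
      expect_true(all(fit$coefficients >= lower - 1e-12))
      expect_true(all(fit$coefficients <= 1))
      expect_true(all(fit$grades > 0 & fit$grades <= 1))
      expect_true(all(fit$deltas >= fit$delta_min & fit$deltas <= fit$delta_max))
    }
  })
})

test_that("self-inspection always grades exactly 1 and scale never matters", {
  withr::with_seed(29, {
    x0 <- runif(8, 1, 4)
    others <- matrix(runif(16, 1, 4), 8, 2)
    fit <- gra_coefficients(x0, cbind(self = x0, others))
    expect_equal(unname(fit$grades["self"]), 1)

    scaled <- cbind(self = 3.7 * x0, others)
    scaled[, 2] <- 0.01 * scaled[, 2]
    fit_scaled <- gra_coefficients(x0, scaled)
    expect_equal(unname(fit_scaled$grades), unname(fit$grades), tolerance = 1e-12)
  })
})

test_that("larger distinguishing coefficients compress coefficients toward 1", {
  withr::with_seed(31, {
    standard <- runif(6, 1, 5)
    inspected <- matrix(runif(12, 1, 5), 6, 2)
  })
  ps <- c(0.1, 0.3, 0.5, 0.8, 1)
  mins <- vapply(ps, function(p) {
    min(gra_coefficients(standard, inspected, p = p)$coefficients)
  }, numeric(1))
  expect_true(all(diff(mins) > 0))
})

test_that("classification applies the published cuts with closed boundaries", {
  rc <- rank_and_classify(c(a = 0.95, b = 0.9, c = 0.8, d = 0.79))
  expect_equal(as.character(rc$class), c("strong", "moderate", "moderate", "weak"))
  expect_equal(rc$rank, 1:4)

  all_strong <- rank_and_classify(rep(1, 4))
  expect_true(all(all_strong$class == "strong"))
  expect_equal(all_strong$rank, 1:4)     # ties keep input order
})

test_that("the published grade vector classifies 10 strong, 3 moderate, 3 weak", {
  tab <- trampoline_grades()
  rc <- rank_and_classify(setNames(tab$grade, tab$indicator))
  counts <- table(rc$class)
  expect_equal(unname(counts[["strong"]]), 10)
  expect_equal(unname(counts[["moderate"]]), 3)
  expect_equal(unname(counts[["weak"]]), 3)
  expect_equal(rc$indicator[rc$rank == 1], "standing_long_jump")
})

test_that("pearson returns textbook values and a t-based p-value", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)
  p <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(p$r, 1.5 / sqrt(7 / 3), tolerance = 1e-12)  # ~0.982
  # independent t-transform check
  tstat <- p$r * sqrt((3 - 2) / (1 - p$r^2))
  expect_equal(p$p_value, 2 * pt(-abs(tstat), df = 1), tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson(1:2, 1:2), "length >= 3")
})

test_that("an indicator proportional to the criterion tops the ranking with grade 1", {
  withr::with_seed(41, {
    crit <- runif(10, 2, 4)
    cohort <- tibble::tibble(
      y = crit,
      proportional = 2.5 * crit,
      noise1 = runif(10, 2, 4),
      noise2 = runif(10, 2, 4)
    )
  })
  tab <- run_gra_table(cohort, criterion = "y")
  expect_equal(tab$indicator[1], "proportional")
  expect_equal(tab$grade[1], 1)
  expect_equal(tab$rank, 1:3)
  expect_true(all(diff(tab$grade) <= 0))     # ordered by descending grade
})

test_that("the cohort-level report agrees with the brute-force oracle end to end", {
  withr::with_seed(43, {
    cohort <- tibble::tibble(
      y = runif(4, 1, 5), a = runif(4, 1, 5),
      b = runif(4, 1, 5), c = runif(4, 1, 5)
    )
  })
  res <- run_gra(cohort, criterion = "y")
  oracle <- brute_force_gra(cohort$y, as.matrix(cohort[c("a", "b", "c")]))
  expect_equal(sort(res$table$grade, decreasing = TRUE),
               sort(oracle$grades, decreasing = TRUE), tolerance = 1e-12)
  g <- glance(res)
  expect_equal(g$n_indicators, 3)
  expect_equal(g$delta_max, oracle$d_max)
  td <- tidy(res)
  expect_identical(td, res$table)
})
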