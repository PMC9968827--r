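# Source-configuration enumeration, combination and empirical ranking.

topoOf <- function(vals, labels = sprintf("e%d", seq_along(vals))) {
  new("ScalpTopography", labels = labels,
      positions = matrix(0, length(vals), 3), values = as.matrix(vals),
      dt = 0, condition = "unspecified")
}

test_that("configuration enumeration yields all non-empty subsets", {
  expect_length(enumerateConfigurations(c("V4", "lusV4", "LIP", "7a", "FEF")),
                31L)
  expect_length(enumerateConfigurations(letters[1:3]), 7L)
  expect_identical(enumerateConfigurations("V4"), list("V4"))
  expect_error(enumerateConfigurations(character(0)), "at least one")
  cfgs <- enumerateConfigurations(letters[1:4])
  expect_equal(length(unique(vapply(cfgs, paste, "", collapse = "+"))), 15L)
})

test_that("topography sums and differences behave element-wise", {
  a <- topoOf(c(1, 2, 3))
  b <- topoOf(c(1, 1, 1))
  expect_equal(topoValues(sumTopographies(list(a))), topoValues(a))
  expect_equal(topoValues(sumTopographies(list(b, b, b))),
               matrix(3, 3, 1))
  negA <- a; negA@values <- -a@values
  expect_true(all(topoValues(sumTopographies(list(a, negA))) == 0))

  expect_true(all(topoValues(differenceTopography(a, a)) == 0))
  d <- differenceTopography(a, b)
  expect_identical(conditionTag(d), "difference")
  expect_equal(topoValues(differenceTopography(b, a)), -topoValues(d))
  other <- topoOf(c(1, 2, 3), labels = c("x", "y", "z"))
  expect_error(differenceTopography(a, other), "montages")
})

test_that("an exactly matching configuration wins with r = 1", {
  set.seed(21)
  lead <- matrix(rnorm(15 * 3), 15, 3)
  modeled <- lapply(1:3, function(j) matrix(lead[, j], 15, 4))
  names(modeled) <- c("A", "B", "C")
  empirical <- lead[, 1] + lead[, 3]
  rk <- rankAgainstEmpirical(modeled, empirical)
  expect_setequal(rk@winner, c("A", "C"))
  expect_equal(rk@table$r[1], 1, tolerance = 1e-12)
  expect_true(rk@table$significant[1])
  expect_equal(nrow(rk@table), 7L)
})

test_that("negatively correlated configurations are recorded as zero", {
  set.seed(22)
  lead <- matrix(rnorm(15 * 2), 15, 2)
  modeled <- lapply(1:2, function(j) matrix(lead[, j], 15, 3))
  names(modeled) <- c("A", "B")
  rk <- rankAgainstEmpirical(modeled, -lead[, 1])
  tab <- rk@table
  expect_true(all(tab$R2[tab$r < 0] == 0))
  expect_true(all(tab$R2[tab$r >= 0] == tab$r[tab$r >= 0]^2))
  expect_false(any(tab$significant[tab$r < 0]))
})

test_that("the ranking is invariant under common positive rescaling", {
  set.seed(23)
  lead <- matrix(rnorm(15 * 3), 15, 3)
  noise <- rnorm(15, 0, 0.3)
  modeled <- lapply(1:3, function(j) matrix(lead[, j], 15, 5))
  names(modeled) <- c("A", "B", "C")
  empirical <- lead[, 1] + lead[, 2] + noise
  rk1 <- rankAgainstEmpirical(modeled, empirical)
  rk2 <- rankAgainstEmpirical(lapply(modeled, function(m) 37 * m), empirical)
  expect_identical(rk1@table$configuration, rk2@table$configuration)
  expect_equal(rk1@table$R2, rk2@table$R2, tolerance = 1e-12)
})

test_that("ranking validates montage and session structure", {
  lead <- matrix(rnorm(15 * 2), 15, 2)
  modeled <- list(A = matrix(lead[, 1], 15, 3), B = matrix(lead[1:14, 2], 14, 3))
  expect_error(rankAgainstEmpirical(modeled, lead[, 1]), "montage")
  modeled2 <- list(A = matrix(lead[, 1], 15, 1), B = matrix(lead[, 2], 15, 1))
  expect_error(rankAgainstEmpirical(modeled2, lead[, 1]), "2 sessions")
  modeled3 <- list(A = matrix(lead[, 1], 15, 3), B = matrix(lead[, 2], 15, 3))
  expect_error(rankAgainstEmpirical(modeled3, rep(1, 15)), "variance")
})

test_that("window averaging of a topography matches a direct mean", {
  tr <- new("ScalpTopography", labels = c("a", "b"),
            positions = matrix(0, 2, 3),
            values = rbind(sin(0.1 * 0:99), cos(0.1 * 0:99)), dt = 1,
            condition = "contra")
  w <- windowTopography(tr, c(10, 20))
  expect_equal(topoValues(w)[, 1], rowMeans(tr@values[, 11:21]),
               tolerance = 1e-12)
  expect_error(windowTopography(tr, c(500, 600)), "no samples")
})
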