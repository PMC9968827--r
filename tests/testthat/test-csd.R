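# CSD estimation: standard second derivative, spline iCSD, preprocessing.

recOf <- function(x, depths = NULL, dt = 1, sigma = 0.33) {
  x <- as.matrix(x)
  if (is.null(depths)) depths <- 0.1 * seq_len(nrow(x))
  new("LaminarRecording", depths = depths, lfp = x, dt = dt, sigma = sigma)
}

test_that("standard CSD matches the hand-computed second difference", {
  # linear profile -> zero interior CSD
  expect_equal(csdValues(standardCSD(recOf(c(1, 2, 3)))), matrix(0, 1, 1),
               tolerance = 1e-12)
  # (1, 3, 1) mV at 0.1 mm spacing, sigma 0.33 -> 132 uA/mm^3
  expect_equal(csdValues(standardCSD(recOf(c(1, 3, 1))))[1, 1], 132,
               tolerance = 1e-12)
  expect_equal(csdValues(standardCSD(recOf(c(2, 2, 2)))), matrix(0, 1, 1),
               tolerance = 1e-12)
})

test_that("standard CSD drops edges by default and pads on request", {
  r <- recOf(c(1, 3, 1, 2))
  expect_length(depths(standardCSD(r)), 2L)
  expect_length(depths(standardCSD(r, pad = "replicate")), 4L)
  expect_error(standardCSD(recOf(c(1, 2))), "3 electrodes")
  expect_error(standardCSD(recOf(c(1, 2, 3, 4), depths = c(0.1, 0.2, 0.35, 0.4))),
               "uniform")
})

test_that("standard CSD is linear in the LFP", {
  a <- matrix(rnorm(5 * 4), 5, 4)
  b <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(csdValues(standardCSD(recOf(2 * a + 3 * b))),
               2 * csdValues(standardCSD(recOf(a))) +
                 3 * csdValues(standardCSD(recOf(b))),
               tolerance = 1e-10)
})

test_that("spline iCSD returns zero for zero LFP and a finer grid", {
  r <- recOf(matrix(0, 8, 3))
  est <- splineICSD(r)
  expect_true(all(csdValues(est) == 0))
  expect_gte(length(depths(est)), 4L * length(depths(r)))
  expect_identical(est@method, "spline-iCSD")
  expect_error(splineICSD(recOf(c(1, 2, 3))), "4 electrodes")
})

test_that("spline iCSD recovers a disk source and round-trips the LFP", {
  elec <- 0.1 * (1:16)
  z0 <- 0.85
  zf <- seq(elec[1], elec[16], length.out = 601)
  dens <- ifelse(abs(zf - z0) <= 0.15, 1, 0)
  truth <- new("CSDProfile", depths = zf, csd = matrix(dens, ncol = 1), dt = 1,
               method = "standard", diameter = 3, sigma = 0.33)
  lfp <- forwardLFP(truth, elec)                  # independent forward oracle

  est <- splineICSD(lfp, diameter = 3)
  peakZ <- depths(est)[which.max(csdValues(est)[, 1])]
  expect_lt(abs(peakZ - z0), 0.1)                 # within one electrode step

  rt <- forwardLFP(est, elec)
  relErr <- sqrt(sum((lfpValues(rt) - lfpValues(lfp))^2)) /
    sqrt(sum(lfpValues(lfp)^2))
  expect_lt(relErr, 0.01)
})

test_that("standard and spline CSD agree in laminar sign pattern", {
  rec <- lowpassFilter(lfpPointSource(smallCurrents()))
  std <- standardCSD(rec)
  spl <- splineICSD(rec)
  tPeak <- which.max(colSums(csdValues(std)^2))
  sharedIdx <- match(round(depths(std), 6), round(depths(spl), 6))
  expect_false(anyNA(sharedIdx))
  rho <- cor(csdValues(std)[, tPeak], csdValues(spl)[sharedIdx, tPeak],
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("baseline correction subtracts the window mean exactly", {
  m <- matrix(rnorm(4 * 50), 4, 50)
  prof <- new("CSDProfile", depths = 0.1 * (1:4), csd = m, dt = 1,
              method = "standard", diameter = Inf, sigma = 0.33)
  # constant-in-time profile -> all zeros
  constProf <- prof; constProf@csd <- matrix(5, 4, 50)
  expect_true(all(csdValues(baselineCorrect(constProf, c(0, 49))) == 0))
  # signal + offset -> signal restored when the baseline covers a zero-mean span
  base <- baselineCorrect(prof, c(10, 20))
  sel <- 11:21   # samples with t in [10, 20] at dt = 1
  oracle <- m - rowMeans(m[, sel])
  expect_equal(csdValues(base), oracle, tolerance = 1e-12)
  expect_error(baselineCorrect(prof, c(100, 120)), "no samples")
})

test_that("event clipping removes the lead window and is idempotent", {
  m <- matrix(rnorm(3 * 1000), 3, 1000)   # 100 ms at dt = 0.1
  prof <- new("CSDProfile", depths = 0.1 * (1:3), csd = m, dt = 0.1,
              method = "standard", diameter = Inf, sigma = 0.33)
  clipped <- clipAtEvent(prof, 60, lead = 10)
  expect_equal(ncol(csdValues(clipped)), 500L)    # 50 ms retained
  again <- clipAtEvent(clipped, 60, lead = 10)
  expect_identical(csdValues(again), csdValues(clipped))
  # event beyond the trace with zero lead leaves the profile unchanged
  expect_identical(csdValues(clipAtEvent(prof, 100, lead = 0)), m)
  expect_error(clipAtEvent(prof, -5), "before")
})
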