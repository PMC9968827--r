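# Point-source LFP and the zero-phase low-pass filter.

monoSet <- function(coords, currents, nt = 1L, radii = 0.001) {
  coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  new("CompartmentCurrentSet", coords = coords,
      currents = matrix(currents, nrow = nrow(coords), ncol = nt),
      radii = rep(radii, nrow(coords)), neuron = seq_len(nrow(coords)),
      population = rep("L3", nrow(coords)), dt = 0.1,
      naEvents = list(), caEvents = list(), seed = 1L)
}

test_that("a single monopole reproduces the closed-form potential", {
  cs <- monoSet(c(0, 0, 0), 1)   # +1 nA at the origin
  rec <- lfpPointSource(cs, electrodes = cbind(0, 0, 10), sigma = 0.33)
  # 1/(4 pi 0.33 S/m x 0.01 m) x 1 nA = 2.411e-8 V = 2.411e-5 mV
  expect_equal(lfpValues(rec)[1, 1], 2.411e-5, tolerance = 1e-3)
})

test_that("zero currents give zero LFP and superposition holds", {
  cs0 <- monoSet(c(0, 0, 0), 0)
  expect_true(all(lfpValues(lfpPointSource(cs0, cbind(0, 0, 5))) == 0))

  csA <- monoSet(c(0, 0, -0.5), 1)
  csB <- monoSet(c(0.3, 0, -1.2), -1)
  csAB <- monoSet(c(0, 0, -0.5, 0.3, 0, -1.2), c(1, -1))
  el <- laminarElectrodes()
  expect_equal(lfpValues(lfpPointSource(csA, el)) +
                 lfpValues(lfpPointSource(csB, el)),
               lfpValues(lfpPointSource(csAB, el)), tolerance = 1e-12)
})

test_that("opposite monopoles cancel on the perpendicular bisector plane", {
  cs <- monoSet(c(1, 0, -0.5, -1, 0, -0.5), c(1, -1))
  # the x = 0 plane is the bisector; the array lies in it
  rec <- suppressWarnings(
    lfpPointSource(cs, electrodes = cbind(0, c(0, 3), c(-1, -2))))
  expect_equal(max(abs(lfpValues(rec))), 0, tolerance = 1e-15)
})

test_that("an isolated monopole decays as 1/r", {
  cs <- monoSet(c(0, 0, 0), 1)
  v <- lfpValues(lfpPointSource(cs, electrodes = cbind(0, 0, c(-5, -10))))
  expect_equal(v[2, 1] / v[1, 1], 0.5, tolerance = 1e-12)
})

test_that("off-axis electrodes trigger a co-linearity warning", {
  cs <- monoSet(c(0, 0, 0), 1)
  expect_warning(lfpPointSource(cs, electrodes = cbind(c(0, 1), 0, c(-1, -2))),
                 "co-linear")
})

test_that("the low-pass filter has unit DC gain and the stated roll-off", {
  dt <- 0.1
  tt <- (0:19999) * dt / 1000            # seconds
  const <- matrix(1, 1, length(tt))
  expect_equal(lowpassFilter(const, 100, dt = dt), const, tolerance = 1e-6)

  mid <- 5000:15000
  s300 <- matrix(sin(2 * pi * 300 * tt), 1)
  f300 <- lowpassFilter(s300, 100, dt = dt)
  expect_gt(max(abs(s300[1, mid])) / max(abs(f300[1, mid])), 20)

  s10 <- matrix(sin(2 * pi * 10 * tt), 1)
  f10 <- lowpassFilter(s10, 100, dt = dt)
  expect_equal(max(abs(f10[1, mid])), 1, tolerance = 0.01)
})

test_that("the filter rejects cutoffs at or above Nyquist", {
  expect_error(lowpassFilter(matrix(0, 1, 100), cutoff = 6000, dt = 0.1),
               "Nyquist")
})
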