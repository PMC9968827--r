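# Equivalent dipoles from CSD profiles and from compartment currents.

profOf <- function(z, m) new("CSDProfile", depths = z, csd = as.matrix(m),
                             dt = 1, method = "standard", diameter = Inf,
                             sigma = 0.33)

test_that("CSD dipole amplitude vanishes for symmetric sources", {
  z <- seq(0, 2, by = 0.1)
  # mass only at the reference depth
  m <- matrix(0, length(z), 1); m[z == 1] <- 3
  expect_equal(amplitude(dipoleFromCSD(profOf(z, m), zRef = 1)), 0,
               tolerance = 1e-12)
  # even-symmetric profile about the reference depth
  m2 <- matrix(exp(-(z - 1)^2 / 0.05), ncol = 1)
  expect_equal(amplitude(dipoleFromCSD(profOf(z, m2), zRef = 1)), 0,
               tolerance = 1e-10)
})

test_that("CSD dipole reproduces the hand-computed two-point value", {
  z <- seq(0, 2, by = 0.1); zm <- 1
  m <- matrix(0, length(z), 1)
  m[abs(z - (zm - 0.5)) < 1e-9] <- 1     # shallower point, +1 uA/mm^3
  m[abs(z - (zm + 0.5)) < 1e-9] <- -1    # deeper point, -1 uA/mm^3
  d <- amplitude(dipoleFromCSD(profOf(z, m), rc = 1.5, zRef = zm))
  expect_equal(d * 1e-9, 7.069e-10, tolerance = 5e-4)  # nA*m -> A*m
})

test_that("CSD dipole is linear in the CSD", {
  z <- seq(0, 1.6, by = 0.1)
  a <- matrix(rnorm(length(z) * 3), length(z))
  b <- matrix(rnorm(length(z) * 3), length(z))
  expect_equal(amplitude(dipoleFromCSD(profOf(z, 2 * a + b))),
               2 * amplitude(dipoleFromCSD(profOf(z, a))) +
                 amplitude(dipoleFromCSD(profOf(z, b))),
               tolerance = 1e-10)
})

test_that("STC dipole matches the two-monopole hand sum for any rm", {
  cs <- new("CompartmentCurrentSet",
            coords = rbind(c(0, 0, 0), c(0, 0, 1)),
            currents = matrix(c(1, -1), 2, 1), radii = c(0.01, 0.01),
            neuron = c(1L, 1L), population = c("L3", "L3"), dt = 0.1,
            naEvents = list(), caEvents = list(), seed = 1L)
  # d = sum (r_c - r_m) I_c = (0,0,-1) nA*mm = (0,0,-1e-3) nA*m
  for (rm in list(c(0, 0, 0), c(5, 5, 5), c(-3, 2, 17))) {
    d <- momentValues(dipoleFromSTC(cs, rm = rm))
    expect_equal(as.numeric(d), c(0, 0, -1e-3), tolerance = 1e-12)
  }
})

test_that("STC dipole of conserved currents is invariant to rm", {
  cs <- smallCurrents()
  d0 <- momentValues(dipoleFromSTC(cs))
  d1 <- momentValues(dipoleFromSTC(cs, rm = c(5, 5, 5)))
  expect_lt(max(abs(d1 - d0)), 1e-9 * max(abs(d0)))
})

test_that("STC dipole warns when charge is not conserved", {
  cs <- new("CompartmentCurrentSet",
            coords = rbind(c(0, 0, 0), c(0, 0, 1)),
            currents = matrix(c(1, -0.5), 2, 1), radii = c(0.01, 0.01),
            neuron = c(1L, 1L), population = c("L3", "L3"), dt = 0.1,
            naEvents = list(), caEvents = list(), seed = 1L)
  expect_warning(dipoleFromSTC(cs), "conserve")
})

test_that("zero currents give a zero moment", {
  cs <- smallCurrents()
  cs@currents[] <- 0
  expect_true(all(momentValues(dipoleFromSTC(cs)) == 0))
})

test_that("mesh orientation is the area-weighted 1-ring normal", {
  expect_equal(orientFromMesh(planarMesh(), c(0.5, 0.5, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  ico <- icosphere(2, 1)
  v <- ico$vertices[37, ]
  mu <- orientFromMesh(ico, v)
  angle <- acos(sum(mu * v)) * 180 / pi
  expect_lt(angle, 2)
  expect_error(orientFromMesh(ico, c(5, 5, 5)), "1 mm")
})

test_that("placeAtSite is a rigid motion aligning z with the site normal", {
  nrm <- unname(c(1, 2, 2) / 3)
  pos <- c(10, -5, 3)
  pts <- rbind(c(0, 0, -1), c(0.5, 0, -2))
  out <- placeAtSite(pts, pos, nrm)
  expect_equal(as.numeric(out[1, ]), pos - nrm, tolerance = 1e-12)
  expect_equal(dist(out)[1], dist(pts)[1], tolerance = 1e-12)
})
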