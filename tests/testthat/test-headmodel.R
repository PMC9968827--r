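# Head model: meshes, infinite-medium terms, analytic oracle, BEM, montage.

test_that("icospheres have the predicted vertex and face counts", {
  for (lv in 0:3) {
    ico <- icosphere(lv)
    expect_equal(nrow(ico$vertices), 10 * 4^lv + 2)
    expect_equal(nrow(ico$faces), 20 * 4^lv)
    expect_true(meshIsClosed(ico))
    expect_gt(meshVolume(ico), 0)
  }
})

test_that("nested sphere models enforce ordering and nesting", {
  m <- buildNestedSpheres(c(1, 2, 3), level = 2,
                          conductivities = c(0.3, 0.01, 0.4, 0))
  expect_length(surfaces(m), 3L)
  expect_true(validObject(m))
  expect_error(buildNestedSpheres(c(3, 2, 1), level = 2), "increasing")
  expect_equal(nrow(surfaces(buildNestedSpheres(level = 3))[[1]]$vertices), 642L)
})

test_that("monopole and dipole infinite-medium terms match closed forms", {
  expect_equal(v0Monopoles(c(0, 0, 0), 1, 0.33, c(10, 0, 0))[1, 1],
               0.02411, tolerance = 1e-3)         # 2.411e-8 V
  expect_true(all(v0Monopoles(c(0, 0, 0), 0, 0.33, cbind(1:3, 0, 0)) == 0))
  # balanced pair decays as 1/r^2 in the far field
  pos <- rbind(c(0, 0, 0.5), c(0, 0, -0.5))
  v <- v0Monopoles(pos, c(1, -1), 0.33, rbind(c(0, 0, 100), c(0, 0, 200)))
  expect_equal(v[1, 1] / v[2, 1], 4, tolerance = 0.01)

  expect_equal(v0Dipole(c(0, 0, 0), 0.33, c(0, 0, 10),
                        moment = c(0, 0, 1e-3))[1, 1],
               2.411e-3, tolerance = 1e-3)        # 2.411e-9 V
  expect_equal(v0Dipole(c(0, 0, 0), 0.33, c(10, 0, 0),
                        moment = c(0, 0, 1))[1, 1], 0)
  expect_equal(v0Dipole(c(0, 0, 0), 0.33, c(0, 0, 10), moment = c(0, 0, 2)),
               2 * v0Dipole(c(0, 0, 0), 0.33, c(0, 0, 10), moment = c(0, 0, 1)))
})

test_that("the analytic shell series reduces to known solutions", {
  R <- 30; sig <- 0.33; p <- 1
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(0.6, 0, 0.8))
  v <- analyticMultishell(R, sig, c(0, 0, 0), c(0, 0, p), dirs)
  closed <- 1e3 * 3 * p * dirs[, 3] / (4 * pi * sig * R^2)
  expect_equal(as.numeric(v), closed, tolerance = 1e-6)

  # equal shell conductivities reduce to the homogeneous sphere
  off <- c(0, 0, 12)
  vh <- analyticMultishell(R, sig, off, c(1, 2, 0.5), icosphere(1)$vertices)
  v3 <- analyticMultishell(c(20, 25, 30), c(sig, sig, sig), off, c(1, 2, 0.5),
                           icosphere(1)$vertices)
  expect_equal(v3, vh, tolerance = 1e-6, ignore_attr = TRUE)

  # surface integral of the potential vanishes (no monopole term)
  vc <- analyticMultishell(R, sig, c(0, 0, 0), c(0, 0, 1),
                           icosphere(2)$vertices)
  expect_lt(abs(mean(vc)), 1e-8 * max(abs(vc)))

  expect_lt(attr(vh, "truncationBound"), 1e-6)
  expect_error(analyticMultishell(R, sig, c(0, 0, 40), c(0, 0, 1), dirs),
               "inside")
})

test_that("BEM with no conductivity jumps returns the infinite-medium term", {
  mdl <- buildNestedSpheres(c(10, 12, 14), level = 2,
                            conductivities = c(0.33, 0.33, 0.33, 0.33))
  op <- bemOperator(mdl)
  dip <- new("DipoleSource", position = c(0, 0, 4),
             moment = matrix(c(0, 0, 1), 3, 1), orientation = c(0, 0, 1),
             dt = 1, rc = 1.5, method = "CSD")
  sol <- bemSolve(op, dip, isolated = FALSE)
  v0 <- v0Dipole(dip, 0.33, op$centroids)
  scalp <- sol$faceSurface == 3
  expect_equal(sol$potentials[scalp, 1] - mean(sol$potentials[scalp, 1]),
               v0[scalp, 1] - mean(v0[scalp, 1]), tolerance = 1e-9)
})

test_that("flipping the dipole flips the topography exactly", {
  mdl <- buildNestedSpheres(c(10, 12, 14), level = 2)
  op <- bemOperator(mdl)
  mont <- placeMontage(mdl, "1020")
  dipUp <- new("DipoleSource", position = c(0, 0, 4),
               moment = matrix(c(0, 0, 1), 3, 1), orientation = c(0, 0, 1),
               dt = 1, rc = 1.5, method = "CSD")
  dipDown <- dipUp; dipDown@moment <- -dipUp@moment
  dipDown@orientation <- -dipUp@orientation
  expect_equal(topoValues(bemSolve(op, dipUp, mont)),
               -topoValues(bemSolve(op, dipDown, mont)), tolerance = 1e-10)
})

test_that("BEM electrode potentials superpose over sources", {
  mdl <- buildNestedSpheres(c(10, 12, 14), level = 2)
  op <- bemOperator(mdl)
  mont <- placeMontage(mdl, "1020")
  m1 <- list(positions = rbind(c(0, 0, 3), c(0, 0, 5)), currents = c(1, -1))
  m2 <- list(positions = rbind(c(1, 0, 2), c(0, 1, 4)), currents = c(2, -2))
  m12 <- list(positions = rbind(m1$positions, m2$positions),
              currents = c(m1$currents, m2$currents))
  expect_equal(topoValues(bemSolve(op, m1, mont)) +
                 topoValues(bemSolve(op, m2, mont)),
               topoValues(bemSolve(op, m12, mont)), tolerance = 1e-9)
})

test_that("a coarse 3-shell BEM already tracks the analytic oracle", {
  mdl <- buildNestedSpheres(c(10, 12, 14), level = 2)
  op <- bemOperator(mdl)
  dirs <- icosphere(1)$vertices
  mont <- new("ElectrodeMontage", labels = sprintf("e%02d", seq_len(nrow(dirs))),
              positions = dirs * 14, system = "custom")
  dip <- new("DipoleSource", position = c(0, 0, 4),
             moment = matrix(c(1, 0, 0), 3, 1), orientation = c(1, 0, 0),
             dt = 1, rc = 1.5, method = "CSD")
  va <- analyticMultishell(c(10, 12, 14), c(0.33, 0.0063, 0.43),
                           dip@position, dip@moment, dirs)
  va <- va - mean(va)
  vb <- topoValues(bemSolve(op, dip, mont))
  expect_lt(rdm(va, vb), 0.08)
  expect_gt(mag(va, vb), 0.85)
  expect_lt(mag(va, vb), 1.15)
})

test_that("BEM rejects sources outside the innermost surface", {
  mdl <- buildNestedSpheres(c(10, 12, 14), level = 2)
  op <- bemOperator(mdl)
  dip <- new("DipoleSource", position = c(0, 0, 11),
             moment = matrix(c(0, 0, 1), 3, 1), orientation = c(0, 0, 1),
             dt = 1, rc = 1.5, method = "CSD")
  expect_error(bemSolve(op, dip), "inside")
})

test_that("standard montages have the published site counts and geometry", {
  scalp <- icosphere(3, 1)
  m10 <- placeMontage(scalp, "1010")
  expect_length(electrodeLabels(m10), 61L)
  m20 <- placeMontage(scalp, "1020")
  expect_length(electrodeLabels(m20), 15L)
  expect_setequal(electrodeLabels(m20),
                  c("FpFz", "Fpz", "F3", "F4", "Fz", "Cz", "C3", "C4", "Pz",
                    "P5", "P6", "POz", "O1", "O2", "Oz"))
  cz <- electrodePositions(m10)[electrodeLabels(m10) == "Cz", ]
  expect_gt(cz[3], 0.99)
  expect_lt(sqrt(sum(cz[1:2]^2)), 0.02)
  # all sites on (within chord error of) the unit scalp
  r <- sqrt(rowSums(electrodePositions(m10)^2))
  expect_true(all(r > 0.95 & r <= 1 + 1e-9))
})
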