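# RDM/MAG identities, point-to-mesh distance, depth regression, site sampling.

test_that("MAG and RDM satisfy their defining identities", {
  y <- c(3, 4)
  expect_equal(mag(y, y), 1, tolerance = 1e-15)
  expect_equal(mag(y, 2 * y), 2, tolerance = 1e-15)
  expect_equal(mag(c(3, 4), c(0, 5)), 1, tolerance = 1e-15)
  expect_equal(rdm(y, 7 * y), 0, tolerance = 1e-12)
  expect_equal(rdm(y, -y), 2, tolerance = 1e-12)
  expect_equal(rdm(c(1, 0), c(0, 1)), sqrt(2), tolerance = 1e-12)
  expect_error(mag(c(0, 0), y), "zero")
  expect_error(rdm(y, c(0, 0)), "zero")
})

test_that("RDM is scale invariant and obeys rdm^2 = 2 - 2 cos(angle)", {
  set.seed(5)
  for (i in 1:25) {
    y <- rnorm(8); yh <- rnorm(8)
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(rdm(y, yh), rdm(a * y, b * yh), tolerance = 1e-12)
    cosang <- sum(y * yh) / sqrt(sum(y^2) * sum(yh^2))
    expect_equal(rdm(y, yh)^2, 2 - 2 * cosang, tolerance = 1e-12)
  }
})

test_that("column depth is the exact point-to-mesh distance", {
  ico <- icosphere(3, 1)
  expect_equal(columnDepth(ico, c(0, 0, 0)), 1, tolerance = 0.01)
  expect_equal(columnDepth(ico, ico$vertices[5, ]), 0, tolerance = 1e-12)

  # exhaustive oracle: dense barycentric sampling over every triangle
  mesh <- planarMesh(3)
  set.seed(8)
  pts <- cbind(runif(5), runif(5), runif(5, -1, 1))
  fast <- columnDepth(mesh, pts)
  gr <- expand.grid(u = seq(0, 1, by = 0.02), v = seq(0, 1, by = 0.02))
  gr <- gr[gr$u + gr$v <= 1, ]
  for (i in seq_len(nrow(pts))) {
    brute <- Inf
    for (f in seq_len(nrow(mesh$faces))) {
      tri <- mesh$vertices[mesh$faces[f, ], ]
      samp <- cbind(1 - gr$u - gr$v, gr$u, gr$v) %*% tri
      brute <- min(brute, sqrt(min(colSums((t(samp) - pts[i, ])^2))))
    }
    expect_equal(fast[i], brute, tolerance = 0.02)
    expect_lte(fast[i], brute + 1e-12)
  }
  expect_error(columnDepth(list(vertices = NULL, faces = NULL), c(0, 0, 0)),
               "empty")
})

test_that("depth regression matches the normal-equations oracle", {
  depth <- c(1, 2, 4, 7)
  metric <- c(0.3, 0.8, 0.5, 1.1)
  fit <- depthRegression(depth, metric)
  X <- cbind(1, depth)
  beta <- solve(t(X) %*% X, t(X) %*% metric)
  rss <- sum((metric - X %*% beta)^2)
  tss <- sum((metric - mean(metric))^2)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$r.squared, 1 - rss / tss, tolerance = 1e-12)

  suppressWarnings({   # summary.lm warns on exact fits
    expect_equal(depthRegression(depth, 2 + 0.5 * depth)$r.squared, 1,
                 tolerance = 1e-12)
    expect_equal(depthRegression(depth, rep(3, 4))$r.squared, 0,
                 tolerance = 1e-12)
  })
  expect_error(depthRegression(c(2, 2, 2), metric[1:3]), "constant")
  expect_error(depthRegression(c(1, 2), c(1, 2)), "3 locations")
})

test_that("random column sites are distinct, on-mesh and seeded", {
  ico <- icosphere(2, 1)
  s <- randomColumnSites(ico, 15, seed = 3)
  expect_equal(nrow(s$positions), 15L)
  expect_equal(length(unique(s$vertexIds)), 15L)
  expect_identical(s, randomColumnSites(ico, 15, seed = 3))
  expect_equal(sqrt(rowSums(s$orientations^2)), rep(1, 15), tolerance = 1e-9)
  # orientations point outward on a sphere
  expect_true(all(rowSums(s$orientations * s$positions) > 0.9))

  all_ <- randomColumnSites(ico, nrow(ico$vertices), seed = 1)
  expect_setequal(all_$vertexIds, seq_len(nrow(ico$vertices)))
  expect_error(randomColumnSites(ico, nrow(ico$vertices) + 1), "more sites")
})

test_that("the search chance level is one over the item count", {
  expect_identical(searchChanceLevel(6), 1 / 6)
  expect_identical(searchChanceLevel(4), 0.25)
})
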