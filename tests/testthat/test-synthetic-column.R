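# Population generator: reduced cells, placement, cable simulation, events.

test_that("reduced cells have the stated default geometry", {
  n3 <- buildReducedCell("L3")
  expect_equal(nrow(n3@centers), 11L)
  # apical tip ~600 um above the soma
  expect_equal(unname(max(n3@centers[, 3]) - n3@centers[1, 3]), 0.6,
               tolerance = 0.1)

  n5 <- buildReducedCell("L5")
  expect_equal(nrow(n5@centers), 21L)
  # tip within 100 um of the pia (z = 0)
  tipEnd <- max(n5@centers[, 3]) + n5@lengths[which.max(n5@centers[, 3])] / 2
  expect_lt(abs(tipEnd), 0.1)

  expect_error(buildReducedCell("L5", trunkLength = -1), "positive")
  expect_error(buildReducedCell("L9"), "arg")
})

test_that("population placement is uniform in the disk and seeded", {
  spec <- new("PopulationSpec")
  expect_equal(spec@nL3, 2200L)
  expect_equal(spec@nL5, 1000L)

  pop <- placePopulation(new("PopulationSpec", nL3 = 300L, nL5 = 150L), seed = 7)
  expect_length(pop, 450L)
  somaXY <- t(vapply(pop, function(nr) nr@centers[1, 1:2], numeric(2)))
  expect_true(all(sqrt(rowSums(somaXY^2)) <= 1.5 + 1e-12))
  cls <- vapply(pop, function(nr) nr@cellClass, "")
  d <- vapply(pop, function(nr) nr@somaDepth, 0)
  expect_true(all(d[cls == "L3"] >= 0.675 & d[cls == "L3"] <= 0.750))
  expect_true(all(d[cls == "L5"] >= 1.250 & d[cls == "L5"] <= 1.750))

  pop2 <- placePopulation(new("PopulationSpec", nL3 = 300L, nL5 = 150L), seed = 7)
  expect_identical(pop, pop2)

  single <- placePopulation(new("PopulationSpec", nL3 = 0L, nL5 = 1L), seed = 1)
  expect_length(single, 1L)
  expect_identical(single[[1]]@cellClass, "L5")
})

test_that("zero-amplitude stimulus yields identically zero currents", {
  pop <- placePopulation(new("PopulationSpec", nL3 = 2L, nL5 = 2L), seed = 1)
  cs <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = 0,
                                    sdAmplitude = 0, seed = 1L))
  expect_true(all(cs@currents == 0))
})

test_that("per-neuron transmembrane currents conserve charge", {
  cs <- smallCurrents()
  peak <- max(abs(cs@currents))
  for (idx in split(seq_len(nrow(cs@coords)), cs@neuron)) {
    tot <- colSums(cs@currents[idx, , drop = FALSE])
    expect_lt(max(abs(tot)), 1e-9 * peak)
  }
})

test_that("the passive response is linear in the stimulus amplitude", {
  pop <- placePopulation(new("PopulationSpec", nL3 = 3L, nL5 = 2L), seed = 4)
  cs1 <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = 1,
                                     sdAmplitude = 0, seed = 9L), events = FALSE)
  cs2 <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = 2,
                                     sdAmplitude = 0, seed = 9L), events = FALSE)
  expect_equal(2 * cs1@currents, cs2@currents, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  pop <- placePopulation(new("PopulationSpec", nL3 = 3L, nL5 = 2L), seed = 4)
  a <- simulatePopulation(pop, new("StimulusSpec", seed = 5L))
  b <- simulatePopulation(pop, new("StimulusSpec", seed = 5L))
  expect_identical(a@currents, b@currents)
  expect_identical(a@caEvents, b@caEvents)
})

test_that("a stronger stimulus mean never recruits fewer L5 Ca events", {
  pop <- placePopulation(new("PopulationSpec", nL3 = 0L, nL5 = 60L), seed = 3)
  strong <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = 1.90,
                                        seed = 11L))
  weak <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = 1.85,
                                      seed = 11L))
  expect_gte(countCaEvents(strong), countCaEvents(weak))
  expect_gt(countCaEvents(strong), 0L)
})

test_that("simulation rejects invalid spans and empty populations", {
  pop <- placePopulation(new("PopulationSpec", nL3 = 1L, nL5 = 0L), seed = 1)
  expect_error(simulatePopulation(list(), new("StimulusSpec")), "empty")
  expect_error(simulatePopulation(pop, new("StimulusSpec"), duration = 50),
               "tail")
  expect_error(simulatePopulation(pop, new("StimulusSpec"), dt = 0.5), "dt")
})
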