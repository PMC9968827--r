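# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

#' Small simulated column (20 L3 + 10 L5 cells), cached
smallCurrents <- function() {
  if (is.null(.fixtures$small)) {
    pop <- placePopulation(new("PopulationSpec", nL3 = 20L, nL5 = 10L),
                           seed = 101L)
    .fixtures$small <- simulatePopulation(
      pop, new("StimulusSpec", meanAmplitude = 1.9, seed = 102L))
  }
  .fixtures$small
}

#' Scaled-down study column (220 L3 + 100 L5 cells), cached
studyCurrents <- function() {
  if (is.null(.fixtures$study)) {
    pop <- placePopulation(new("PopulationSpec", nL3 = 220L, nL5 = 100L),
                           seed = 1L)
    .fixtures$study <- simulatePopulation(
      pop, new("StimulusSpec", meanAmplitude = 1.9, seed = 1L))
  }
  .fixtures$study
}

#' Fifteen scaled study columns (one placement + stimulus draw each), cached
studyCurrentsList <- function() {
  if (is.null(.fixtures$studyList)) {
    spec <- new("PopulationSpec", nL3 = 220L, nL5 = 100L)
    .fixtures$studyList <- c(list(studyCurrents()), lapply(2:15, function(i)
      simulatePopulation(placePopulation(spec, seed = i),
                         new("StimulusSpec", meanAmplitude = 1.9,
                             seed = as.integer(i)))))
  }
  .fixtures$studyList
}

#' Default 3-shell head model at icosphere level 3, cached
defaultSpheres <- function() {
  if (is.null(.fixtures$spheres)) .fixtures$spheres <- buildNestedSpheres()
  .fixtures$spheres
}

#' A planar square mesh in the z = 0 plane (faces CCW seen from +z)
planarMesh <- function(n = 4) {
  g <- expand.grid(x = seq(0, 1, length.out = n), y = seq(0, 1, length.out = n))
  v <- cbind(g$x, g$y, 0)
  f <- NULL
  idx <- function(i, j) (j - 1L) * n + i
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    f <- rbind(f, c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  list(vertices = v, faces = f)
}
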