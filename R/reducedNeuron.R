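# Reduced pyramidal-cell geometry and population placement.

#' Build a reduced ball-and-stick pyramidal cell
#'
#' Constructs a passive reduction of a pyramidal cell as a somatic compartment
#' plus a straight apical stick pointing toward the pia. The L3 default is a
#' soma plus a 10-compartment, 600 um apical stick; the L5 default is a soma
#' plus a 20-compartment apical trunk whose length is chosen so the distal tip
#' ends 50 um below the pia (for the default soma depth of 1.5 mm this gives
#' a trunk of about 1.5 mm reaching the top of the column).
#'
#' @param cellClass `"L3"` or `"L5"`.
#' @param somaDepth soma-center depth below the pia, mm (defaults: L3 0.7125,
#'   the middle of the 675-750 um band; L5 1.5, the middle of 1250-1750 um).
#' @param nApical number of apical compartments (L3: 10, L5: 20).
#' @param trunkLength apical stick length, mm (L3 default 0.6; L5 default
#'   `somaDepth - 0.05` so the tip reaches within 100 um of the pia).
#' @param origin length-2 lateral position (x, y) of the soma in mm.
#' @param somaLength,somaRadius somatic compartment dimensions, mm.
#' @param apicalRadius apical compartment radius, mm.
#' @param membrane list with `cm` (uF/cm^2), `rm` (Ohm cm^2), `ra` (Ohm cm).
#' @return a \linkS4class{ReducedNeuron}
#' @examples
#' n3 <- buildReducedCell("L3")   # 11 compartments
#' n5 <- buildReducedCell("L5")   # 21 compartments, tip 50 um below pia
#' @export
buildReducedCell <- function(cellClass = c("L3", "L5"), somaDepth = NULL,
                             nApical = NULL, trunkLength = NULL,
                             origin = c(0, 0), somaLength = 0.02,
                             somaRadius = 0.01, apicalRadius = NULL,
                             membrane = list(cm = 1, rm = 30000, ra = 150)) {
  cellClass <- match.arg(cellClass)
  if (is.null(somaDepth)) somaDepth <- if (cellClass == "L3") 0.7125 else 1.5
  if (is.null(nApical)) nApical <- if (cellClass == "L3") 10L else 20L
  if (is.null(trunkLength))
    trunkLength <- if (cellClass == "L3") 0.6 else somaDepth - 0.05
  if (is.null(apicalRadius)) apicalRadius <- if (cellClass == "L3") 0.002 else 0.003
  if (somaDepth <= 0 || trunkLength <= 0 || somaLength <= 0 ||
      somaRadius <= 0 || apicalRadius <= 0 || nApical < 1L)
    stop("geometry values must be strictly positive")

  # column frame: z toward pia, pia at z = 0, soma center at z = -somaDepth
  nApical <- as.integer(nApical)
  dz <- trunkLength / nApical
  zs <- -somaDepth + c(0, somaLength / 2 + (seq_len(nApical) - 0.5) * dz)
  centers <- cbind(rep(origin[1], nApical + 1L), rep(origin[2], nApical + 1L), zs)
  colnames(centers) <- c("x", "y", "z")
  new("ReducedNeuron",
      centers = centers,
      lengths = c(somaLength, rep(dz, nApical)),
      radii = c(somaRadius, rep(apicalRadius, nApical)),
      parent = c(0L, seq_len(nApical)),
      cellClass = cellClass, somaDepth = somaDepth, membrane = membrane)
}

#' Place a two-population pyramidal-cell column
#'
#' Draws soma positions uniformly: (x, y) uniform over a disk of the column
#' radius, depth uniform within the class-specific band. L5 trunk lengths are
#' set per neuron so the apical tip ends 50 um below the pia (quantized to a
#' 20 um grid so that neurons sharing a geometry can share one cable
#' solution).
#'
#' @param spec a \linkS4class{PopulationSpec} (defaults: 2200 L3 + 1000 L5 in
#'   a 3 mm diameter cylinder).
#' @param seed integer RNG seed; identical seeds give identical placements.
#' @return list of positioned \linkS4class{ReducedNeuron} objects (L3 first).
#' @examples
#' pop <- placePopulation(new("PopulationSpec", nL3 = 5L, nL5 = 3L), seed = 1)
#' length(pop)  # 8
#' @export
placePopulation <- function(spec = new("PopulationSpec"), seed = 1L) {
  validObject(spec)
  withSeed(seed, {
    place <- function(n, band, cls) {
      if (n == 0L) return(list())
      r <- spec@columnRadius * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      depth <- runif(n, band[1], band[2])
      lapply(seq_len(n), function(i) {
        tl <- if (cls == "L5") {
          # tip 50 um below pia; 20 um quantization for template sharing
          max(round((depth[i] - 0.05) / 0.02) * 0.02, 0.1)
        } else NULL
        buildReducedCell(cls, somaDepth = depth[i], trunkLength = tl,
                         origin = c(r[i] * cos(th[i]), r[i] * sin(th[i])))
      })
    }
    c(place(spec@nL3, spec@l3Band, "L3"), place(spec@nL5, spec@l5Band, "L5"))
  })
}
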