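# S4 classes for the forward-modeling chain.

#' Reduced pyramidal-cell morphology
#'
#' A passive ball-and-stick reduction of a pyramidal cell: a somatic
#' compartment plus an apical stick, represented as a rooted compartment tree.
#' Coordinates are column-local mm with z pointing toward the pia; the soma
#' center sits at depth `somaDepth` below the pia, and the lateral position is
#' `origin` (x, y in mm relative to the column axis).
#'
#' @slot centers numeric matrix (n x 3), compartment centers, column frame, mm.
#' @slot lengths numeric, compartment lengths (mm), all positive.
#' @slot radii numeric, compartment radii (mm), all positive.
#' @slot parent integer, parent compartment index (0 for the root/soma).
#' @slot cellClass character, `"L3"` or `"L5"`.
#' @slot somaDepth numeric, soma-center depth below the pia (mm).
#' @slot membrane list with `cm` (uF/cm^2), `rm` (Ohm cm^2), `ra` (Ohm cm).
#' @exportClass ReducedNeuron
setClass("ReducedNeuron",
  representation(centers = "matrix", lengths = "numeric", radii = "numeric",
                 parent = "integer", cellClass = "character",
                 somaDepth = "numeric", membrane = "list"))

setValidity("ReducedNeuron", function(object) {
  n <- nrow(object@centers)
  if (ncol(object@centers) != 3L) return("centers must be an n x 3 matrix")
  if (length(object@lengths) != n || length(object@radii) != n ||
      length(object@parent) != n)
    return("lengths, radii and parent must match the number of compartments")
  if (any(object@lengths <= 0) || any(object@radii <= 0))
    return("compartment lengths and radii must be strictly positive")
  if (!object@cellClass %in% c("L3", "L5"))
    return("cellClass must be 'L3' or 'L5'")
  if (object@parent[1] != 0L) return("the first compartment must be the root")
  if (n > 1L && any(object@parent[-1] < 1L | object@parent[-1] >= seq_len(n)[-1]))
    return("parent indices must describe a rooted tree (parent < child)")
  TRUE
})

#' Population specification for the simulated cortical column
#'
#' Defaults follow the simulated two-population column: 2200 L3 and 1000 L5
#' pyramidal cells with somata distributed uniformly in a 3 mm diameter
#' cylinder, L3 somata at 675-750 um and L5 somata at 1250-1750 um below the
#' pia.
#'
#' @slot nL3,nL5 integer cell counts (>= 0).
#' @slot columnRadius numeric, cylinder radius (mm).
#' @slot l3Band,l5Band numeric length-2, soma depth bands below pia (mm).
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(nL3 = "integer", nL5 = "integer", columnRadius = "numeric",
                 l3Band = "numeric", l5Band = "numeric"),
  prototype(nL3 = 2200L, nL5 = 1000L, columnRadius = 1.5,
            l3Band = c(0.675, 0.750), l5Band = c(1.250, 1.750)))

setValidity("PopulationSpec", function(object) {
  if (object@nL3 < 0L || object@nL5 < 0L) return("cell counts must be >= 0")
  if (object@columnRadius <= 0) return("columnRadius must be positive")
  for (b in list(object@l3Band, object@l5Band))
    if (length(b) != 2L || b[1] >= b[2] || any(b < 0))
      return("depth bands must be increasing non-negative length-2 vectors")
  if (max(object@l3Band) > min(object@l5Band))
    return("the L3 and L5 soma depth bands must not overlap")
  TRUE
})

#' Stimulus specification: a noisy somatic current pulse
#'
#' Each neuron receives a current pulse of fixed duration whose amplitude is
#' Gaussian across neurons (mean `meanAmplitude`, SD `sdAmplitude`) and whose
#' onset is uniform over `onsetWindow`.
#'
#' @slot duration numeric, pulse duration (ms).
#' @slot meanAmplitude,sdAmplitude numeric, amplitude mean and SD (nA).
#' @slot onsetWindow numeric length-2, onset window (ms).
#' @slot seed integer RNG seed.
#' @exportClass StimulusSpec
setClass("StimulusSpec",
  representation(duration = "numeric", meanAmplitude = "numeric",
                 sdAmplitude = "numeric", onsetWindow = "numeric",
                 seed = "integer"),
  prototype(duration = 30, meanAmplitude = 1.9, sdAmplitude = 0.3,
            onsetWindow = c(10, 20), seed = 1L))

setValidity("StimulusSpec", function(object) {
  if (object@duration <= 0) return("pulse duration must be positive")
  if (object@sdAmplitude < 0) return("amplitude SD must be >= 0")
  if (length(object@onsetWindow) != 2L ||
      object@onsetWindow[1] > object@onsetWindow[2] ||
      any(object@onsetWindow < 0))
    return("onsetWindow must be a non-negative increasing length-2 vector")
  TRUE
})

#' Ground-truth compartment transmembrane currents for a population
#'
#' Per-compartment coordinates and transmembrane current traces for every
#' simulated neuron. Injected stimulus and event currents are booked as
#' transmembrane currents, so the currents of each neuron sum to zero at every
#' sample (no spurious monopoles).
#'
#' @slot coords numeric matrix (ncomp x 3), compartment centers, mm.
#' @slot currents numeric matrix (ncomp x nt), transmembrane currents, nA.
#' @slot radii numeric, compartment radii (mm), used as the point-source clamp.
#' @slot neuron integer, neuron id per compartment.
#' @slot population character, population label per compartment (`L3`/`L5`).
#' @slot dt numeric, sample interval (ms).
#' @slot naEvents,caEvents list of event times (ms) per neuron.
#' @slot seed integer seed used for the stimulus draws.
#' @exportClass CompartmentCurrentSet
setClass("CompartmentCurrentSet",
  representation(coords = "matrix", currents = "matrix", radii = "numeric",
                 neuron = "integer", population = "character", dt = "numeric",
                 naEvents = "list", caEvents = "list", seed = "integer"))

setValidity("CompartmentCurrentSet", function(object) {
  nc <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be ncomp x 3")
  if (nrow(object@currents) != nc)
    return("currents must have one row per compartment")
  if (length(object@neuron) != nc || length(object@population) != nc ||
      length(object@radii) != nc)
    return("neuron, population and radii must match the compartment count")
  if (object@dt <= 0) return("dt must be positive")
  TRUE
})

#' Laminar field-potential recording
#'
#' Depth-ordered LFP time series from a linear electrode array together with
#' its geometry. Depths are mm below the pia and must increase strictly.
#'
#' @slot depths numeric, electrode depths below pia (mm), strictly increasing.
#' @slot lfp numeric matrix (n_elec x n_t), potentials in mV.
#' @slot dt numeric, sample interval (ms).
#' @slot sigma numeric, extracellular conductivity (S/m), > 0.
#' @slot events named numeric, event markers in ms (may be empty).
#' @slot layers character, optional per-channel layer labels.
#' @exportClass LaminarRecording
setClass("LaminarRecording",
  representation(depths = "numeric", lfp = "matrix", dt = "numeric",
                 sigma = "numeric", events = "numeric", layers = "character"),
  prototype(events = numeric(0), layers = character(0), sigma = 0.33))

setValidity("LaminarRecording", function(object) {
  if (length(object@depths) != nrow(object@lfp))
    return("one LFP row per electrode depth is required")
  if (any(diff(object@depths) <= 0))
    return("electrode depths must be strictly increasing")
  if (object@dt <= 0) return("dt must be positive")
  if (object@sigma <= 0) return("conductivity must be positive")
  if (length(object@layers) && length(object@layers) != length(object@depths))
    return("layers must be empty or one label per channel")
  TRUE
})

#' Volumetric current source density profile
#'
#' CSD on a depth grid, in uA/mm^3. Depths are mm below the pia (the column z
#' axis points toward the supragranular surface; sources toward the pia are
#' reported at smaller depths).
#'
#' @slot depths numeric, depth grid below pia (mm), strictly increasing.
#' @slot csd numeric matrix (n_z x n_t), uA/mm^3.
#' @slot dt numeric, sample interval (ms).
#' @slot method character, `"standard"` or `"spline-iCSD"`.
#' @slot diameter numeric, assumed source disk diameter (mm).
#' @slot sigma numeric, conductivity used (S/m).
#' @exportClass CSDProfile
setClass("CSDProfile",
  representation(depths = "numeric", csd = "matrix", dt = "numeric",
                 method = "character", diameter = "numeric", sigma = "numeric"))

setValidity("CSDProfile", function(object) {
  if (length(object@depths) != nrow(object@csd))
    return("one CSD row per depth-grid point is required")
  if (any(diff(object@depths) <= 0))
    return("the depth grid must be strictly increasing")
  if (object@dt <= 0) return("dt must be positive")
  if (!length(object@method)) return("a method tag is required")
  TRUE
})

#' Equivalent current dipole source
#'
#' A point dipole summarizing the polarized transmembrane current of a
#' cortical column: position, a 3 x n_t moment time series (nA*m), and for
#' CSD-derived dipoles the fixed unit orientation along the column axis.
#'
#' @slot position numeric length-3, dipole location (mm).
#' @slot moment numeric matrix (3 x n_t), moment time series (nA*m).
#' @slot orientation numeric length-3 unit vector, or length-0 when the
#'   moment orientation is time-varying (summed-transmembrane-current dipoles).
#' @slot dt numeric, sample interval (ms).
#' @slot rc numeric, column radius (mm), > 0.
#' @slot method character, provenance: `"CSD"` or `"STC"`.
#' @exportClass DipoleSource
setClass("DipoleSource",
  representation(position = "numeric", moment = "matrix",
                 orientation = "numeric", dt = "numeric", rc = "numeric",
                 method = "character"))

setValidity("DipoleSource", function(object) {
  if (length(object@position) != 3L) return("position must be a 3-vector")
  if (nrow(object@moment) != 3L) return("moment must be a 3 x n_t matrix")
  if (length(object@orientation) &&
      abs(sqrt(sum(object@orientation^2)) - 1) > 1e-9)
    return("orientation must be a unit vector (|mu| = 1 +/- 1e-9)")
  if (object@rc <= 0) return("column radius rc must be positive")
  if (!object@method %in% c("CSD", "STC"))
    return("method must be 'CSD' or 'STC'")
  TRUE
})

#' Piecewise-homogeneous head model with nested closed surfaces
#'
#' Ordered closed triangulated surfaces, innermost first (brain, skull,
#' scalp), with the conductivity of the region inside each surface plus the
#' conductivity outside the outermost surface (air, normally 0).
#'
#' @slot surfaces list of meshes, each `list(vertices = n x 3, faces = m x 3)`
#'   with outward-oriented faces, innermost first.
#' @slot conductivities numeric of length `length(surfaces) + 1`: inside
#'   surface 1, ..., inside surface K, outside surface K (S/m).
#' @exportClass HeadModel
setClass("HeadModel",
  representation(surfaces = "list", conductivities = "numeric"))

setValidity("HeadModel", function(object) {
  k <- length(object@surfaces)
  if (k < 1L) return("at least one surface is required")
  if (length(object@conductivities) != k + 1L)
    return("conductivities must have length(surfaces) + 1 entries")
  if (any(object@conductivities < 0)) return("conductivities must be >= 0")
  for (s in object@surfaces) {
    if (!is.list(s) || is.null(s$vertices) || is.null(s$faces))
      return("each surface must be list(vertices, faces)")
    if (!meshIsClosed(s)) return("all surfaces must be closed")
  }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      d <- .pointMeshDistance(object@surfaces[[i]]$vertices,
                              object@surfaces[[i + 1L]]$vertices,
                              object@surfaces[[i + 1L]]$faces)
      inside <- pointsInMesh(object@surfaces[[i]]$vertices,
                             object@surfaces[[i + 1L]])
      if (!all(inside) || any(d <= 0))
        return("surfaces must be properly nested (innermost first)")
    }
  }
  TRUE
})

#' Electrode montage on the scalp
#'
#' @slot labels character, unique electrode labels.
#' @slot positions numeric matrix (n x 3), electrode positions (mm).
#' @slot system character, `"1010"`, `"1020"` or `"custom"`.
#' @exportClass ElectrodeMontage
setClass("ElectrodeMontage",
  representation(labels = "character", positions = "matrix",
                 system = "character"))

setValidity("ElectrodeMontage", function(object) {
  if (nrow(object@positions) != length(object@labels))
    return("one position per label is required")
  if (anyDuplicated(object@labels)) return("electrode labels must be unique")
  if (ncol(object@positions) != 3L) return("positions must be n x 3")
  TRUE
})

#' Scalp voltage topography
#'
#' Per-electrode voltages (uV): either a full time series (n_elec x n_t
#' matrix) or a static map (single column), for a condition or a contrast.
#'
#' @slot labels character, electrode labels (montage reference).
#' @slot positions numeric matrix (n x 3), electrode positions (mm).
#' @slot values numeric matrix (n_elec x n_t), uV.
#' @slot dt numeric, sample interval in ms (0 for a static map).
#' @slot condition character tag, e.g. `"contra"`, `"ipsi"`, `"difference"`.
#' @exportClass ScalpTopography
setClass("ScalpTopography",
  representation(labels = "character", positions = "matrix",
                 values = "matrix", dt = "numeric", condition = "character"),
  prototype(condition = "unspecified", dt = 0))

setValidity("ScalpTopography", function(object) {
  if (nrow(object@values) != length(object@labels))
    return("electrode count must match the montage labels")
  if (nrow(object@positions) != length(object@labels))
    return("one position per electrode is required")
  TRUE
})

#' Ranking of multi-dipole source configurations against an empirical map
#'
#' @slot table data.frame with one row per configuration: members, r, R2,
#'   p-value and Bonferroni-corrected significance, sorted by decreasing R2.
#' @slot winner character, member sources of the best configuration.
#' @slot alpha numeric, family-wise significance level.
#' @slot nSessions integer, sessions pooled into each correlation.
#' @exportClass ConfigurationRanking
setClass("ConfigurationRanking",
  representation(table = "data.frame", winner = "character", alpha = "numeric",
                 nSessions = "integer"))

setValidity("ConfigurationRanking", function(object) {
  need <- c("configuration", "r", "R2", "p", "significant")
  if (!all(need %in% names(object@table)))
    return("ranking table is missing required columns")
  TRUE
})
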