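# Generics for accessors shared across the data classes.

#' Electrode or grid depths below the pia (mm)
#' @param x a \linkS4class{LaminarRecording} or \linkS4class{CSDProfile}
#' @return numeric vector of depths (mm below pia)
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' Sampling interval in ms
#' @param x an object with a time axis
#' @return numeric scalar (ms)
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' Time axis in ms (first sample at 0)
#' @param x an object with a time axis
#' @return numeric vector of sample times (ms)
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' LFP matrix (electrodes x time, mV)
#' @param x a \linkS4class{LaminarRecording}
#' @return numeric matrix
#' @export
setGeneric("lfpValues", function(x) standardGeneric("lfpValues"))

#' CSD matrix (depth x time, uA/mm^3)
#' @param x a \linkS4class{CSDProfile}
#' @return numeric matrix
#' @export
setGeneric("csdValues", function(x) standardGeneric("csdValues"))

#' Dipole moment time series (3 x n_t, nA*m)
#' @param x a \linkS4class{DipoleSource}
#' @return numeric matrix
#' @export
setGeneric("momentValues", function(x) standardGeneric("momentValues"))

#' Scalar dipole amplitude time series d(t) (nA*m)
#'
#' For fixed-orientation (CSD) dipoles this is the signed amplitude along the
#' orientation; otherwise the Euclidean norm of the moment.
#' @param x a \linkS4class{DipoleSource}
#' @return numeric vector
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' Compartment transmembrane currents (ncomp x n_t, nA)
#' @param x a \linkS4class{CompartmentCurrentSet}
#' @return numeric matrix
#' @export
setGeneric("compartmentCurrents", function(x) standardGeneric("compartmentCurrents"))

#' Compartment center coordinates (ncomp x 3, mm)
#' @param x a \linkS4class{CompartmentCurrentSet}
#' @return numeric matrix
#' @export
setGeneric("compartmentCoords", function(x) standardGeneric("compartmentCoords"))

#' Surfaces of a head model (innermost first)
#' @param x a \linkS4class{HeadModel}
#' @return list of meshes
#' @export
setGeneric("surfaces", function(x) standardGeneric("surfaces"))

#' Compartment conductivities of a head model (S/m)
#' @param x a \linkS4class{HeadModel}
#' @return numeric vector, inside surface 1 ... outside outermost surface
#' @export
setGeneric("conductivities", function(x) standardGeneric("conductivities"))

#' Electrode labels
#' @param x an \linkS4class{ElectrodeMontage} or \linkS4class{ScalpTopography}
#' @return character vector
#' @export
setGeneric("electrodeLabels", function(x) standardGeneric("electrodeLabels"))

#' Electrode positions (n x 3, mm)
#' @param x an \linkS4class{ElectrodeMontage} or \linkS4class{ScalpTopography}
#' @return numeric matrix
#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))

#' Topography voltage values (n_elec x n_t, uV)
#' @param x a \linkS4class{ScalpTopography}
#' @return numeric matrix
#' @export
setGeneric("topoValues", function(x) standardGeneric("topoValues"))

#' Condition tag of a topography
#' @param x a \linkS4class{ScalpTopography}
#' @return character scalar
#' @export
setGeneric("conditionTag", function(x) standardGeneric("conditionTag"))

#' Subtract a per-channel baseline window mean
#' @param x a \linkS4class{CSDProfile} or \linkS4class{LaminarRecording}
#' @param window numeric length-2, baseline window in ms on the time axis
#' @return an object of the same class
#' @export
setGeneric("baselineCorrect", function(x, window) standardGeneric("baselineCorrect"))

#' Remove samples from an event time onward (minus a safety lead)
#' @param x a \linkS4class{CSDProfile} or \linkS4class{LaminarRecording}
#' @param eventTime event time in ms on the object's time axis
#' @param lead safety lead in ms removed before the event (default 10)
#' @return an object of the same class, clipped in time
#' @export
setGeneric("clipAtEvent", function(x, eventTime, lead = 10) standardGeneric("clipAtEvent"))

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, unit DC
#' gain).
#' @param x a \linkS4class{LaminarRecording}, \linkS4class{DipoleSource} or a
#'   numeric matrix with one signal per row
#' @param cutoff cutoff frequency in Hz (default 100)
#' @param dt sample interval in ms (only needed for plain matrices)
#' @return an object of the same class, filtered
#' @export
setGeneric("lowpassFilter", function(x, cutoff = 100, dt = NULL) standardGeneric("lowpassFilter"))
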