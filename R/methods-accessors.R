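# Accessor and show methods.

#' @rdname depths
#' @export
setMethod("depths", "LaminarRecording", function(x) x@depths)

#' @rdname depths
#' @export
setMethod("depths", "CSDProfile", function(x) x@depths)

#' @rdname timeStep
#' @export
setMethod("timeStep", "LaminarRecording", function(x) x@dt)

#' @rdname timeStep
#' @export
setMethod("timeStep", "CSDProfile", function(x) x@dt)

#' @rdname timeStep
#' @export
setMethod("timeStep", "DipoleSource", function(x) x@dt)

#' @rdname timeStep
#' @export
setMethod("timeStep", "CompartmentCurrentSet", function(x) x@dt)

#' @rdname timeAxis
#' @export
setMethod("timeAxis", "LaminarRecording", function(x) timeAxisOf(ncol(x@lfp), x@dt))

#' @rdname timeAxis
#' @export
setMethod("timeAxis", "CSDProfile", function(x) timeAxisOf(ncol(x@csd), x@dt))

#' @rdname timeAxis
#' @export
setMethod("timeAxis", "DipoleSource", function(x) timeAxisOf(ncol(x@moment), x@dt))

#' @rdname timeAxis
#' @export
setMethod("timeAxis", "CompartmentCurrentSet",
          function(x) timeAxisOf(ncol(x@currents), x@dt))

#' @rdname lfpValues
#' @export
setMethod("lfpValues", "LaminarRecording", function(x) x@lfp)

#' @rdname csdValues
#' @export
setMethod("csdValues", "CSDProfile", function(x) x@csd)

#' @rdname momentValues
#' @export
setMethod("momentValues", "DipoleSource", function(x) x@moment)

#' @rdname amplitude
#' @export
setMethod("amplitude", "DipoleSource", function(x) {
  if (length(x@orientation) == 3L) as.numeric(crossprod(x@orientation, x@moment))
  else sqrt(colSums(x@moment^2))
})

#' @rdname compartmentCurrents
#' @export
setMethod("compartmentCurrents", "CompartmentCurrentSet", function(x) x@currents)

#' @rdname compartmentCoords
#' @export
setMethod("compartmentCoords", "CompartmentCurrentSet", function(x) x@coords)

#' @rdname surfaces
#' @export
setMethod("surfaces", "HeadModel", function(x) x@surfaces)

#' @rdname conductivities
#' @export
setMethod("conductivities", "HeadModel", function(x) x@conductivities)

#' @rdname electrodeLabels
#' @export
setMethod("electrodeLabels", "ElectrodeMontage", function(x) x@labels)

#' @rdname electrodeLabels
#' @export
setMethod("electrodeLabels", "ScalpTopography", function(x) x@labels)

#' @rdname electrodePositions
#' @export
setMethod("electrodePositions", "ElectrodeMontage", function(x) x@positions)

#' @rdname electrodePositions
#' @export
setMethod("electrodePositions", "ScalpTopography", function(x) x@positions)

#' @rdname topoValues
#' @export
setMethod("topoValues", "ScalpTopography", function(x) x@values)

#' @rdname conditionTag
#' @export
setMethod("conditionTag", "ScalpTopography", function(x) x@condition)

setMethod("show", "ReducedNeuron", function(object) {
  cat(sprintf("ReducedNeuron (%s): %d compartments, soma depth %.3f mm, apical extent %.3f mm\n",
              object@cellClass, nrow(object@centers), object@somaDepth,
              max(object@centers[, 3]) - object@centers[1, 3]))
})

setMethod("show", "CompartmentCurrentSet", function(object) {
  cat(sprintf("CompartmentCurrentSet: %d compartments, %d neurons (%s), %d samples at dt = %g ms\n",
              nrow(object@coords), length(unique(object@neuron)),
              paste(sprintf("%s: %d", names(table(object@population[!duplicated(object@neuron)])),
                            table(object@population[!duplicated(object@neuron)])),
                    collapse = ", "),
              ncol(object@currents), object@dt))
})

setMethod("show", "LaminarRecording", function(object) {
  cat(sprintf("LaminarRecording: %d electrodes (%.2f-%.2f mm below pia), %d samples at dt = %g ms, sigma = %g S/m\n",
              length(object@depths), min(object@depths), max(object@depths),
              ncol(object@lfp), object@dt, object@sigma))
})

setMethod("show", "CSDProfile", function(object) {
  cat(sprintf("CSDProfile (%s): %d depth points (%.2f-%.2f mm), %d samples at dt = %g ms\n",
              object@method, length(object@depths), min(object@depths),
              max(object@depths), ncol(object@csd), object@dt))
})

setMethod("show", "DipoleSource", function(object) {
  amp <- amplitude(object)
  cat(sprintf("DipoleSource (%s): position (%.1f, %.1f, %.1f) mm, rc = %g mm, peak |d| = %.3g nA*m over %d samples\n",
              object@method, object@position[1], object@position[2],
              object@position[3], object@rc, max(abs(amp)), length(amp)))
})

setMethod("show", "HeadModel", function(object) {
  k <- length(object@surfaces)
  cat(sprintf("HeadModel: %d nested surfaces (%s faces), conductivities %s S/m\n",
              k, paste(vapply(object@surfaces, function(s) nrow(s$faces), 1L),
                       collapse = "/"),
              paste(signif(object@conductivities, 3), collapse = "/")))
})

setMethod("show", "ElectrodeMontage", function(object) {
  cat(sprintf("ElectrodeMontage (%s): %d electrodes\n", object@system,
              length(object@labels)))
})

setMethod("show", "ScalpTopography", function(object) {
  cat(sprintf("ScalpTopography (%s): %d electrodes x %d samples (uV)\n",
              object@condition, length(object@labels), ncol(object@values)))
})

setMethod("show", "ConfigurationRanking", function(object) {
  cat(sprintf("ConfigurationRanking: %d configurations, winner = {%s} (R2 = %.3f)\n",
              nrow(object@table), paste(object@winner, collapse = ", "),
              object@table$R2[1]))
})
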