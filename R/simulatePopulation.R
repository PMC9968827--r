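# Passive cable simulation of the population with stereotyped event currents.
#
# The cable is linear, and stimulus onsets are snapped to the sample grid, so
# each distinct cell geometry needs only three Crank-Nicolson solves (unit
# pulse, Na transient, Ca transient); per-neuron responses are amplitude-scaled,
# time-shifted copies. Injected currents are booked as transmembrane currents:
# the reported compartment current is -G_axial * V, whose compartment sum is
# zero to machine precision for every neuron (no spurious monopoles).

#' @noRd
cableMatrices <- function(neuron) {
  n <- nrow(neuron@centers)
  rCm <- neuron@radii * 0.1        # mm -> cm
  lCm <- neuron@lengths * 0.1
  area <- 2 * pi * rCm * lCm       # cm^2
  Cn <- neuron@membrane$cm * area * 1e3      # uF/cm^2 * cm^2 -> nF
  gL <- area / neuron@membrane$rm * 1e6      # S -> uS
  Gax <- matrix(0, n, n)
  for (c_ in which(neuron@parent > 0L)) {
    p <- neuron@parent[c_]
    res <- neuron@membrane$ra * (lCm[c_] / 2) / (pi * rCm[c_]^2) +
           neuron@membrane$ra * (lCm[p] / 2) / (pi * rCm[p]^2)   # Ohm
    g <- 1 / res * 1e6                                           # uS
    Gax[c_, c_] <- Gax[c_, c_] + g
    Gax[p, p] <- Gax[p, p] + g
    Gax[c_, p] <- Gax[c_, p] - g
    Gax[p, c_] <- Gax[p, c_] - g
  }
  list(C = Cn, gL = gL, Gax = Gax)
}

#' Crank-Nicolson solve for injected-current matrix Iinj (ncomp x nt, nA).
#' Returns transmembrane currents (nA) and the soma voltage trace (mV).
#' @noRd
cableSolve <- function(mats, Iinj, dt) {
  n <- length(mats$C)
  nt <- ncol(Iinj)
  G <- mats$Gax + diag(mats$gL, n)
  A1 <- diag(mats$C / dt, n) + G / 2
  A2 <- diag(mats$C / dt, n) - G / 2
  A1inv <- solve(A1)
  M <- A1inv %*% A2
  V <- matrix(0, n, nt)
  for (k in seq_len(nt - 1L)) {
    imid <- (Iinj[, k] + Iinj[, k + 1L]) / 2
    V[, k + 1L] <- M %*% V[, k] + A1inv %*% imid
  }
  if (any(!is.finite(V))) stop("unstable cable solve")
  list(currents = -mats$Gax %*% V, somaV = V[1, ])
}

#' @noRd
geometryTemplates <- function(neuron, nt, dt, stimDuration, naAmplitude,
                              caPeak, cache) {
  key <- paste(neuron@cellClass, nrow(neuron@centers),
               format(sum(neuron@lengths), digits = 10), sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  mats <- cableMatrices(neuron)
  n <- nrow(neuron@centers)
  tt <- timeAxisOf(nt, dt)

  pulseI <- matrix(0, n, nt)
  pulseI[1, tt < stimDuration] <- 1          # unit 1 nA pulse from t = 0
  pulse <- cableSolve(mats, pulseI, dt)

  naI <- matrix(0, n, nt)
  naI[1, tt < 1] <- naAmplitude              # 2 ms biphasic somatic transient
  naI[1, tt >= 1 & tt < 2] <- -naAmplitude
  na <- cableSolve(mats, naI, dt)

  ca <- NULL
  if (neuron@cellClass == "L5" && n >= 4L) {
    caI <- matrix(0, n, nt)                  # 40 ms triangular inward current
    shape <- pmax(0, pmin(tt / 15, (40 - tt) / 25)) * caPeak / 3
    distal <- (n - 2L):n
    for (d in distal) caI[d, ] <- shape
    ca <- cableSolve(mats, caI, dt)
  }
  tpl <- list(pulse = pulse$currents, somaV = pulse$somaV,
              na = na$currents, ca = if (is.null(ca)) NULL else ca$currents)
  cache[[key]] <- tpl
  tpl
}

#' Simulate compartment transmembrane currents for a placed population
#'
#' Each neuron receives a somatic current pulse (duration, Gaussian amplitude
#' and uniform onset drawn per `stim`), solved on its passive cable by
#' unconditionally stable Crank-Nicolson stepping. Somatic Na events are
#' emulated as stereotyped 2 ms biphasic transmembrane transients triggered
#' when the somatic depolarization crosses `naThreshold` (with a refractory
#' period); for L5 cells a dendritic Ca event - a 40 ms triangular inward
#' current at the distal three compartments, with return currents distributed
#' by the cable - is triggered when the somatic drive exceeds `caThreshold`.
#' Raising the stimulus mean therefore never decreases the expected number of
#' L5 Ca events. All injected currents are booked as transmembrane currents,
#' so per-neuron currents sum to zero at every sample.
#'
#' @param neurons list of positioned \linkS4class{ReducedNeuron} objects
#'   (see [placePopulation()]).
#' @param stim a \linkS4class{StimulusSpec}.
#' @param duration simulated span, ms (default 120: onset window + pulse +
#'   Ca tail). Must cover `max(onsetWindow) + duration(pulse) + 60`.
#' @param dt time step, ms (must be <= 0.1; default 0.1).
#' @param events logical; disable to obtain the purely passive (linear)
#'   response.
#' @param naThreshold somatic depolarization threshold for Na events, mV.
#' @param naRefractory Na refractory period, ms.
#' @param naAmplitude amplitude of the biphasic Na transient, nA.
#' @param caThreshold somatic drive (pulse amplitude) threshold for L5 Ca
#'   events, nA.
#' @param caLatency delay from pulse onset to the Ca event, ms.
#' @param caPeak peak amplitude of the triangular Ca current, nA.
#' @return a \linkS4class{CompartmentCurrentSet}
#' @examples
#' pop <- placePopulation(new("PopulationSpec", nL3 = 3L, nL5 = 2L), seed = 1)
#' cs <- simulatePopulation(pop, new("StimulusSpec", seed = 1L))
#' max(abs(colSums(compartmentCurrents(cs))))  # ~0 (charge conservation)
#' @export
simulatePopulation <- function(neurons, stim = new("StimulusSpec"),
                               duration = 120, dt = 0.1, events = TRUE,
                               naThreshold = 20, naRefractory = 5,
                               naAmplitude = 2, caThreshold = 2,
                               caLatency = 12, caPeak = 2.5) {
  if (!length(neurons)) stop("empty population")
  validObject(stim)
  if (dt > 0.1 + 1e-12) stop("dt must be <= 0.1 ms")
  if (duration < max(stim@onsetWindow) + stim@duration + 60)
    stop("duration must cover the onset window + pulse + 60 ms tail")
  nt <- as.integer(round(duration / dt)) + 1L
  nn <- length(neurons)

  draws <- withSeed(stim@seed, {
    list(onset = runif(nn, stim@onsetWindow[1], stim@onsetWindow[2]),
         z = rnorm(nn))
  })
  amp <- stim@meanAmplitude + stim@sdAmplitude * draws$z

  cache <- new.env(parent = emptyenv())
  ncomp <- vapply(neurons, function(nr) nrow(nr@centers), 1L)
  total <- sum(ncomp)
  coords <- matrix(0, total, 3)
  currents <- matrix(0, total, nt)
  radii <- numeric(total)
  neuronId <- integer(total)
  population <- character(total)
  naEvents <- vector("list", nn)
  caEvents <- vector("list", nn)

  off <- 0L
  for (i in seq_len(nn)) {
    nr <- neurons[[i]]
    n <- ncomp[i]
    idx <- off + seq_len(n)
    coords[idx, ] <- nr@centers
    radii[idx] <- nr@radii
    neuronId[idx] <- i
    population[idx] <- nr@cellClass

    tpl <- geometryTemplates(nr, nt, dt, stim@duration, naAmplitude, caPeak,
                             cache)
    k <- as.integer(round(draws$onset[i] / dt))
    cur <- matrix(0, n, nt)
    if (amp[i] != 0) cur <- amp[i] * shiftColumns(tpl$pulse, k)

    naEvents[[i]] <- numeric(0)
    caEvents[[i]] <- numeric(0)
    if (events && amp[i] > 0) {
      v <- amp[i] * tpl$somaV
      above <- v >= naThreshold
      cross <- which(above[-1] & !above[-length(above)]) + 1L
      keep <- numeric(0)
      for (cidx in cross) {
        if (!length(keep) || (cidx - keep[length(keep)]) * dt >= naRefractory)
          keep <- c(keep, cidx)
      }
      for (cidx in keep) cur <- cur + shiftColumns(tpl$na, k + cidx - 1L)
      naEvents[[i]] <- (k + keep - 1L) * dt
      if (!is.null(tpl$ca) && amp[i] > caThreshold) {
        kc <- k + as.integer(round(caLatency / dt))
        cur <- cur + shiftColumns(tpl$ca, kc)
        caEvents[[i]] <- kc * dt
      }
    }
    currents[idx, ] <- cur
    off <- off + n
  }

  new("CompartmentCurrentSet", coords = coords, currents = currents,
      radii = radii, neuron = neuronId, population = population, dt = dt,
      naEvents = naEvents, caEvents = caEvents, seed = stim@seed)
}

#' Count dendritic Ca events in a simulated current set
#'
#' @param currents a \linkS4class{CompartmentCurrentSet}
#' @return integer, total number of L5 Ca events
#' @export
countCaEvents <- function(currents) {
  sum(lengths(currents@caEvents))
}
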