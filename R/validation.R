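# Validation experiment: compare dipole-based EEG estimates against the
# compartment-based ground truth across random cortical sites.

#' Compare STC- and CSD-dipole EEG against compartment-based ground truth
#'
#' For a simulated column, computes three scalp EEG estimates at each of
#' `nSites` randomly selected cortical sites: (i) the compartment-based
#' ground truth (every transmembrane current as a monopole source in the
#' BEM), (ii) the summed-transmembrane-current (STC) single dipole and
#' (iii) the CSD single dipole estimated from the laminar LFP via spline
#' iCSD. Agreement with the ground truth is quantified per site by RDM and
#' MAG over the pooled electrode-by-time samples, and each metric is
#' regressed on the column depth below the scalp.
#'
#' All signals are low-pass filtered at `cutoff` Hz; the EEG time axis is
#' decimated by `downsample` after filtering (the metrics are insensitive to
#' consistent decimation). Real cortical columns sampled across a folded
#' brain vary in their depth below the scalp and in the orientation of the
#' column axis relative to the cranial surface; on a spherical cortex both
#' would otherwise be constant, so each site embeds the column's pial
#' surface at a depth drawn uniformly from `embedDepthRange` and tilts the
#' column axis away from the surface normal by an angle drawn uniformly from
#' `tiltRange` (about a random tangent axis, seeded).
#'
#' @param currents column-local compartment currents (from
#'   [simulatePopulation()]): either one \linkS4class{CompartmentCurrentSet}
#'   reused at every site, or a list with one per site - fifteen randomly
#'   selected columns are fifteen different columns, each with its own cell
#'   placement and stimulus realization.
#' @param model a \linkS4class{HeadModel} (default: nested 30/35/38 mm
#'   spheres at icosphere level 3).
#' @param nSites number of random cortical sites (default 5).
#' @param seed RNG seed for site selection.
#' @param rc column radius for the dipole models, mm.
#' @param electrodes laminar electrode positions for the CSD pathway.
#' @param diameter spline-iCSD source diameter, mm.
#' @param cutoff low-pass cutoff, Hz.
#' @param downsample decimation factor for the EEG time axis.
#' @param embedDepthRange range (mm) of the per-site depth of the column's
#'   pial surface below the cortical site.
#' @param tiltRange range (degrees) of the per-site tilt of the column axis
#'   away from the surface normal.
#' @param montageSystem montage used for the scalp comparison.
#' @return list with `table` (per-site depth, RDM and MAG for both
#'   approaches), `regressions` (per metric: slope and R-squared on depth)
#'   and `means`.
#' @export
compareDipoleApproaches <- function(currents, model = buildNestedSpheres(),
                                    nSites = 5, seed = 1L, rc = 1.5,
                                    electrodes = laminarElectrodes(),
                                    diameter = 3, cutoff = 100,
                                    downsample = 5L,
                                    embedDepthRange = c(1.5, 8),
                                    tiltRange = c(0, 45),
                                    montageSystem = "1010") {
  op <- bemOperator(model)
  montage <- placeMontage(model, montageSystem)
  cortex <- model@surfaces[[1]]
  scalp <- model@surfaces[[length(model@surfaces)]]

  # filter in the column frame; all downstream signals stay consistent
  prepare <- function(cs) {
    filtered <- cs
    filtered@currents <- lowpassFilter(cs@currents, cutoff, cs@dt)
    rec <- lfpPointSource(filtered, electrodes)
    icsd <- splineICSD(rec, diameter = diameter)
    zRef <- (min(rec@depths) + max(rec@depths)) / 2
    list(filtered = filtered,
         dCSD = dipoleFromCSD(icsd, rc = rc, zRef = zRef),
         dSTC = dipoleFromSTC(filtered, rm = c(0, 0, -zRef), rc = rc))
  }
  shared <- is(currents, "CompartmentCurrentSet")
  if (shared) {
    prepShared <- prepare(currents)
  } else {
    currents <- rep_len(currents, nSites)
  }

  sites <- randomColumnSites(cortex, nSites, seed = seed)
  draws <- withSeed(seed + 1L, list(
    embed = runif(nSites, embedDepthRange[1], embedDepthRange[2]),
    tilt = runif(nSites, tiltRange[1], tiltRange[2]) * pi / 180,
    tangentPhi = runif(nSites, 0, 2 * pi)))
  rows <- vector("list", nSites)
  for (s in seq_len(nSites)) {
    n0 <- sites$orientations[s, ]
    pos <- sites$positions[s, ] - draws$embed[s] * n0
    # tilt the column axis about a random tangent axis
    t1 <- if (abs(n0[1]) < 0.9) unitVector(c(1, 0, 0) - n0[1] * n0)
          else unitVector(c(0, 1, 0) - n0[2] * n0)
    t2 <- c(n0[2] * t1[3] - n0[3] * t1[2], n0[3] * t1[1] - n0[1] * t1[3],
            n0[1] * t1[2] - n0[2] * t1[1])
    tang <- cos(draws$tangentPhi[s]) * t1 + sin(draws$tangentPhi[s]) * t2
    nrm <- unitVector(cos(draws$tilt[s]) * n0 + sin(draws$tilt[s]) * tang)

    p <- if (shared) prepShared else prepare(currents[[s]])
    keep <- seq(1L, ncol(p$filtered@currents), by = downsample)
    placed <- p$filtered
    placed@coords <- placeAtSite(p$filtered@coords, pos, nrm)
    placed@currents <- placed@currents[, keep, drop = FALSE]
    gt <- bemSolve(op, placed, montage, condition = "ground-truth")

    solveDip <- function(d, tag) {
      d@moment <- d@moment[, keep, drop = FALSE]
      bemSolve(op, placeAtSite(d, pos, nrm), montage, condition = tag)
    }
    tSTC <- solveDip(p$dSTC, "STC-dipole")
    tCSD <- solveDip(p$dCSD, "CSD-dipole")

    com <- colMeans(placed@coords)
    rows[[s]] <- data.frame(
      site = s, depth = columnDepth(scalp, com),
      rdm_stc = rdm(topoValues(gt), topoValues(tSTC)),
      rdm_csd = rdm(topoValues(gt), topoValues(tCSD)),
      mag_stc = mag(topoValues(gt), topoValues(tSTC)),
      mag_csd = mag(topoValues(gt), topoValues(tCSD)))
  }
  tab <- do.call(rbind, rows)
  regs <- lapply(c(rdm_stc = "rdm_stc", rdm_csd = "rdm_csd",
                   mag_stc = "mag_stc", mag_csd = "mag_csd"),
                 function(mcol) depthRegression(tab$depth, tab[[mcol]]))
  list(table = tab, regressions = regs,
       means = colMeans(tab[, c("rdm_stc", "rdm_csd", "mag_stc", "mag_csd")]))
}

#' Lateralized two-column EEG simulation (attention asymmetry)
#'
#' Simulates one cortical column per hemisphere at mirrored posterior sites.
#' In condition A the left-hemisphere column receives the stronger mean
#' stimulus (`meanStrong`, default 1.90 nA) and the right column the weaker
#' one (`meanWeak`, default 1.85 nA); condition B mirrors the assignment.
#' The weaker drive recruits fewer L5 Ca events, yielding a weaker dipole,
#' and the condition difference map is sign-lateralized over posterior
#' electrodes. Dipoles use the summed-transmembrane-current approach and are
#' low-pass filtered at 100 Hz.
#'
#' @param model a \linkS4class{HeadModel}.
#' @param nL3,nL5 population sizes per column.
#' @param meanStrong,meanWeak stimulus means, nA.
#' @param seed RNG seed (placement and stimulus draws derive from it).
#' @param directionLeft unit direction of the left posterior site (the right
#'   site is its x mirror).
#' @param embedDepth column embedding depth below the cortical surface, mm.
#' @param montageSystem montage for the scalp maps.
#' @return list with `difference` (static \linkS4class{ScalpTopography}:
#'   condition A minus B, extracted at the time of the largest global
#'   difference, the analog of reading an ERP component at its peak),
#'   `differenceTrace` (full time course), `peakTime` (ms), `conditionA`,
#'   `conditionB`, and the peak dipole amplitudes `ampStrong`, `ampWeak`
#'   (nA*m) of the two drives.
#' @export
simulateLateralizedEEG <- function(model = buildNestedSpheres(),
                                   nL3 = 220L, nL5 = 100L,
                                   meanStrong = 1.90, meanWeak = 1.85,
                                   seed = 1L,
                                   directionLeft = c(-0.55, -0.65, 0.52),
                                   embedDepth = 1.5,
                                   montageSystem = "1010") {
  op <- bemOperator(model)
  montage <- placeMontage(model, montageSystem)
  cortex <- model@surfaces[[1]]

  siteFor <- function(dirn) {
    dirn <- unitVector(dirn)
    iv <- which.max(cortex$vertices %*% dirn)
    pos <- cortex$vertices[iv, ]
    nrm <- orientFromMesh(cortex, pos)
    list(position = pos - embedDepth * nrm, normal = nrm)
  }
  siteL <- siteFor(directionLeft)
  siteR <- siteFor(directionLeft * c(-1, 1, 1))

  spec <- new("PopulationSpec", nL3 = as.integer(nL3), nL5 = as.integer(nL5))
  columnDipole <- function(placeSeed, stimSeed, meanAmp) {
    pop <- placePopulation(spec, seed = placeSeed)
    cs <- simulatePopulation(pop, new("StimulusSpec", meanAmplitude = meanAmp,
                                      seed = as.integer(stimSeed)))
    lowpassFilter(dipoleFromSTC(cs))
  }
  # per-column stimulus draws are paired across conditions (same seeds)
  dLstrong <- columnDipole(seed + 1L, seed + 3L, meanStrong)
  dLweak <- columnDipole(seed + 1L, seed + 3L, meanWeak)
  dRstrong <- columnDipole(seed + 2L, seed + 4L, meanStrong)
  dRweak <- columnDipole(seed + 2L, seed + 4L, meanWeak)

  solveAt <- function(d, site, tag)
    bemSolve(op, placeAtSite(d, site$position, site$normal), montage,
             condition = tag)
  condA <- sumTopographies(list(solveAt(dLstrong, siteL, "contra"),
                                solveAt(dRweak, siteR, "contra")),
                           condition = "contra")
  condB <- sumTopographies(list(solveAt(dLweak, siteL, "ipsi"),
                                solveAt(dRstrong, siteR, "ipsi")),
                           condition = "ipsi")
  diffTrace <- differenceTopography(condA, condB)
  v <- topoValues(diffTrace)
  tstar <- which.max(colSums(v^2))
  diffMap <- diffTrace
  diffMap@values <- v[, tstar, drop = FALSE]
  diffMap@dt <- 0
  list(difference = diffMap, differenceTrace = diffTrace,
       peakTime = (tstar - 1) * diffTrace@dt,
       conditionA = condA, conditionB = condB,
       ampStrong = max(abs(amplitude(dLstrong))),
       ampWeak = max(abs(amplitude(dLweak))),
       sites = list(left = siteL, right = siteR))
}

#' Model-selection recovery experiment
#'
#' Monte-Carlo check of [rankAgainstEmpirical()]: `nSources` candidate
#' dipole sources are placed at seeded random cortical sites (upper
#' hemisphere, mutually separated, emulating distinct cortical areas under
#' the electrode cap). Because a single measured dipole waveform is applied
#' to every candidate area, session-to-session amplitude variability is a
#' common multiplicative factor shared by all sources within a session;
#' per-session modeled maps are therefore the lead fields scaled by one
#' jittered session amplitude. A pseudo-empirical map is generated from a
#' known subset of the sources plus Gaussian electrode noise at the given
#' signal-to-noise ratio (RMS amplitude ratio: noise SD = map SD / `snr`),
#' and the experiment records how often the generating subset attains the
#' top R-squared.
#'
#' @param model a \linkS4class{HeadModel}.
#' @param nSources number of candidate sources (default 5).
#' @param trueSubset indices of the generating sources (default 1:3).
#' @param nSessions sessions per source (default 30).
#' @param snr signal-to-noise ratio of the pseudo-empirical map, as the RMS
#'   amplitude ratio between the noiseless map and the added noise
#'   (default 5).
#' @param sessionJitter SD of the multiplicative per-session amplitude
#'   jitter (default 0.2).
#' @param nReplicates Monte-Carlo replicates (default 100).
#' @param seed RNG seed.
#' @param embedDepth source depth below the cortical surface, mm.
#' @param montageSystem montage (default the 15-electrode array).
#' @param minSeparation minimum pairwise angular separation of the candidate
#'   sources in degrees (default 35), with sources restricted to the upper
#'   hemisphere: the candidates emulate distinct cortical areas under the
#'   electrode cap rather than arbitrary points, which can be electrically
#'   indistinguishable at 15 electrodes.
#' @return list with `recoveryRate`, `nConfigurations`, `pointsPerCorrelation`
#'   and the last replicate's \linkS4class{ConfigurationRanking}.
#' @export
modelRecoveryExperiment <- function(model = buildNestedSpheres(),
                                    nSources = 5, trueSubset = 1:3,
                                    nSessions = 30, snr = 5,
                                    sessionJitter = 0.2, nReplicates = 100,
                                    seed = 1L, embedDepth = 1.5,
                                    montageSystem = "1020",
                                    minSeparation = 35) {
  op <- bemOperator(model)
  montage <- placeMontage(model, montageSystem)
  cortex <- model@surfaces[[1]]

  # seeded greedy selection: upper-hemisphere vertices, pairwise separation
  center <- colMeans(cortex$vertices)
  vdir <- sweep(cortex$vertices, 2L, center)
  vdir <- vdir / sqrt(rowSums(vdir^2))
  upper <- which(vdir[, 3] > 0.2)
  perm <- withSeed(seed, sample(upper))
  chosen <- integer(0)
  cosMin <- cos(minSeparation * pi / 180)
  for (iv in perm) {
    if (length(chosen) == nSources) break
    if (!length(chosen) || all(vdir[chosen, , drop = FALSE] %*% vdir[iv, ] < cosMin))
      chosen <- c(chosen, iv)
  }
  if (length(chosen) < nSources)
    stop("could not place that many separated sources; lower minSeparation")
  sites <- list(positions = cortex$vertices[chosen, , drop = FALSE],
                orientations = t(vapply(chosen, function(iv)
                  orientFromMesh(cortex, cortex$vertices[iv, ]), numeric(3))))
  labels <- paste0("S", seq_len(nSources))

  lead <- vapply(seq_len(nSources), function(j) {
    pos <- sites$positions[j, ] - embedDepth * sites$orientations[j, ]
    dip <- new("DipoleSource", position = pos,
               moment = matrix(sites$orientations[j, ], 3L, 1L),
               orientation = sites$orientations[j, ], dt = 0, rc = 1.5,
               method = "CSD")
    as.numeric(topoValues(bemSolve(op, dip, montage)))
  }, numeric(length(montage@labels)))          # nelec x nSources, uV/(nA*m)

  trueMap <- rowSums(lead[, trueSubset, drop = FALSE])
  noiseSD <- sd(trueMap) / snr
  wins <- 0L
  lastRanking <- NULL
  withSeed(seed + 1L, {
    for (rep_ in seq_len(nReplicates)) {
      jit <- 1 + sessionJitter * rnorm(nSessions)   # shared across sources
      modeled <- lapply(seq_len(nSources), function(j) outer(lead[, j], jit))
      names(modeled) <- labels
      empirical <- trueMap + rnorm(length(trueMap), 0, noiseSD)
      rk <- rankAgainstEmpirical(modeled, empirical)
      if (setequal(rk@winner, labels[trueSubset])) wins <- wins + 1L
      lastRanking <- rk
    }
  })
  list(recoveryRate = wins / nReplicates,
       nConfigurations = nrow(lastRanking@table),
       pointsPerCorrelation = length(montage@labels) * as.integer(nSessions),
       ranking = lastRanking)
}
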