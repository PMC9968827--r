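# End-to-end pipeline: simulate -> LFP -> CSD -> dipole -> forward -> metrics.

#' Default pipeline configuration
#'
#' Returns the default configuration of the forward-modeling chain: the
#' two-population column (2200 L3 + 1000 L5 cells, 3 mm diameter), 30 ms
#' noisy current pulses (SD 0.3 nA), a 17-contact laminar array at 100 um
#' spacing, 100 Hz low-pass, spline-iCSD with a 3 mm source disk, a 1.5 mm
#' column radius for the CSD dipole, nested 30/35/38 mm spheres with
#' conductivities 0.33/0.0063/0.43 S/m, and the 61-channel montage.
#'
#' @return a nested list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(seed = 1L,
       population = list(nL3 = 2200L, nL5 = 1000L, columnRadius = 1.5),
       stimulus = list(meanAmplitude = 1.9, sdAmplitude = 0.3, duration = 30,
                       onsetWindow = c(10, 20)),
       duration = 120, dt = 0.1,
       electrodes = list(n = 17L, spacing = 0.1, top = 0.1),
       filter = list(cutoff = 100),
       csd = list(method = "spline", diameter = 3, lambda = 0),
       dipole = list(rc = 1.5),
       head = list(radii = c(30, 35, 38), level = 3L,
                   conductivities = c(0.33, 0.0063, 0.43, 0), meshes = NULL),
       montage = list(system = "1010"),
       site = list(direction = c(0.5, -0.7, 0.5)),
       groundTruth = TRUE,
       outDir = "columnEEG-run")
}

#' @noRd
mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' @noRd
runStage <- function(name, expr) {
  tryCatch(force(expr),
           error = function(e) stop(sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)), call. = FALSE))
}

#' Run the full forward-modeling pipeline
#'
#' Executes simulate -> LFP -> CSD -> dipole (CSD and summed-transmembrane-
#' current variants) -> BEM forward model -> agreement metrics, persisting
#' every stage's outputs with checksums. Reruns with the same configuration
#' and seed are bit-identical.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]; partial
#'   lists are merged over the defaults) or the path to a YAML file with the
#'   same structure.
#' @param outDir output directory (default from the config).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  if (is.null(outDir)) outDir <- cfg$outDir
  # validate referenced files before any compute
  if (!is.null(cfg$head$meshes)) {
    missing <- cfg$head$meshes[!file.exists(unlist(cfg$head$meshes))]
    if (length(missing))
      stop("configuration references missing mesh files: ",
           paste(missing, collapse = ", "))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  head <- runStage("head-model", {
    if (!is.null(cfg$head$meshes)) {
      surfs <- lapply(cfg$head$meshes, function(p) ensureOutward(readMesh(p)))
      new("HeadModel", surfaces = surfs,
          conductivities = cfg$head$conductivities)
    } else {
      buildNestedSpheres(cfg$head$radii, cfg$head$level,
                         cfg$head$conductivities)
    }
  })
  cortex <- head@surfaces[[1]]
  site <- runStage("site", {
    dirn <- unitVector(unlist(cfg$site$direction))
    iv <- if (!is.null(cfg$site$vertexId)) as.integer(cfg$site$vertexId)
          else which.max(cortex$vertices %*% dirn)
    pos <- cortex$vertices[iv, ]
    list(position = pos, normal = orientFromMesh(cortex, pos), vertexId = iv)
  })

  currents <- runStage("simulate", {
    spec <- new("PopulationSpec", nL3 = as.integer(cfg$population$nL3),
                nL5 = as.integer(cfg$population$nL5),
                columnRadius = cfg$population$columnRadius)
    stim <- new("StimulusSpec", meanAmplitude = cfg$stimulus$meanAmplitude,
                sdAmplitude = cfg$stimulus$sdAmplitude,
                duration = cfg$stimulus$duration,
                onsetWindow = cfg$stimulus$onsetWindow, seed = seed + 1L)
    pop <- placePopulation(spec, seed = seed + 1L)
    simulatePopulation(pop, stim, duration = cfg$duration, dt = cfg$dt)
  })

  lfp <- runStage("lfp", {
    rec <- lfpPointSource(currents,
                          laminarElectrodes(cfg$electrodes$n,
                                            cfg$electrodes$spacing,
                                            cfg$electrodes$top))
    lowpassFilter(rec, cutoff = cfg$filter$cutoff)
  })
  writeRecording(lfp, file.path(outDir, "lfp.csv"), meta = list(seed = seed))

  csd <- runStage("csd", {
    if (identical(cfg$csd$method, "standard")) standardCSD(lfp)
    else splineICSD(lfp, diameter = cfg$csd$diameter, lambda = cfg$csd$lambda)
  })
  writeCSD(csd, file.path(outDir, "csd.csv"), meta = list(seed = seed))

  dipoles <- runStage("dipole", {
    zRef <- if (is.null(cfg$dipole$zRef))
      (min(depths(lfp)) + max(depths(lfp))) / 2 else cfg$dipole$zRef
    dCSD <- dipoleFromCSD(csd, rc = cfg$dipole$rc, zRef = zRef)
    dSTC <- lowpassFilter(dipoleFromSTC(currents, rm = c(0, 0, -zRef),
                                        rc = cfg$dipole$rc),
                          cutoff = cfg$filter$cutoff)
    list(csd = placeAtSite(dCSD, site$position, site$normal),
         stc = placeAtSite(dSTC, site$position, site$normal))
  })
  writeDipole(dipoles$csd, file.path(outDir, "dipole_csd"),
              meta = list(seed = seed))
  writeDipole(dipoles$stc, file.path(outDir, "dipole_stc"),
              meta = list(seed = seed))

  forward <- runStage("forward", {
    op <- bemOperator(head)
    montage <- placeMontage(head, cfg$montage$system)
    out <- list(op = op, montage = montage,
                csd = bemSolve(op, dipoles$csd, montage, condition = "CSD-dipole"),
                stc = bemSolve(op, dipoles$stc, montage, condition = "STC-dipole"))
    if (isTRUE(cfg$groundTruth)) {
      placed <- placeAtSite(currents, site$position, site$normal)
      out$gt <- bemSolve(op, placed, montage, condition = "ground-truth")
    }
    out
  })
  writeTopography(forward$csd, file.path(outDir, "topo_csd.csv"),
                  meta = list(seed = seed))
  writeTopography(forward$stc, file.path(outDir, "topo_stc.csv"),
                  meta = list(seed = seed))
  if (!is.null(forward$gt))
    writeTopography(forward$gt, file.path(outDir, "topo_gt.csv"),
                    meta = list(seed = seed))

  metrics <- runStage("metrics", {
    res <- list(seed = seed,
                depth_mm = columnDepth(head@surfaces[[length(head@surfaces)]],
                                       dipoles$stc@position),
                caEvents = countCaEvents(currents))
    if (!is.null(forward$gt)) {
      res$rdm_stc <- rdm(topoValues(forward$gt), topoValues(forward$stc))
      res$rdm_csd <- rdm(topoValues(forward$gt), topoValues(forward$csd))
      res$mag_stc <- mag(topoValues(forward$gt), topoValues(forward$stc))
      res$mag_csd <- mag(topoValues(forward$gt), topoValues(forward$csd))
    }
    res
  })
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- c("lfp.csv", "csd.csv", "dipole_csd.json", "dipole_csd.csv",
             "dipole_stc.json", "dipole_stc.csv", "topo_csd.csv",
             "topo_stc.csv", if (!is.null(forward$gt)) "topo_gt.csv",
             "metrics.json")
  manifest <- list(package = "columnEEG",
                   version = as.character(utils::packageVersion("columnEEG")),
                   seed = seed, config = cfg,
                   checksums = as.list(tools::md5sum(file.path(outDir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(currents = currents, lfp = lfp, csd = csd,
                 dipoles = dipoles, topographies = forward[c("csd", "stc", "gt")],
                 metrics = metrics, manifest = manifest, outDir = outDir))
}
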