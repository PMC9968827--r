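# Plain-text file formats for recordings, CSD profiles, topographies and
# dipoles. All writers emit commented metadata headers with explicit units
# (the chain crosses five unit systems; silent mismatch is the dominant
# failure mode), and all round-trip to 1e-12 relative precision or better.

#' @noRd
writeMetaLines <- function(con, kind, fields, meta = list()) {
  writeLines(sprintf("# columnEEG %s", kind), con)
  for (nm in names(fields))
    writeLines(sprintf("# %s: %s", nm, fields[[nm]]), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
}

#' @noRd
readMetaLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metaLines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(metaLines, regexec("^#\\s*([^:]+):\\s*(.*)$", metaLines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, function(x) trimws(x[[2]]), ""))
}

#' @noRd
fmtNum <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' @noRd
writeDepthTimeCSV <- function(path, kind, depthsVec, mat, fields, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeMetaLines(con, kind, fields, meta)
  tt <- timeAxisOf(ncol(mat), as.numeric(fields[["dt_ms"]]))
  writeLines(paste(c("depth_mm", fmtNum(tt)), collapse = ","), con)
  for (i in seq_along(depthsVec))
    writeLines(paste(c(fmtNum(depthsVec[i]), fmtNum(mat[i, ])), collapse = ","), con)
  invisible(path)
}

#' @noRd
readDepthTimeCSV <- function(path) {
  df <- read.csv(path, comment.char = "#", header = TRUE, check.names = FALSE)
  list(depths = df[[1]], mat = as.matrix(df[, -1, drop = FALSE]),
       meta = readMetaLines(path))
}

#' Write a laminar recording to CSV
#'
#' First column is electrode depth (mm below pia), remaining columns are time
#' samples (header row of times in ms); potentials in mV. Metadata (units,
#' dt, conductivity, event markers) is stored in commented header lines.
#'
#' @param recording a \linkS4class{LaminarRecording}.
#' @param path output path.
#' @param meta optional named list of extra provenance fields (e.g. seed).
#' @return invisibly, the path.
#' @export
writeRecording <- function(recording, path, meta = list()) {
  fields <- list(units = "depth=mm lfp=mV time=ms sigma=S/m",
                 dt_ms = fmtNum(recording@dt),
                 sigma_Sm = fmtNum(recording@sigma))
  if (length(recording@events))
    fields$events <- paste(sprintf("%s=%s", names(recording@events),
                                   fmtNum(recording@events)), collapse = ";")
  if (length(recording@layers))
    fields$layers <- paste(recording@layers, collapse = ";")
  writeDepthTimeCSV(path, "LaminarRecording", recording@depths,
                    recording@lfp, fields, meta)
}

#' Read a laminar recording written by [writeRecording()]
#' @param path file path.
#' @return a \linkS4class{LaminarRecording}.
#' @export
readRecording <- function(path) {
  d <- readDepthTimeCSV(path)
  if (is.null(d$meta$dt_ms)) stop("malformed recording file: missing dt_ms")
  if (is.null(d$meta$sigma_Sm)) stop("malformed recording file: missing sigma_Sm")
  events <- numeric(0)
  if (!is.null(d$meta$events)) {
    parts <- strsplit(strsplit(d$meta$events, ";")[[1]], "=")
    events <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                              vapply(parts, `[[`, "", 1L))
  }
  layers <- if (!is.null(d$meta$layers)) strsplit(d$meta$layers, ";")[[1]]
            else character(0)
  new("LaminarRecording", depths = d$depths, lfp = unname(d$mat),
      dt = as.numeric(d$meta$dt_ms), sigma = as.numeric(d$meta$sigma_Sm),
      events = events, layers = layers)
}

#' Write a CSD profile to CSV (layout mirrors [writeRecording()])
#' @param profile a \linkS4class{CSDProfile}.
#' @param path output path.
#' @param meta optional named list of extra provenance fields.
#' @return invisibly, the path.
#' @export
writeCSD <- function(profile, path, meta = list()) {
  fields <- list(units = "depth=mm csd=uA/mm^3 time=ms sigma=S/m",
                 dt_ms = fmtNum(profile@dt), method = profile@method,
                 diameter_mm = fmtNum(profile@diameter),
                 sigma_Sm = fmtNum(profile@sigma))
  writeDepthTimeCSV(path, "CSDProfile", profile@depths, profile@csd,
                    fields, meta)
}

#' Read a CSD profile written by [writeCSD()]
#' @param path file path.
#' @return a \linkS4class{CSDProfile}.
#' @export
readCSD <- function(path) {
  d <- readDepthTimeCSV(path)
  if (is.null(d$meta$method)) stop("malformed CSD file: missing method")
  new("CSDProfile", depths = d$depths, csd = unname(d$mat),
      dt = as.numeric(d$meta$dt_ms), method = d$meta$method,
      diameter = as.numeric(d$meta$diameter_mm),
      sigma = as.numeric(d$meta$sigma_Sm))
}

#' Write a scalp topography to CSV (label, then one column per sample, uV)
#' @param topo a \linkS4class{ScalpTopography}.
#' @param path output path.
#' @param meta optional named list of extra provenance fields.
#' @return invisibly, the path.
#' @export
writeTopography <- function(topo, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeMetaLines(con, "ScalpTopography",
                 list(units = "voltage=uV position=mm time=ms",
                      dt_ms = fmtNum(topo@dt), condition = topo@condition),
                 meta)
  nt <- ncol(topo@values)
  hdr <- if (nt == 1L) "value" else paste0("t", fmtNum(timeAxisOf(nt, topo@dt)))
  writeLines(paste(c("label", "x", "y", "z", hdr), collapse = ","), con)
  for (i in seq_along(topo@labels))
    writeLines(paste(c(topo@labels[i], fmtNum(topo@positions[i, ]),
                       fmtNum(topo@values[i, ])), collapse = ","), con)
  invisible(path)
}

#' Read a scalp topography written by [writeTopography()]
#' @param path file path.
#' @return a \linkS4class{ScalpTopography}.
#' @export
readTopography <- function(path) {
  meta <- readMetaLines(path)
  df <- read.csv(path, comment.char = "#", header = TRUE, check.names = FALSE)
  new("ScalpTopography", labels = as.character(df$label),
      positions = as.matrix(df[, c("x", "y", "z")]),
      values = as.matrix(df[, -(1:4), drop = FALSE]),
      dt = as.numeric(meta$dt_ms),
      condition = if (is.null(meta$condition)) "unspecified" else meta$condition)
}

#' Write a dipole source (JSON header + CSV moment trace)
#'
#' Writes `<path>.json` (position, orientation, rc, dt, method, units) and
#' `<path>.csv` (time and the three moment components in nA*m).
#'
#' @param dipole a \linkS4class{DipoleSource}.
#' @param path output path stem (without extension).
#' @param meta optional named list merged into the JSON header.
#' @return invisibly, the two paths.
#' @export
writeDipole <- function(dipole, path, meta = list()) {
  hdr <- c(list(position_mm = dipole@position,
                orientation = if (length(dipole@orientation))
                  dipole@orientation else NULL,
                rc_mm = dipole@rc, dt_ms = dipole@dt, method = dipole@method,
                units = "moment=nA*m time=ms position=mm"), meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".csv"), "w")
  on.exit(close(con))
  writeLines("t_ms,dx,dy,dz", con)
  tt <- timeAxisOf(ncol(dipole@moment), dipole@dt)
  writeLines(sprintf("%s,%s,%s,%s", fmtNum(tt), fmtNum(dipole@moment[1, ]),
                     fmtNum(dipole@moment[2, ]), fmtNum(dipole@moment[3, ])), con)
  invisible(c(paste0(path, ".json"), paste0(path, ".csv")))
}

#' Read a dipole source written by [writeDipole()]
#' @param path path stem used at writing time.
#' @return a \linkS4class{DipoleSource}.
#' @export
readDipole <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(path, ".csv"), header = TRUE)
  new("DipoleSource", position = as.numeric(hdr$position_mm),
      moment = t(as.matrix(df[, c("dx", "dy", "dz")])),
      orientation = if (is.null(hdr$orientation)) numeric(0)
                    else as.numeric(hdr$orientation),
      dt = as.numeric(hdr$dt_ms), rc = as.numeric(hdr$rc_mm),
      method = hdr$method)
}
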