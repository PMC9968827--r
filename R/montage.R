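# EEG electrode montages: standard-system coordinates on the unit sphere and
# projection onto a scalp surface.
#
# Head frame: +z through the vertex (Cz), +y anterior (nasion), +x right.
# Positions are constructed geometrically: midline and coronal electrodes at
# 10% steps (18 degrees) along their arcs, the outer ring at 72 degrees
# inclination, and intermediate rows interpolated along the spherical circle
# through the row's lateral ring electrodes and its midline electrode.

#' @noRd
sphPoint <- function(inclDeg, azimDeg) {
  # inclination from the vertex; azimuth from anterior midline, + to the right
  th <- inclDeg * pi / 180; ph <- azimDeg * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

#' Point at arc fraction f from L toward M on the circle through L, M, R
#' @noRd
arcPoint <- function(L, M, R, f) {
  # plane through the three points; circle = plane intersect unit sphere
  n <- c((M - L)[2] * (R - L)[3] - (M - L)[3] * (R - L)[2],
         (M - L)[3] * (R - L)[1] - (M - L)[1] * (R - L)[3],
         (M - L)[1] * (R - L)[2] - (M - L)[2] * (R - L)[1])
  n <- unitVector(n)
  c0 <- sum(n * L) * n                      # circle center (foot of plane)
  u1 <- unitVector(L - c0)
  rad <- sqrt(sum((L - c0)^2))
  u2 <- c(n[2] * u1[3] - n[3] * u1[2],
          n[3] * u1[1] - n[1] * u1[3],
          n[1] * u1[2] - n[2] * u1[1])
  angM <- atan2(sum((M - c0) * u2), sum((M - c0) * u1))
  ang <- f * angM
  c0 + rad * (cos(ang) * u1 + sin(ang) * u2)
}

#' Unit-sphere coordinates of the 61-channel 10-10 electrode set
#'
#' Returns the standard 61-position subset of the 10-10 system (rows Fp, AF,
#' F, FC, C, CP, P, PO, O), plus the anterior midline site `FpFz` (midway
#' between Fpz and Fz) used by chronically implanted monkey arrays.
#'
#' @return named numeric matrix (62 x 3) of unit vectors; the 61 standard
#'   10-10 labels plus `FpFz`.
#' @export
montageCoords1010 <- function() {
  pos <- list()
  # sagittal midline (10% = 18 degree steps from Cz)
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0, CPz = -18,
           Pz = -36, POz = -54, Oz = -72)
  for (nm in names(mid))
    pos[[nm]] <- sphPoint(abs(mid[[nm]]), if (mid[[nm]] >= 0) 0 else 180)
  # outer ring at 72 degrees inclination, 18 degree azimuth steps
  ring <- c(Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
            FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
            P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162)
  for (nm in names(ring)) pos[[nm]] <- sphPoint(72, ring[[nm]])
  # intermediate rows on the circle (lateral ring electrode .. midline)
  rows <- list(
    F = list(ends = c("F7", "F8"), mid = "Fz",
             left = c(F5 = 0.25, F3 = 0.5, F1 = 0.75),
             right = c(F6 = 0.25, F4 = 0.5, F2 = 0.75)),
    FC = list(ends = c("FT7", "FT8"), mid = "FCz",
              left = c(FC5 = 0.25, FC3 = 0.5, FC1 = 0.75),
              right = c(FC6 = 0.25, FC4 = 0.5, FC2 = 0.75)),
    C = list(ends = c("T7", "T8"), mid = "Cz",
             left = c(C5 = 0.25, C3 = 0.5, C1 = 0.75),
             right = c(C6 = 0.25, C4 = 0.5, C2 = 0.75)),
    CP = list(ends = c("TP7", "TP8"), mid = "CPz",
              left = c(CP5 = 0.25, CP3 = 0.5, CP1 = 0.75),
              right = c(CP6 = 0.25, CP4 = 0.5, CP2 = 0.75)),
    P = list(ends = c("P7", "P8"), mid = "Pz",
             left = c(P5 = 0.25, P3 = 0.5, P1 = 0.75),
             right = c(P6 = 0.25, P4 = 0.5, P2 = 0.75)),
    AF = list(ends = c("AF7", "AF8"), mid = "AFz",
              left = c(AF3 = 0.5), right = c(AF4 = 0.5)),
    PO = list(ends = c("PO7", "PO8"), mid = "POz",
              left = c(PO3 = 0.5), right = c(PO4 = 0.5)))
  for (rw in rows) {
    L <- pos[[rw$ends[1]]]; R <- pos[[rw$ends[2]]]; M <- pos[[rw$mid]]
    for (nm in names(rw$left))
      pos[[nm]] <- unitVector(arcPoint(L, M, R, rw$left[[nm]]))
    for (nm in names(rw$right))
      pos[[nm]] <- unitVector(arcPoint(R, M, L, rw$right[[nm]]))
  }
  pos[["FpFz"]] <- sphPoint(54, 0)   # anterior midline site of monkey arrays
  out <- do.call(rbind, pos)
  rownames(out) <- names(pos)
  out
}

#' @noRd
montageLabels <- function(system) {
  all1010 <- setdiff(rownames(montageCoords1010()), "FpFz")
  switch(system,
    "1010" = all1010,                                   # 61 sites
    "1020" = c("FpFz", "Fpz", "F3", "F4", "Fz", "Cz", "C3", "C4", "Pz",
               "P5", "P6", "POz", "O1", "O2", "Oz"),    # 15-site monkey array
    stop("unknown montage system: ", system))
}

#' Place a standard electrode montage on a scalp surface
#'
#' Projects unit-sphere standard-system coordinates radially (from the mesh
#' centroid) onto the scalp mesh.
#'
#' @param scalp a closed scalp mesh `list(vertices, faces)` or a
#'   \linkS4class{HeadModel} (its outermost surface is used).
#' @param system `"1010"` (the full modeled set, 61 sites) or `"1020"` (the
#'   15-electrode chronically implanted array subset).
#' @param subset optional character vector of labels to keep.
#' @return an \linkS4class{ElectrodeMontage}.
#' @export
placeMontage <- function(scalp, system = c("1010", "1020"), subset = NULL) {
  system <- match.arg(system)
  if (is(scalp, "HeadModel")) scalp <- scalp@surfaces[[length(scalp@surfaces)]]
  if (!meshIsClosed(scalp)) stop("the scalp mesh must be closed")
  labels <- montageLabels(system)
  if (!is.null(subset)) {
    missing <- setdiff(subset, labels)
    if (length(missing)) stop("unknown electrode labels: ",
                              paste(missing, collapse = ", "))
    labels <- subset
  }
  coords <- montageCoords1010()[labels, , drop = FALSE]
  center <- colMeans(scalp$vertices)
  hits <- rayMeshIntersect(scalp, center, coords)
  if (anyNA(hits)) stop("radial projection missed the scalp mesh")
  rownames(hits) <- labels
  new("ElectrodeMontage", labels = labels, positions = hits, system = system)
}

#' Read an electrode montage from a TSV file (label, x, y, z in mm)
#' @param path file path.
#' @return an \linkS4class{ElectrodeMontage} with system `"custom"`.
#' @export
readMontage <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) stop("montage TSV must have columns label, x, y, z")
  if (anyDuplicated(df$label)) stop("duplicate electrode labels in montage file")
  new("ElectrodeMontage", labels = as.character(df$label),
      positions = as.matrix(df[, c("x", "y", "z")]), system = "custom")
}

#' Write an electrode montage to a TSV file (label, x, y, z in mm)
#' @param montage an \linkS4class{ElectrodeMontage}.
#' @param path output path.
#' @param meta optional named list written as `# key: value` header lines.
#' @return invisibly, the path.
#' @export
writeMontage <- function(montage, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# columnEEG ElectrodeMontage", "# units: mm",
               sprintf("# system: %s", montage@system),
               sprintf("# %s: %s", names(meta), unlist(meta))), con)
  writeLines("label\tx\ty\tz", con)
  writeLines(sprintf("%s\t%s\t%s\t%s", montage@labels,
                     format(montage@positions[, 1], digits = 17),
                     format(montage@positions[, 2], digits = 17),
                     format(montage@positions[, 3], digits = 17)), con)
  invisible(path)
}
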