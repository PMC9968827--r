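# Equivalent current dipoles from CSD profiles or compartment currents.

#' Equivalent dipole amplitude from a CSD profile
#'
#' Integrates the first depth moment of the CSD over the column cross-section,
#' \deqn{d_z(t) = \pi r_c^2 \int CSD(z,t)\,(z - z_m)\, dz,}
#' by the trapezoidal method on the profile's depth grid (each subinterval is
#' one grid step). The column z axis points toward the supragranular surface,
#' so with depths measured below the pia the integrand uses
#' \eqn{(z_{ref} - depth)}; positive amplitudes point toward the pia (along
#' the outward cortical normal). Units: uA/mm^3 x mm^2 x mm x mm = nA*m.
#'
#' @param profile a \linkS4class{CSDProfile}.
#' @param rc column radius, mm (default 1.5, i.e. a 3 mm diameter cylinder).
#' @param zRef reference depth \eqn{z_m} (mm below pia); default the midpoint
#'   of the profile's depth grid.
#' @param position dipole location, length-3 (mm); default the origin of the
#'   column frame at `zRef` depth.
#' @param orientation unit 3-vector giving the column axis in the frame of
#'   `position` (default `c(0, 0, 1)`, the local column frame).
#' @return a \linkS4class{DipoleSource} with method `"CSD"` and moment
#'   `orientation %o% d(t)` in nA*m.
#' @export
dipoleFromCSD <- function(profile, rc = 1.5, zRef = NULL, position = NULL,
                          orientation = c(0, 0, 1)) {
  stopifnot(is(profile, "CSDProfile"))
  if (rc <= 0) stop("column radius rc must be positive")
  z <- profile@depths
  if (length(z) < 2L) stop("the depth grid must have at least 2 points")
  if (is.null(zRef)) zRef <- (z[1] + z[length(z)]) / 2
  if (zRef < z[1] || zRef > z[length(z)])
    stop("the profile grid must span the reference depth zRef")
  orientation <- unitVector(orientation)
  if (is.null(position)) position <- c(0, 0, -zRef)

  w <- trapzWeights(z)
  d <- as.numeric(crossprod(w * (zRef - z), profile@csd))  # nA*m
  d <- pi * rc^2 * d
  new("DipoleSource", position = as.numeric(position),
      moment = outer(orientation, d), orientation = orientation,
      dt = profile@dt, rc = rc, method = "CSD")
}

#' Equivalent dipole from summed transmembrane currents (STC)
#'
#' Sums the elementary dipoles between an expansion point and every
#' compartment,
#' \deqn{d(t) = \sum_c (r_c - r_m)\, I_c(t).}
#' When the per-neuron currents conserve charge (sum to zero), the result is
#' exactly independent of the expansion point \eqn{r_m}.
#'
#' @param currents a \linkS4class{CompartmentCurrentSet}.
#' @param rm expansion point (mm); default the center of mass of the
#'   compartment coordinates.
#' @param rc column radius recorded on the dipole, mm.
#' @param conservationTol relative tolerance for the per-neuron charge
#'   conservation check (a warning is emitted if violated).
#' @return a \linkS4class{DipoleSource} with method `"STC"` and a full
#'   3 x n_t moment (nA*m).
#' @export
dipoleFromSTC <- function(currents, rm = NULL, rc = 1.5,
                          conservationTol = 1e-9) {
  stopifnot(is(currents, "CompartmentCurrentSet"))
  if (is.null(rm)) rm <- colMeans(currents@coords)
  if (length(rm) != 3L) stop("rm must be a 3-vector")

  peak <- max(abs(currents@currents))
  if (peak > 0) {
    worst <- max(vapply(split(seq_len(nrow(currents@coords)), currents@neuron),
                        function(idx) {
                          max(abs(colSums(currents@currents[idx, , drop = FALSE])))
                        }, numeric(1)))
    if (worst > conservationTol * peak)
      warning(sprintf("per-neuron currents do not conserve charge (max |sum| = %.3g x peak)",
                      worst / peak))
  }
  disp <- sweep(currents@coords, 2L, rm)               # mm
  moment <- crossprod(disp, currents@currents) * 1e-3  # 3 x n_t, nA*mm -> nA*m
  new("DipoleSource", position = as.numeric(rm), moment = moment,
      orientation = numeric(0), dt = currents@dt, rc = rc, method = "STC")
}

#' Dipole orientation from a cortical surface mesh
#'
#' Area-weighted average of the normals of the triangles incident to the mesh
#' vertex nearest to `position` (the 1-ring neighborhood), normalized and
#' oriented outward (away from the mesh centroid, i.e. toward the scalp).
#'
#' @param mesh a mesh `list(vertices, faces)`.
#' @param position length-3 query position (mm); must lie within 1 mm of a
#'   mesh vertex.
#' @return unit length-3 vector.
#' @export
orientFromMesh <- function(mesh, position) {
  v <- mesh$vertices
  d2 <- colSums((t(v) - position)^2)
  iv <- which.min(d2)
  if (sqrt(d2[iv]) > 1) stop("position is farther than 1 mm from every mesh vertex")
  inc <- which(mesh$faces[, 1] == iv | mesh$faces[, 2] == iv |
                 mesh$faces[, 3] == iv)
  nsum <- c(0, 0, 0)
  for (f in inc) {
    tri <- mesh$faces[f, ]
    e1 <- v[tri[2], ] - v[tri[1], ]
    e2 <- v[tri[3], ] - v[tri[1], ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])   # |n| = 2 * area
    nsum <- nsum + nrm / 2
  }
  if (sqrt(sum(nsum^2)) == 0)
    stop("all incident triangles are degenerate (zero area)")
  mu <- unitVector(nsum)
  outward <- v[iv, ] - colMeans(v)
  if (sum(mu * outward) < 0) mu <- -mu
  mu
}

#' Rigidly place column-frame objects at a cortical site
#'
#' Maps column-local coordinates (z toward the pia, pia at z = 0) into head
#' coordinates: the local z axis is rotated onto the site's outward normal
#' and the pial origin of the column is translated to the site position.
#'
#' @param x a \linkS4class{CompartmentCurrentSet}, \linkS4class{DipoleSource}
#'   or an (n x 3) coordinate matrix in the column frame.
#' @param sitePosition length-3 site position on the cortical surface (mm).
#' @param siteNormal outward cortical normal at the site (unit 3-vector).
#' @return the same kind of object with coordinates in head space; dipole
#'   moments and orientations are rotated accordingly.
#' @export
placeAtSite <- function(x, sitePosition, siteNormal) {
  Rm <- rotationToZ(unitVector(siteNormal))
  if (is.matrix(x)) return(sweep(x %*% t(Rm), 2L, sitePosition, "+"))
  if (is(x, "CompartmentCurrentSet")) {
    x@coords <- sweep(x@coords %*% t(Rm), 2L, sitePosition, "+")
    return(x)
  }
  if (is(x, "DipoleSource")) {
    x@position <- as.numeric(Rm %*% x@position + sitePosition)
    x@moment <- Rm %*% x@moment
    if (length(x@orientation)) x@orientation <- as.numeric(Rm %*% x@orientation)
    return(x)
  }
  stop("unsupported object for placeAtSite")
}
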