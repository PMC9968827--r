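# EEG forward problem for nested piecewise-homogeneous head models.
#
# Double-layer boundary integral formulation collocated at face centroids
# with piecewise-constant potentials per face. All element integrals are the
# analytic signed solid angles of van Oosterom & Strackee, which makes the
# principal-value self terms vanish exactly (a centroid lies in the plane of
# its own face) and the (sigma_in + sigma_out)/2 collocation coefficient
# exact. The additive-constant rank deficiency is removed by deflation, and
# the isolated-skull approach is available (and on by default) to stop the
# poorly conducting skull from amplifying discretization error.

#' Infinite-medium potential of monopole current sources
#'
#' \deqn{V_0(r_e) = \frac{1}{4\pi\sigma} \sum_c \frac{I_c}{\max(|r_e - r_c|, r_{min})}}
#'
#' @param positions source positions, (n x 3) mm.
#' @param currents source currents: length-n vector or (n x n_t) matrix, nA.
#' @param sigma conductivity, S/m.
#' @param fieldPoints (m x 3) field points, mm.
#' @param rmin per-source distance clamp (mm); 0 means an exact point source
#'   (coincident field point is an error).
#' @return (m x n_t) matrix of potentials in uV.
#' @export
v0Monopoles <- function(positions, currents, sigma, fieldPoints, rmin = 0) {
  positions <- matrix(positions, ncol = 3L)
  fieldPoints <- matrix(fieldPoints, ncol = 3L)
  if (sigma <= 0) stop("conductivity must be positive")
  if (!is.matrix(currents)) currents <- matrix(currents, ncol = 1L)
  if (nrow(currents) != nrow(positions))
    stop("one current trace per source position is required")
  K <- .invDistMatrix(fieldPoints, positions, rep_len(rmin, nrow(positions)))
  (K %*% currents) / (4 * pi * sigma)     # nA, mm -> uV
}

#' Infinite-medium potential of a current dipole
#'
#' \deqn{V_0(r_e) = \frac{d \cdot (r_e - r_m)}{4\pi\sigma\,|r_e - r_m|^3}}
#'
#' @param dipole a \linkS4class{DipoleSource}, or a length-3 position when
#'   `moment` is given separately.
#' @param sigma conductivity, S/m.
#' @param fieldPoints (m x 3) field points, mm.
#' @param moment optional (3 x n_t) moment matrix in nA*m (when `dipole` is a
#'   plain position).
#' @return (m x n_t) matrix of potentials in uV.
#' @export
v0Dipole <- function(dipole, sigma, fieldPoints, moment = NULL) {
  if (is(dipole, "DipoleSource")) {
    pos <- dipole@position
    moment <- dipole@moment
  } else {
    pos <- as.numeric(dipole)
    if (is.null(moment)) stop("a moment matrix is required")
    if (!is.matrix(moment)) moment <- matrix(moment, ncol = 1L)
  }
  fieldPoints <- matrix(fieldPoints, ncol = 3L)
  if (sigma <= 0) stop("conductivity must be positive")
  D <- sweep(fieldPoints, 2L, pos)
  r <- sqrt(rowSums(D^2))
  if (any(r == 0)) stop("field point coincides with the dipole position")
  W <- D / r^3
  # nA*m over mm^2 -> mV; x 1e3 -> uV
  1e3 * (W %*% moment) / (4 * pi * sigma)
}

#' Precompute the BEM system for a head model
#'
#' Assembles and inverts the deflated double-layer collocation matrix (and,
#' for models with more than one surface, the isolated-skull system on the
#' innermost surface), so that many sources can be solved against the same
#' head model cheaply.
#'
#' @param model a \linkS4class{HeadModel}.
#' @return an object of class `bemOperator` (a list), to be passed to
#'   [bemSolve()].
#' @export
bemOperator <- function(model) {
  stopifnot(is(model, "HeadModel"))
  validObject(model)
  surfs <- model@surfaces
  K <- length(surfs)
  cond <- model@conductivities
  geo <- lapply(surfs, faceGeometry)
  nf <- vapply(surfs, function(s) nrow(s$faces), 1L)
  faceSurface <- rep(seq_len(K), nf)
  centroids <- do.call(rbind, lapply(geo, `[[`, "centroids"))
  N <- nrow(centroids)

  sigmaIn <- cond[seq_len(K)]
  sigmaOut <- cond[seq_len(K) + 1L]
  dSigma <- (sigmaIn - sigmaOut)[faceSurface]
  sigmaBar <- ((sigmaIn + sigmaOut) / 2)[faceSurface]

  A <- matrix(0, N, N)
  colOff <- c(0L, cumsum(nf))
  for (l in seq_len(K)) {
    om <- .solidAngleMatrix(centroids, surfs[[l]]$vertices, surfs[[l]]$faces)
    cols <- (colOff[l] + 1L):colOff[l + 1L]
    A[, cols] <- -om / (4 * pi)
  }
  A <- sweep(A, 2L, dSigma, "*")
  # exact zero for a centroid against its own face (coplanar)
  diag(A) <- diag(A) * 0
  diag(A) <- sigmaBar
  A <- A + mean(sigmaBar) / N        # deflation of the constant mode
  Ainv <- solve(A)

  AisoInv <- NULL
  if (K >= 2L) {
    rows1 <- which(faceSurface == 1L)
    om11 <- .solidAngleMatrix(geo[[1L]]$centroids, surfs[[1L]]$vertices,
                              surfs[[1L]]$faces)
    Aiso <- -om11 / (4 * pi)
    diag(Aiso) <- 0
    diag(Aiso) <- 0.5
    Aiso <- Aiso + 0.5 / length(rows1)
    AisoInv <- solve(Aiso)
  }

  structure(list(model = model, centroids = centroids,
                 faceSurface = faceSurface, Ainv = Ainv, AisoInv = AisoInv,
                 scalp = surfs[[K]], scalpGeo = geo[[K]],
                 sigma0 = cond[1L], sigma2 = if (K >= 2L) cond[2L] else cond[1L]),
            class = "bemOperator")
}

#' @noRd
sourceV0 <- function(op, source, rminMonopole = 0) {
  inner <- op$model@surfaces[[1L]]
  if (is(source, "DipoleSource")) {
    if (!pointsInMesh(matrix(source@position, 1L), inner))
      stop("the source must lie strictly inside the innermost surface")
    list(v0 = v0Dipole(source, op$sigma0, op$centroids), dt = source@dt)
  } else if (is(source, "CompartmentCurrentSet")) {
    if (!all(pointsInMesh(source@coords, inner)))
      stop("the source must lie strictly inside the innermost surface")
    list(v0 = v0Monopoles(source@coords, source@currents, op$sigma0,
                          op$centroids, rmin = source@radii),
         dt = source@dt)
  } else if (is.list(source) && !is.null(source$positions)) {
    if (!all(pointsInMesh(matrix(source$positions, ncol = 3L), inner)))
      stop("the source must lie strictly inside the innermost surface")
    list(v0 = v0Monopoles(source$positions, source$currents, op$sigma0,
                          op$centroids, rmin = rminMonopole),
         dt = if (is.null(source$dt)) 0 else source$dt)
  } else stop("unsupported source type")
}

#' Solve the EEG forward problem for a head model and a primary source
#'
#' Computes surface potentials on all model surfaces for a dipolar or
#' monopolar (compartment-current) primary source and, when a montage is
#' given, interpolates the scalp potentials at the electrodes.
#'
#' @param model a \linkS4class{HeadModel} or a precomputed [bemOperator()].
#' @param source a \linkS4class{DipoleSource}, a
#'   \linkS4class{CompartmentCurrentSet} already placed in head coordinates,
#'   or `list(positions, currents)`.
#' @param montage an optional \linkS4class{ElectrodeMontage}.
#' @param isolated use the isolated-skull approach (default TRUE; ignored for
#'   single-surface models).
#' @param reference `"average"` (default; potentials are average-referenced
#'   over the montage electrodes, or over the scalp faces when no montage is
#'   given) or `"none"`.
#' @param condition condition tag stored on the returned topography.
#' @return a \linkS4class{ScalpTopography} when a montage is given, otherwise
#'   a list with `potentials` (face values on all surfaces, uV), `centroids`
#'   and `faceSurface`.
#' @export
bemSolve <- function(model, source, montage = NULL, isolated = TRUE,
                     reference = c("average", "none"),
                     condition = "unspecified") {
  reference <- match.arg(reference)
  op <- if (inherits(model, "bemOperator")) model else bemOperator(model)
  K <- length(op$model@surfaces)
  src <- sourceV0(op, source)
  v0 <- src$v0

  if (isolated && K >= 2L) {
    rows1 <- which(op$faceSurface == 1L)
    u <- op$AisoInv %*% v0[rows1, , drop = FALSE]
    b <- op$sigma2 * v0
    b[rows1, ] <- op$sigma2 * (v0[rows1, , drop = FALSE] - u)
    x <- op$Ainv %*% b
    x[rows1, ] <- x[rows1, , drop = FALSE] + u   # v = u + w on the inner surface
  } else {
    x <- op$Ainv %*% (op$sigma0 * v0)
  }

  scalpRows <- which(op$faceSurface == K)
  if (is.null(montage)) {
    pots <- x
    if (reference == "average")
      pots <- sweep(pots, 2L, colMeans(pots[scalpRows, , drop = FALSE]))
    return(list(potentials = pots, centroids = op$centroids,
                faceSurface = op$faceSurface))
  }
  vertexVals <- faceToVertexValues(op$scalp, op$scalpGeo,
                                   x[scalpRows, , drop = FALSE])
  elec <- interpolateMesh(op$scalp, vertexVals, montage@positions)
  if (reference == "average") elec <- sweep(elec, 2L, colMeans(elec))
  new("ScalpTopography", labels = montage@labels,
      positions = montage@positions, values = elec, dt = src$dt,
      condition = condition)
}

#' Area-weighted transfer of face values to vertices
#' @noRd
faceToVertexValues <- function(mesh, geo, faceVals) {
  wvals <- geo$areas * faceVals                 # nf x nc
  idxAll <- as.vector(mesh$faces)               # every vertex of a closed mesh
  acc <- rowsum(rbind(wvals, wvals, wvals), idxAll)   # appears at least once
  wt <- rowsum(rep(geo$areas, 3L), idxAll)
  acc / as.numeric(wt)
}

#' Barycentric interpolation of vertex values at points near the mesh
#' @noRd
interpolateMesh <- function(mesh, vertexVals, points) {
  geo <- faceGeometry(mesh)
  out <- matrix(0, nrow(points), ncol(vertexVals))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    fi <- which.min(colSums((t(geo$centroids) - p)^2))
    tri <- mesh$faces[fi, ]
    a <- mesh$vertices[tri[1], ]; b <- mesh$vertices[tri[2], ]
    c_ <- mesh$vertices[tri[3], ]
    v0 <- b - a; v1 <- c_ - a; v2 <- p - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    w1 <- (d11 * d20 - d01 * d21) / den
    w2 <- (d00 * d21 - d01 * d20) / den
    w1 <- min(max(w1, 0), 1); w2 <- min(max(w2, 0), 1 - w1)
    w0 <- 1 - w1 - w2
    out[i, ] <- w0 * vertexVals[tri[1], ] + w1 * vertexVals[tri[2], ] +
      w2 * vertexVals[tri[3], ]
  }
  out
}

#' Analytic scalp potential for concentric spherical shells
#'
#' Legendre-series solution for a current dipole inside nested concentric
#' spherical shells with an insulating exterior: the reference oracle used to
#' validate the BEM solver. The dipole's field is expanded into radial and
#' tangential parts in a frame aligned with its position; per harmonic degree
#' the interface conditions (continuity of potential and of radial current)
#' and the outer zero-flux condition are solved for the shell coefficients.
#'
#' @param radii increasing shell radii, mm (outermost = scalp).
#' @param sigmas shell conductivities, S/m (one per shell; exterior is 0).
#' @param position dipole position, mm (strictly inside the innermost shell).
#' @param moment dipole moment: length-3 vector or (3 x n_t) matrix, nA*m.
#' @param directions (m x 3) unit vectors; potentials are evaluated at
#'   `max(radii) * directions`.
#' @param nmax series truncation degree (default 80; >= 60 recommended). The
#'   attribute `"truncationBound"` of the result reports the magnitude of the
#'   last retained term relative to the largest potential.
#' @return (m x n_t) matrix of potentials in uV.
#' @export
analyticMultishell <- function(radii, sigmas, position, moment, directions,
                               nmax = 80) {
  K <- length(radii)
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (length(sigmas) != K) stop("one conductivity per shell is required")
  if (!is.matrix(moment)) moment <- matrix(moment, ncol = 1L)
  if (nrow(moment) != 3L) stop("moment must be a 3 x n_t matrix")
  directions <- matrix(directions, ncol = 3L)
  directions <- directions / sqrt(rowSums(directions^2))
  RK <- radii[K]
  r0 <- sqrt(sum(position^2))
  if (r0 >= radii[1]) stop("the dipole must lie inside the innermost shell")

  # local frame: zhat along the dipole position (radial); for a central
  # dipole the orientation is arbitrary and zhat is taken along +z
  zhat <- if (r0 > 1e-12) position / r0 else c(0, 0, 1)
  xhat <- if (abs(zhat[1]) < 0.9) unitVector(c(1, 0, 0) - zhat[1] * zhat)
          else unitVector(c(0, 1, 0) - zhat[2] * zhat)
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])

  ct <- as.numeric(directions %*% zhat)
  ct <- pmin(pmax(ct, -1), 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  tangential <- directions - outer(ct, zhat)
  tnorm <- sqrt(rowSums(tangential^2))
  cphi <- ifelse(tnorm > 1e-12, (tangential %*% xhat) / tnorm, 0)
  sphi <- ifelse(tnorm > 1e-12, (tangential %*% yhat) / tnorm, 0)

  # Legendre P_n and Q_n = sin(theta) * P_n'(cos theta) up to nmax
  m <- length(ct)
  P <- matrix(0, m, nmax); dP <- matrix(0, m, nmax)
  Pm1 <- rep(1, m); Pcur <- ct
  dPm1 <- rep(0, m); dPcur <- rep(1, m)
  P[, 1] <- Pcur; dP[, 1] <- dPcur
  for (n in 2:nmax) {
    Pnew <- ((2 * n - 1) * ct * Pcur - (n - 1) * Pm1) / n
    dPnew <- dPm1 + (2 * n - 1) * Pcur
    Pm1 <- Pcur; Pcur <- Pnew
    dPm1 <- dPcur; dPcur <- dPnew
    P[, n] <- Pcur; dP[, n] <- dPcur
  }
  Q <- dP * st

  # per-degree scalp factor for unit source coefficient (scaled radii)
  rho <- radii / RK
  fn <- numeric(nmax)
  for (n in seq_len(nmax)) {
    nun <- 2L * K - 1L
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    # unknowns: A_1, then (A_k, B_k) for k = 2..K
    idxA <- function(k) if (k == 1L) 1L else 2L * (k - 1L)
    idxB <- function(k) 2L * (k - 1L) + 1L
    row <- 0L
    for (k in seq_len(K - 1L)) {
      r_ <- rho[k]
      # potential continuity at interface k
      row <- row + 1L
      M[row, idxA(k)] <- r_^n
      if (k > 1L) M[row, idxB(k)] <- r_^(-(n + 1))
      M[row, idxA(k + 1L)] <- -r_^n
      M[row, idxB(k + 1L)] <- -r_^(-(n + 1))
      rhs[row] <- if (k == 1L) -r_^(-(n + 1)) else 0
      # radial current continuity at interface k
      row <- row + 1L
      M[row, idxA(k)] <- sigmas[k] * n * r_^(n - 1)
      if (k > 1L) M[row, idxB(k)] <- -sigmas[k] * (n + 1) * r_^(-(n + 2))
      M[row, idxA(k + 1L)] <- -sigmas[k + 1L] * n * r_^(n - 1)
      M[row, idxB(k + 1L)] <- sigmas[k + 1L] * (n + 1) * r_^(-(n + 2))
      rhs[row] <- if (k == 1L) sigmas[1L] * (n + 1) * r_^(-(n + 2)) else 0
    }
    # insulated outer boundary at rho = 1
    row <- row + 1L
    M[row, idxA(K)] <- n
    if (K > 1L) M[row, idxB(K)] <- -(n + 1)
    rhs[row] <- if (K == 1L) (n + 1) else 0
    # row/column equilibration: the r^n vs r^-(n+1) terms span many orders
    # of magnitude at high degree
    rs <- apply(abs(M), 1L, max)
    M <- M / rs
    cs <- apply(abs(M), 2L, max)
    sol <- solve(sweep(M, 2L, cs, "/"), rhs / rs) / cs
    # scalp potential factor at rho = 1; the source term s r^-(n+1) lives in
    # shell 1 only, so for K = 1 it contributes directly at the surface
    fn[n] <- if (K == 1L) sol[1L] + 1 else sol[idxA(K)] + sol[idxB(K)]
  }

  # source coefficients per unit moment (scaled): radial n * t^(n-1), tangential t^(n-1)
  tq <- r0 / RK
  tpow <- if (r0 > 1e-12) tq^(seq_len(nmax) - 1) else c(1, rep(0, nmax - 1L))
  pref <- 1e3 / (4 * pi * sigmas[1L] * RK^2)    # nA*m, mm -> uV

  leadRad <- pref * (P %*% (fn * seq_len(nmax) * tpow))
  leadTanX <- pref * ((Q * as.numeric(cphi)) %*% (fn * tpow))
  leadTanY <- pref * ((Q * as.numeric(sphi)) %*% (fn * tpow))

  mloc <- rbind(as.numeric(moment[1, ] * xhat[1] + moment[2, ] * xhat[2] + moment[3, ] * xhat[3]),
                as.numeric(moment[1, ] * yhat[1] + moment[2, ] * yhat[2] + moment[3, ] * yhat[3]),
                as.numeric(moment[1, ] * zhat[1] + moment[2, ] * zhat[2] + moment[3, ] * zhat[3]))
  V <- leadTanX %*% mloc[1, , drop = FALSE] +
       leadTanY %*% mloc[2, , drop = FALSE] +
       leadRad %*% mloc[3, , drop = FALSE]
  lastTerm <- max(abs(pref * fn[nmax] * nmax * tpow[nmax] * P[, nmax]))
  attr(V, "truncationBound") <- lastTerm / max(abs(V), .Machine$double.eps)
  V
}
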