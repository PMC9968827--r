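# Current source density estimation from laminar LFP.

#' Standard (second spatial derivative) CSD
#'
#' Estimates the CSD as the negative second spatial difference of the LFP
#' along the electrode axis,
#' \deqn{CSD(t,d) = -\sigma \frac{x(t,d-z) + x(t,d+z) - 2x(t,d)}{z^2},}
#' where \eqn{z} is the (uniform) inter-electrode spacing. With conductivity
#' in S/m, potentials in mV and spacing in mm the result is in uA/mm^3.
#' Boundary channels are dropped unless `pad = "replicate"` (Vaknin padding:
#' the edge potentials are replicated so the CSD is defined on all channels).
#'
#' @param recording a \linkS4class{LaminarRecording} with >= 3 electrodes at
#'   uniform spacing.
#' @param pad `"none"` (drop edge channels, default) or `"replicate"`.
#' @param spacingTol relative tolerance on spacing uniformity.
#' @return a \linkS4class{CSDProfile} with method tag `"standard"`.
#' @examples
#' rec <- new("LaminarRecording", depths = c(0.1, 0.2, 0.3),
#'            lfp = matrix(c(1, 3, 1), 3, 1), dt = 1, sigma = 0.33)
#' csdValues(standardCSD(rec))  # 132 uA/mm^3 at the interior channel
#' @export
standardCSD <- function(recording, pad = c("none", "replicate"),
                        spacingTol = 1e-6) {
  pad <- match.arg(pad)
  stopifnot(is(recording, "LaminarRecording"))
  d <- recording@depths
  if (length(d) < 3L) stop("standard CSD needs at least 3 electrodes")
  h <- diff(d)
  if (max(abs(h - h[1])) > spacingTol * h[1])
    stop("standard CSD requires uniform electrode spacing")
  h <- h[1]
  x <- recording@lfp
  if (pad == "replicate")
    x <- rbind(x[1, , drop = FALSE], x, x[nrow(x), , drop = FALSE])
  n <- nrow(x)
  csd <- -recording@sigma *
    (x[1:(n - 2L), , drop = FALSE] + x[3:n, , drop = FALSE] -
       2 * x[2:(n - 1L), , drop = FALSE]) / h^2
  zOut <- if (pad == "replicate") d else d[-c(1L, length(d))]
  new("CSDProfile", depths = zOut, csd = csd, dt = recording@dt,
      method = "standard", diameter = Inf, sigma = recording@sigma)
}

#' Natural-spline cardinal basis evaluated on a set of points
#' @noRd
splineBasis <- function(knots, at) {
  n <- length(knots)
  vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    splinefun(knots, e, method = "natural")(at)
  }, numeric(length(at)))
}

#' Disk-source potential kernel: on-axis potential (mV) at depth `ze` of a
#' planar disk of radius R at depth `z` with unit volumetric density
#' (uA/mm^3) and unit thickness; 1/(2*sigma) prefactor applied by callers.
#' @noRd
diskKernel <- function(ze, z, R) sqrt((ze - z)^2 + R^2) - abs(ze - z)

#' Composite-Simpson quadrature nodes/weights on each inter-knot interval
#' @noRd
simpsonGrid <- function(knots, nsub = 24L) {
  nodes <- c(); weights <- c()
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    xs <- seq(a, b, length.out = nsub + 1L)
    h <- (b - a) / nsub
    w <- h / 3 * c(1, rep(c(4, 2), length.out = nsub - 1L), 1)
    w[seq(2, nsub, by = 2)] <- 4 * h / 3
    if (nsub > 2L) w[seq(3, nsub - 1L, by = 2)] <- 2 * h / 3
    nodes <- c(nodes, xs); weights <- c(weights, w)
  }
  list(nodes = nodes, weights = weights)
}

#' Spline inverse CSD (iCSD)
#'
#' Estimates the CSD by inverting the forward mapping from planar disk
#' sources to electrode potentials, with the depth profile parameterized as a
#' natural cubic spline through nodal values at the electrode depths
#' (disk-source forward matrix + cubic spline interpolation). The returned
#' profile is evaluated on a grid `upsample` times finer than the electrode
#' spacing. Optionally applies Tikhonov regularization (`lambda`) and a
#' 5-point Gaussian depth smoother (`smooth`).
#'
#' @param recording a \linkS4class{LaminarRecording} with >= 4 electrodes.
#' @param diameter assumed diameter of the columnar disk sources, mm
#'   (default 3, the simulated column diameter).
#' @param sigma conductivity, S/m (default: the recording's).
#' @param lambda Tikhonov regularization parameter (default 0).
#' @param upsample output grid refinement factor (>= 4; default 8).
#' @param smooth logical, apply a 5-point Gaussian smoother across depth.
#' @return a \linkS4class{CSDProfile} with method tag `"spline-iCSD"`.
#' @seealso [forwardLFP()] for the forward mapping (round-trip check).
#' @export
splineICSD <- function(recording, diameter = 3, sigma = NULL, lambda = 0,
                       upsample = 8L, smooth = FALSE) {
  stopifnot(is(recording, "LaminarRecording"))
  if (is.null(sigma)) sigma <- recording@sigma
  if (diameter <= 0) stop("source diameter must be positive")
  if (upsample < 4L) stop("the output grid must be >= 4x finer than the spacing")
  z <- recording@depths
  n <- length(z)
  if (n < 4L) stop("spline iCSD needs at least 4 electrodes")
  R <- diameter / 2

  quad <- simpsonGrid(z)
  B <- splineBasis(z, quad$nodes)                     # nq x n
  # F[i, j] = 1/(2 sigma) * int phi_j(z') K(z_i, z') dz'
  K <- outer(z, quad$nodes, diskKernel, R = R)        # n x nq
  Fm <- (K %*% (quad$weights * B)) / (2 * sigma)
  if (lambda > 0) Fm <- Fm + lambda * diag(n)
  cond <- rcond(Fm)
  if (cond < 1e-14)
    stop("forward matrix is singular or ill-conditioned; use regularization")
  coefs <- solve(Fm, recording@lfp)                   # nodal CSD values

  zf <- seq(z[1], z[n], length.out = (n - 1L) * upsample + 1L)
  Sf <- splineBasis(z, zf)                            # nzf x n
  csd <- Sf %*% coefs
  if (smooth) {
    g <- exp(-((-2):2)^2 / 2); g <- g / sum(g)
    csd <- apply(csd, 2L, function(col) {
      padded <- c(rep(col[1], 2), col, rep(col[length(col)], 2))
      stats::filter(padded, g, sides = 2)[3:(length(col) + 2)]
    })
  }
  new("CSDProfile", depths = zf, csd = csd, dt = recording@dt,
      method = "spline-iCSD", diameter = diameter, sigma = sigma)
}

#' Forward-map a CSD profile to electrode potentials (disk-source model)
#'
#' Computes the LFP that a depth profile of planar disk sources of the
#' profile's diameter would produce on the electrode axis, by trapezoid
#' quadrature over the profile's depth grid. Used to verify that
#' `forwardLFP(splineICSD(lfp))` reproduces the input LFP.
#'
#' @param profile a \linkS4class{CSDProfile} with a finite source diameter.
#' @param depths electrode depths (mm below pia).
#' @param sigma conductivity, S/m (default: the profile's).
#' @return a \linkS4class{LaminarRecording} with the forward-mapped LFP (mV).
#' @export
forwardLFP <- function(profile, depths, sigma = NULL) {
  stopifnot(is(profile, "CSDProfile"))
  if (!is.finite(profile@diameter))
    stop("forward mapping requires a finite disk-source diameter")
  if (is.null(sigma)) sigma <- profile@sigma
  R <- profile@diameter / 2
  w <- trapzWeights(profile@depths)
  K <- outer(depths, profile@depths, diskKernel, R = R)
  lfp <- (K %*% (w * profile@csd)) / (2 * sigma)
  new("LaminarRecording", depths = depths, lfp = lfp, dt = profile@dt,
      sigma = sigma)
}

#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "CSDProfile", function(x, window) {
  x@csd <- baselineCorrectMatrix(x@csd, x@dt, window)
  x
})

#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "LaminarRecording", function(x, window) {
  x@lfp <- baselineCorrectMatrix(x@lfp, x@dt, window)
  x
})

#' @noRd
baselineCorrectMatrix <- function(m, dt, window) {
  tt <- timeAxisOf(ncol(m), dt)
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("the baseline window contains no samples")
  m - rowMeans(m[, sel, drop = FALSE])
}

#' @rdname clipAtEvent
#' @export
setMethod("clipAtEvent", "CSDProfile", function(x, eventTime, lead = 10) {
  keep <- clipKeep(ncol(x@csd), x@dt, eventTime, lead)
  x@csd <- x@csd[, keep, drop = FALSE]
  x
})

#' @rdname clipAtEvent
#' @export
setMethod("clipAtEvent", "LaminarRecording", function(x, eventTime, lead = 10) {
  keep <- clipKeep(ncol(x@lfp), x@dt, eventTime, lead)
  x@lfp <- x@lfp[, keep, drop = FALSE]
  x
})

#' @noRd
clipKeep <- function(nt, dt, eventTime, lead) {
  if (eventTime < 0) stop("event occurs before the recording starts")
  tt <- timeAxisOf(nt, dt)
  keep <- tt < eventTime - lead - 1e-9
  if (!any(keep)) stop("clipping removes the whole recording")
  keep
}
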