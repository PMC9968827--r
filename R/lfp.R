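# Extracellular potentials at a laminar array (point-source approximation).

#' Default laminar electrode geometry
#'
#' Positions of a linear microelectrode array on the column axis: `n` contacts
#' at `spacing` mm vertical spacing, the most superficial contact at depth
#' `top` mm below the pia.
#'
#' @param n number of contacts (default 17).
#' @param spacing inter-electrode distance, mm (default 0.1).
#' @param top depth of the most superficial contact, mm (default 0.1).
#' @param x,y lateral position of the array, mm (default on the axis).
#' @return numeric matrix (n x 3) of positions in the column frame (mm).
#' @export
laminarElectrodes <- function(n = 17, spacing = 0.1, top = 0.1, x = 0, y = 0) {
  z <- -(top + (seq_len(n) - 1) * spacing)
  cbind(x = rep(x, n), y = rep(y, n), z = z)
}

#' Laminar LFP from compartment currents (point-source approximation)
#'
#' Superposes the potentials of all compartment currents treated as point
#' sources in an infinite homogeneous medium:
#' \deqn{V(r_e, t) = \frac{1}{4\pi\sigma} \sum_c \frac{I_c(t)}{\max(|r_e - r_c|, r_{min})}}
#' The singularity guard \eqn{r_{min}} defaults to each compartment's radius.
#'
#' @param currents a \linkS4class{CompartmentCurrentSet}.
#' @param electrodes electrode positions: an (n x 3) matrix in the column
#'   frame (mm), e.g. from [laminarElectrodes()]. Electrodes are expected to
#'   be co-linear on the column axis; a warning is emitted otherwise and the
#'   potentials are still computed.
#' @param sigma extracellular conductivity, S/m (default 0.33).
#' @param rmin per-compartment distance clamp in mm, or `NULL` to use the
#'   compartment radii. With `rmin = 0`, an electrode coinciding with a
#'   compartment center is an error.
#' @return a \linkS4class{LaminarRecording} (LFP in mV; depths below pia).
#' @export
lfpPointSource <- function(currents, electrodes = laminarElectrodes(),
                           sigma = 0.33, rmin = NULL) {
  stopifnot(is(currents, "CompartmentCurrentSet"))
  if (sigma <= 0) stop("conductivity must be positive")
  electrodes <- as.matrix(electrodes)
  if (ncol(electrodes) != 3L) stop("electrodes must be an n x 3 matrix")
  lateral <- max(abs(electrodes[, 1] - electrodes[1, 1]),
                 abs(electrodes[, 2] - electrodes[1, 2]))
  if (lateral > 1e-9)
    warning("electrodes are not co-linear on the column axis")
  if (is.null(rmin)) rmin <- currents@radii
  rmin <- rep_len(rmin, nrow(currents@coords))

  K <- .invDistMatrix(electrodes, currents@coords, rmin)   # 1/mm
  # nA / (S/m * mm) -> uV; divide by 1000 for mV
  lfp <- (K %*% currents@currents) / (4 * pi * sigma) / 1000

  ord <- order(-electrodes[, 3])    # increasing depth below pia
  new("LaminarRecording", depths = -electrodes[ord, 3],
      lfp = lfp[ord, , drop = FALSE], dt = currents@dt, sigma = sigma)
}

#' @noRd
butterworthLowpass <- function(m, cutoff, dt) {
  fs <- 1000 / dt                       # Hz
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  n <- ncol(m)
  nc <- length(bf$a) - 1L
  onePass <- function(x) {
    # steady-state initial conditions: exact for a constant lead-in
    as.numeric(signal::filter(bf$b, bf$a, x, init.x = rep(x[1], nc),
                              init.y = rep(x[1], nc)))
  }
  # odd-reflection padding suppresses the forward-backward edge transients
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  out <- t(apply(m, 1L, function(row) {
    ext <- c(2 * row[1] - row[(pad + 1L):2],
             row,
             2 * row[n] - row[(n - 1L):(n - pad)])
    y <- rev(onePass(rev(onePass(ext))))
    y[(pad + 1L):(pad + n)]
  }))
  if (n == 1L) out <- matrix(out, nrow = nrow(m))
  out
}

#' @rdname lowpassFilter
#' @export
setMethod("lowpassFilter", "matrix", function(x, cutoff = 100, dt = NULL) {
  if (is.null(dt)) stop("dt (ms) is required for plain matrices")
  butterworthLowpass(x, cutoff, dt)
})

#' @rdname lowpassFilter
#' @export
setMethod("lowpassFilter", "LaminarRecording", function(x, cutoff = 100, dt = NULL) {
  x@lfp <- butterworthLowpass(x@lfp, cutoff, x@dt)
  x
})

#' @rdname lowpassFilter
#' @export
setMethod("lowpassFilter", "DipoleSource", function(x, cutoff = 100, dt = NULL) {
  x@moment <- butterworthLowpass(x@moment, cutoff, x@dt)
  x
})
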