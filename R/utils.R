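# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Trapezoid rule on a (possibly non-uniform) grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapezoid integration needs a grid of length >= 2")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Trapezoid quadrature weights for a grid
#' @noRd
trapzWeights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trapezoid integration needs a grid of length >= 2")
  h <- diff(x)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Rotation matrix mapping the unit z axis onto a given unit vector
#' (Rodrigues formula; for u = -z a 180 degree rotation about x is used)
#' @noRd
rotationToZ <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2],
         z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Normalize a vector to unit length
#' @noRd
unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Shift the columns of a matrix right by k samples, zero-padding on the left
#' @noRd
shiftColumns <- function(m, k) {
  if (k == 0L) return(m)
  nt <- ncol(m)
  out <- matrix(0, nrow(m), nt)
  if (k < nt) out[, (k + 1L):nt] <- m[, 1L:(nt - k), drop = FALSE]
  out
}

#' Stable per-row comparison of a time axis
#' @noRd
timeAxisOf <- function(nt, dt) (seq_len(nt) - 1) * dt
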