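# Agreement metrics between forward solutions, column depth and the
# depth-dependence regression.

#' Magnitude ratio (MAG) between two forward solutions
#'
#' \deqn{MAG = \|\hat y\| / \|y\|} with the root-sum-square norm taken over
#' all elements (time samples for traces, electrodes for static maps;
#' matrices are flattened, which pools both).
#'
#' @param y ground-truth signal (vector or matrix).
#' @param yhat candidate signal, same shape.
#' @return scalar; 1 indicates equal magnitude.
#' @export
mag <- function(y, yhat) {
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("MAG is undefined for an identically zero ground truth")
  sqrt(sum(yhat^2)) / ny
}

#' Relative difference measure (RDM) between two forward solutions
#'
#' \deqn{RDM = \left\| \frac{y}{\|y\|} - \frac{\hat y}{\|\hat y\|} \right\|}
#' Scale-invariant in each argument; ranges from 0 (same shape) to 2
#' (opposite shape), with \eqn{\sqrt 2} for orthogonal signals.
#'
#' @inheritParams mag
#' @return scalar in \[0, 2\].
#' @export
rdm <- function(y, yhat) {
  ny <- sqrt(sum(y^2)); nyh <- sqrt(sum(yhat^2))
  if (ny == 0 || nyh == 0) stop("RDM is undefined for zero signals")
  sqrt(sum((y / ny - yhat / nyh)^2))
}

#' Depth of a cortical column below the scalp surface
#'
#' Shortest Euclidean distance between a point (e.g. the column's center of
#' mass) and a triangulated scalp surface, with exact face/edge/vertex
#' closest-point handling.
#'
#' @param scalp scalp mesh `list(vertices, faces)`.
#' @param points length-3 vector or (n x 3) matrix of query points (mm).
#' @return numeric vector of distances (mm).
#' @export
columnDepth <- function(scalp, points) {
  if (!length(scalp$faces)) stop("empty mesh")
  points <- matrix(points, ncol = 3L)
  as.numeric(.pointMeshDistance(points, scalp$vertices, scalp$faces))
}

#' Linear regression of an agreement metric on column depth
#'
#' Ordinary least squares of `metric` on `depth`, as used to test whether
#' RDM/MAG vary with the depth of the column below the scalp.
#'
#' @param depth numeric depths (mm), at least 3 distinct locations.
#' @param metric numeric metric values (same length).
#' @return list with `slope`, `intercept` and `r.squared`.
#' @export
depthRegression <- function(depth, metric) {
  if (length(depth) < 3L) stop("at least 3 locations are required")
  if (sd(depth) == 0) stop("depth is constant; the regression is undefined")
  fit <- lm(metric ~ depth)
  rs <- summary(fit)$r.squared
  if (!is.finite(rs)) rs <- 0   # constant metric: no depth dependence
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = rs)
}

#' Random cortical column sites on a surface mesh
#'
#' Samples `n` mesh vertices without replacement (uniform by vertex, or
#' area-weighted by the summed area of each vertex's incident triangles) and
#' attaches outward cortical-normal orientations from the 1-ring normals.
#'
#' @param cortex cortical surface mesh.
#' @param n number of sites.
#' @param seed RNG seed (identical seeds give identical sites).
#' @param areaWeighted logical; weight vertices by incident triangle area.
#' @return list with `positions` (n x 3), `orientations` (n x 3) and
#'   `vertexIds`.
#' @export
randomColumnSites <- function(cortex, n, seed = 1L, areaWeighted = FALSE) {
  nv <- nrow(cortex$vertices)
  if (!nv) stop("empty mesh")
  if (n > nv) stop("cannot sample more sites than mesh vertices")
  prob <- NULL
  if (areaWeighted) {
    geo <- faceGeometry(cortex)
    w <- rowsum(rep(geo$areas, 3L), as.vector(cortex$faces))
    prob <- as.numeric(w)[seq_len(nv)]
  }
  ids <- withSeed(seed, sample.int(nv, n, replace = FALSE, prob = prob))
  ori <- t(vapply(ids, function(iv) orientFromMesh(cortex, cortex$vertices[iv, ]),
                  numeric(3)))
  list(positions = cortex$vertices[ids, , drop = FALSE], orientations = ori,
       vertexIds = ids)
}

#' Chance level of an n-alternative search task
#'
#' Probability of selecting the target by chance among `nItems` equally
#' likely array positions (6-item search: 1/6).
#'
#' @param nItems number of array items (default 6).
#' @return numeric scalar.
#' @export
searchChanceLevel <- function(nItems = 6) {
  if (nItems < 1) stop("nItems must be >= 1")
  1 / nItems
}
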