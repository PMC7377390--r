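# Small internal vector/geometry helpers shared across modules.

vecNorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Angle between two 3-vectors in degrees
#' @noRd
vecAngleDeg <- function(a, b) {
  a <- unitVec(a); b <- unitVec(b)
  d <- max(-1, min(1, sum(a * b)))
  acos(d) * 180 / pi
}

#' Project vector onto the plane with unit normal n
#' @noRd
projectOntoPlane <- function(v, n) {
  n <- unitVec(n)
  v - sum(v * n) * n
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees
#' @noRd
rotationAboutAxis <- function(axis, angleDeg) {
  u <- unitVec(axis)
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation taking unit vector a onto unit vector b
#' @noRd
rotationBetween <- function(a, b) {
  a <- unitVec(a); b <- unitVec(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- vecNorm(v)
  if (s < 1e-14) {
    if (sum(a * b) > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitVec(p - sum(p * a) * a)
    return(rotationAboutAxis(axis, 180))
  }
  ang <- atan2(s, sum(a * b)) * 180 / pi
  rotationAboutAxis(v / s, ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pairwise nearest neighbours between point clouds (brute force, chunked)
#'
#' Returns for each row of `x` the index of the nearest row of `y` and the
#' distance. Adequate for the point-cloud sizes used here (<= ~10k).
#' @noRd
nearestNeighbours <- function(x, y, chunk = 2048L) {
  x <- as.matrix(x); y <- as.matrix(y)
  ny2 <- rowSums(y * y)
  n <- nrow(x)
  idx <- integer(n)
  d2 <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    xs <- x[s:e, , drop = FALSE]
    # squared distances: |x|^2 + |y|^2 - 2 x.y
    g <- outer(rowSums(xs * xs), ny2, "+") - 2 * xs %*% t(y)
    j <- max.col(-g, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- g[cbind(seq_len(nrow(g)), j)]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

#' Least-squares sphere fit
#'
#' Solves the linear formulation |p|^2 = 2 p.c + (R^2 - |c|^2).
#' @return list(center, radius, rms)
#' @noRd
fitSphere <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 10)
    stop("sphere fit needs at least 10 points, got ", nrow(pts))
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts * pts)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr * ctr)
  if (r2 <= 0) stop("sphere fit is ill-conditioned (non-positive radius)")
  r <- sqrt(r2)
  resid <- sqrt(rowSums(sweep(pts, 2, ctr)^2)) - r
  list(center = as.numeric(ctr), radius = r, rms = sqrt(mean(resid^2)))
}

#' Clamp helper
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
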