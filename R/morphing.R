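# Surface-driven mesh morphing: rigid registration (ICP with optional
# landmark seeding), host-mesh fitting with a tricubic Bezier control
# lattice, and application of both transforms to full hex meshes including
# their internal (passive) nodes.

.asPoints <- function(x) {
  if (is(x, "TriSurface")) x@vertices
  else if (is(x, "HexMesh")) x@nodeCoords
  else as.matrix(x)
}

#' Apply a rigid transform to points, a surface or a mesh
#'
#' @param x matrix of points, [TriSurface-class] or [HexMesh-class]
#' @param transform a [RigidTransform-class]
#' @return object of the same type with transformed coordinates.
#' @export
applyTransform <- function(x, transform) {
  tf <- function(p) {
    p %*% t(transform@rotation) * transform@scale +
      matrix(transform@translation, nrow(p), 3, byrow = TRUE)
  }
  if (is(x, "TriSurface")) {
    x@vertices <- tf(x@vertices); x
  } else if (is(x, "HexMesh")) {
    x@nodeCoords <- tf(x@nodeCoords); x
  } else tf(.asPoints(x))
}

# Kabsch / Umeyama estimation from corresponding point pairs
.kabsch <- function(X, Y, scale = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (scale) sum(sv$d * diag(S)) / sum(Xc^2) else 1
  t <- cy - s * as.numeric(R %*% cx)
  new("RigidTransform", rotation = R, translation = t, scale = s)
}

#' Rigid registration of two point clouds (ICP)
#'
#' Iterative closest point: alternate nearest-neighbour correspondence with a
#' Kabsch (optionally Umeyama, `scale = TRUE`) estimate until the mean
#' squared distance stops improving. When corresponding landmark pairs are
#' given the initial transform is estimated from them, which makes the
#' method robust to large initial misalignment.
#'
#' @param source,target point matrices, [TriSurface-class] or
#'   [HexMesh-class] objects.
#' @param landmarksSource,landmarksTarget optional k x 3 matrices of
#'   corresponding seed points (k >= 3).
#' @param scale estimate a uniform scale factor.
#' @param maxIter,tol iteration controls.
#' @return A [RigidTransform-class]; attribute `rms` carries the final RMS
#'   nearest-point distance.
#' @export
rigidRegister <- function(source, target, landmarksSource = NULL,
                          landmarksTarget = NULL, scale = FALSE,
                          maxIter = 50L, tol = 1e-12) {
  X <- .asPoints(source); Y <- .asPoints(target)
  if (nrow(X) < 3 || nrow(Y) < 3) stop("need at least 3 points per cloud")
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate source cloud: points are (nearly) collinear")
  tr <- if (!is.null(landmarksSource)) {
    .kabsch(as.matrix(landmarksSource), as.matrix(landmarksTarget), scale)
  } else {
    new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0),
        scale = 1)
  }
  prev <- Inf
  for (it in seq_len(maxIter)) {
    Xt <- applyTransform(X, tr)
    nn <- nearestNeighbours(Xt, Y)
    ms <- mean(nn$dist^2)
    if (prev - ms < tol * max(ms, 1e-300)) break
    prev <- ms
    tr <- .kabsch(X, Y[nn$index, , drop = FALSE], scale)
  }
  attr(tr, "rms") <- sqrt(mean(nearestNeighbours(applyTransform(X, tr),
                                                 Y)$dist^2))
  tr
}

# ---- point-to-surface distance --------------------------------------------

# k nearest neighbours (small k) by repeated masked 1-NN passes
.knn <- function(x, y, k) {
  idx <- matrix(0L, nrow(x), k)
  ny2 <- rowSums(y * y)
  g <- outer(rowSums(x * x), ny2, "+") - 2 * x %*% t(y)
  for (j in seq_len(k)) {
    jj <- max.col(-g, ties.method = "first")
    idx[, j] <- jj
    g[cbind(seq_len(nrow(x)), jj)] <- Inf
  }
  idx
}

# distance from one point to k triangles (rows of A, B, C)
.pointTriDist <- function(p, A, B, C) {
  e0 <- B - A; e1 <- C - A
  w <- -sweep(A, 2, p)
  d00 <- rowSums(e0 * e0); d01 <- rowSums(e0 * e1); d11 <- rowSums(e1 * e1)
  w0 <- rowSums(w * e0); w1 <- rowSums(w * e1)
  den <- pmax(d00 * d11 - d01^2, 1e-300)
  v <- (d11 * w0 - d01 * w1) / den
  u <- (d00 * w1 - d01 * w0) / den
  inside <- v >= 0 & u >= 0 & v + u <= 1
  dIn <- sqrt(pmax(rowSums((w - v * e0 - u * e1)^2), 0))
  segDist <- function(P0, Dv) {
    tt <- clamp(rowSums(-sweep(P0, 2, p) * Dv) / pmax(rowSums(Dv * Dv), 1e-300), 0, 1)
    sqrt(rowSums((sweep(P0, 2, p) + tt * Dv)^2))
  }
  dEdge <- pmin(segDist(A, e0), segDist(A, e1), segDist(B, C - B))
  ifelse(inside, dIn, dEdge)
}

# nearest distance from each point to a surface (candidate triangles from
# the stars of the 3 nearest vertices)
.pointsToSurfaceDist <- function(pts, surface) {
  v <- surface@vertices; tr <- surface@triangles
  inc <- vector("list", nrow(v))
  for (c in 1:3) {
    for (i in seq_len(nrow(tr))) {
      vv <- tr[i, c]
      inc[[vv]] <- c(inc[[vv]], i)
    }
  }
  nn <- .knn(pts, v, 3L)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cand <- unique(unlist(inc[nn[i, ]]))
    Ai <- v[tr[cand, 1], , drop = FALSE]
    Bi <- v[tr[cand, 2], , drop = FALSE]
    Ci <- v[tr[cand, 3], , drop = FALSE]
    out[i] <- min(.pointTriDist(pts[i, ], Ai, Bi, Ci))
  }
  out
}

#' Symmetrized RMS surface distance
#'
#' RMS of nearest-point distances from the vertices of `a` to the surface of
#' `b`, symmetrized as the mean of the two directed RMS values.
#'
#' @param a,b [TriSurface-class] objects
#' @return distance in mm.
#' @export
surfaceRMS <- function(a, b) {
  if (!nrow(a@triangles) || !nrow(b@triangles)) stop("empty surface")
  dab <- .pointsToSurfaceDist(a@vertices, b)
  dba <- .pointsToSurfaceDist(b@vertices, a)
  (sqrt(mean(dab^2)) + sqrt(mean(dba^2))) / 2
}

# ---- host-mesh fitting -----------------------------------------------------

.bernstein3 <- function(u) {
  cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
}

# basis matrix (n x 64) of tricubic Bernstein products for normalized coords
.ffdBasis <- function(U) {
  Bx <- .bernstein3(U[, 1]); By <- .bernstein3(U[, 2]); Bz <- .bernstein3(U[, 3])
  A <- matrix(0, nrow(U), 64)
  col <- 0L
  for (k in 1:4) for (j in 1:4) for (i in 1:4) {
    col <- col + 1L
    A[, col] <- Bx[, i] * By[, j] * Bz[, k]
  }
  A
}

# deterministic principal-axis frame of a point cloud (right-handed; axis
# signs fixed by third-moment skewness, falling back to the largest-|coord|
# rule for near-symmetric axes)
.pcaFrame <- function(pts) {
  ctr <- colMeans(pts)
  Xc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
  for (j in 1:3) {
    pj <- Xc %*% ev[, j]
    sk <- mean(pj^3)
    if (abs(sk) > 1e-6 * max(abs(pj))^3) {
      if (sk < 0) ev[, j] <- -ev[, j]
    } else if (ev[which.max(abs(ev[, j])), j] < 0) ev[, j] <- -ev[, j]
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  list(center = ctr, frame = ev)
}

.ffdEmbed <- function(deform, pts, strict = TRUE) {
  loc <- sweep(pts, 2, deform@origin) %*% deform@frame
  U <- sweep(loc, 2, deform@extent, "/")
  if (strict && (min(U) < -1e-6 || max(U) > 1 + 1e-6))
    stop("points fall outside the host lattice box")
  clamp(U, 0, 1)
}

#' Fit a host-mesh (free-form lattice) deformation between two surfaces
#'
#' A `dims` (default 4 x 4 x 4, tricubic Bezier) control lattice is laid over
#' the principal-axis bounding box of both surfaces. Control points are
#' fitted by iteratively re-matching source vertices to their nearest target
#' vertices (pairs with normals more than `normalMaxDeg` apart are rejected)
#' and solving the ridge-regularized least-squares problem
#' `sum |FFD(p) - q|^2 + lambda * |control displacement|^2`.
#'
#' @param sourceSurface,targetSurface [TriSurface-class] objects, rigidly
#'   pre-aligned (see [rigidRegister()]).
#' @param dims control lattice dimensions (only 4 x 4 x 4 supported).
#' @param lambda ridge weight on control-point displacement (mm^2 scale).
#' @param maxIter correspondence refits.
#' @param normalMaxDeg normal-compatibility threshold, degrees.
#' @param tol relative improvement threshold for early stopping.
#' @param correspondence `"nearest"` (default): iterated symmetric
#'   nearest-neighbour matching; `"index"`: vertices correspond by position
#'   in the vertex list (surfaces from the same parametric template), which
#'   pins landmarks and avoids tangential sliding.
#' @return A [HostMeshDeformation-class]; `report` holds the surface RMS
#'   after rigid alignment alone and after fitting.
#' @export
hostMeshFit <- function(sourceSurface, targetSurface, dims = c(4L, 4L, 4L),
                        lambda = 1e-3, maxIter = 10L, normalMaxDeg = 60,
                        tol = 1e-4, correspondence = c("nearest", "index")) {
  correspondence <- match.arg(correspondence)
  if (!all(dims == 4L)) stop("only a 4 x 4 x 4 (tricubic) lattice is supported")
  src <- sourceSurface@vertices
  tgt <- targetSurface@vertices
  pf <- .pcaFrame(tgt)
  allPts <- rbind(src, tgt)
  loc <- sweep(allPts, 2, pf$center) %*% pf$frame
  lo <- apply(loc, 2, min); hi <- apply(loc, 2, max)
  pad <- 0.05 * (hi - lo)
  lo <- lo - pad; hi <- hi + pad
  origin <- pf$center + as.numeric(pf$frame %*% lo)
  extent <- hi - lo

  grid <- as.matrix(expand.grid(i = 0:3, j = 0:3, k = 0:3)) / 3
  P0 <- matrix(origin, 64, 3, byrow = TRUE) +
    (grid %*% diag(extent)) %*% t(pf$frame)

  proto <- new("HostMeshDeformation", dims = as.integer(dims),
               frame = pf$frame, origin = origin, extent = extent,
               controlOrig = P0, controlFit = P0, lambda = lambda,
               embedding = matrix(0, 0, 3), report = list())
  U <- .ffdEmbed(proto, src)
  A <- .ffdBasis(U)

  srcN <- vertexAreasNormals(sourceSurface)$normals
  tgtN <- vertexAreasNormals(targetSurface)$normals
  cosMin <- cos(normalMaxDeg * pi / 180)

  rms0 <- surfaceRMS(sourceSurface, targetSurface)
  P <- P0
  bestP <- P
  bestMs <- Inf
  prevMs <- Inf
  it <- 0L
  if (correspondence == "index") {
    if (nrow(src) != nrow(tgt))
      stop("index correspondence needs equal vertex counts")
    M <- crossprod(A) + diag(lambda, 64)
    bestP <- solve(M, crossprod(A, tgt) + lambda * P0)
    it <- 1L
  } else {
    for (it in seq_len(maxIter)) {
      cur <- A %*% P
      nn <- nearestNeighbours(cur, tgt)
      ok <- rowSums(srcN * tgtN[nn$index, , drop = FALSE]) >= cosMin
      if (sum(ok) < 64) ok <- rep(TRUE, nrow(cur))  # filter too aggressive
      # symmetric matching: pull unmatched target regions toward coverage
      nnR <- nearestNeighbours(tgt, cur)
      okR <- rowSums(tgtN * srcN[nnR$index, , drop = FALSE]) >= cosMin
      Aall <- rbind(A[ok, , drop = FALSE], A[nnR$index[okR], , drop = FALSE])
      Tall <- rbind(tgt[nn$index[ok], , drop = FALSE], tgt[okR, , drop = FALSE])
      M <- crossprod(Aall) + diag(lambda, 64)
      P <- solve(M, crossprod(Aall, Tall) + lambda * P0)
      ms <- mean(rowSums((A %*% P - tgt[nn$index, , drop = FALSE])^2))
      if (ms < bestMs) { bestMs <- ms; bestP <- P }
      if (is.finite(prevMs) && prevMs - ms < tol * max(ms, 1e-300)) break
      prevMs <- ms
    }
  }
  fitted <- sourceSurface
  fitted@vertices <- .ffdBasis(U) %*% bestP
  rms1 <- surfaceRMS(fitted, targetSurface)
  if (rms1 > rms0 + 1e-9)
    stop(sprintf(paste0("host-mesh fit failed to improve on rigid ",
                        "registration (RMS %.3f mm vs %.3f mm)"), rms1, rms0))
  new("HostMeshDeformation", dims = as.integer(dims), frame = pf$frame,
      origin = origin, extent = extent, controlOrig = P0, controlFit = bestP,
      lambda = lambda, embedding = U,
      report = list(rmsRigid = rms0, rmsFit = rms1, iterations = it))
}

#' Evaluate a host-mesh deformation at arbitrary points
#'
#' Points are embedded in the lattice box (an error is raised for points
#' outside it) and mapped through the fitted control grid.
#'
#' @param deform a [HostMeshDeformation-class]
#' @param pts n x 3 matrix
#' @return deformed n x 3 matrix.
#' @export
evalDeformation <- function(deform, pts) {
  U <- .ffdEmbed(deform, as.matrix(pts))
  .ffdBasis(U) %*% deform@controlFit
}

#' Morph a hex mesh through a rigid transform and a host-mesh deformation
#'
#' Applies both transforms to every node (surface and internal passive
#' points); connectivity, element/node sets and materials are carried over
#' unchanged. Elements that end up with a non-positive corner Jacobian are
#' flagged in `metadata$invertedElements` for downstream handling (see
#' [dropInvertedElements()]).
#'
#' @param mesh a [HexMesh-class]
#' @param rigid a [RigidTransform-class] (identity allowed)
#' @param deform a [HostMeshDeformation-class], fitted on this mesh's surface
#' @return the morphed [HexMesh-class]
#' @export
morphMesh <- function(mesh, rigid, deform = NULL) {
  out <- applyTransform(mesh, rigid)
  if (!is.null(deform))
    out@nodeCoords <- evalDeformation(deform, out@nodeCoords)
  out@metadata$invertedElements <- which(minCornerJacobian(out) <= 0)
  out
}

#' Remove negative-volume elements after morphing
#'
#' Elements with non-positive corner Jacobians are removed, provided they lie
#' distal to the growth plate (condyle or shaft region). If any inverted
#' element belongs to the growth plate, a transition zone, the neck or the
#' head, the function aborts: growth-plate integrity is required by the
#' growth engine.
#'
#' @param mesh a [HexMesh-class]
#' @return list(mesh, report) where report lists `count`, `ids`, `fraction`
#'   and `location` (element-set labels of the removed elements).
#' @export
dropInvertedElements <- function(mesh) {
  bad <- which(minCornerJacobian(mesh) <= 0)
  locLabel <- function(e) {
    hits <- names(mesh@elementSets)[vapply(mesh@elementSets,
                                           function(s) e %in% s, TRUE)]
    paste(hits, collapse = "+")
  }
  if (!length(bad)) {
    return(list(mesh = mesh,
                report = list(count = 0L, ids = integer(0), fraction = 0,
                              location = character(0))))
  }
  protected <- unique(unlist(mesh@elementSets[
    grepl("^growth_plate_row_|^transition_|^neck$|^head$",
          names(mesh@elementSets))]))
  inProt <- intersect(bad, protected)
  if (length(inProt))
    stop("inverted elements in or proximal to the growth plate (ids ",
         paste(inProt, collapse = ", "), "); morph rejected")
  keep <- setdiff(seq_len(nElements(mesh)), bad)
  remap <- integer(nElements(mesh))
  remap[keep] <- seq_along(keep)
  out <- mesh
  out@elements <- mesh@elements[keep, , drop = FALSE]
  out@elementE <- mesh@elementE[keep]
  out@elementNu <- mesh@elementNu[keep]
  out@elementSets <- lapply(mesh@elementSets, function(s) {
    s2 <- remap[setdiff(s, bad)]
    as.integer(s2[s2 > 0])
  })
  out@metadata$invertedElements <- integer(0)
  out@metadata$removedElements <- bad
  list(mesh = out,
       report = list(count = length(bad), ids = bad,
                     fraction = length(bad) / nElements(mesh),
                     location = vapply(bad, locLabel, "")))
}

#' One-call morph of a reference femur mesh onto a target surface
#'
#' Convenience wrapper: rigid registration of the reference surface onto the
#' target, host-mesh fitting, application to the full mesh, and removal of
#' any inverted distal elements.
#'
#' @param mesh reference [HexMesh-class]
#' @param targetSurface target [TriSurface-class]
#' @param ... passed to [hostMeshFit()] (e.g. `correspondence = "index"`
#'   when the target comes from the same parametric template)
#' @return list(mesh, rigid, deform, report); report includes surface RMS
#'   after rigid registration and after fitting.
#' @export
morphToTarget <- function(mesh, targetSurface, ...) {
  srcSurf <- extractSurface(mesh)
  rigid <- rigidRegister(srcSurf, targetSurface)
  aligned <- applyTransform(srcSurf, rigid)
  deform <- hostMeshFit(aligned, targetSurface, ...)
  morphed <- morphMesh(mesh, rigid, deform)
  dropped <- dropInvertedElements(morphed)
  rep <- dropped$report
  rep$rmsRigid <- deform@report$rmsRigid
  rep$rmsFit <- deform@report$rmsFit
  list(mesh = dropped$mesh, rigid = rigid, deform = deform, report = rep)
}
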