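# Parametric femur mesh generation and angle measurement.
#
# The solid is swept from circular cross-sections along a centerline with a
# single miter kink at the neck base. Cross-sections use a butterfly (O-grid)
# disk template so the mesh is all-hex with no degenerate center wedges.

# ---- disk template ---------------------------------------------------------

# Butterfly template of the unit disk: core square (m x m quads, m even) plus
# nr blended rings; boundary nodes sit at exact multiples of 2*pi/(4m).
# Returns node coords (k x 2), quads (q x 4, CCW), boundary ring indices in
# angular order, and the center node index.
diskTemplate <- function(m, nr) {
  stopifnot(m >= 2, m %% 2 == 0, nr >= 1)
  s <- 0.55  # core half-size relative to unit radius
  g <- seq(-s, s, length.out = m + 1)
  core <- cbind(rep(g, times = m + 1), rep(g, each = m + 1))
  idx <- function(i, j) j * (m + 1) + i + 1  # i, j in 0..m
  quads <- matrix(0L, 0, 4)
  for (j in 0:(m - 1)) for (i in 0:(m - 1)) {
    quads <- rbind(quads, c(idx(i, j), idx(i + 1, j),
                            idx(i + 1, j + 1), idx(i, j + 1)))
  }
  # core boundary traversal, CCW starting at (s, 0)
  half <- m %/% 2
  per <- integer(0)
  for (j in half:(m - 1)) per <- c(per, idx(m, j))          # up right edge
  for (i in m:1) per <- c(per, idx(i, m))                   # top, right->left
  for (j in m:1) per <- c(per, idx(0, j))                   # down left edge
  for (i in 0:(m - 1)) per <- c(per, idx(i, 0))             # bottom
  for (j in 0:(half - 1)) per <- c(per, idx(m, j))          # back up to (s,0)
  nper <- 4L * m
  stopifnot(length(per) == nper)
  theta <- 2 * pi * (seq_len(nper) - 1) / nper
  circ <- cbind(cos(theta), sin(theta))
  nodes <- core
  ringIdx <- vector("list", nr)
  for (r in seq_len(nr)) {
    t <- r / nr
    pts <- (1 - t) * core[per, , drop = FALSE] + t * circ
    ringIdx[[r]] <- nrow(nodes) + seq_len(nper)
    nodes <- rbind(nodes, pts)
  }
  ringPrev <- per
  for (r in seq_len(nr)) {
    ringCur <- ringIdx[[r]]
    np <- c(seq(2, nper), 1)
    quads <- rbind(quads, cbind(ringPrev, ringCur, ringCur[np], ringPrev[np]))
    ringPrev <- ringCur
  }
  list(nodes = nodes, quads = quads, boundary = ringIdx[[nr]],
       center = idx(half, half), nPerim = nper)
}

# ---- generator -------------------------------------------------------------

#' Generate a parametric femur hexahedral mesh
#'
#' Builds an idealized femur with prescribed neck-shaft angle (NSA) and
#' anteversion angle (AVA): condyle block and shaft along the superior (+y)
#' axis, neck leaving the shaft at the NSA in the frontal plane and rotated
#' anteriorly about the shaft axis by the AVA, spherical head capping the
#' neck. The growth plate is modelled as `nGpRows` contiguous transverse
#' element rows near the head-neck junction, flanked by `nTransitionRows`
#' rows on each side whose modulus grades linearly from trabecular bone to
#' growth-plate cartilage.
#'
#' Coordinate frame (right femur): origin at the distal condyle face centre,
#' +y superior along the shaft axis, +x anterior, +z lateral. The frontal
#' plane is y-z, the sagittal plane x-y, the transverse plane x-z.
#'
#' @param params a [FemurParams-class] (see [femurParams()]).
#' @param materials a [MaterialSpec-class] (see [materialSpec()]).
#' @return A [HexMesh-class] with the element/node sets documented in
#'   [HexMesh-class]; `metadata` records the parameters and exact landmark
#'   coordinates used in construction.
#' @examples
#' mesh <- generateFemur(femurParams(nsaDeg = 130, avaDeg = 30, nCirc = 8,
#'                                   nGpRows = 2, nTransitionRows = 1))
#' measureAngles(mesh)
#' @export
generateFemur <- function(params = femurParams(), materials = materialSpec()) {
  validObject(params)
  validObject(materials)
  p <- params
  m <- p@nCirc %/% 4L
  nr <- max(1L, m %/% 2L)
  tpl <- diskTemplate(m, nr)
  nDisk <- nrow(tpl$nodes)

  # centerline geometry
  L <- p@femurLengthMM
  hCond <- 0.12 * L
  hProx <- 0.88 * L
  theta <- (180 - p@nsaDeg) * pi / 180
  phi <- p@avaDeg * pi / 180
  neckDir <- c(sin(theta) * sin(phi), cos(theta), -sin(theta) * cos(phi))
  yAxis <- c(0, 1, 0)
  Rfull <- rotationBetween(yAxis, neckDir)
  bendAxis <- cross3(yAxis, neckDir)
  bendAng <- vecAngleDeg(yAxis, neckDir)
  Rhalf <- if (vecNorm(bendAxis) > 1e-12)
    rotationAboutAxis(bendAxis, bendAng / 2) else diag(3)

  R <- p@headRadiusMM
  rNeck <- p@neckRadiusMM
  sHC <- p@neckLengthMM + sqrt(R^2 - rNeck^2)

  # stations: list of (center, E = 3x2 in-plane map including radius/stretch)
  stations <- list()
  addStation <- function(center, e1, e2, radius, stretchDir = NULL,
                         stretchFac = 1) {
    M <- cbind(e1, e2) * radius
    if (!is.null(stretchDir) && abs(stretchFac - 1) > 1e-12) {
      # stretch in-plane along stretchDir (world 3-vector within the plane)
      d <- unitVec(stretchDir)
      M <- M + (stretchFac - 1) * (d %*% (t(d) %*% M))
    }
    stations[[length(stations) + 1L]] <<- list(center = center, M = M)
  }
  # in-plane axes chosen so e1 x e2 = +y (the sweep direction): e1 lateral,
  # e2 anterior; boundary node p sits at angle 2*pi*p/nCirc from +e1.
  e1g <- c(0, 0, 1); e2g <- c(1, 0, 0)

  nCondLayers <- 2L
  rCond <- p@condyleWidthMM / 2
  # condyle block: radius blends into the shaft
  for (k in 0:nCondLayers) {
    t <- k / nCondLayers
    y <- hCond * t
    r <- rCond + (p@shaftRadiusMM - rCond) * (0.5 - 0.5 * cos(pi * t))
    addStation(c(0, y, 0), e1g, e2g, r)
  }
  nCondStations <- length(stations)

  # shaft: slight taper toward the neck radius over the proximal half
  shaftStations <- integer(0)
  for (k in seq_len(p@nAxial)) {
    t <- k / p@nAxial
    y <- hCond + (hProx - hCond) * t
    taper <- max(0, (t - 0.5) / 0.5)
    r <- p@shaftRadiusMM + (rNeck - p@shaftRadiusMM) * taper
    if (k < p@nAxial) {
      addStation(c(0, y, 0), e1g, e2g, r)
      shaftStations <- c(shaftStations, length(stations))
    }
  }

  # neck base (kink) station: bisector plane with miter stretch
  NB <- c(0, hProx, 0)
  e1k <- as.numeric(Rhalf %*% e1g)
  e2k <- as.numeric(Rhalf %*% e2g)
  nbis <- unitVec(yAxis + neckDir)
  bendInPlane <- neckDir - sum(neckDir * nbis) * nbis
  stretch <- 1 / cos(bendAng / 2 * pi / 180)
  addStation(NB, e1k, e2k, rNeck, stretchDir = bendInPlane,
             stretchFac = stretch)
  kinkStation <- length(stations)

  e1n <- as.numeric(Rfull %*% e1g)
  e2n <- as.numeric(Rfull %*% e2g)

  # neck: 2 coarse pad layers then the fine growth-plate stack. The first pad
  # station must clear the axial overshoot of the mitered kink ring
  # (rNeck * tan(bend/2)) or the first neck layer inverts.
  nFine <- 2L * p@nTransitionRows + p@nGpRows
  nPad <- 2L
  overshoot <- rNeck * tan(bendAng / 2 * pi / 180)
  s1 <- max(0.125 * p@neckLengthMM, 1.6 * overshoot)
  if (s1 > 0.45 * p@neckLengthMM)
    stop("degenerate geometry: neck too short for this neck-shaft angle ",
         "(mitered junction would invert the first neck layer)")
  sFineStart <- max(0.25 * p@neckLengthMM, s1 + 0.06 * p@neckLengthMM)
  for (s in c(s1, sFineStart)) {
    addStation(NB + s * neckDir, e1n, e2n, rNeck)
  }
  for (k in seq_len(nFine)) {
    s <- sFineStart + (p@neckLengthMM - sFineStart) * k / nFine
    addStation(NB + s * neckDir, e1n, e2n, rNeck)
  }
  neckEndStation <- length(stations)

  # head: stations at equal polar-angle steps along the sphere
  HC <- NB + sHC * neckDir
  psi0 <- -acos(rNeck / R) + 1e-9
  psi1 <- asin(0.95)
  nHead <- 8L
  headStations <- integer(0)
  for (k in seq_len(nHead)) {
    psi <- psi0 + (psi1 - psi0) * k / nHead
    u <- R * sin(psi)
    r <- R * cos(psi)
    addStation(HC + u * neckDir, e1n, e2n, r)
    headStations <- c(headStations, length(stations))
  }

  # assemble nodes
  nStations <- length(stations)
  coords <- matrix(0, nStations * nDisk, 3)
  for (k in seq_len(nStations)) {
    st <- stations[[k]]
    rows <- (k - 1L) * nDisk + seq_len(nDisk)
    coords[rows, ] <- tpl$nodes %*% t(st$M) +
      matrix(st$center, nDisk, 3, byrow = TRUE)
  }
  # the head ends in a small flat cap at 0.95 R polar height; its boundary
  # ring (like all head station rings) lies exactly on the head sphere

  # elements: layer l connects stations l and l+1
  nQuads <- nrow(tpl$quads)
  nLayers <- nStations - 1L
  conn <- matrix(0L, nLayers * nQuads, 8)
  for (l in seq_len(nLayers)) {
    off0 <- (l - 1L) * nDisk
    off1 <- l * nDisk
    rows <- (l - 1L) * nQuads + seq_len(nQuads)
    conn[rows, ] <- cbind(tpl$quads + off0, tpl$quads + off1)
  }

  layerEls <- function(ls) {
    as.integer(unlist(lapply(ls, function(l) (l - 1L) * nQuads + seq_len(nQuads))))
  }
  # layer classification (layer index = distal station index)
  condLayers <- seq_len(nCondStations - 1L)
  shaftLayers <- seq(nCondStations, kinkStation - 1L)
  padLayers <- seq(kinkStation, kinkStation + nPad - 1L)
  fineStart <- kinkStation + nPad
  belowLayers <- if (p@nTransitionRows > 0)
    seq(fineStart, length.out = p@nTransitionRows) else integer(0)
  gpLayers <- seq(fineStart + p@nTransitionRows, length.out = p@nGpRows)
  aboveLayers <- if (p@nTransitionRows > 0)
    seq(fineStart + p@nTransitionRows + p@nGpRows,
        length.out = p@nTransitionRows) else integer(0)
  headLayers <- seq(neckEndStation, nStations - 1L)

  elementSets <- list(
    condyles = layerEls(condLayers),
    shaft = layerEls(shaftLayers),
    neck = layerEls(c(padLayers, belowLayers, gpLayers, aboveLayers)),
    head = layerEls(headLayers),
    cortical = layerEls(c(condLayers, shaftLayers)),
    trabecular = layerEls(c(padLayers, headLayers)),
    transition_below = layerEls(belowLayers),
    transition_above = layerEls(aboveLayers)
  )
  for (k in seq_len(p@nGpRows))
    elementSets[[paste0("growth_plate_row_", k)]] <- layerEls(gpLayers[k])

  # materials
  nEl <- nrow(conn)
  E <- rep(materials@ETrabecularMPa, nEl)
  nu <- rep(materials@nuBone, nEl)
  E[elementSets$cortical] <- materials@ECorticalMPa
  gpAll <- layerEls(gpLayers)
  E[gpAll] <- materials@EGrowthPlateMPa
  nu[gpAll] <- materials@nuGrowthPlate
  nT <- p@nTransitionRows
  if (nT > 0) {
    for (i in seq_len(nT)) {
      f <- i / (nT + 1)  # 0 at trabecular side, 1 at plate side
      Ei <- materials@ETrabecularMPa +
        (materials@EGrowthPlateMPa - materials@ETrabecularMPa) * f
      nui <- materials@nuBone + (materials@nuGrowthPlate - materials@nuBone) * f
      # transition_below: row nearest shaft is farthest from the plate
      E[layerEls(belowLayers[i])] <- Ei
      nu[layerEls(belowLayers[i])] <- nui
      # transition_above: row nearest the plate comes first
      E[layerEls(aboveLayers[nT - i + 1L])] <- Ei
      nu[layerEls(aboveLayers[nT - i + 1L])] <- nui
    }
  }

  stNodes <- function(k) (k - 1L) * nDisk + seq_len(nDisk)
  stBoundary <- function(k) (k - 1L) * nDisk + tpl$boundary
  headSurf <- unique(as.integer(
    unlist(lapply(c(neckEndStation, headStations), stBoundary))))
  nodeSets <- list(
    condyle_fixed = as.integer(stNodes(1L)),
    neck_base_ring = as.integer(stBoundary(kinkStation)),
    head_surface = headSurf,
    shaft_axis_markers = as.integer(vapply(
      c(nCondStations, shaftStations), function(k) stNodes(k)[tpl$center], 0L)),
    condyle_axis_markers = as.integer(c(stBoundary(1L)[2L * m + 1L],  # medial (-z)
                                        stBoundary(1L)[1L]))          # lateral (+z)
  )

  if (p@side == "left") {
    coords[, 3] <- -coords[, 3]
    conn <- conn[, c(4, 3, 2, 1, 8, 7, 6, 5)]
  }

  storage.mode(conn) <- "integer"
  mesh <- new("HexMesh", nodeCoords = coords, elements = conn,
              elementSets = elementSets, nodeSets = nodeSets,
              elementE = E, elementNu = nu,
              metadata = list(
                params = p, materials = materials,
                landmarks = list(headCenter = HC, neckBase = NB,
                                 neckDir = neckDir),
                generator = "parametricFemur"))
  bad <- which(minCornerJacobian(mesh) <= 0)
  if (length(bad))
    stop("degenerate geometry: ", length(bad),
         " elements with non-positive Jacobian; refine the parameters")
  mesh
}

# ---- mesh quality ----------------------------------------------------------

# local corner coordinates of the hex reference element
hexCorners <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                       -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                     8, 3, byrow = TRUE)

# edge triads per corner: indices of the three corner-adjacent nodes
hexCornerEdges <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                       c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))

#' Corner Jacobians of every element
#'
#' For each element and corner the determinant of the three outgoing edge
#' vectors (ordered so a right-handed element is positive). `scaled = TRUE`
#' divides by the product of the edge lengths (the scaled Jacobian quality
#' metric, 1 for a cube corner).
#'
#' @param mesh a [HexMesh-class]
#' @param scaled logical
#' @return m x 8 matrix of (scaled) corner Jacobians.
#' @export
cornerJacobians <- function(mesh, scaled = FALSE) {
  xyz <- mesh@nodeCoords
  conn <- mesh@elements
  out <- matrix(0, nrow(conn), 8)
  for (cidx in 1:8) {
    e <- hexCornerEdges[[cidx]]
    a <- xyz[conn[, e[1]], , drop = FALSE] - xyz[conn[, cidx], , drop = FALSE]
    b <- xyz[conn[, e[2]], , drop = FALSE] - xyz[conn[, cidx], , drop = FALSE]
    d <- xyz[conn[, e[3]], , drop = FALSE] - xyz[conn[, cidx], , drop = FALSE]
    # corner parity: edges are (xi, eta, zeta)-wards at corner 1 etc.
    detv <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
            a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
            a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
    if (scaled) {
      la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); ld <- sqrt(rowSums(d^2))
      detv <- detv / pmax(la * lb * ld, 1e-300)
    }
    out[, cidx] <- detv
  }
  out
}

#' @rdname cornerJacobians
#' @export
minCornerJacobian <- function(mesh, scaled = FALSE) {
  apply(cornerJacobians(mesh, scaled = scaled), 1, min)
}

# ---- angle measurement -----------------------------------------------------

#' Measure neck-shaft and anteversion angles on a mesh
#'
#' The femoral head centre (HC) is the least-squares sphere fit to the
#' `head_surface` nodes; the neck base (NB) is the centroid of the
#' `neck_base_ring` nodes; the neck axis is the unit vector NB -> HC. The
#' shaft axis is the principal line through the `shaft_axis_markers` nodes,
#' oriented proximally. NSA is defined as 180 degrees minus the 3D angle
#' between the neck axis and the proximal shaft axis (equivalently the angle
#' between the neck axis and the distally directed shaft, measured in the
#' plane the two axes span). AVA is the angle between the neck axis and the
#' medially directed condylar axis, both projected onto the transverse plane
#' (normal to the shaft axis).
#'
#' All quantities derive from node coordinates only, so the measures are
#' invariant under rigid motion of the mesh.
#'
#' @param mesh a [HexMesh-class] carrying `head_surface`, `neck_base_ring`,
#'   `shaft_axis_markers` and `condyle_axis_markers` node sets.
#' @return An [AngleMeasures-class] object.
#' @export
measureAngles <- function(mesh) {
  ns <- mesh@nodeSets
  need <- c("head_surface", "neck_base_ring", "shaft_axis_markers",
            "condyle_axis_markers")
  miss <- setdiff(need, names(ns))
  if (length(miss))
    stop("mesh lacks node sets: ", paste(miss, collapse = ", "))
  headPts <- mesh@nodeCoords[ns$head_surface, , drop = FALSE]
  if (nrow(headPts) < 10)
    stop("sphere fit needs at least 10 head-surface nodes")
  sf <- fitSphere(headPts)
  HC <- sf$center
  NB <- colMeans(mesh@nodeCoords[ns$neck_base_ring, , drop = FALSE])
  neckAxis <- unitVec(HC - NB)

  sm <- mesh@nodeCoords[ns$shaft_axis_markers, , drop = FALSE]
  if (nrow(sm) < 2) stop("need at least 2 shaft axis marker nodes")
  ctr <- colMeans(sm)
  sv <- svd(sweep(sm, 2, ctr))$v[, 1]
  shaftAxis <- unitVec(sv)
  if (sum(shaftAxis * (NB - ctr)) < 0) shaftAxis <- -shaftAxis  # proximal

  cm <- mesh@nodeCoords[ns$condyle_axis_markers, , drop = FALSE]
  if (nrow(cm) != 2) stop("condyle_axis_markers must contain exactly 2 nodes")
  condylarAxis <- unitVec(cm[2, ] - cm[1, ])  # medial -> lateral

  nsa <- 180 - vecAngleDeg(neckAxis, shaftAxis)
  medial <- -condylarAxis
  pn <- projectOntoPlane(neckAxis, shaftAxis)
  pm <- projectOntoPlane(medial, shaftAxis)
  ava <- vecAngleDeg(pn, pm)

  ySup <- shaftAxis
  zLat <- unitVec(projectOntoPlane(condylarAxis, ySup))
  xAnt <- cross3(ySup, zLat)
  frame <- cbind(xAnt, ySup, zLat)
  colnames(frame) <- c("anterior", "superior", "lateral")

  new("AngleMeasures", nsaDeg = nsa, avaDeg = ava, neckAxis = neckAxis,
      shaftAxis = shaftAxis, condylarAxis = condylarAxis, frame = frame,
      headCenter = HC, headRadius = sf$radius, neckBase = NB,
      alphaDeg = NA_real_, betaDeg = NA_real_,
      projections = data.frame(angle = character(), frontal = numeric(),
                               sagittal = numeric(), transverse = numeric()))
}

# ---- surface extraction ----------------------------------------------------

#' Triangulated surface
#'
#' Exterior surface of a hex mesh: vertices (a subset of mesh nodes),
#' consistently outward-oriented triangles, and the originating mesh node id
#' of every vertex.
#'
#' @slot vertices v x 3 coordinates, mm.
#' @slot triangles t x 3 integer, rows index `vertices`.
#' @slot nodeIds mesh node id per vertex (0 when not mesh-derived).
#' @export
setClass("TriSurface", representation(
  vertices = "matrix", triangles = "matrix", nodeIds = "integer"
))

setValidity("TriSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3) msg <- c(msg, "vertices must be v x 3")
  if (ncol(object@triangles) != 3) msg <- c(msg, "triangles must be t x 3")
  if (nrow(object@triangles) &&
      (min(object@triangles) < 1 || max(object@triangles) > nrow(object@vertices)))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(object@vertices), nrow(object@triangles),
              surfaceArea(object)))
})

#' @describeIn TriSurface total surface area in mm^2
#' @param x a `TriSurface`
#' @export
surfaceArea <- function(x) {
  v <- x@vertices; tr <- x@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# outward-oriented local quad faces of the hex reference element
hexFaces <- matrix(c(1, 4, 3, 2,   5, 6, 7, 8,   2, 3, 7, 6,
                     1, 5, 8, 4,   1, 2, 6, 5,   3, 4, 8, 7),
                   6, 4, byrow = TRUE)

#' Extract the exterior triangulated surface of a hex mesh
#'
#' Collects the quad faces that appear in exactly one element, splits each
#' into two triangles preserving the outward orientation, and compacts the
#' vertex list. Errors if any face is shared by more than two elements
#' (non-manifold exterior).
#'
#' @param mesh a [HexMesh-class]
#' @return A [TriSurface-class].
#' @export
extractSurface <- function(mesh) {
  conn <- mesh@elements
  nEl <- nrow(conn)
  faces <- matrix(0L, nEl * 6L, 4L)
  for (f in 1:6) {
    faces[seq(f, by = 6L, length.out = nEl), ] <-
      conn[, hexFaces[f, ], drop = FALSE]
  }
  key <- apply(faces, 1, function(r) paste(sort.int(r), collapse = "_"))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold exterior: face shared by >2 elements")
  ext <- faces[cnt[key] == 1L, , drop = FALSE]
  tri <- rbind(ext[, c(1, 2, 3)], ext[, c(1, 3, 4)])
  used <- sort(unique(as.integer(tri)))
  remap <- integer(nrow(mesh@nodeCoords))
  remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  new("TriSurface", vertices = mesh@nodeCoords[used, , drop = FALSE],
      triangles = tri, nodeIds = as.integer(used))
}

#' Per-vertex tributary areas and area-weighted normals of a surface
#' @param surface a [TriSurface-class]
#' @return list(areas, normals): tributary area (1/3 of incident triangle
#'   areas, mm^2) and unit outward normal per vertex.
#' @export
vertexAreasNormals <- function(surface) {
  v <- surface@vertices; tr <- surface@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  triArea <- sqrt(rowSums(nrm^2)) / 2
  nv <- nrow(v)
  areas <- numeric(nv)
  normals <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- tr[, k]
    areas <- areas + unname(tapply_add(idx, triArea / 3, nv))
    for (d in 1:3)
      normals[, d] <- normals[, d] + tapply_add(idx, nrm[, d], nv)
  }
  len <- sqrt(rowSums(normals^2))
  normals <- normals / pmax(len, 1e-300)
  list(areas = areas, normals = normals)
}

# accumulate values by index into a length-n vector
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Euler characteristic of a triangulated surface
#' @param surface a [TriSurface-class]
#' @return integer V - E + F (2 for a genus-0 closed surface).
#' @export
eulerCharacteristic <- function(surface) {
  tr <- surface@triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  ed <- t(apply(ed, 1, sort.int))
  nE <- nrow(unique(ed))
  nrow(surface@vertices) - nE + nrow(tr)
}

# ---- structured box mesh ---------------------------------------------------

#' Structured hexahedral box mesh
#'
#' Axis-aligned box `[0,Lx] x [0,Ly] x [0,Lz]` with `nx x ny x nz` elements
#' and uniform material; node sets `face_xmin`, `face_xmax`, ... name the six
#' boundary faces. Used for verification problems (patch tests, cantilever
#' benchmarks).
#'
#' @param nx,ny,nz element counts per direction
#' @param Lx,Ly,Lz box edge lengths, mm
#' @param E,nu material
#' @return A [HexMesh-class]
#' @export
hexBox <- function(nx, ny, nz, Lx = nx, Ly = ny, Lz = nz, E = 1000, nu = 0.3) {
  gx <- seq(0, Lx, length.out = nx + 1)
  gy <- seq(0, Ly, length.out = ny + 1)
  gz <- seq(0, Lz, length.out = nz + 1)
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  nid <- function(i, j, k) (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  conn <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                   nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                   nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  storage.mode(conn) <- "integer"
  tol <- 1e-9
  nodeSets <- list(
    face_xmin = which(coords[, 1] < tol),
    face_xmax = which(coords[, 1] > Lx - tol),
    face_ymin = which(coords[, 2] < tol),
    face_ymax = which(coords[, 2] > Ly - tol),
    face_zmin = which(coords[, 3] < tol),
    face_zmax = which(coords[, 3] > Lz - tol))
  new("HexMesh", nodeCoords = coords, elements = conn,
      elementSets = list(all = seq_len(nrow(conn))),
      nodeSets = lapply(nodeSets, as.integer),
      elementE = rep(E, nrow(conn)), elementNu = rep(nu, nrow(conn)),
      metadata = list(generator = "hexBox"))
}
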