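# Small-strain linear elasticity on 8-node hexahedra.
#
# Elements are trilinear bricks with 2x2x2 Gauss quadrature; by default the
# three Wilson incompatible bending modes (Taylor-corrected so the patch test
# is exact) are added per element and statically condensed, the standard cure
# for the parasitic shear stiffness of the plain trilinear brick in
# bending-dominated problems. Units are mm-N-MPa throughout.

# Gauss points and shape-function derivative tables (reference element)
.gaussPts <- as.matrix(expand.grid(x = c(-1, 1) / sqrt(3),
                                   y = c(-1, 1) / sqrt(3),
                                   z = c(-1, 1) / sqrt(3)))

# dN[[g]] is 8 x 3: d N_a / d xi_j at Gauss point g
.dNTables <- lapply(seq_len(8), function(g) {
  xi <- .gaussPts[g, 1]; eta <- .gaussPts[g, 2]; zeta <- .gaussPts[g, 3]
  t(vapply(seq_len(8), function(a) {
    s <- hexCorners[a, ]
    c(s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta),
      s[2] * (1 + s[1] * xi) * (1 + s[3] * zeta),
      s[3] * (1 + s[1] * xi) * (1 + s[2] * eta)) / 8
  }, numeric(3)))
})

#' Isotropic elasticity matrix (Voigt order xx, yy, zz, xy, yz, zx)
#'
#' @param E elastic modulus, MPa
#' @param nu Poisson ratio
#' @return 6 x 6 matrix mapping engineering strains to stresses, MPa.
#' @export
elasticD <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# 6 x 24 strain-displacement matrix from dNdx (8 x 3)
.bMatrix <- function(dNdx) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- dNdx[, 1]
  B[2, ix + 1] <- dNdx[, 2]
  B[3, ix + 2] <- dNdx[, 3]
  B[4, ix] <- dNdx[, 2];     B[4, ix + 1] <- dNdx[, 1]
  B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
  B[6, ix] <- dNdx[, 3];     B[6, ix + 2] <- dNdx[, 1]
  B
}

# 6 x 9 incompatible-mode matrix from dPdx (3 x 3, mode k in row k)
.gMatrix <- function(dPdx) {
  G <- matrix(0, 6, 9)
  ix <- 3 * (1:3) - 2
  G[1, ix] <- dPdx[, 1]
  G[2, ix + 1] <- dPdx[, 2]
  G[3, ix + 2] <- dPdx[, 3]
  G[4, ix] <- dPdx[, 2];     G[4, ix + 1] <- dPdx[, 1]
  G[5, ix + 1] <- dPdx[, 3]; G[5, ix + 2] <- dPdx[, 2]
  G[6, ix] <- dPdx[, 3];     G[6, ix + 2] <- dPdx[, 1]
  G
}

#' Assemble and factorize the finite-element system for a mesh
#'
#' Builds the global stiffness matrix, applies homogeneous Dirichlet
#' conditions on `fixedNodes` (all three components fixed) and factorizes the
#' reduced system with a sparse Cholesky decomposition. The returned context
#' can be reused across any number of right-hand sides (load instances,
#' growth eigenstrain loads) on the same mesh.
#'
#' @param mesh a [HexMesh-class]
#' @param fixedNodes node indices to clamp (all three components); defaults
#'   to the `condyle_fixed` node set.
#' @param enhanced use incompatible bending modes (default TRUE).
#' @param fixedDofs additional individual degrees of freedom to clamp
#'   (dof index = 3*(node-1) + component, component 1..3), for
#'   minimal-constraint verification problems.
#' @return An opaque list: stiffness, factorization, per-element
#'   volume-integrated strain-displacement operators for stress recovery.
#' @export
feContext <- function(mesh, fixedNodes = NULL, enhanced = TRUE,
                      fixedDofs = NULL) {
  if (is.null(fixedNodes) && is.null(fixedDofs)) {
    fixedNodes <- mesh@nodeSets$condyle_fixed
    if (is.null(fixedNodes))
      stop("no fixedNodes given and mesh has no 'condyle_fixed' node set")
  }
  fixedNodes <- sort(unique(as.integer(fixedNodes)))
  if (!length(fixedNodes) && !length(fixedDofs))
    stop("constraint set is empty: the mesh would have rigid-body modes")
  conn <- mesh@elements
  xyz <- mesh@nodeCoords
  mEl <- nrow(conn)
  nDof <- 3L * nrow(xyz)

  # distinct materials -> distinct D matrices
  matKey <- paste(mesh@elementE, mesh@elementNu)
  uKey <- unique(matKey)
  Dlist <- lapply(uKey, function(k) {
    i <- match(k, matKey)
    elasticD(mesh@elementE[i], mesh@elementNu[i])
  })
  matIdx <- match(matKey, uKey)

  trip_x <- numeric(mEl * 576L)
  trip_i <- integer(mEl * 576L)
  trip_j <- integer(mEl * 576L)
  Bw <- matrix(0, mEl, 144L)
  vol <- numeric(mEl)
  dN <- .dNTables
  gp <- .gaussPts
  for (e in seq_len(mEl)) {
    nodes <- conn[e, ]
    X <- xyz[nodes, , drop = FALSE]
    D <- Dlist[[matIdx[e]]]
    Kuu <- matrix(0, 24, 24)
    Bsum <- matrix(0, 6, 24)
    ve <- 0
    if (enhanced) {
      # centroid Jacobian (Taylor correction reference)
      J0 <- crossprod(X, hexCorners / 8)
      detJ0 <- det(J0)
      invJ0 <- solve(J0)
      Kua <- matrix(0, 24, 9)
      Kaa <- matrix(0, 9, 9)
    }
    for (g in seq_len(8)) {
      J <- crossprod(X, dN[[g]])
      detJ <- det(J)
      if (detJ <= 0) stop("non-positive Jacobian in element ", e)
      dNdx <- dN[[g]] %*% solve(J)
      B <- .bMatrix(dNdx)
      DB <- D %*% B
      Kuu <- Kuu + crossprod(B, DB) * detJ
      Bsum <- Bsum + B * detJ
      ve <- ve + detJ
      if (enhanced) {
        dPdx <- (-2 * detJ0 / detJ) * (diag(gp[g, ]) %*% invJ0)
        G <- .gMatrix(dPdx)
        DG <- D %*% G
        Kua <- Kua + crossprod(B, DG) * detJ
        Kaa <- Kaa + crossprod(G, DG) * detJ
      }
    }
    ke <- if (enhanced) Kuu - Kua %*% solve(Kaa, t(Kua)) else Kuu
    dofs <- as.integer(rbind(3L * nodes - 2L, 3L * nodes - 1L, 3L * nodes))
    rng <- (e - 1L) * 576L + seq_len(576L)
    trip_i[rng] <- rep(dofs, times = 24L)
    trip_j[rng] <- rep(dofs, each = 24L)
    trip_x[rng] <- as.numeric(ke)
    Bw[e, ] <- as.numeric(Bsum)
    vol[e] <- ve
  }
  K <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nDof, nDof))
  allFixed <- sort(unique(c(
    as.integer(rbind(3L * fixedNodes - 2L, 3L * fixedNodes - 1L,
                     3L * fixedNodes)),
    as.integer(fixedDofs))))
  free <- setdiff(seq_len(nDof), allFixed)
  Kff <- Matrix::forceSymmetric(K[free, free])
  fac <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE), error = function(e)
    stop("singular stiffness system (floating mesh or rank-deficient ",
         "constraints): ", conditionMessage(e)))
  list(K = K, fac = fac, free = free, fixedDofs = allFixed,
       fixedNodes = fixedNodes, Bw = Bw, vol = vol, matIdx = matIdx,
       Dlist = Dlist, nDof = nDof, enhanced = enhanced)
}

# internal: solve for possibly many right-hand sides (nDof x k matrix), in N
.feSolve <- function(ctx, F) {
  Ff <- F[ctx$free, , drop = FALSE]
  uf <- as.matrix(Matrix::solve(ctx$fac, Ff))
  U <- matrix(0, ctx$nDof, ncol(F))
  U[ctx$free, ] <- uf
  U
}

#' Solve one quasi-static load instance
#'
#' Applies the distributed hip contact force patch and the concentrated
#' muscle forces of a load instance (or any raw nodal force matrix) to the
#' mesh, with all displacement components fixed on the constraint node set,
#' and returns the equilibrium displacement field with equilibrium
#' diagnostics (relative residual on the free equations; sum of reactions vs
#' sum of applied forces).
#'
#' @param mesh a [HexMesh-class]
#' @param load a load instance (list with `jcfVectorN`, `patchNodes`,
#'   `patchWeights`, optional `muscleForces`), or an n x 3 nodal force matrix
#'   in newtons.
#' @param fixedNodes constrained nodes (default: `condyle_fixed` set).
#' @param context an optional pre-built [feContext()]; must match
#'   `fixedNodes` when both are given.
#' @return A [DisplacementField-class]
#' @export
solveInstance <- function(mesh, load, fixedNodes = NULL, context = NULL) {
  if (is.null(context)) context <- feContext(mesh, fixedNodes = fixedNodes)
  f <- nodalForces(mesh, load)
  fv <- as.numeric(t(f))
  U <- .feSolve(context, matrix(fv, ncol = 1))
  u <- matrix(U[, 1], ncol = 3, byrow = TRUE)
  resid <- sqrt(sum((as.numeric(context$K[context$free, , drop = FALSE] %*%
                                  U[, 1]) - fv[context$free])^2))
  fn <- sqrt(sum(fv[context$free]^2))
  reac <- as.numeric(context$K %*% U[, 1]) - fv
  reacM <- matrix(reac, ncol = 3, byrow = TRUE)
  instId <- if (is.list(load) && !is.null(load$index)) as.integer(load$index) else 0L
  new("DisplacementField", disp = u,
      instanceId = instId,
      fixedNodes = context$fixedNodes,
      diagnostics = list(residual = resid / max(fn, 1e-300),
                         reactionSum = colSums(reacM[context$fixedNodes, , drop = FALSE]),
                         appliedSum = colSums(f)))
}

#' Assemble the nodal force matrix (n x 3, newtons) of a load instance
#'
#' @param mesh a [HexMesh-class]
#' @param load load instance list or n x 3 matrix (returned unchanged).
#' @export
nodalForces <- function(mesh, load) {
  n <- nNodes(mesh)
  if (is.matrix(load)) {
    stopifnot(nrow(load) == n, ncol(load) == 3)
    return(load)
  }
  f <- matrix(0, n, 3)
  f[load$patchNodes, ] <- f[load$patchNodes, , drop = FALSE] +
    outer(load$patchWeights, load$jcfVectorN)
  mf <- load$muscleForces
  if (!is.null(mf) && nrow(mf)) {
    for (i in seq_len(nrow(mf)))
      f[mf$node[i], ] <- f[mf$node[i], ] + c(mf$fx[i], mf$fy[i], mf$fz[i])
  }
  f
}

#' Solve all instances of a gait load set (shared factorization)
#'
#' @param mesh a [HexMesh-class]
#' @param loadSet a [GaitLoadSet-class]
#' @param context optional [feContext()]
#' @return list of [DisplacementField-class], one per instance.
#' @export
solveLoadSet <- function(mesh, loadSet, context = NULL) {
  if (is.null(context)) context <- feContext(mesh)
  F <- vapply(loadSet@instances,
              function(ins) as.numeric(t(nodalForces(mesh, ins))),
              numeric(context$nDof))
  U <- .feSolve(context, F)
  lapply(seq_along(loadSet@instances), function(k) {
    u <- matrix(U[, k], ncol = 3, byrow = TRUE)
    fv <- F[, k]
    resid <- sqrt(sum((as.numeric(context$K[context$free, , drop = FALSE] %*%
                                    U[, k]) - fv[context$free])^2))
    fn <- sqrt(sum(fv[context$free]^2))
    new("DisplacementField", disp = u,
        instanceId = as.integer(loadSet@instances[[k]]$index %||% k),
        fixedNodes = context$fixedNodes,
        diagnostics = list(residual = resid / max(fn, 1e-300)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Octahedral shear stress from principal stresses
#'
#' `sqrt((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 3`; zero for any hydrostatic
#' state.
#' @param s1,s2,s3 principal stresses, MPa
#' @export
octahedralShear <- function(s1, s2, s3) {
  sqrt((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2) / 3
}

#' Hydrostatic (mean) stress from principal stresses
#' @param s1,s2,s3 principal stresses, MPa
#' @export
hydrostaticStress <- function(s1, s2, s3) (s1 + s2 + s3) / 3

#' Centroid-averaged element principal stresses
#'
#' The element stress tensor is the volume-weighted Gauss-point average of
#' `D B u`; its eigenvalues (sorted descending, tension positive) and the
#' derived octahedral shear and hydrostatic invariants are returned.
#'
#' @param mesh a [HexMesh-class]
#' @param disp a [DisplacementField-class]
#' @param elements element ids to evaluate (default: all).
#' @param context optional [feContext()] to reuse assembly byproducts.
#' @return A [PrincipalStressField-class]
#' @export
elementStresses <- function(mesh, disp, elements = NULL, context = NULL) {
  if (is.null(context)) context <- feContext(mesh)
  if (is.null(elements)) elements <- seq_len(nElements(mesh))
  elements <- as.integer(elements)
  uAll <- as.numeric(t(disp@disp))
  k <- length(elements)
  sig <- matrix(0, k, 3)
  d1 <- matrix(0, k, 3)
  ev <- matrix(0, k, 9)
  sS <- numeric(k); sH <- numeric(k)
  conn <- mesh@elements
  for (ii in seq_len(k)) {
    e <- elements[ii]
    nodes <- conn[e, ]
    dofs <- as.integer(rbind(3L * nodes - 2L, 3L * nodes - 1L, 3L * nodes))
    Bbar <- matrix(context$Bw[e, ], 6, 24) / context$vol[e]
    sv <- context$Dlist[[context$matIdx[e]]] %*% (Bbar %*% uAll[dofs])
    S <- matrix(c(sv[1], sv[4], sv[6],
                  sv[4], sv[2], sv[5],
                  sv[6], sv[5], sv[3]), 3, 3)
    eg <- eigen(S, symmetric = TRUE)
    sig[ii, ] <- eg$values
    d1[ii, ] <- eg$vectors[, 1]
    ev[ii, ] <- as.numeric(eg$vectors)
    sS[ii] <- octahedralShear(eg$values[1], eg$values[2], eg$values[3])
    sH[ii] <- hydrostaticStress(eg$values[1], eg$values[2], eg$values[3])
  }
  new("PrincipalStressField", elementIds = elements, sigma = sig,
      sigmaS = sS, sigmaH = sH, dir1 = d1, eigvecs = ev,
      instanceId = disp@instanceId)
}

#' Mean deflection of the femoral head centre and neck base
#'
#' `dHC` is the mean displacement of the `head_surface` nodes, `dNB` the mean
#' displacement of the `neck_base_ring` nodes.
#'
#' @param mesh a [HexMesh-class]
#' @param disp a [DisplacementField-class]
#' @return list(dHC, dNB), mm.
#' @export
neckDeflection <- function(mesh, disp) {
  hs <- mesh@nodeSets$head_surface
  nb <- mesh@nodeSets$neck_base_ring
  if (!length(hs) || !length(nb))
    stop("mesh lacks head_surface / neck_base_ring node sets")
  list(dHC = colMeans(disp@disp[hs, , drop = FALSE]),
       dNB = colMeans(disp@disp[nb, , drop = FALSE]))
}

#' Eigenstrain (growth) load vector
#'
#' Equivalent nodal forces of a stress-free strain `strain[k]` acting purely
#' along the unit direction `dirs[k, ]` in element `elementIds[k]` (the
#' thermal-expansion analogy with coefficient one along the growth direction
#' and zero transverse).
#'
#' @param mesh a [HexMesh-class]
#' @param context a [feContext()]
#' @param elementIds elements carrying growth strain
#' @param strains strain magnitude per element
#' @param dirs k x 3 matrix (or single 3-vector) of growth directions
#' @return n x 3 nodal force matrix, N.
#' @export
growthForces <- function(mesh, context, elementIds, strains, dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, length(elementIds), 3, byrow = TRUE)
  f <- matrix(0, nNodes(mesh), 3)
  conn <- mesh@elements
  for (k in seq_along(elementIds)) {
    e <- elementIds[k]
    d <- unitVec(dirs[k, ])
    eps0 <- strains[k] * c(d[1]^2, d[2]^2, d[3]^2,
                           2 * d[1] * d[2], 2 * d[2] * d[3], 2 * d[3] * d[1])
    Bw <- matrix(context$Bw[e, ], 6, 24)
    fe <- crossprod(Bw, context$Dlist[[context$matIdx[e]]] %*% eps0)
    nodes <- conn[e, ]
    fm <- matrix(fe, 8, 3, byrow = TRUE)
    f[nodes, ] <- f[nodes, , drop = FALSE] + fm
  }
  f
}
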