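# minimal rigid-body constraints for a unit cube at the origin:
# node at (0,0,0) fully fixed, (1,0,0) fixed in y,z, (0,1,0) fixed in z
.cubeMinimalDofs <- function(mesh) {
  co <- nodeCoords(mesh)
  nid <- function(p) which(colSums(abs(t(co) - p)) < 1e-9)
  n1 <- nid(c(0, 0, 0)); n2 <- nid(c(1, 0, 0)); n3 <- nid(c(0, 1, 0))
  c(3 * n1 - 2, 3 * n1 - 1, 3 * n1, 3 * n2 - 1, 3 * n2, 3 * n3)
}

test_that("zero load produces zero displacement", {
  mesh <- hexBox(2, 2, 2, 2, 2, 2)
  ctx <- feContext(mesh, fixedNodes = nodeSets(mesh)$face_xmin)
  d <- solveInstance(mesh, matrix(0, nNodes(mesh), 3), context = ctx)
  expect_equal(max(abs(d@disp)), 0)
})

test_that("single-element uniaxial patch test is exact", {
  E <- 1000; nu <- 0.3; sigma0 <- 7
  mesh <- hexBox(1, 1, 1, 1, 1, 1, E = E, nu = nu)
  ctx <- feContext(mesh, fixedDofs = .cubeMinimalDofs(mesh))
  f <- matrix(0, 8, 3)
  f[nodeSets(mesh)$face_xmax, 1] <- sigma0 / 4
  f[nodeSets(mesh)$face_xmin, 1] <- -sigma0 / 4
  d <- solveInstance(mesh, f, context = ctx)
  co <- nodeCoords(mesh)
  uExact <- cbind(sigma0 / E * co[, 1], -nu * sigma0 / E * co[, 2],
                  -nu * sigma0 / E * co[, 3])
  expect_lt(max(abs(d@disp - uExact)), 1e-12)
  st <- elementStresses(mesh, d, context = ctx)
  expect_equal(st@sigma[1, ], c(sigma0, 0, 0), tolerance = 1e-12)
  expect_equal(st@sigmaS, sqrt(2) / 3 * sigma0, tolerance = 1e-12)
  expect_equal(st@sigmaH, sigma0 / 3, tolerance = 1e-12)
})

test_that("stress invariants match direct evaluation", {
  expect_equal(octahedralShear(3, 2, 1), sqrt(6) / 3, tolerance = 1e-15)
  expect_equal(hydrostaticStress(3, 2, 1), 2)
  expect_identical(octahedralShear(5, 5, 5), 0)
  expect_equal(octahedralShear(9, 0, 0), sqrt(2) / 3 * 9, tolerance = 1e-15)
})

test_that("solution is linear in the load", {
  mesh <- tinyFemur()
  ctx <- feContext(mesh)
  set.seed(7)
  f1 <- matrix(0, nNodes(mesh), 3)
  hs <- nodeSets(mesh)$head_surface
  f1[hs, ] <- matrix(rnorm(3 * length(hs), sd = 10), length(hs), 3)
  f2 <- matrix(0, nNodes(mesh), 3)
  f2[hs, 2] <- -25
  u1 <- solveInstance(mesh, f1, context = ctx)@disp
  u2 <- solveInstance(mesh, f2, context = ctx)@disp
  u12 <- solveInstance(mesh, f1 + f2, context = ctx)@disp
  u2x <- solveInstance(mesh, 2 * f1, context = ctx)@disp
  scale <- max(abs(u12))
  expect_lt(max(abs(u12 - (u1 + u2))) / scale, 1e-9)
  expect_lt(max(abs(u2x - 2 * u1)) / scale, 1e-9)
})

test_that("principal stresses are invariant under rigid rotation", {
  mesh <- tinyFemur()
  ctx <- feContext(mesh)
  ls <- buildLoadSet(mesh, synthHipJCF(), muscleSpec = NULL)
  d <- solveInstance(mesh, ls@instances[[3]], context = ctx)
  st <- elementStresses(mesh, d, elements = 1:50, context = ctx)

  R <- femurFE:::rotationAboutAxis(c(1, 1, 2), 37)
  m2 <- mesh
  m2@nodeCoords <- mesh@nodeCoords %*% t(R)
  ctx2 <- feContext(m2)
  f <- nodalForces(mesh, ls@instances[[3]]) %*% t(R)
  d2 <- solveInstance(m2, f, context = ctx2)
  st2 <- elementStresses(m2, d2, elements = 1:50, context = ctx2)
  expect_lt(max(abs(st2@sigma - st@sigma)) / max(abs(st@sigma)), 1e-6)
})

test_that("global equilibrium holds for femur gait solves", {
  mesh <- tinyFemur()
  ctx <- feContext(mesh)
  ls <- buildLoadSet(mesh, synthHipJCF())
  for (k in c(1, 5, 9)) {
    d <- solveInstance(mesh, ls@instances[[k]], context = ctx)
    expect_lt(d@diagnostics$residual, 1e-9)
    imbalance <- d@diagnostics$reactionSum + d@diagnostics$appliedSum
    expect_lt(max(abs(imbalance)) / max(abs(d@diagnostics$appliedSum)), 1e-9)
  }
})

test_that("neck deflection is the mean landmark displacement", {
  mesh <- tinyFemur()
  zero <- new("DisplacementField", disp = matrix(0, nNodes(mesh), 3),
              instanceId = 0L, fixedNodes = integer(0),
              diagnostics = list(residual = 0))
  nd <- neckDeflection(mesh, zero)
  expect_equal(nd$dHC, c(0, 0, 0))
  expect_equal(nd$dNB, c(0, 0, 0))

  t0 <- c(1.5, -2, 0.25)
  rigid <- zero
  rigid@disp <- matrix(t0, nNodes(mesh), 3, byrow = TRUE)
  rigid@fixedNodes <- integer(0)
  nd2 <- neckDeflection(mesh, rigid)
  expect_equal(nd2$dHC, t0, ignore_attr = TRUE)
  expect_equal(nd2$dNB, t0, ignore_attr = TRUE)

  # additivity under superposed loads (solver linearity)
  ctx <- feContext(mesh)
  ls <- buildLoadSet(mesh, synthHipJCF(), muscleSpec = NULL)
  fA <- nodalForces(mesh, ls@instances[[2]])
  fB <- nodalForces(mesh, ls@instances[[7]])
  dA <- neckDeflection(mesh, solveInstance(mesh, fA, context = ctx))
  dB <- neckDeflection(mesh, solveInstance(mesh, fB, context = ctx))
  dAB <- neckDeflection(mesh, solveInstance(mesh, fA + fB, context = ctx))
  expect_equal(dAB$dHC, dA$dHC + dB$dHC, tolerance = 1e-9)
  expect_equal(dAB$dNB, dA$dNB + dB$dNB, tolerance = 1e-9)
})

test_that("floating meshes are rejected with a clear error", {
  mesh <- hexBox(1, 1, 1)
  expect_error(feContext(mesh, fixedNodes = integer(0)), "empty")
  # constraints that leave a rigid-body mode -> singular factorization
  expect_error(suppressWarnings(feContext(mesh, fixedDofs = c(1L, 2L, 3L))),
               "singular")
})
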