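test_that("rigid registration recovers known transforms", {
  surf <- extractSurface(tinyFemur())
  X <- surf@vertices

  # identity
  tr0 <- rigidRegister(X, X)
  expect_lt(max(abs(tr0@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr0@translation)), 1e-6)

  # apply-then-recover, moderate misalignment
  R0 <- femurFE:::rotationAboutAxis(c(0.2, 1, 0.4), 15)
  t0 <- c(8, -5, 12)
  Y <- X %*% t(R0) + matrix(t0, nrow(X), 3, byrow = TRUE)
  tr <- rigidRegister(X, Y)
  expect_lt(max(abs(tr@rotation - R0)), 1e-6)
  expect_lt(max(abs(tr@translation - t0)), 1e-4)

  # large misalignment with landmark seeding
  R1 <- femurFE:::rotationAboutAxis(c(1, 0.3, -0.5), 95)
  Y1 <- X %*% t(R1) + 40
  lm <- round(seq(1, nrow(X), length.out = 4))
  tr1 <- rigidRegister(X, Y1, landmarksSource = X[lm, ],
                       landmarksTarget = Y1[lm, ])
  expect_lt(max(abs(tr1@rotation - R1)), 1e-6)
})

test_that("registration of noisy clouds reaches the noise floor", {
  X <- extractSurface(tinyFemur())@vertices
  set.seed(11)
  Y <- X + matrix(rnorm(length(X), sd = 0.1), nrow(X), 3)
  tr <- rigidRegister(X, Y)
  expect_lte(attr(tr, "rms"), 0.2)
})

test_that("degenerate point clouds are rejected", {
  line <- cbind(seq_len(30), 0, 0)
  expect_error(rigidRegister(line, line + 1), "collinear")
})

test_that("host-mesh fit of identical surfaces is the identity", {
  s <- extractSurface(tinyFemur())
  hm <- hostMeshFit(s, s)
  expect_lt(max(abs(hm@controlFit - hm@controlOrig)), 1e-6)
  expect_lt(hm@report$rmsFit, 1e-6)
  expect_true(all(hm@embedding >= -1e-9 & hm@embedding <= 1 + 1e-9))
})

test_that("an affine stretch is representable by the lattice", {
  s <- extractSurface(tinyFemur())
  t <- s
  t@vertices[, 2] <- 1.1 * t@vertices[, 2]  # 10% stretch along the shaft
  hm <- hostMeshFit(s, t, correspondence = "index")
  expect_lte(hm@report$rmsFit, 0.1)
})

test_that("host-mesh fitting never loses to rigid registration alone", {
  ref <- tinyFemur(127, 27)
  for (g in list(c(140, 20), c(120, 40))) {
    tgt <- extractSurface(tinyFemur(g[1], g[2]))
    res <- morphToTarget(ref, tgt)
    expect_lte(res$report$rmsFit, res$report$rmsRigid)
  }
})

test_that("morphing a full mesh preserves structure and hits the target", {
  ref <- defaultFemur(127, 27)
  tgt <- defaultFemur(150, 20)
  res <- morphToTarget(ref, extractSurface(tgt), correspondence = "index")
  expect_lt(res$report$rmsFit, 3)
  am <- measureAngles(res$mesh)
  expect_lt(abs(nsaDeg(am) - 150), 2)
  expect_lt(abs(avaDeg(am) - 20), 2)
  # connectivity, sets and materials carried over
  expect_identical(res$mesh@elements, ref@elements)
  expect_identical(res$mesh@elementSets, ref@elementSets)
  expect_identical(res$mesh@elementE, ref@elementE)
})

test_that("identity and rigid morphs behave as expected", {
  mesh <- tinyFemur()
  ident <- new("RigidTransform", rotation = diag(3),
               translation = c(0, 0, 0), scale = 1)
  m0 <- morphMesh(mesh, ident)
  expect_equal(m0@nodeCoords, mesh@nodeCoords)
  expect_length(m0@metadata$invertedElements, 0)

  tr <- new("RigidTransform", rotation = rotationZ(25),
            translation = c(3, 1, -2), scale = 1)
  m1 <- morphMesh(mesh, tr)
  v0 <- femurFE:::minCornerJacobian(mesh)
  v1 <- femurFE:::minCornerJacobian(m1)
  expect_lt(max(abs(v1 - v0)) / max(abs(v0)), 1e-9)
})

test_that("negative-volume element removal follows the distal-only policy", {
  mesh <- tinyFemur()
  clean <- dropInvertedElements(mesh)
  expect_identical(clean$report$count, 0L)
  expect_identical(clean$mesh@elements, mesh@elements)

  # hand-invert one condyle (distal) element
  bad <- mesh
  e <- elementSets(mesh)$condyles[1]
  bad@elements[e, ] <- bad@elements[e, c(5:8, 1:4)]
  res <- dropInvertedElements(bad)
  expect_identical(res$report$count, 1L)
  expect_identical(res$report$ids, e)
  expect_equal(res$report$fraction, 1 / nElements(mesh))
  expect_match(res$report$location, "condyles")
  expect_equal(nElements(res$mesh), nElements(mesh) - 1L)

  # inverted growth-plate element -> abort
  bad2 <- mesh
  e2 <- elementSets(mesh)$growth_plate_row_2[1]
  bad2@elements[e2, ] <- bad2@elements[e2, c(5:8, 1:4)]
  expect_error(dropInvertedElements(bad2), "growth plate")
})

test_that("surface RMS matches closed-form distances", {
  sq <- function(z) new("TriSurface",
                        vertices = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), z),
                        triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                        nodeIds = integer(4))
  expect_equal(surfaceRMS(sq(0), sq(0)), 0)
  expect_equal(surfaceRMS(sq(0), sq(0.7)), 0.7, tolerance = 1e-12)

  s1 <- uvSphere(c(1, 2, 3), 10)
  s2 <- uvSphere(c(1, 2, 3), 10.5)
  expect_equal(surfaceRMS(s1, s2), 0.5, tolerance = 0.1)
  expect_error(surfaceRMS(s1, new("TriSurface",
                                  vertices = matrix(0, 0, 3),
                                  triangles = matrix(0L, 0, 3),
                                  nodeIds = integer(0))), "empty")
})

test_that("morphing commutes with rigid motion of the problem", {
  mesh <- tinyFemur(127, 27)
  tgt <- extractSurface(tinyFemur(140, 20))
  resA <- morphToTarget(mesh, tgt)

  R <- femurFE:::rotationAboutAxis(c(0.3, 1, 0.2), 28)
  t0 <- c(10, -4, 6)
  rot <- function(P) P %*% t(R) + matrix(t0, nrow(P), 3, byrow = TRUE)
  meshR <- mesh; meshR@nodeCoords <- rot(mesh@nodeCoords)
  tgtR <- tgt; tgtR@vertices <- rot(tgt@vertices)
  resB <- morphToTarget(meshR, tgtR)
  expect_lt(max(abs(resB$mesh@nodeCoords - rot(resA$mesh@nodeCoords))), 1e-6)
})
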