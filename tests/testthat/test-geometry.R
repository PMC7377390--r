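test_that("generated femurs reproduce the requested NSA and AVA", {
  for (nsa in c(120, 130, 140, 150)) for (ava in c(20, 30, 40, 50)) {
    am <- measureAngles(tinyFemur(nsa, ava))
    expect_lt(abs(nsaDeg(am) - nsa), 0.5)
    expect_lt(abs(avaDeg(am) - ava), 0.5)
  }
})

test_that("generated meshes are valid all-hex meshes with correct layering", {
  mesh <- tinyFemur()
  expect_true(all(minCornerJacobian(mesh) > 0))
  es <- elementSets(mesh)
  gpNames <- grep("^growth_plate_row_", names(es), value = TRUE)
  expect_length(gpNames, 3L)
  ringCount <- length(es$growth_plate_row_1)
  # each growth-plate row is one full transverse element ring
  for (nm in gpNames) expect_length(es[[nm]], ringCount)
  # material partition and regional partition each cover the mesh exactly
  matSets <- c("cortical", "trabecular", "transition_below",
               "transition_above", gpNames)
  regSets <- c("condyles", "shaft", "neck", "head")
  for (group in list(matSets, regSets)) {
    ids <- unlist(es[group], use.names = FALSE)
    expect_length(ids, nElements(mesh))
    expect_false(any(duplicated(ids)))
  }
  expect_gt(length(nodeSets(mesh)$condyle_fixed), 0)
})

test_that("mesh quality holds across the default parameter grid", {
  for (g in list(c(120, 20), c(150, 50), c(127, 27))) {
    sj <- minCornerJacobian(defaultFemur(g[1], g[2]), scaled = TRUE)
    expect_gt(min(sj), 0.2)
  }
})

test_that("transition-zone modulus grades linearly and symmetrically", {
  mesh <- generateFemur(femurParams(nCirc = 8, nGpRows = 3,
                                    nTransitionRows = 4))
  es <- elementSets(mesh)
  mat <- elementMaterials(mesh)
  ETrab <- materialSpec()@ETrabecularMPa
  EGp <- materialSpec()@EGrowthPlateMPa
  # per-row moduli, ordered distal -> proximal through the stack
  rowE <- function(ids) unique(mat$E[ids])
  nT <- 4
  below <- vapply(seq_len(nT), function(i) {
    ids <- es$transition_below
    rowE(ids[seq((i - 1) * 12 + 1, i * 12)])
  }, 0)
  above <- vapply(seq_len(nT), function(i) {
    ids <- es$transition_above
    rowE(ids[seq((i - 1) * 12 + 1, i * 12)])
  }, 0)
  # strictly monotone between trabecular and growth-plate values
  expect_true(all(diff(below) < 0))
  expect_true(all(below < ETrab) && all(below > EGp))
  # symmetric about the plate: above (plate->trabecular) mirrors below
  expect_equal(rev(above), below, tolerance = 1e-12)
  # linear: constant second difference
  expect_lt(max(abs(diff(below, differences = 2))), 1e-9)
})

test_that("angle measurement matches an analytic construction", {
  # straight neck at exactly 130 degrees, zero torsion, spherical head
  mesh <- generateFemur(femurParams(nsaDeg = 130, avaDeg = 0, nCirc = 8,
                                    nGpRows = 2, nTransitionRows = 1))
  am <- measureAngles(mesh)
  expect_lt(abs(nsaDeg(am) - 130), 0.1)
  expect_lt(abs(avaDeg(am) - 0), 0.1)
  expect_equal(am@headRadius, femurParams()@headRadiusMM, tolerance = 1e-6)
})

test_that("angle measures are invariant under rigid motion", {
  mesh <- tinyFemur(135, 35)
  a0 <- measureAngles(mesh)
  set.seed(42)
  for (k in 1:3) {
    ax <- rnorm(3); ang <- runif(1, 10, 170)
    R <- femurFE:::rotationAboutAxis(ax, ang)
    m2 <- mesh
    m2@nodeCoords <- mesh@nodeCoords %*% t(R) +
      matrix(rnorm(3, sd = 50), nNodes(mesh), 3, byrow = TRUE)
    a1 <- measureAngles(m2)
    expect_lt(abs(nsaDeg(a1) - nsaDeg(a0)), 1e-6)
    expect_lt(abs(avaDeg(a1) - avaDeg(a0)), 1e-6)
  }
})

test_that("degenerate geometry and missing landmarks raise errors", {
  expect_error(femurParams(neckRadiusMM = 20, headRadiusMM = 17),
               "neckRadiusMM")
  expect_error(femurParams(nCirc = 10), "multiple of 8")
  mesh <- tinyFemur()
  crippled <- mesh
  crippled@nodeSets$head_surface <- crippled@nodeSets$head_surface[1:5]
  expect_error(measureAngles(crippled), "at least 10 head-surface")
})

test_that("surface extraction yields a closed, correctly oriented surface", {
  cube <- hexBox(1, 1, 1, 1, 1, 1)
  s <- extractSurface(cube)
  expect_equal(nrow(s@triangles), 12)
  expect_equal(surfaceArea(s), 6, tolerance = 1e-12)
  # outward orientation: signed volume of the surface equals the cube volume
  v <- s@vertices; tr <- s@triangles
  vol <- sum(vapply(seq_len(nrow(tr)), function(i) {
    det(rbind(v[tr[i, 1], ], v[tr[i, 2], ], v[tr[i, 3], ])) / 6
  }, 0))
  expect_equal(vol, 1, tolerance = 1e-12)

  femSurf <- extractSurface(tinyFemur())
  expect_equal(eulerCharacteristic(femSurf), 2)
})

test_that("STL round trip preserves the vertex set", {
  s <- extractSurface(tinyFemur())
  for (binary in c(FALSE, TRUE)) {
    f <- tempfile(fileext = ".stl")
    writeSTL(s, f, binary = binary)
    s2 <- readSTL(f)
    expect_equal(nrow(s2@triangles), nrow(s@triangles))
    # same vertex set up to ordering and write precision
    idx <- femurFE:::nearestNeighbours(s2@vertices, s@vertices)$index
    d <- abs(s2@vertices - s@vertices[idx, ])
    expect_lt(max(d), if (binary) 1e-3 else 1e-6)
    unlink(f)
  }
})

test_that("VTK and INP round trips preserve mesh structure", {
  mesh <- tinyFemur()
  fv <- tempfile(fileext = ".vtk")
  writeVTK(mesh, fv, cellData = list(E = mesh@elementE))
  m2 <- readVTK(fv)
  expect_equal(m2@nodeCoords, mesh@nodeCoords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(m2@elements, mesh@elements)
  unlink(fv)

  fi <- tempfile(fileext = ".inp")
  writeINP(mesh, fi)
  m3 <- readINP(fi)
  expect_equal(m3@nodeCoords, mesh@nodeCoords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(m3@elements, mesh@elements)
  expect_setequal(names(m3@elementSets), names(mesh@elementSets))
  expect_identical(m3@nodeSets$condyle_fixed, mesh@nodeSets$condyle_fixed)
  unlink(fi)
})
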