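# build a synthetic principal-stress field over k elements
.mkField <- function(sigma, ids = seq_len(nrow(sigma)), inst = 1L,
                     eigvecs = NULL) {
  k <- nrow(sigma)
  if (is.null(eigvecs)) eigvecs <- matrix(rep(as.numeric(diag(3)), k), k, 9,
                                          byrow = TRUE)
  new("PrincipalStressField", elementIds = as.integer(ids), sigma = sigma,
      sigmaS = octahedralShear(sigma[, 1], sigma[, 2], sigma[, 3]),
      sigmaH = hydrostaticStress(sigma[, 1], sigma[, 2], sigma[, 3]),
      dir1 = eigvecs[, 1:3, drop = FALSE], eigvecs = eigvecs,
      instanceId = as.integer(inst))
}

test_that("osteogenic index follows its defining combination", {
  # uniaxial tension along the neck with superposed hydrostatic compression:
  # (1.5 + p, p, p) with p = -sqrt(2)/2 gives sigmaS = sqrt(2)/2 exactly and
  # sigmaH = 0.5 - sqrt(2)/2; with a = 1, b = 0.5 the OI is their combination
  p <- -sqrt(2) / 2
  fields <- lapply(1:9, function(i)
    .mkField(matrix(c(1.5 + p, p, p), 1, 3), inst = i))
  sS <- octahedralShear(1.5 + p, p, p)
  sH <- hydrostaticStress(1.5 + p, p, p)
  gf <- osteogenicIndex(fields, growthConfig(a = 1, b = 0.5))
  expect_equal(gf@maxSigmaS, sS)
  expect_equal(gf@minSigmaH, sH)
  expect_equal(gf@oi, 1 * sS + 0.5 * sH, tolerance = 1e-15)
  # hand value: sigmaS of a uniaxial 1.5 MPa state is sqrt(2)/2
  expect_equal(sS, sqrt(2) / 2, tolerance = 1e-15)

  zero <- lapply(1:9, function(i) .mkField(matrix(0, 2, 3), inst = i))
  expect_equal(osteogenicIndex(zero)@oi, c(0, 0))

  expect_error(osteogenicIndex(fields[1:5]), "exactly 9")
})

test_that("osteogenic index is linear in the applied loads", {
  mesh <- tinyFemur()
  ctx <- feContext(mesh)
  ls <- buildLoadSet(mesh, synthHipJCF(), muscleSpec = NULL)
  gpe <- femurFE:::.growthPlateElements(mesh)
  getOI <- function(scale) {
    fields <- lapply(ls@instances, function(ins) {
      f <- scale * nodalForces(mesh, ins)
      elementStresses(mesh, solveInstance(mesh, f, context = ctx),
                      elements = gpe$all, context = ctx)
    })
    osteogenicIndex(fields)@oi
  }
  oi1 <- getOI(1)
  oi2 <- getOI(2)
  expect_equal(oi2, 2 * oi1, tolerance = 1e-9)
})

test_that("neck-deflection growth direction reproduces hand-computed values", {
  HC <- c(0, 10, 0); NB <- c(0, 0, 0)
  zero <- lapply(1:9, function(i) list(dHC = c(0, 0, 0), dNB = c(0, 0, 0)))
  expect_equal(growthDirectionNeckDeflection(HC, NB, zero), c(0, 1, 0))

  defl <- lapply(1:9, function(i) list(dHC = c(1, 0, 0), dNB = c(0, 0, 0)))
  expect_equal(growthDirectionNeckDeflection(HC, NB, defl),
               c(1, 10, 0) / sqrt(101), tolerance = 1e-12)

  set.seed(3)
  for (k in 1:10) {
    d <- lapply(1:9, function(i) list(dHC = rnorm(3), dNB = rnorm(3)))
    g <- growthDirectionNeckDeflection(HC, NB, d)
    expect_equal(sum(g^2), 1, tolerance = 1e-12)
  }
  coincide <- lapply(1:9, function(i) list(dHC = c(0, -10, 0), dNB = c(0, 0, 0)))
  expect_error(growthDirectionNeckDeflection(HC, NB, coincide), "degenerate")
})

test_that("principal-stress growth direction handles signs and degeneracy", {
  neck <- c(0, 1, 0)
  # uniaxial tension along x, eigenvector pointing -x: sign flipped to +neck
  V <- cbind(c(-1, 0.2, 0), c(0.2, 1, 0), c(0, 0, 1))
  V <- qr.Q(qr(V))
  fields <- lapply(1:9, function(i)
    .mkField(matrix(c(5, 0, 0), 1, 3), eigvecs = matrix(as.numeric(V), 1, 9),
             inst = i))
  d <- growthDirectionPrincipalStress(fields, neck)
  expect_gte(sum(d[1, ] * neck), 0)
  expect_equal(abs(sum(d[1, ] * V[, 1])), 1, tolerance = 1e-12)

  hydro <- lapply(1:9, function(i) .mkField(matrix(c(2, 2, 2), 1, 3), inst = i))
  expect_message(dh <- growthDirectionPrincipalStress(hydro, neck),
                 "degenerate")
  expect_true(attr(dh, "degenerate")[1])

  # equivariance under rotation of the stress state
  R <- femurFE:::rotationAboutAxis(c(1, 2, 0.5), 41)
  fieldsR <- lapply(1:9, function(i)
    .mkField(matrix(c(5, 0, 0), 1, 3),
             eigvecs = matrix(as.numeric(R %*% V), 1, 9), inst = i))
  dR <- growthDirectionPrincipalStress(fieldsR, as.numeric(R %*% neck))
  expect_equal(abs(sum(dR[1, ] * (R %*% d[1, ]))), 1, tolerance = 1e-9)
})

test_that("eigenstrain growth stretches a free element exactly", {
  g <- 0.02
  mesh <- hexBox(1, 1, 1, 1, 1, 1, E = 500, nu = 0.25)
  co <- nodeCoords(mesh)
  nid <- function(p) which(colSums(abs(t(co) - p)) < 1e-9)
  fixed <- c(3 * nid(c(0, 0, 0)) - 2, 3 * nid(c(0, 0, 0)) - 1,
             3 * nid(c(0, 0, 0)), 3 * nid(c(1, 0, 0)) - 1,
             3 * nid(c(1, 0, 0)), 3 * nid(c(0, 1, 0)))
  ctx <- feContext(mesh, fixedDofs = fixed)
  gf <- new("GrowthField", elementIds = 1L, maxSigmaS = 0, minSigmaH = 0,
            oi = 0, strain = g, direction = c(1, 0, 0),
            headCenter = numeric(0), neckBase = numeric(0),
            meanDeflHC = numeric(0), meanDeflNB = numeric(0), meta = list())
  grown <- applyGrowth(mesh, gf, growthConfig(amplification = 1),
                       context = ctx)
  ext <- function(m, j) diff(range(nodeCoords(m)[, j]))
  expect_equal(ext(grown, 1), 1 + g, tolerance = 1e-6)
  expect_equal(ext(grown, 2), 1, tolerance = 1e-6)
  expect_equal(ext(grown, 3), 1, tolerance = 1e-6)

  # amplification multiplies the growth displacement exactly
  grown10 <- applyGrowth(mesh, gf, growthConfig(amplification = 10),
                         context = ctx)
  d1 <- grown@nodeCoords - mesh@nodeCoords
  d10 <- grown10@nodeCoords - mesh@nodeCoords
  expect_equal(d10, 10 * d1, tolerance = 1e-12)

  # zero strain -> identity mesh
  gf0 <- gf; gf0@strain <- 0
  same <- applyGrowth(mesh, gf0, growthConfig(), context = ctx)
  expect_identical(same@nodeCoords, mesh@nodeCoords)
})

test_that("growth strains clamp at zero under strong compression", {
  sigma <- matrix(c(-5, -6, -7), 1, 3)  # near-hydrostatic compression
  fields <- lapply(1:9, function(i) .mkField(sigma, inst = i))
  gf <- osteogenicIndex(fields)
  expect_lt(gf@oi, 0)
  cfg <- growthConfig(epsBio = 0.005)
  gs <- growthStrains(gf, cfg, kScale = 1)  # strong mechanical inhibition
  expect_identical(gs@strain, 0)
  gsWeak <- growthStrains(gf, cfg, kScale = 1e-6)
  expect_lt(abs(gsWeak@strain - cfg@epsBio) / cfg@epsBio, 1e-2)
  expect_lte(gsWeak@strain, cfg@epsBio)
})
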