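test_that("synthetic waveform has the prescribed double-peak structure", {
  wf <- synthHipJCF()
  r <- resultantBW(wf)
  expect_gte(max(r), 4)
  expect_lte(max(r), 5)
  # exactly two interior local maxima over the stance phase
  expect_identical(sum(diff(sign(diff(r))) == -2), 2L)
  # near-zero late swing
  expect_lt(max(r[wf@phase > 60]), 1e-12)
})

test_that("waveform is deterministic and symmetric when peaks are equal", {
  a <- synthHipJCF(noiseSD = 0.1, seed = 99L)
  b <- synthHipJCF(noiseSD = 0.1, seed = 99L)
  expect_identical(a@forceBW, b@forceBW)

  s <- synthHipJCF(peak1BW = 4.5, peak2BW = 4.5)
  r <- resultantBW(s)
  mid <- which(s@phase == 30)
  for (u in 1:30)
    expect_lt(abs(r[mid + u] - r[mid - u]), 1e-9)
})

test_that("instance selection spans stance and includes the peaks", {
  wf <- synthHipJCF()
  idx <- selectLoadInstances(wf)
  expect_length(idx, 9L)
  expect_true(all(diff(idx) > 0))
  expect_true(which.max(resultantBW(wf)) %in% idx)
  expect_identical(idx, selectLoadInstances(wf))

  ramp <- new("ForceWaveform", phase = seq(0, 100),
              forceBW = outer(seq(0, 1, length.out = 101), c(0, -1, 0)),
              bodyWeightN = 300, meta = list())
  ir <- selectLoadInstances(ramp)
  expect_true(all(diff(ir) > 0))
  expect_identical(ir[length(ir)], 101L)
  expect_error(selectLoadInstances(wf, n = 1000L), "fewer")
})

test_that("load sets conserve force and respect the patch rules", {
  mesh <- defaultFemur()
  wf <- synthHipJCF()
  ls <- buildLoadSet(mesh, wf)
  hs <- nodeSets(mesh)$head_surface
  for (ins in ls@instances) {
    patchSum <- colSums(outer(ins$patchWeights, ins$jcfVectorN))
    expect_lt(max(abs(patchSum - ins$jcfVectorN)), 1e-9)
    expect_true(all(ins$patchWeights >= 0))
    expect_equal(sum(ins$patchWeights), 1, tolerance = 1e-12)
    expect_true(all(ins$patchNodes %in% hs))
    expect_lt(abs(ins$patchAreaMM2 - 30) / 30, 0.25)
  }
  # total applied force = JCF + sum of muscle forces, exactly
  ins <- ls@instances[[1]]
  f <- nodalForces(mesh, ins)
  mf <- ins$muscleForces
  expected <- ins$jcfVectorN + c(sum(mf$fx), sum(mf$fy), sum(mf$fz))
  expect_equal(colSums(f), expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("neck-tracking keeps a constant angle to the neck axis", {
  wf <- synthHipJCF()
  angles <- vapply(list(tinyFemur(120, 20), tinyFemur(150, 20)), function(m) {
    ls <- buildLoadSet(m, wf, muscleSpec = NULL)
    n <- measureAngles(m)@neckAxis
    femurFE:::vecAngleDeg(-ls@instances[[1]]$jcfVectorN, n)
  }, 0)
  expect_lt(abs(diff(angles)), 0.5)
  expect_equal(angles[1], 25, tolerance = 1e-6)
})

test_that("muscle forces are single-node at anatomical landmarks", {
  mesh <- tinyFemur()
  ls <- buildLoadSet(mesh, synthHipJCF())
  ins <- ls@instances[[1]]
  gm <- ins$muscleForces[ins$muscleForces$muscle == "gluteus_medius", ]
  expect_identical(nrow(gm), 1L)
  lmk <- landmarkPoints(mesh)
  expect_identical(gm$node, lmk$greater_trochanter$node)
  # the greater trochanter is the most lateral proximal point
  meas <- measureAngles(mesh)
  loc <- (mesh@nodeCoords[gm$node, ] - meas@neckBase) %*% meas@frame
  expect_gt(loc[3], 0)
})

test_that("nodal loads scale linearly with body weight", {
  mesh <- tinyFemur()
  f1 <- nodalForces(mesh, buildLoadSet(mesh, synthHipJCF(bodyWeightN = 300))@instances[[4]])
  f2 <- nodalForces(mesh, buildLoadSet(mesh, synthHipJCF(bodyWeightN = 600))@instances[[4]])
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("waveform RMSD matches closed forms", {
  a <- synthHipJCF()
  expect_identical(rmsdWaveforms(a, a), 0)
  b <- a
  d <- a@meta$direction
  b@forceBW <- (resultantBW(a) + 0.25) %o% d
  expect_equal(rmsdWaveforms(a, b), 0.25, tolerance = 1e-12)
  neg <- a
  neg@forceBW <- -a@forceBW
  expect_identical(rmsdWaveforms(a, neg), 0)
})

test_that("waveform files round trip and fail loudly on bad input", {
  wf <- synthHipJCF()
  fs <- tempfile(fileext = ".sto")
  writeForceWaveform(wf, fs, "sto")
  w2 <- readForceWaveform(fs)
  expect_equal(w2@forceBW, wf@forceBW, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(w2@phase, wf@phase, tolerance = 1e-8)
  expect_equal(w2@bodyWeightN, wf@bodyWeightN)

  # corrupt declared row count
  lines <- readLines(fs)
  lines[3] <- "nRows=9999"
  writeLines(lines, fs)
  expect_error(readForceWaveform(fs), "nRows")
  unlink(fs)

  fc <- tempfile(fileext = ".csv")
  writeForceWaveform(wf, fc, "csv")
  w3 <- readForceWaveform(fc)
  expect_equal(w3@forceBW, wf@forceBW, tolerance = 1e-8, ignore_attr = TRUE)
  df <- read.csv(fc)
  write.csv(df[, c("t", "fx", "fy")], fc, row.names = FALSE)
  expect_error(readForceWaveform(fc), "fz")
  unlink(fc)
})
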