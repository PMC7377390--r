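# Mechanobiological growth engine: osteogenic index over the nine load
# instances, growth direction from the average femoral-neck deflection (or
# per-element maximum principal stress), and growth applied as an
# anisotropic eigenstrain along the growth direction.

#' Osteogenic index over the load instances
#'
#' For every growth-plate element the maximum octahedral shear stress and
#' minimum (most compressive, signed) hydrostatic stress across the
#' instances are combined into `OI = a * max sigmaS + b * min sigmaH`.
#' Octahedral shear promotes growth, hydrostatic compression (negative
#' sigmaH) inhibits it. The maximum and minimum are taken per element
#' independently: the instance achieving them may differ between elements
#' and between the two invariants.
#'
#' @param stressFields list of exactly nine [PrincipalStressField-class]
#'   objects over the same element set (one per load instance).
#' @param config a [GrowthConfig-class]
#' @return A [GrowthField-class] with the OI part filled (growth strain and
#'   direction are added by [growthStrains()] / the direction functions).
#' @export
osteogenicIndex <- function(stressFields, config = growthConfig()) {
  if (length(stressFields) != 9)
    stop("osteogenic index is defined over exactly 9 load instances, got ",
         length(stressFields))
  ids <- stressFields[[1]]@elementIds
  for (f in stressFields)
    if (!identical(f@elementIds, ids))
      stop("stress fields cover different element sets")
  SS <- vapply(stressFields, function(f) f@sigmaS, numeric(length(ids)))
  HH <- vapply(stressFields, function(f) f@sigmaH, numeric(length(ids)))
  if (length(ids) == 1) { SS <- matrix(SS, 1); HH <- matrix(HH, 1) }
  maxS <- apply(SS, 1, max)
  minH <- apply(HH, 1, min)
  oi <- config@a * maxS + config@b * minH
  new("GrowthField", elementIds = ids, maxSigmaS = maxS, minSigmaH = minH,
      oi = oi, strain = numeric(0), direction = numeric(0),
      headCenter = numeric(0), neckBase = numeric(0),
      meanDeflHC = numeric(0), meanDeflNB = numeric(0), meta = list())
}

#' Growth strain per element from the osteogenic index
#'
#' `eps = max(0, epsBio + kScale * OI)` per step; negative totals are
#' clamped to zero (resorption is not modelled).
#'
#' @param field a [GrowthField-class] with OI filled
#' @param config a [GrowthConfig-class]
#' @param kScale overrides `config@kScale` (strain per MPa); needed when the
#'   config requests calibration (`kScale = NA`).
#' @return the field with `strain` filled; `meta$kScale` records the value
#'   used.
#' @export
growthStrains <- function(field, config = growthConfig(), kScale = NULL) {
  ks <- kScale %||% config@kScale
  if (is.na(ks))
    stop("kScale is NA: calibrate it on the reference model first ",
         "(see runGrowthPipeline) or pass kScale explicitly")
  field@strain <- pmax(0, config@epsBio + ks * field@oi)
  field@meta$kScale <- ks
  field
}

#' Growth direction from the average femoral-neck deflection
#'
#' The head centre (HC) and neck base (NB) are displaced by the mean of
#' their deflections over the nine load instances; the growth direction is
#' the unit vector from the deflected NB to the deflected HC.
#'
#' @param HC,NB original landmark coordinates (mm)
#' @param deflections list of 9 `list(dHC, dNB)` pairs (see
#'   [neckDeflection()])
#' @return unit 3-vector.
#' @export
growthDirectionNeckDeflection <- function(HC, NB, deflections) {
  if (!length(deflections)) stop("no deflection pairs given")
  dHC <- Reduce(`+`, lapply(deflections, `[[`, "dHC")) / length(deflections)
  dNB <- Reduce(`+`, lapply(deflections, `[[`, "dNB")) / length(deflections)
  gd <- (HC + dHC) - (NB + dNB)
  if (vecNorm(gd) < 1e-9)
    stop("degenerate growth direction: deflected HC coincides with NB")
  unitVec(gd)
}

#' Per-element growth direction along the maximum principal stress
#'
#' For each element, the unit eigenvector of the largest principal stress at
#' the instance of maximum octahedral shear, with its sign resolved toward
#' the femoral head (positive component along the neck axis). Elements with
#' a (near-)repeated largest eigenvalue fall back to the eigenvector most
#' aligned with the neck axis; the fallback is reported via a message and in
#' the returned attribute `degenerate`.
#'
#' @param stressFields list of [PrincipalStressField-class] (9 instances)
#' @param neckAxis unit 3-vector used for sign resolution
#' @return k x 3 matrix of unit directions, one row per element.
#' @export
growthDirectionPrincipalStress <- function(stressFields, neckAxis) {
  ids <- stressFields[[1]]@elementIds
  SS <- vapply(stressFields, function(f) f@sigmaS, numeric(length(ids)))
  if (length(ids) == 1) SS <- matrix(SS, 1)
  pick <- apply(SS, 1, which.max)
  out <- matrix(0, length(ids), 3)
  degen <- logical(length(ids))
  for (i in seq_along(ids)) {
    f <- stressFields[[pick[i]]]
    vals <- f@sigma[i, ]
    V <- matrix(f@eigvecs[i, ], 3, 3)
    if (abs(vals[1] - vals[2]) < 1e-9) {
      degen[i] <- TRUE
      al <- abs(as.numeric(t(V) %*% neckAxis))
      d <- V[, which.max(al)]
    } else {
      d <- V[, 1]
    }
    if (sum(d * neckAxis) < 0) d <- -d
    out[i, ] <- d
  }
  if (any(degen))
    message(sum(degen), " element(s) with degenerate principal stresses; ",
            "used the neck-axis-nearest eigenvector")
  attr(out, "degenerate") <- degen
  out
}

#' Apply growth to a mesh as an anisotropic eigenstrain
#'
#' Runs a second elastic solve in which every growth-plate element carries a
#' stress-free strain `field@strain` acting only along the growth direction
#' (expansion coefficient one along the direction, zero transverse), with
#' the same condyle constraints as the load solves. Nodal coordinates of the
#' whole femur are then updated by the growth displacement multiplied by
#' `config@amplification` (default 10).
#'
#' @param mesh a [HexMesh-class]
#' @param field a [GrowthField-class] with strain and direction(s) filled
#' @param config a [GrowthConfig-class]
#' @param context optional [feContext()] for this mesh
#' @return the grown [HexMesh-class]; `metadata$growth` records the
#'   displacement field and applied strains. Errors if growth inverts any
#'   element.
#' @export
applyGrowth <- function(mesh, field, config = growthConfig(),
                        context = NULL) {
  if (!length(field@strain))
    stop("growth strains not computed; call growthStrains() first")
  if (is.null(context)) context <- feContext(mesh)
  dirs <- if (config@directionMode == "neck_deflection") {
    if (length(field@direction) != 3)
      stop("global growth direction missing from field")
    matrix(field@direction, length(field@elementIds), 3, byrow = TRUE)
  } else {
    dm <- field@meta$elementDirections
    if (is.null(dm)) stop("per-element growth directions missing from field")
    dm
  }
  f <- growthForces(mesh, context, field@elementIds, field@strain, dirs)
  U <- .feSolve(context, matrix(as.numeric(t(f)), ncol = 1))
  u <- matrix(U[, 1], ncol = 3, byrow = TRUE)
  out <- mesh
  out@nodeCoords <- mesh@nodeCoords + config@amplification * u
  bad <- which(minCornerJacobian(out) <= 0)
  if (length(bad))
    stop("growth step inverted ", length(bad), " element(s): ",
         paste(head(bad, 10), collapse = ", "))
  out@metadata$growth <- list(displacement = u,
                              amplification = config@amplification,
                              strains = field@strain,
                              elementIds = field@elementIds)
  out
}

# all growth-plate element ids of a mesh, distal row first
.growthPlateElements <- function(mesh) {
  nms <- grep("^growth_plate_row_", names(mesh@elementSets), value = TRUE)
  if (!length(nms)) stop("mesh has no growth_plate_row_* element sets")
  ord <- order(as.integer(sub("growth_plate_row_", "", nms)))
  list(byRow = mesh@elementSets[nms[ord]],
       all = as.integer(unlist(mesh@elementSets[nms[ord]], use.names = FALSE)))
}
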