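#' @import methods
#' @importFrom stats approx optim sd quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Parameter containers
# ---------------------------------------------------------------------------

#' Parametric femur geometry description
#'
#' Describes the idealized paediatric femur used by [generateFemur()]: a
#' condyle block and straight shaft along the superior axis, a neck segment
#' leaving the shaft at the neck-shaft angle (NSA) and rotated anteriorly by
#' the anteversion angle (AVA), and a spherical head capping the neck. Lengths
#' are millimetres, angles degrees.
#'
#' @slot nsaDeg neck-shaft angle, degrees, in [110, 160].
#' @slot avaDeg anteversion angle, degrees, in [0, 60].
#' @slot femurLengthMM overall condyle-to-neck-base span driving the shaft length.
#' @slot headRadiusMM,neckLengthMM,neckRadiusMM,shaftRadiusMM,condyleWidthMM
#'   section dimensions of the parametric solid.
#' @slot nCirc number of elements around the circumference (multiple of 8).
#' @slot nAxial number of element layers along the shaft.
#' @slot nGpRows number of growth-plate element rows (default 7).
#' @slot nTransitionRows transition-zone rows flanking the growth plate on each
#'   side (default 10).
#' @slot side `"right"` or `"left"`.
#' @seealso [femurParams()] for the user constructor with defaults.
#' @export
setClass("FemurParams", representation(
  nsaDeg = "numeric", avaDeg = "numeric",
  femurLengthMM = "numeric", headRadiusMM = "numeric",
  neckLengthMM = "numeric", neckRadiusMM = "numeric",
  shaftRadiusMM = "numeric", condyleWidthMM = "numeric",
  nCirc = "integer", nAxial = "integer",
  nGpRows = "integer", nTransitionRows = "integer",
  side = "character"
))

setValidity("FemurParams", function(object) {
  msg <- character()
  if (object@nsaDeg < 110 || object@nsaDeg > 160)
    msg <- c(msg, "nsaDeg must lie in [110, 160]")
  if (object@avaDeg < 0 || object@avaDeg > 60)
    msg <- c(msg, "avaDeg must lie in [0, 60]")
  lens <- c(object@femurLengthMM, object@headRadiusMM, object@neckLengthMM,
            object@neckRadiusMM, object@shaftRadiusMM, object@condyleWidthMM)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive and finite")
  if (object@neckRadiusMM >= object@headRadiusMM)
    msg <- c(msg, "neckRadiusMM must be smaller than headRadiusMM")
  if (object@nCirc < 8 || object@nCirc %% 8 != 0)
    msg <- c(msg, "nCirc must be a multiple of 8 (>= 8)")
  if (object@nAxial < 2) msg <- c(msg, "nAxial must be >= 2")
  if (object@nGpRows < 1) msg <- c(msg, "nGpRows must be >= 1")
  if (object@nTransitionRows < 0) msg <- c(msg, "nTransitionRows must be >= 0")
  if (!object@side %in% c("right", "left"))
    msg <- c(msg, "side must be 'right' or 'left'")
  if (length(msg)) msg else TRUE
})

#' Construct femur geometry parameters
#'
#' Defaults correspond to a paediatric femur (roughly an 8-year-old child):
#' 260 mm femur, 17 mm head radius, 27 mm neck. The default discretization
#' (`nCirc = 24`, `nAxial = 8`, 7 growth-plate rows, 10 transition rows each
#' side) yields roughly 5,000 hexahedral elements.
#'
#' @param nsaDeg,avaDeg target neck-shaft and anteversion angles, degrees.
#' @param femurLengthMM,headRadiusMM,neckLengthMM,neckRadiusMM,shaftRadiusMM,condyleWidthMM
#'   dimensions in mm.
#' @param nCirc elements around the circumference (multiple of 8).
#' @param nAxial element layers along the shaft.
#' @param nGpRows growth-plate element rows.
#' @param nTransitionRows transition rows on each side of the growth plate.
#' @param side `"right"` (default) or `"left"`.
#' @return A [FemurParams-class] object.
#' @examples
#' p <- femurParams(nsaDeg = 130, avaDeg = 30)
#' @export
femurParams <- function(nsaDeg = 120, avaDeg = 20,
                        femurLengthMM = 260, headRadiusMM = 17,
                        neckLengthMM = 27, neckRadiusMM = 9.5,
                        shaftRadiusMM = 10, condyleWidthMM = 52,
                        nCirc = 24L, nAxial = 8L,
                        nGpRows = 7L, nTransitionRows = 10L,
                        side = "right") {
  new("FemurParams", nsaDeg = nsaDeg, avaDeg = avaDeg,
      femurLengthMM = femurLengthMM, headRadiusMM = headRadiusMM,
      neckLengthMM = neckLengthMM, neckRadiusMM = neckRadiusMM,
      shaftRadiusMM = shaftRadiusMM, condyleWidthMM = condyleWidthMM,
      nCirc = as.integer(nCirc), nAxial = as.integer(nAxial),
      nGpRows = as.integer(nGpRows),
      nTransitionRows = as.integer(nTransitionRows), side = side)
}

#' Layered material description
#'
#' Isotropic linear-elastic moduli for cortical bone, trabecular bone and the
#' growth-plate cartilage, with a linear modulus grade through the transition
#' zones (mineralizing tissue) between trabecular bone and growth plate.
#' Units: MPa.
#'
#' @slot ECorticalMPa,ETrabecularMPa,EGrowthPlateMPa elastic moduli.
#' @slot nuBone,nuGrowthPlate Poisson ratios.
#' @slot transition grading rule through the transition zone; only `"linear"`.
#' @export
setClass("MaterialSpec", representation(
  ECorticalMPa = "numeric", ETrabecularMPa = "numeric",
  EGrowthPlateMPa = "numeric", nuBone = "numeric",
  nuGrowthPlate = "numeric", transition = "character"
))

setValidity("MaterialSpec", function(object) {
  msg <- character()
  if (!(object@EGrowthPlateMPa < object@ETrabecularMPa &&
        object@ETrabecularMPa < object@ECorticalMPa))
    msg <- c(msg, "moduli must satisfy E_gp < E_trab < E_cort")
  if (any(c(object@nuBone, object@nuGrowthPlate) <= 0) ||
      any(c(object@nuBone, object@nuGrowthPlate) >= 0.5))
    msg <- c(msg, "Poisson ratios must lie in (0, 0.5)")
  if (!identical(object@transition, "linear"))
    msg <- c(msg, "only linear transition grading is supported")
  if (length(msg)) msg else TRUE
})

#' Construct a material specification
#'
#' Default moduli: cortical 17,000 MPa, trabecular 300 MPa, growth plate 6 MPa
#' with Poisson ratios 0.3 (bone) and 0.45 (cartilage); all configurable.
#'
#' @param ECorticalMPa,ETrabecularMPa,EGrowthPlateMPa elastic moduli, MPa.
#' @param nuBone,nuGrowthPlate Poisson ratios.
#' @return A [MaterialSpec-class] object.
#' @export
materialSpec <- function(ECorticalMPa = 17000, ETrabecularMPa = 300,
                         EGrowthPlateMPa = 6, nuBone = 0.3,
                         nuGrowthPlate = 0.45) {
  new("MaterialSpec", ECorticalMPa = ECorticalMPa,
      ETrabecularMPa = ETrabecularMPa, EGrowthPlateMPa = EGrowthPlateMPa,
      nuBone = nuBone, nuGrowthPlate = nuGrowthPlate, transition = "linear")
}

# ---------------------------------------------------------------------------
# Mesh container
# ---------------------------------------------------------------------------

#' All-hexahedral finite-element mesh
#'
#' Nodes, 8-node brick connectivity, named element and node sets and
#' per-element isotropic material. Element node ordering follows the usual
#' brick convention (bottom face counter-clockwise, then top face).
#'
#' Element sets produced by [generateFemur()] include `cortical`,
#' `trabecular`, `growth_plate_row_k` (k = 1..nGpRows, numbered from the
#' distal/shaft side), `transition_above`, `transition_below`, `head`, `neck`,
#' `shaft`, `condyles`. Node sets include `head_surface`, `neck_base_ring`,
#' `condyle_fixed`, `shaft_axis_markers` and `condyle_axis_markers` (medial
#' then lateral).
#'
#' @slot nodeCoords numeric n x 3 matrix, mm.
#' @slot elements integer m x 8 connectivity.
#' @slot elementSets,nodeSets named lists of integer index vectors.
#' @slot elementE,elementNu per-element modulus (MPa) and Poisson ratio.
#' @slot metadata free-form list (provenance, growth diagnostics, ...).
#' @export
setClass("HexMesh", representation(
  nodeCoords = "matrix", elements = "matrix",
  elementSets = "list", nodeSets = "list",
  elementE = "numeric", elementNu = "numeric",
  metadata = "list"
))

setValidity("HexMesh", function(object) {
  msg <- character()
  if (ncol(object@nodeCoords) != 3) msg <- c(msg, "nodeCoords must be n x 3")
  if (ncol(object@elements) != 8) msg <- c(msg, "elements must be m x 8")
  m <- nrow(object@elements); n <- nrow(object@nodeCoords)
  if (m > 0 && (min(object@elements) < 1 || max(object@elements) > n))
    msg <- c(msg, "element connectivity references invalid nodes")
  for (nm in names(object@nodeSets)) {
    s <- object@nodeSets[[nm]]
    if (length(s) && (min(s) < 1 || max(s) > n))
      msg <- c(msg, sprintf("node set '%s' references invalid nodes", nm))
  }
  for (nm in names(object@elementSets)) {
    s <- object@elementSets[[nm]]
    if (length(s) && (min(s) < 1 || max(s) > m))
      msg <- c(msg, sprintf("element set '%s' references invalid elements", nm))
  }
  if (length(object@elementE) != m || length(object@elementNu) != m)
    msg <- c(msg, "per-element materials must match element count")
  if (length(msg)) msg else TRUE
})

#' @describeIn HexMesh number of nodes
#' @param object,x a `HexMesh`
#' @export
nNodes <- function(x) nrow(x@nodeCoords)

#' @describeIn HexMesh number of elements
#' @export
nElements <- function(x) nrow(x@elements)

#' Accessors for HexMesh
#'
#' @param x a [HexMesh-class]
#' @return `nodeCoords`: n x 3 coordinate matrix; `elements`: m x 8 integer
#'   connectivity; `elementSets`/`nodeSets`: named lists of indices;
#'   `elementMaterials`: data.frame with columns `E` and `nu`.
#' @export
nodeCoords <- function(x) x@nodeCoords

#' @rdname nodeCoords
#' @export
elements <- function(x) x@elements

#' @rdname nodeCoords
#' @export
elementSets <- function(x) x@elementSets

#' @rdname nodeCoords
#' @export
nodeSets <- function(x) x@nodeSets

#' @rdname nodeCoords
#' @export
elementMaterials <- function(x) data.frame(E = x@elementE, nu = x@elementNu)

setMethod("show", "HexMesh", function(object) {
  cat("HexMesh:", nNodes(object), "nodes,", nElements(object), "elements\n")
  if (length(object@elementSets))
    cat("  element sets:", paste(names(object@elementSets), collapse = ", "), "\n")
  if (length(object@nodeSets))
    cat("  node sets:   ", paste(names(object@nodeSets), collapse = ", "), "\n")
  er <- range(object@elementE)
  cat(sprintf("  E range: %.3g - %.3g MPa\n", er[1], er[2]))
})

# ---------------------------------------------------------------------------
# Angle measures
# ---------------------------------------------------------------------------

#' Femoral angle measurements
#'
#' Result of [measureAngles()]: neck-shaft angle (NSA), anteversion angle
#' (AVA), the anatomical axes they derive from, and the anatomical frame
#' (columns: anterior, superior, lateral). `alphaDeg` (hip contact force vs
#' neck axis) and `betaDeg` (growth direction vs neck axis) are filled by the
#' pipeline when those vectors are known, `NA` otherwise. `projections` holds
#' the per-plane (frontal/sagittal/transverse) angles of alpha and beta.
#'
#' @slot nsaDeg,avaDeg angles in degrees.
#' @slot neckAxis,shaftAxis,condylarAxis unit 3-vectors; shaft axis points
#'   proximally (toward the head), condylar axis medial to lateral.
#' @slot headCenter,neckBase landmark coordinates, mm.
#' @slot headRadius sphere-fit head radius, mm.
#' @slot alphaDeg,betaDeg optional relative angles, degrees.
#' @slot projections data.frame of per-plane angles.
#' @export
setClass("AngleMeasures", representation(
  nsaDeg = "numeric", avaDeg = "numeric",
  neckAxis = "numeric", shaftAxis = "numeric", condylarAxis = "numeric",
  frame = "matrix", headCenter = "numeric", headRadius = "numeric",
  neckBase = "numeric", alphaDeg = "numeric", betaDeg = "numeric",
  projections = "data.frame"
))

setValidity("AngleMeasures", function(object) {
  msg <- character()
  for (nm in c("neckAxis", "shaftAxis", "condylarAxis")) {
    v <- slot(object, nm)
    if (length(v) != 3 || abs(vecNorm(v) - 1) > 1e-8)
      msg <- c(msg, sprintf("%s must be a unit 3-vector", nm))
  }
  ang <- c(object@nsaDeg, object@avaDeg)
  if (any(ang < 0 | ang > 180)) msg <- c(msg, "angles must lie in [0, 180]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AngleMeasures neck-shaft angle in degrees
#' @param x an `AngleMeasures`
#' @export
nsaDeg <- function(x) x@nsaDeg

#' @describeIn AngleMeasures anteversion angle in degrees
#' @export
avaDeg <- function(x) x@avaDeg

setMethod("show", "AngleMeasures", function(object) {
  cat(sprintf("AngleMeasures: NSA = %.2f deg, AVA = %.2f deg\n",
              object@nsaDeg, object@avaDeg))
  if (is.finite(object@alphaDeg))
    cat(sprintf("  alpha (JCF vs neck axis) = %.2f deg\n", object@alphaDeg))
  if (is.finite(object@betaDeg))
    cat(sprintf("  beta (growth dir vs neck axis) = %.2f deg\n", object@betaDeg))
})

# ---------------------------------------------------------------------------
# Morphing containers
# ---------------------------------------------------------------------------

#' Rigid-body transform
#'
#' @slot rotation 3 x 3 orthonormal matrix with det +1.
#' @slot translation length-3 vector, mm.
#' @slot scale uniform scale factor (1 for a pure rigid transform).
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix", translation = "numeric", scale = "numeric"
))

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)) || max(abs(t(R) %*% R - diag(3))) > 1e-6 ||
      det(R) < 0)
    msg <- c(msg, "rotation must be orthonormal with det +1")
  if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(clamp((sum(diag(object@rotation)) - 1) / 2, -1, 1)) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.2f deg, |t| = %.3f mm, scale %.4f\n",
              ang, vecNorm(object@translation), object@scale))
})

#' Host-mesh (free-form lattice) deformation
#'
#' A tricubic Bezier control lattice spanning the target's principal-axis
#' bounding box. Points are embedded by their normalized box coordinates in
#' `[0,1]^3`; moving control points carries embedded surface and internal
#' points along. With `controlFit == controlOrig` the deformation is the
#' identity.
#'
#' @slot dims control-point grid dimensions (4, 4, 4 for tricubic).
#' @slot frame 3 x 3 lattice axes (columns), a rotation.
#' @slot origin box corner in world coordinates, mm.
#' @slot extent box edge lengths along the lattice axes, mm.
#' @slot controlOrig,controlFit control points (prod(dims) x 3, world mm).
#' @slot lambda ridge weight on control displacements.
#' @slot embedding normalized coordinates of the fitted source points.
#' @slot report list with per-iteration RMS diagnostics.
#' @export
setClass("HostMeshDeformation", representation(
  dims = "integer", frame = "matrix", origin = "numeric", extent = "numeric",
  controlOrig = "matrix", controlFit = "matrix", lambda = "numeric",
  embedding = "matrix", report = "list"
))

setValidity("HostMeshDeformation", function(object) {
  msg <- character()
  if (length(object@dims) != 3 || any(object@dims < 2))
    msg <- c(msg, "dims must be three values >= 2")
  if (nrow(object@controlOrig) != prod(object@dims) ||
      nrow(object@controlFit) != prod(object@dims))
    msg <- c(msg, "control grids must have prod(dims) rows")
  if (nrow(object@embedding) > 0 &&
      (min(object@embedding) < -1e-9 || max(object@embedding) > 1 + 1e-9))
    msg <- c(msg, "embedding coordinates must lie in [0,1]^3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HostMeshDeformation", function(object) {
  d <- sqrt(rowSums((object@controlFit - object@controlOrig)^2))
  cat(sprintf("HostMeshDeformation: %d x %d x %d lattice, max control move %.3f mm\n",
              object@dims[1], object@dims[2], object@dims[3], max(d)))
  if (!is.null(object@report$rmsFit))
    cat(sprintf("  surface RMS after fit: %.3f mm\n", object@report$rmsFit))
})

# ---------------------------------------------------------------------------
# Loads
# ---------------------------------------------------------------------------

#' Hip joint contact force waveform
#'
#' Force samples over the gait cycle in body-weight (BW) multiples, expressed
#' in the femur frame (columns anterior, superior, lateral).
#'
#' @slot phase percent gait cycle, strictly increasing over [0, 100].
#' @slot forceBW n x 3 force in BW.
#' @slot bodyWeightN subject body weight in newtons.
#' @slot meta list (provenance, generator settings).
#' @export
setClass("ForceWaveform", representation(
  phase = "numeric", forceBW = "matrix", bodyWeightN = "numeric",
  meta = "list"
))

setValidity("ForceWaveform", function(object) {
  msg <- character()
  if (length(object@phase) != nrow(object@forceBW))
    msg <- c(msg, "phase and forceBW must agree in length")
  if (any(diff(object@phase) <= 0))
    msg <- c(msg, "phase grid must be strictly increasing")
  if (object@phase[1] > 1e-9 || tail(object@phase, 1) < 100 - 1e-9)
    msg <- c(msg, "phase grid must cover 0-100% of the gait cycle")
  if (any(!is.finite(object@forceBW))) msg <- c(msg, "forces must be finite")
  if (object@bodyWeightN <= 0) msg <- c(msg, "bodyWeightN must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ForceWaveform resultant magnitude in BW per sample
#' @param x a `ForceWaveform`
#' @export
resultantBW <- function(x) sqrt(rowSums(x@forceBW^2))

setMethod("show", "ForceWaveform", function(object) {
  cat(sprintf("ForceWaveform: %d samples, peak resultant %.2f BW (BW = %.1f N)\n",
              length(object@phase), max(resultantBW(object)), object@bodyWeightN))
})

#' Gait load set
#'
#' Nine (by default) quasi-static load instances sampled from the stance
#' phase. Each instance is a list with elements `index`, `phasePct`,
#' `jcfVectorN` (3-vector, N), `patchNodes`, `patchWeights` (non-negative,
#' summing to 1), `patchAreaMM2` and `muscleForces` (data.frame: muscle, node,
#' fx, fy, fz in N).
#'
#' @slot bodyWeightN body weight, N.
#' @slot instances list of load instances.
#' @slot provenance `"synthetic"` or `"imported"`.
#' @slot mode `"neck_tracking"` or `"pelvis_fixed"` JCF orientation rule.
#' @slot meta list.
#' @export
setClass("GaitLoadSet", representation(
  bodyWeightN = "numeric", instances = "list", provenance = "character",
  mode = "character", meta = "list"
))

setValidity("GaitLoadSet", function(object) {
  msg <- character()
  if (!length(object@instances)) msg <- c(msg, "needs at least one instance")
  for (ins in object@instances) {
    if (!all(c("jcfVectorN", "patchNodes", "patchWeights") %in% names(ins))) {
      msg <- c(msg, "instances must carry jcfVectorN, patchNodes, patchWeights")
      break
    }
    if (any(ins$patchWeights < -1e-12) ||
        abs(sum(ins$patchWeights) - 1) > 1e-9) {
      msg <- c(msg, "patch weights must be non-negative and sum to 1")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaitLoadSet", function(object) {
  pk <- max(vapply(object@instances, function(i) vecNorm(i$jcfVectorN), 0))
  cat(sprintf("GaitLoadSet: %d instances (%s, %s), peak JCF %.2f BW\n",
              length(object@instances), object@provenance, object@mode,
              pk / object@bodyWeightN))
})

# ---------------------------------------------------------------------------
# Solver fields
# ---------------------------------------------------------------------------

#' Nodal displacement field
#'
#' @slot disp n x 3 displacements, mm.
#' @slot instanceId integer id of the load instance (0 for ad-hoc loads).
#' @slot fixedNodes constrained node indices.
#' @slot diagnostics list: `residual` (relative equilibrium residual),
#'   `reactionSum`, `appliedSum` (3-vectors, N).
#' @export
setClass("DisplacementField", representation(
  disp = "matrix", instanceId = "integer", fixedNodes = "integer",
  diagnostics = "list"
))

setValidity("DisplacementField", function(object) {
  msg <- character()
  if (ncol(object@disp) != 3) msg <- c(msg, "disp must be n x 3")
  if (any(!is.finite(object@disp))) msg <- c(msg, "displacements must be finite")
  if (length(object@fixedNodes) &&
      max(abs(object@disp[object@fixedNodes, ])) > 1e-9)
    msg <- c(msg, "displacements must vanish at constrained nodes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField: %d nodes, max |u| = %.4g mm, residual %.2g\n",
              nrow(object@disp), sqrt(max(rowSums(object@disp^2))),
              object@diagnostics$residual))
})

#' Element principal stress field
#'
#' Centroid-averaged principal stresses (tension positive, MPa) with the
#' octahedral shear stress `sigmaS = sqrt((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2)/3`
#' and hydrostatic stress `sigmaH = (s1+s2+s3)/3`.
#'
#' @slot elementIds elements the rows refer to.
#' @slot sigma k x 3 principal stresses, sorted descending.
#' @slot sigmaS,sigmaH derived invariants, MPa.
#' @slot dir1 k x 3 unit eigenvectors of the largest principal stress.
#' @slot eigvecs k x 9 full eigenvector sets (column-major 3 x 3 per row).
#' @slot instanceId load instance id.
#' @export
setClass("PrincipalStressField", representation(
  elementIds = "integer", sigma = "matrix", sigmaS = "numeric",
  sigmaH = "numeric", dir1 = "matrix", eigvecs = "matrix",
  instanceId = "integer"
))

setValidity("PrincipalStressField", function(object) {
  msg <- character()
  if (nrow(object@sigma) && any(object@sigma[, 1] + 1e-9 < object@sigma[, 2] |
                                object@sigma[, 2] + 1e-9 < object@sigma[, 3]))
    msg <- c(msg, "principal stresses must be sorted descending")
  if (any(object@sigmaS < -1e-12)) msg <- c(msg, "sigmaS must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PrincipalStressField", function(object) {
  cat(sprintf("PrincipalStressField: %d elements, sigmaS in [%.3g, %.3g] MPa\n",
              length(object@elementIds), min(object@sigmaS), max(object@sigmaS)))
})

# ---------------------------------------------------------------------------
# Growth
# ---------------------------------------------------------------------------

#' Growth simulation configuration
#'
#' The growth rate per step is `eps = epsBio + kScale * OI`, clamped at zero
#' (no resorption), applied as an eigenstrain acting only along the growth
#' direction in growth-plate elements. `kScale = NA` asks the pipeline to
#' calibrate it on the reference model so that the largest magnitude of the
#' mechanical term equals `targetMechStrain`.
#'
#' @slot a,b osteogenic-index weights (`OI = a*max sigmaS + b*min sigmaH`);
#'   defaults a = 1, b = 0.5 (ratio b/a = 0.5).
#' @slot epsBio biological growth strain per step.
#' @slot kScale mechanical scaling, strain per MPa of OI (NA = calibrate).
#' @slot targetMechStrain calibration target for `kScale`.
#' @slot amplification displacement multiplier applied to the growth solve
#'   (default 10).
#' @slot directionMode `"neck_deflection"` (single global direction) or
#'   `"principal_stress"` (per-element).
#' @slot nSteps number of growth iterations.
#' @export
setClass("GrowthConfig", representation(
  a = "numeric", b = "numeric", epsBio = "numeric", kScale = "numeric",
  targetMechStrain = "numeric", amplification = "numeric",
  directionMode = "character", nSteps = "integer"
))

setValidity("GrowthConfig", function(object) {
  msg <- character()
  if (object@a <= 0) msg <- c(msg, "a must be positive")
  if (object@amplification < 1) msg <- c(msg, "amplification must be >= 1")
  if (!is.na(object@kScale) && object@kScale < 0)
    msg <- c(msg, "kScale must be >= 0")
  if (!object@directionMode %in% c("neck_deflection", "principal_stress"))
    msg <- c(msg, "directionMode must be neck_deflection or principal_stress")
  if (object@nSteps < 1) msg <- c(msg, "nSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a growth configuration
#'
#' @param a,b stimulus weights; only the ratio matters for trends, default
#'   b/a = 0.5.
#' @param epsBio biological growth strain per step (default 0.005).
#' @param kScale strain per MPa of osteogenic index; `NA` = calibrate on the
#'   reference model via `targetMechStrain`.
#' @param targetMechStrain calibration target (default 0.01).
#' @param amplification growth displacement multiplier (default 10).
#' @param directionMode `"neck_deflection"` or `"principal_stress"`.
#' @param nSteps growth iterations (default 1).
#' @return A [GrowthConfig-class] object.
#' @export
growthConfig <- function(a = 1, b = 0.5, epsBio = 0.005, kScale = NA_real_,
                         targetMechStrain = 0.01, amplification = 10,
                         directionMode = "neck_deflection", nSteps = 1L) {
  new("GrowthConfig", a = a, b = b, epsBio = epsBio,
      kScale = as.numeric(kScale),
      targetMechStrain = targetMechStrain, amplification = amplification,
      directionMode = directionMode, nSteps = as.integer(nSteps))
}

#' Growth stimulus field
#'
#' Per growth-plate element osteogenic index and growth strain, plus the
#' global growth direction derived from the mean femoral-neck deflection.
#'
#' @slot elementIds growth-plate element ids.
#' @slot maxSigmaS per-element max octahedral shear over the instances, MPa.
#' @slot minSigmaH per-element min (most compressive) hydrostatic stress, MPa.
#' @slot oi osteogenic index, MPa.
#' @slot strain applied growth strain per element (>= 0).
#' @slot direction global unit growth direction (neck-deflection mode);
#'   per-element directions live in `meta$elementDirections` for the
#'   principal-stress mode.
#' @slot headCenter,neckBase original landmark coordinates, mm.
#' @slot meanDeflHC,meanDeflNB mean landmark deflections over instances, mm.
#' @slot meta list.
#' @export
setClass("GrowthField", representation(
  elementIds = "integer", maxSigmaS = "numeric", minSigmaH = "numeric",
  oi = "numeric", strain = "numeric", direction = "numeric",
  headCenter = "numeric", neckBase = "numeric",
  meanDeflHC = "numeric", meanDeflNB = "numeric", meta = "list"
))

setValidity("GrowthField", function(object) {
  msg <- character()
  if (length(object@direction) == 3 &&
      abs(vecNorm(object@direction) - 1) > 1e-9)
    msg <- c(msg, "growth direction must be a unit vector")
  if (length(object@strain) && any(object@strain < -1e-12))
    msg <- c(msg, "growth strains must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GrowthField", function(object) {
  cat(sprintf("GrowthField: %d growth-plate elements, OI in [%.3g, %.3g] MPa\n",
              length(object@elementIds), min(object@oi), max(object@oi)))
  if (length(object@direction) == 3)
    cat(sprintf("  growth direction: (%.3f, %.3f, %.3f)\n",
                object@direction[1], object@direction[2], object@direction[3]))
})
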