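# Synthetic gait loading: hip joint contact force (JCF) waveform generation,
# selection of the nine quasi-static load instances, assembly of per-instance
# nodal loads (distributed JCF patch + concentrated muscle forces), and
# import/export of force waveforms (OpenSim STO/MOT, CSV).

#' Synthesize a double-peak hip JCF gait waveform
#'
#' The resultant is the sum of two raised-cosine (Hann) bumps centred in
#' early and late stance; it is exactly zero in late swing and, when the two
#' peaks are equal, exactly symmetric about mid-stance. The default peak of
#' 4.9 BW matches hip contact forces reported for typically developing
#' children walking at self-selected speed. The force direction in the femur
#' frame (anterior, superior, lateral) is inferior-lateral-posterior.
#'
#' @param peak1BW,peak2BW peak magnitudes (body-weight multiples), in [1, 8].
#' @param phase1,phase2 bump centres, percent gait cycle.
#' @param width bump half-width, percent gait cycle.
#' @param direction 3-vector force direction in the femur frame (normalized
#'   internally).
#' @param bodyWeightN subject weight, N (default 298 N, a 30.4 kg child).
#' @param nPoints samples over the 0-100% cycle.
#' @param noiseSD standard deviation of optional Gaussian magnitude noise
#'   (BW); 0 disables noise.
#' @param seed RNG seed for the noise; the waveform is bitwise reproducible
#'   for a fixed seed.
#' @return A [ForceWaveform-class]
#' @examples
#' wf <- synthHipJCF()
#' max(resultantBW(wf))  # ~4.9
#' @export
synthHipJCF <- function(peak1BW = 4.9, peak2BW = 4.2, phase1 = 18,
                        phase2 = 42, width = 15,
                        direction = c(-0.25, -0.92, 0.30),
                        bodyWeightN = 298.2, nPoints = 101L, noiseSD = 0,
                        seed = 1L) {
  if (any(c(peak1BW, peak2BW) < 1) || any(c(peak1BW, peak2BW) > 8))
    stop("peak magnitudes must lie in [1, 8] BW")
  if (width <= 0 || phase1 >= phase2)
    stop("invalid bump configuration: need width > 0 and phase1 < phase2")
  phase <- seq(0, 100, length.out = nPoints)
  bump <- function(p, c0) {
    out <- numeric(length(phase))
    inb <- abs(phase - c0) <= width
    out[inb] <- p * 0.5 * (1 + cos(pi * (phase[inb] - c0) / width))
    out
  }
  mag <- bump(peak1BW, phase1) + bump(peak2BW, phase2)
  if (noiseSD > 0) {
    set.seed(seed)
    mag <- pmax(mag + stats::rnorm(length(mag), 0, noiseSD) * (mag > 0), 0)
  }
  d <- unitVec(direction)
  new("ForceWaveform", phase = phase, forceBW = outer(mag, d),
      bodyWeightN = bodyWeightN,
      meta = list(provenance = "synthetic", peak1BW = peak1BW,
                  peak2BW = peak2BW, phase1 = phase1, phase2 = phase2,
                  width = width, direction = d, noiseSD = noiseSD,
                  seed = seed))
}

#' Select the quasi-static load instances from a waveform
#'
#' Picks `n` strictly increasing sample indices spanning the stance phase:
#' both resultant peaks and the inter-peak valley (when a double-peak shape
#' is present), the remaining slots filled by samples equally spaced over the
#' stance support. The instance of maximum resultant is always included.
#'
#' @param waveform a [ForceWaveform-class]
#' @param n number of instances (default 9)
#' @return integer vector of sample indices, strictly increasing.
#' @export
selectLoadInstances <- function(waveform, n = 9L) {
  r <- resultantBW(waveform)
  if (length(r) < n) stop("waveform has fewer samples than requested instances")
  supp <- which(r > 1e-9 * max(r))
  if (length(supp) < n) stop("stance support has fewer samples than n")
  i0 <- supp[1]; i1 <- supp[length(supp)]
  # interior + right-boundary local maxima
  lm <- supp[vapply(supp, function(i) {
    left <- if (i > 1) r[i] > r[i - 1] else TRUE
    right <- if (i < length(r)) r[i] >= r[i + 1] else TRUE
    left && right
  }, TRUE)]
  essential <- if (length(lm) >= 2) {
    pk <- lm[order(r[lm], decreasing = TRUE)][1:2]
    pk <- sort(pk)
    valley <- (pk[1]:pk[2])[which.min(r[pk[1]:pk[2]])]
    c(pk[1], valley, pk[2])
  } else {
    which.max(r)
  }
  base <- unique(round(seq(i0, i1, length.out = n)))
  fill <- setdiff(base, essential)
  out <- sort(unique(c(essential, fill)))
  while (length(out) > n) {
    # drop the fill index closest to its neighbours (never an essential one)
    cand <- setdiff(out, essential)
    gaps <- vapply(cand, function(i) {
      k <- match(i, out)
      lo <- if (k > 1) out[k - 1] else -Inf
      hi <- if (k < length(out)) out[k + 1] else Inf
      min(i - lo, hi - i)
    }, 0)
    out <- setdiff(out, cand[which.min(gaps)])
  }
  spare <- setdiff(supp, out)
  while (length(out) < n && length(spare)) {
    # add the spare index that maximizes the minimum gap
    gaps <- vapply(spare, function(i) min(abs(i - out)), 0)
    out <- sort(c(out, spare[which.max(gaps)]))
    spare <- setdiff(spare, out)
  }
  as.integer(out)
}

# ---- anatomical landmarks and muscle attachment table ----------------------

#' Anatomical landmark points on a femur mesh
#'
#' Heuristic muscle-attachment landmarks derived from the measured anatomical
#' frame: extremal surface points in frame coordinates near prescribed
#' heights (greater/lesser trochanter, linea aspera, distal posterior
#' condyle heads, distal anterior shaft). Works on generated and morphed
#' meshes alike.
#'
#' @param mesh a [HexMesh-class]
#' @param measures optional [AngleMeasures-class] (computed when missing)
#' @return named list of `list(node, point)` entries.
#' @export
landmarkPoints <- function(mesh, measures = NULL) {
  if (is.null(measures)) measures <- measureAngles(mesh)
  fr <- measures@frame
  NB <- measures@neckBase
  loc <- sweep(mesh@nodeCoords, 2, NB) %*% fr  # (anterior, superior, lateral)
  span <- max(loc[, 2]) - min(loc[, 2])
  yBot <- min(loc[, 2])
  pick <- function(score) {
    i <- which.max(score)
    list(node = i, point = mesh@nodeCoords[i, ])
  }
  list(
    greater_trochanter = pick(loc[, 3] - 0.4 * abs(loc[, 2])),
    lesser_trochanter = pick(-loc[, 3] - 0.4 * abs(loc[, 2] + 0.08 * span)),
    posterior_proximal_shaft = pick(-loc[, 1] - 0.4 * abs(loc[, 2] + 0.12 * span)),
    linea_aspera = pick(-loc[, 1] - 0.2 * abs(loc[, 2] - (yBot + 0.5 * span))),
    distal_posterior_medial = pick(-loc[, 1] - 0.5 * loc[, 3] -
                                     0.6 * abs(loc[, 2] - (yBot + 0.08 * span))),
    distal_posterior_lateral = pick(-loc[, 1] + 0.5 * loc[, 3] -
                                      0.6 * abs(loc[, 2] - (yBot + 0.08 * span))),
    anterior_shaft_distal = pick(loc[, 1] - 0.3 * abs(loc[, 2] - (yBot + 0.25 * span)))
  )
}

#' Default muscle force specification
#'
#' One row per muscle acting on the femur during gait: attachment landmark,
#' pull direction in the anatomical frame (anterior, superior, lateral;
#' normalized at application), peak force as a fraction of body weight and a
#' raised-cosine activation window in percent gait cycle. The peak values
#' and windows are configuration defaults standing in for subject-specific
#' muscle forces from musculoskeletal simulation, which is outside this
#' package's scope; they are deliberately conservative and fully
#' user-replaceable.
#'
#' @return data.frame with columns `muscle`, `landmark`, `dirAnt`, `dirSup`,
#'   `dirLat`, `peakBW`, `phaseStart`, `phaseEnd`.
#' @export
defaultMuscleSpec <- function() {
  spec <- rbind(
    c("gluteus_maximus", "posterior_proximal_shaft", -0.30, 0.80, -0.50, 0.40, 0, 30),
    c("gluteus_medius", "greater_trochanter", 0.00, 0.90, -0.44, 0.50, 0, 45),
    c("gluteus_minimus", "greater_trochanter", 0.00, 0.85, -0.50, 0.20, 0, 45),
    c("adductor_longus", "linea_aspera", 0.30, 0.70, -0.65, 0.15, 40, 70),
    c("adductor_brevis", "lesser_trochanter", 0.30, 0.65, -0.70, 0.10, 40, 65),
    c("adductor_magnus", "linea_aspera", 0.00, 0.60, -0.80, 0.20, 35, 65),
    c("pectineus", "lesser_trochanter", 0.40, 0.70, -0.60, 0.08, 40, 60),
    c("iliacus", "lesser_trochanter", 0.50, 0.80, -0.30, 0.25, 50, 75),
    c("psoas", "lesser_trochanter", 0.45, 0.85, -0.28, 0.25, 50, 75),
    c("quadratus_femoris", "posterior_proximal_shaft", -0.50, 0.30, -0.80, 0.05, 0, 40),
    c("gemellus", "greater_trochanter", -0.60, 0.20, -0.77, 0.03, 0, 40),
    c("piriformis", "greater_trochanter", -0.40, 0.50, -0.77, 0.05, 0, 40),
    c("biceps_femoris", "linea_aspera", -0.70, 0.60, 0.00, 0.15, 0, 15),
    c("vastus_medialis", "anterior_shaft_distal", 0.50, -0.85, -0.15, 0.30, 0, 25),
    c("vastus_lateralis", "anterior_shaft_distal", 0.50, -0.85, 0.15, 0.35, 0, 25),
    c("vastus_intermedius", "anterior_shaft_distal", 0.45, -0.90, 0.00, 0.25, 0, 25),
    c("gastrocnemius_medialis", "distal_posterior_medial", -0.40, -0.90, -0.15, 0.25, 25, 55),
    c("gastrocnemius_lateralis", "distal_posterior_lateral", -0.40, -0.90, 0.15, 0.15, 25, 55))
  out <- data.frame(muscle = spec[, 1], landmark = spec[, 2],
                    stringsAsFactors = FALSE)
  for (j in 3:8)
    out[[c("dirAnt", "dirSup", "dirLat", "peakBW", "phaseStart",
           "phaseEnd")[j - 2]]] <- as.numeric(spec[, j])
  out
}

# raised-cosine activation inside [t0, t1], zero outside
.activation <- function(phase, t0, t1) {
  ifelse(phase >= t0 & phase <= t1,
         0.5 * (1 - cos(2 * pi * (phase - t0) / (t1 - t0))), 0)
}

#' Build the gait load set for a mesh
#'
#' For each selected instance the hip JCF is distributed over the
#' head-surface nodes nearest the JCF line of action, accumulating nodal
#' tributary areas until the patch reaches `patchAreaMM2` (about 30 mm^2);
#' nodal weights are proportional to tributary area and sum to one, so the
#' nodal forces sum exactly to the instance JCF vector. Each active muscle is
#' applied as a concentrated force at its landmark node.
#'
#' In `neck_tracking` mode (default) the JCF direction keeps a fixed angle
#' `alpha0Deg` to the femoral neck axis: it is the inverted neck axis tilted
#' by `alpha0Deg` toward an infero-postero-medial direction expressed in a
#' neck-local basis (`tiltLocal`). Because the hip joint rotates with the
#' neck, the contact-force orientation relative to the neck axis is
#' approximately preserved across geometries -- the hip JCF follows the
#' orientation of the femoral neck. In `pelvis_fixed` mode the per-sample
#' waveform direction (femur frame) is used as-is.
#'
#' @param mesh a [HexMesh-class]
#' @param waveform a [ForceWaveform-class]
#' @param instances sample indices (default [selectLoadInstances()], n = 9)
#' @param muscleSpec muscle table (default [defaultMuscleSpec()]); NULL or an
#'   empty data.frame disables muscle loading.
#' @param mode `"neck_tracking"` or `"pelvis_fixed"`
#' @param alpha0Deg neck-tracking angle between (minus) the JCF and the neck
#'   axis, degrees.
#' @param patchAreaMM2 target patch area.
#' @param tiltLocal coefficients (inferior, posterior, medial) of the
#'   neck-local tilt mixture defining where the off-axis JCF component
#'   points relative to the neck axis.
#' @param tiltRef optional 3-vector (anatomical frame: anterior, superior,
#'   lateral) overriding the neck-local mixture.
#' @return A [GaitLoadSet-class]
#' @export
buildLoadSet <- function(mesh, waveform, instances = NULL,
                         muscleSpec = defaultMuscleSpec(),
                         mode = c("neck_tracking", "pelvis_fixed"),
                         alpha0Deg = 25, patchAreaMM2 = 30,
                         tiltLocal = c(1, 0.5, 1), tiltRef = NULL) {
  mode <- match.arg(mode)
  if (is.null(instances)) instances <- selectLoadInstances(waveform, 9L)
  meas <- measureAngles(mesh)
  surf <- extractSurface(mesh)
  van <- vertexAreasNormals(surf)
  hs <- mesh@nodeSets$head_surface
  if (!length(hs)) stop("mesh has no head_surface node set")
  vidx <- match(hs, surf@nodeIds)
  if (anyNA(vidx)) stop("head_surface nodes missing from exterior surface")
  hsAreas <- van$areas[vidx]
  hsPts <- mesh@nodeCoords[hs, , drop = FALSE]
  BW <- waveform@bodyWeightN
  lmk <- if (!is.null(muscleSpec) && nrow(muscleSpec))
    landmarkPoints(mesh, meas) else NULL
  n <- unitVec(meas@neckAxis)
  # Off-axis tilt of the JCF relative to the neck axis. The hip joint
  # rotates with the neck, so the contact-force orientation relative to the
  # neck is approximately preserved across geometries: the tilt is a fixed
  # mixture of the neck-local inferior, posterior and medial directions
  # (each the projection of the anatomical axis onto the plane
  # perpendicular to the neck axis). An explicit `tiltRef` (anatomical
  # frame) overrides the mixture.
  fr <- meas@frame
  eTilt <- if (!is.null(tiltRef)) {
    unitVec(projectOntoPlane(as.numeric(fr %*% unitVec(tiltRef)), n))
  } else {
    eI <- unitVec(projectOntoPlane(-fr[, "superior"], n))
    eP <- unitVec(projectOntoPlane(-fr[, "anterior"], n))
    eM <- unitVec(projectOntoPlane(-fr[, "lateral"], n))
    unitVec(tiltLocal[1] * eI + tiltLocal[2] * eP + tiltLocal[3] * eM)
  }

  mkInstance <- function(k, idx) {
    magBW <- sqrt(sum(waveform@forceBW[idx, ]^2))
    dir <- if (mode == "neck_tracking") {
      -(cos(alpha0Deg * pi / 180) * n) + sin(alpha0Deg * pi / 180) * eTilt
    } else {
      unitVec(waveform@forceBW[idx, ])
    }
    dir <- unitVec(dir)
    jcf <- magBW * BW * dir
    # entry point of the line of action on the head sphere
    pStar <- meas@headCenter - meas@headRadius * dir
    d2 <- rowSums(sweep(hsPts, 2, pStar)^2)
    ord <- order(d2)
    cum <- cumsum(hsAreas[ord])
    nPatch <- which(cum >= patchAreaMM2)[1]
    if (is.na(nPatch)) {
      warning(sprintf(
        "patch area saturates at %.1f mm^2 (< %.1f mm^2 requested)",
        cum[length(cum)], patchAreaMM2))
      nPatch <- length(ord)
    } else if (nPatch > 1 &&
               abs(cum[nPatch - 1] - patchAreaMM2) <
               abs(cum[nPatch] - patchAreaMM2)) {
      nPatch <- nPatch - 1L  # closest achievable area to the target
    }
    sel <- ord[seq_len(nPatch)]
    w <- hsAreas[sel] / sum(hsAreas[sel])
    mf <- data.frame(muscle = character(0), node = integer(0),
                     fx = numeric(0), fy = numeric(0), fz = numeric(0))
    if (!is.null(lmk)) {
      ph <- waveform@phase[idx]
      for (i in seq_len(nrow(muscleSpec))) {
        act <- .activation(ph, muscleSpec$phaseStart[i], muscleSpec$phaseEnd[i])
        if (act < 1e-12) next
        dirA <- unitVec(c(muscleSpec$dirAnt[i], muscleSpec$dirSup[i],
                          muscleSpec$dirLat[i]))
        fW <- as.numeric(meas@frame %*% dirA) * muscleSpec$peakBW[i] * act * BW
        lm <- lmk[[muscleSpec$landmark[i]]]
        if (is.null(lm)) stop("unresolvable muscle landmark: ",
                              muscleSpec$landmark[i])
        mf <- rbind(mf, data.frame(muscle = muscleSpec$muscle[i],
                                   node = lm$node, fx = fW[1], fy = fW[2],
                                   fz = fW[3]))
      }
    }
    list(index = k, sampleIndex = idx, phasePct = waveform@phase[idx],
         jcfVectorN = jcf, patchNodes = hs[sel], patchWeights = w,
         patchAreaMM2 = sum(hsAreas[sel]), muscleForces = mf)
  }
  insts <- lapply(seq_along(instances),
                  function(k) mkInstance(k, instances[k]))
  new("GaitLoadSet", bodyWeightN = BW, instances = insts,
      provenance = waveform@meta$provenance %||% "imported", mode = mode,
      meta = list(alpha0Deg = alpha0Deg, patchAreaMM2 = patchAreaMM2,
                  instanceSamples = as.integer(instances)))
}

#' RMS difference between two force waveforms
#'
#' Resamples `b`'s resultant magnitude onto `a`'s phase grid (linear
#' interpolation) and returns the root-mean-square difference of resultant
#' magnitudes over the cycle, in BW.
#'
#' @param a,b [ForceWaveform-class] objects
#' @return RMSD in body-weight multiples.
#' @export
rmsdWaveforms <- function(a, b) {
  ra <- resultantBW(a)
  if (min(a@phase) < min(b@phase) - 1e-9 ||
      max(a@phase) > max(b@phase) + 1e-9)
    stop("incompatible grids: b does not cover a's phase range")
  rb <- stats::approx(b@phase, resultantBW(b), xout = a@phase)$y
  sqrt(mean((ra - rb)^2))
}

# ---- waveform I/O ----------------------------------------------------------

#' Write a force waveform (OpenSim STO or CSV)
#'
#' @param waveform a [ForceWaveform-class]
#' @param path output file
#' @param format `"sto"` (tab-separated with nRows/nColumns/endheader) or
#'   `"csv"` (columns `t, fx, fy, fz, bw`). Forces are written in BW.
#' @return `path`, invisibly
#' @export
writeForceWaveform <- function(waveform, path, format = c("sto", "csv")) {
  format <- match.arg(format)
  n <- length(waveform@phase)
  if (format == "sto") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("hip_jcf_waveform", "version=1",
                 paste0("nRows=", n), "nColumns=4",
                 paste0("bodyWeightN=", format(waveform@bodyWeightN)),
                 "inDegrees=no", "endheader",
                 paste("time", "fx", "fy", "fz", sep = "\t")), con)
    writeLines(sprintf("%.10g\t%.10g\t%.10g\t%.10g", waveform@phase,
                       waveform@forceBW[, 1], waveform@forceBW[, 2],
                       waveform@forceBW[, 3]), con)
  } else {
    df <- data.frame(t = waveform@phase, fx = waveform@forceBW[, 1],
                     fy = waveform@forceBW[, 2], fz = waveform@forceBW[, 3],
                     bw = waveform@bodyWeightN)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a force waveform (OpenSim STO/MOT or CSV)
#'
#' STO/MOT: header lines through `endheader` (honouring `nRows`/`nColumns`
#' when present), then a tab/whitespace-separated table whose first column is
#' time and next three are force components. CSV: columns `t, fx, fy, fz`
#' with optional `bw`. Forces are interpreted in BW unless `units = "N"`, in
#' which case `bodyWeightN` (argument or `bw` column/header) is required to
#' convert. The time column is rescaled to percent gait cycle.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"sto"` or `"csv"`
#' @param bodyWeightN body weight in newtons (overrides file metadata)
#' @param units `"BW"` (default) or `"N"`
#' @return A [ForceWaveform-class]
#' @export
readForceWaveform <- function(path, format = c("auto", "sto", "csv"),
                              bodyWeightN = NULL, units = c("BW", "N")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sto", "mot")) "sto" else "csv"
  }
  bwFile <- NULL
  if (format == "sto") {
    lines <- readLines(path, warn = FALSE)
    endh <- grep("^\\s*endheader\\s*$", lines)
    if (!length(endh)) stop("malformed STO: missing 'endheader'")
    hdr <- lines[seq_len(endh[1] - 1)]
    getNum <- function(key) {
      ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(ln)) as.numeric(sub(".*=", "", ln[1])) else NULL
    }
    nRows <- getNum("nRows"); nCols <- getNum("nColumns")
    bwFile <- getNum("bodyWeightN")
    body <- lines[(endh[1] + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    colnamesLine <- strsplit(trimws(body[1]), "\\s+")[[1]]
    dat <- do.call(rbind, lapply(body[-1], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (!is.null(nRows) && nrow(dat) != nRows)
      stop(sprintf("STO declares nRows=%d but has %d data rows", nRows,
                   nrow(dat)))
    if (!is.null(nCols) && ncol(dat) != nCols)
      stop(sprintf("STO declares nColumns=%d but has %d columns", nCols,
                   ncol(dat)))
    if (ncol(dat) < 4)
      stop("STO needs a time column plus three force columns")
    tcol <- dat[, 1]
    F <- dat[, 2:4, drop = FALSE]
  } else {
    df <- read.csv(path)
    need <- c("t", "fx", "fy", "fz")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("CSV waveform missing column(s): ", paste(miss, collapse = ", "))
    tcol <- df$t
    F <- as.matrix(df[, c("fx", "fy", "fz")])
    if ("bw" %in% names(df)) bwFile <- df$bw[1]
  }
  bw <- bodyWeightN %||% bwFile
  if (units == "N") {
    if (is.null(bw)) stop("units='N' requires bodyWeightN")
    F <- F / bw
  }
  if (is.null(bw)) bw <- 298.2
  phase <- 100 * (tcol - tcol[1]) / (tcol[length(tcol)] - tcol[1])
  new("ForceWaveform", phase = phase, forceBW = F, bodyWeightN = bw,
      meta = list(provenance = "imported", path = path))
}
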