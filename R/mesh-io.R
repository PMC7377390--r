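# Mesh and surface interchange: STL (ASCII + binary), legacy VTK
# unstructured-grid, and a minimal Abaqus INP dialect (nodes, C3D8 elements,
# ELSET/NSET blocks).

#' Write a triangulated surface as STL
#'
#' @param surface a [TriSurface-class]
#' @param path output file
#' @param binary write binary STL (default ASCII)
#' @return `path`, invisibly.
#' @export
writeSTL <- function(surface, path, binary = FALSE) {
  v <- surface@vertices; tr <- surface@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(nrm[i, ], v[tr[i, 1], ], v[tr[i, 2], ],
                            v[tr[i, 3], ])), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid surface", con)
    fmt <- function(x) sprintf("%.12g", x)
    for (i in seq_len(nrow(tr))) {
      writeLines(c(
        paste(" facet normal", fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3])),
        "  outer loop",
        paste("   vertex", fmt(v[tr[i, 1], 1]), fmt(v[tr[i, 1], 2]), fmt(v[tr[i, 1], 3])),
        paste("   vertex", fmt(v[tr[i, 2], 1]), fmt(v[tr[i, 2], 2]), fmt(v[tr[i, 2], 3])),
        paste("   vertex", fmt(v[tr[i, 3], 1]), fmt(v[tr[i, 3], 2]), fmt(v[tr[i, 3], 3])),
        "  endloop",
        " endfacet"), con)
    }
    writeLines("endsolid surface", con)
  }
  invisible(path)
}

#' Read an STL surface (ASCII or binary, auto-detected)
#'
#' Vertices repeated across facets are merged exactly (bitwise-equal
#' coordinates).
#'
#' @param path STL file
#' @return A [TriSurface-class]
#' @export
readSTL <- function(path) {
  hdr <- readBin(path, "raw", n = 5)
  isAscii <- identical(rawToChar(hdr), "solid")
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    nums <- matrix(0, nt * 3L, 3)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      nums[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "integer", n = 1, size = 2, endian = "little")
    }
  }
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- paste(nums[, 1], nums[, 2], nums[, 3], sep = "_")
  uid <- !duplicated(key)
  verts <- nums[uid, , drop = FALSE]
  map <- match(key, key[uid])
  tri <- matrix(map, ncol = 3, byrow = TRUE)
  new("TriSurface", vertices = verts, triangles = tri,
      nodeIds = integer(nrow(verts)))
}

#' Write a hex mesh as a legacy VTK unstructured grid
#'
#' @param mesh a [HexMesh-class]
#' @param path output file
#' @param pointData,cellData named lists of numeric vectors (scalars) or
#'   3-column matrices (vectors) attached as POINT_DATA / CELL_DATA.
#' @return `path`, invisibly.
#' @export
writeVTK <- function(mesh, path, pointData = list(), cellData = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nNodes(mesh); m <- nElements(mesh)
  writeLines(c("# vtk DataFile Version 3.0", "femurFE hex mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", paste("POINTS", n, "double")), con)
  writeLines(apply(mesh@nodeCoords, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(paste("CELLS", m, m * 9L), con)
  writeLines(apply(mesh@elements - 1L, 1, function(r)
    paste(c(8L, r), collapse = " ")), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("12", m), con)
  writeBlock <- function(data, n) {
    for (nm in names(data)) {
      x <- data[[nm]]
      if (is.matrix(x)) {
        writeLines(paste("VECTORS", nm, "double"), con)
        writeLines(apply(x, 1, function(r)
          paste(sprintf("%.9g", r), collapse = " ")), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", x), con)
      }
    }
  }
  if (length(pointData)) {
    writeLines(paste("POINT_DATA", n), con)
    writeBlock(pointData, n)
  }
  if (length(cellData)) {
    writeLines(paste("CELL_DATA", m), con)
    writeBlock(cellData, m)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of hexahedra
#'
#' Parses POINTS / CELLS / CELL_TYPES only; data arrays are ignored. Element
#' sets, node sets and materials are not part of the format, so the returned
#' mesh carries empty sets and uniform materials.
#'
#' @param path VTK file
#' @param E,nu material assigned uniformly to all elements.
#' @return A [HexMesh-class]
#' @export
readVTK <- function(path, E = 1, nu = 0.3) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("no POINTS block found")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- numeric(0)
  k <- ip + 1L
  while (length(vals) < 3L * n) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]]))
    k <- k + 1L
  }
  pts <- matrix(vals[1:(3 * n)], ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  conn <- matrix(0L, m, 8)
  for (i in seq_len(m)) {
    r <- as.integer(strsplit(trimws(lines[ic + i]), "\\s+")[[1]])
    if (r[1] != 8L) stop("only hexahedral cells are supported")
    conn[i, ] <- r[2:9] + 1L
  }
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(unlist(strsplit(trimws(lines[(it + 1):(it + m)]), "\\s+")))
  if (any(types != 12L)) stop("only VTK_HEXAHEDRON (type 12) cells are supported")
  new("HexMesh", nodeCoords = pts, elements = conn,
      elementSets = list(), nodeSets = list(),
      elementE = rep(E, m), elementNu = rep(nu, m), metadata = list())
}

#' Write a hex mesh as an Abaqus input deck
#'
#' Emits `*NODE`, a single `*ELEMENT, TYPE=C3D8` block, one `*ELSET` per
#' element set and one `*NSET` per node set.
#'
#' @param mesh a [HexMesh-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeINP <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("femurFE hexahedral mesh", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nNodes(mesh)),
                     mesh@nodeCoords[, 1], mesh@nodeCoords[, 2],
                     mesh@nodeCoords[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D8", con)
  writeLines(apply(cbind(seq_len(nElements(mesh)), mesh@elements), 1,
                   function(r) paste(r, collapse = ", ")), con)
  writeIdBlock <- function(kind, nm, ids) {
    writeLines(sprintf("*%s, %s=%s", kind,
                       if (kind == "ELSET") "ELSET" else "NSET", nm), con)
    for (s in seq(1, length(ids), by = 12)) {
      writeLines(paste(ids[s:min(length(ids), s + 11)], collapse = ", "), con)
    }
  }
  for (nm in names(mesh@elementSets))
    writeIdBlock("ELSET", nm, mesh@elementSets[[nm]])
  for (nm in names(mesh@nodeSets))
    writeIdBlock("NSET", nm, mesh@nodeSets[[nm]])
  invisible(path)
}

#' Read an Abaqus input deck written by [writeINP()]
#'
#' Supports `*NODE`, `*ELEMENT TYPE=C3D8`, `*ELSET`, `*NSET`. Node and
#' element ids must be 1-based and contiguous. Materials are not stored in
#' this dialect and are assigned uniformly.
#'
#' @param path INP file
#' @param E,nu uniform material values.
#' @return A [HexMesh-class]
#' @export
readINP <- function(path, E = 1, nu = 0.3) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  nodes <- list(); elems <- list()
  elementSets <- list(); nodeSets <- list()
  nLines <- length(lines)
  while (i <= nLines) {
    ln <- trimws(lines[i])
    up <- toupper(ln)
    if (startsWith(up, "*NODE")) {
      i <- i + 1L
      while (i <= nLines && !startsWith(trimws(lines[i]), "*")) {
        nodes[[length(nodes) + 1L]] <- as.numeric(strsplit(lines[i], ",")[[1]])
        i <- i + 1L
      }
    } else if (startsWith(up, "*ELEMENT")) {
      if (!grepl("C3D8", up)) stop("only C3D8 elements are supported")
      i <- i + 1L
      while (i <= nLines && !startsWith(trimws(lines[i]), "*")) {
        elems[[length(elems) + 1L]] <- as.integer(strsplit(lines[i], ",")[[1]])
        i <- i + 1L
      }
    } else if (startsWith(up, "*ELSET") || startsWith(up, "*NSET")) {
      isEl <- startsWith(up, "*ELSET")
      nm <- sub(".*=\\s*", "", ln)
      ids <- integer(0)
      i <- i + 1L
      while (i <= nLines && !startsWith(trimws(lines[i]), "*")) {
        ids <- c(ids, as.integer(strsplit(lines[i], ",")[[1]]))
        i <- i + 1L
      }
      ids <- ids[!is.na(ids)]
      if (isEl) elementSets[[nm]] <- ids else nodeSets[[nm]] <- ids
    } else {
      i <- i + 1L
    }
  }
  if (!length(nodes)) stop("no *NODE block found")
  nm <- do.call(rbind, nodes)
  ord <- order(nm[, 1])
  coords <- nm[ord, 2:4, drop = FALSE]
  em <- do.call(rbind, elems)
  em <- em[order(em[, 1]), , drop = FALSE]
  conn <- em[, 2:9, drop = FALSE]
  storage.mode(conn) <- "integer"
  mEl <- nrow(conn)
  new("HexMesh", nodeCoords = coords, elements = conn,
      elementSets = elementSets, nodeSets = nodeSets,
      elementE = rep(E, mEl), elementNu = rep(nu, mEl), metadata = list())
}
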