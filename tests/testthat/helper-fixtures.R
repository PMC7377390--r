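# Shared fixtures: coarse femur meshes cached per geometry so each is built
# once per test run. Coarse meshes (12 elements/layer, 3 growth-plate rows)
# keep unit tests fast; resolution-sensitive checks build their own meshes.

.fixtureCache <- new.env(parent = emptyenv())

tinyParams <- function(nsa = 120, ava = 20, ...) {
  femurParams(nsaDeg = nsa, avaDeg = ava, nCirc = 8L, nGpRows = 3L,
              nTransitionRows = 2L, ...)
}

tinyFemur <- function(nsa = 120, ava = 20) {
  key <- sprintf("tiny_%g_%g", nsa, ava)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateFemur(tinyParams(nsa, ava))
  .fixtureCache[[key]]
}

defaultFemur <- function(nsa = 120, ava = 20) {
  key <- sprintf("full_%g_%g", nsa, ava)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateFemur(femurParams(nsaDeg = nsa,
                                                      avaDeg = ava))
  .fixtureCache[[key]]
}

# lat-long triangulated sphere for surface-distance oracles
uvSphere <- function(center, radius, nLat = 12, nLon = 24) {
  lat <- seq(-pi / 2, pi / 2, length.out = nLat)
  lon <- seq(0, 2 * pi, length.out = nLon + 1)[-1]
  verts <- rbind(c(0, 0, -radius), c(0, 0, radius))
  idx <- matrix(0L, nLat, nLon)
  for (i in 2:(nLat - 1)) for (j in seq_len(nLon)) {
    verts <- rbind(verts, radius * c(cos(lat[i]) * cos(lon[j]),
                                     cos(lat[i]) * sin(lon[j]), sin(lat[i])))
    idx[i, j] <- nrow(verts)
  }
  tris <- NULL
  for (j in seq_len(nLon)) {
    jn <- j %% nLon + 1L
    tris <- rbind(tris, c(1L, idx[2, jn], idx[2, j]),
                  c(2L, idx[nLat - 1, j], idx[nLat - 1, jn]))
    for (i in 2:(nLat - 2)) {
      tris <- rbind(tris, c(idx[i, j], idx[i, jn], idx[i + 1, j]),
                    c(idx[i, jn], idx[i + 1, jn], idx[i + 1, j]))
    }
  }
  new("TriSurface", vertices = sweep(verts, 2, -center),
      triangles = tris, nodeIds = integer(nrow(verts)))
}

rotationZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
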