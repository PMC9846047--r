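#' Construct a scalp mesh
#'
#' @param vertices M x 3 matrix, mm.
#' @param faces F x 3 integer matrix (1-based).
#' @param landmarks 4 x 3 matrix with rows NZ, IZ, AL, AR.
#' @return A \code{\linkS4class{ScalpMesh}}.
#' @export
ScalpMesh <- function(vertices, faces, landmarks) {
  vertices <- as.matrix(vertices); dimnames(vertices) <- NULL
  storage.mode(faces) <- "integer"
  faces <- as.matrix(faces); dimnames(faces) <- NULL
  landmarks <- as.matrix(landmarks)
  rownames(landmarks) <- c("NZ", "IZ", "AL", "AR")
  colnames(landmarks) <- NULL
  new("ScalpMesh", vertices = vertices, faces = faces, landmarks = landmarks)
}

#' Landmark accessor
#' @param mesh a \code{ScalpMesh}.
#' @param which landmark label.
#' @return numeric(3).
#' @export
landmark <- function(mesh, which) mesh@landmarks[which, ]

#' Read / write a mesh in ASCII PLY format
#'
#' Landmarks travel in a sidecar TSV (columns label, x, y, z) written next
#' to the PLY with extension \code{.landmarks.tsv}.
#'
#' @param path PLY file path.
#' @param mesh a \code{ScalpMesh}.
#' @return \code{readPly}: a \code{ScalpMesh}; \code{writePly}: the path.
#' @export
writePly <- function(mesh, path) {
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh@vertices, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh@faces - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  lmPath <- sub("\\.ply$", ".landmarks.tsv", path)
  write.table(data.frame(label = rownames(mesh@landmarks),
                         x = mesh@landmarks[, 1], y = mesh@landmarks[, 2],
                         z = mesh@landmarks[, 3]),
              lmPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePly
#' @export
readPly <- function(path) {
  lines <- readLines(path)
  endHdr <- which(lines == "end_header")[1L]
  if (is.na(endHdr)) stop("not an ASCII PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vtx <- matrix(scan(text = lines[(endHdr + 1L):(endHdr + nv)], quiet = TRUE),
                nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fc <- matrix(scan(text = lines[(endHdr + nv + 1L):(endHdr + nv + nf)],
                    quiet = TRUE), nrow = nf, byrow = TRUE)
  faces <- fc[, 2:4, drop = FALSE] + 1L
  storage.mode(faces) <- "integer"
  lmPath <- sub("\\.ply$", ".landmarks.tsv", path)
  lm <- read.delim(lmPath)
  lmm <- as.matrix(lm[match(c("NZ", "IZ", "AL", "AR"), lm$label), c("x", "y", "z")])
  ScalpMesh(vtx, faces, lmm)
}

# ---- internal mesh machinery ------------------------------------------------

.meanEdgeLength <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  mean(sqrt(rowSums((v[e[, 1L], ] - v[e[, 2L], ])^2)))
}

.faceNormals <- function(mesh, oriented = TRUE) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2L], ] - v[f[, 1L], ]
  b <- v[f[, 3L], ] - v[f[, 1L], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1]) # area-weighted (2A)
  if (oriented) {
    ctr <- colMeans(v)
    fc <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
    out <- rowSums(n * sweep(fc, 2L, ctr)) < 0
    n[out, ] <- -n[out, ]
  }
  n
}

# Area-weighted outward vertex normals (all vertices).
.vertexNormals <- function(mesh) {
  fn <- .faceNormals(mesh)
  f <- mesh@faces
  vn <- matrix(0, nrow(mesh@vertices), 3L)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate2(f[, k], fn[, 1], nrow(vn))
    vn[, 2] <- vn[, 2] + tabulate2(f[, k], fn[, 2], nrow(vn))
    vn[, 3] <- vn[, 3] + tabulate2(f[, k], fn[, 3], nrow(vn))
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Index of the face nearest to point p (by distance to the face plane within
# the face's barycentric footprint, approximated by distance to centroid
# pre-screening then exact point-triangle distance on candidates).
.nearestFace <- function(mesh, p) {
  v <- mesh@vertices; f <- mesh@faces
  fc <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
  d2 <- rowSums(sweep(fc, 2L, p)^2)
  cand <- order(d2)[seq_len(min(30L, nrow(f)))]
  best <- cand[1L]; bestD <- Inf
  for (i in cand) {
    d <- .pointTriDist(p, v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ])
    if (d < bestD) { bestD <- d; best <- i }
  }
  best
}

.pointTriDist <- function(p, a, b, c) {
  # Ericson-style closest point on triangle
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3); return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6); return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  q <- a + ab * (vb * denom) + ac * (vc * denom)
  sqrt(sum((p - q)^2))
}

# Exact triangle-plane intersection of a closed mesh: returns the ordered
# closed polyline (k x 3, implicit edge from last row back to the first).
.planeSlice <- function(mesh, p0, n) {
  v <- mesh@vertices; f <- mesh@faces
  n <- .unit(n)
  d <- as.numeric(sweep(v, 2L, p0) %*% n)
  d[abs(d) < 1e-9] <- 1e-9 # nudge on-plane vertices off the plane
  s <- d > 0
  sf <- cbind(s[f[, 1L]], s[f[, 2L]], s[f[, 3L]])
  rs <- rowSums(sf)
  crossing <- which(rs == 1L | rs == 2L)
  if (length(crossing) == 0L) stop("plane does not intersect the mesh")
  segA <- character(length(crossing)); segB <- character(length(crossing))
  ptA <- matrix(0, length(crossing), 3L); ptB <- ptA
  edgeKey <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  edgePoint <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  for (k in seq_along(crossing)) {
    tri <- f[crossing[k], ]
    ss <- s[tri]
    lone <- if (sum(ss) == 1L) which(ss) else which(!ss)
    i0 <- tri[lone]
    others <- tri[-lone]
    segA[k] <- edgeKey(i0, others[1L]); ptA[k, ] <- edgePoint(i0, others[1L])
    segB[k] <- edgeKey(i0, others[2L]); ptB[k, ] <- edgePoint(i0, others[2L])
  }
  # chain segments into a closed loop through shared edge keys
  keys <- c(segA, segB)
  lookup <- split(rep(seq_along(segA), 2L), keys)
  nseg <- length(segA)
  used <- logical(nseg)
  ord <- integer(nseg)
  pts <- matrix(0, nseg, 3L)
  cur <- 1L; curKey <- segA[1L]
  startKey <- segB[1L]
  for (k in seq_len(nseg)) {
    used[cur] <- TRUE
    ord[k] <- cur
    pts[k, ] <- if (segA[cur] == curKey) ptA[cur, ] else ptB[cur, ]
    nextKey <- if (segA[cur] == curKey) segB[cur] else segA[cur]
    cands <- lookup[[nextKey]]
    nxt <- cands[!used[cands]]
    if (length(nxt) == 0L) {
      if (k < nseg)
        pts <- pts[seq_len(k), , drop = FALSE] # open or multi-component
      break
    }
    cur <- nxt[1L]
    curKey <- nextKey
  }
  pts
}

# ---- polyline utilities -----------------------------------------------------

.polyCumLen <- function(pts) {
  seglen <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seglen))
}

# Arc position (distance from the first point, along the closed loop) of the
# point on the closed polyline closest to q. Returns list(arc, dist, point).
.projectClosed <- function(pts, q) {
  k <- nrow(pts)
  a <- pts
  b <- pts[c(2:k, 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  aq <- sweep(a, 2L, q, "-")
  t <- .clamp(-rowSums(aq * ab) / pmax(len2, 1e-300), 0, 1)
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2L, q)^2)
  i <- which.min(d2)
  seglen <- sqrt(len2)
  cum <- c(0, cumsum(seglen))
  list(arc = cum[i] + t[i] * seglen[i], dist = sqrt(d2[i]),
       point = proj[i, ], total = cum[k + 1L])
}

# Extract the open sub-polyline of a closed polyline from arc position a1 to
# arc position a2 walking forward (increasing arc, wrapping).
.extractArc <- function(pts, a1, a2) {
  k <- nrow(pts)
  b <- pts[c(2:k, 1L), , drop = FALSE]
  seglen <- sqrt(rowSums((b - pts)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[k + 1L]
  pointAt <- function(arc) {
    arc <- arc %% total
    i <- findInterval(arc, cum, rightmost.closed = TRUE)
    i <- min(i, k)
    t <- (arc - cum[i]) / max(seglen[i], 1e-300)
    pts[i, ] + t * (b[i, ] - pts[i, ])
  }
  span <- (a2 - a1) %% total
  if (span < 1e-12) return(rbind(pointAt(a1), pointAt(a2)))
  # interior vertices strictly between a1 and a1+span
  arcs <- cum[seq_len(k)]
  rel <- (arcs - a1) %% total
  inner <- arcs[rel > 1e-9 & rel < span - 1e-9]
  innerRel <- sort((inner - a1) %% total)
  out <- rbind(pointAt(a1),
               if (length(innerRel)) t(vapply(a1 + innerRel, pointAt,
                                              numeric(3L))) else NULL,
               pointAt(a1 + span))
  out
}

.pointAtFraction <- function(pts, frac) {
  cum <- .polyCumLen(pts)
  total <- cum[length(cum)]
  arc <- frac * total
  i <- findInterval(arc, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- pts[i + 1L, ] - pts[i, ]
  t <- (arc - cum[i]) / max(sqrt(sum(seg^2)), 1e-300)
  pts[i, ] + t * seg
}

# Arc-length fraction of the projection of q onto an open polyline.
.projectOpen <- function(pts, q) {
  k <- nrow(pts)
  a <- pts[-k, , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  aq <- sweep(a, 2L, q, "-")
  t <- .clamp(-rowSums(aq * ab) / pmax(len2, 1e-300), 0, 1)
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2L, q)^2)
  i <- which.min(d2)
  cum <- .polyCumLen(pts)
  arc <- cum[i] + t[i] * sqrt(len2[i])
  list(frac = arc / cum[k], dist = sqrt(d2[i]), point = proj[i, ])
}
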