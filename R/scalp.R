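#' Sagittal reference curve of the CPC system
#'
#' The scalp curve from nasion (NZ) to inion (IZ) obtained by intersecting
#' the surface with the plane through NZ, IZ and the midpoint of the two
#' preauricular points, and keeping the superior arc. Proportional position
#' \code{p_nz} is arc-length fraction along this curve.
#'
#' @param mesh a \code{ScalpMesh}.
#' @return An ordered polyline (k x 3 matrix) from NZ to IZ on the surface.
#' @export
sagittalCurve <- function(mesh) {
  nz <- landmark(mesh, "NZ"); iz <- landmark(mesh, "IZ")
  al <- landmark(mesh, "AL"); ar <- landmark(mesh, "AR")
  if (sqrt(sum((nz - iz)^2)) < 1e-9) stop("degenerate landmarks: NZ equals IZ")
  mid <- (al + ar) / 2
  nrm <- .cross(iz - nz, mid - nz)
  if (sqrt(sum(nrm^2)) < 1e-6 * sum((iz - nz)^2)) {
    # symmetric head: the preauricular midpoint lies on the NZ-IZ line, so
    # span the plane with the landmark-derived up direction instead
    up0 <- .cross(ar - al, nz - iz)
    nrm <- .cross(iz - nz, up0)
  }
  if (sqrt(sum(nrm^2)) < 1e-9)
    stop("landmarks are collinear; sagittal plane undefined")
  loop <- .planeSlice(mesh, nz, nrm)
  up <- .unit(.cross(ar - al, nz - iz))
  pn <- .projectClosed(loop, nz)
  pi_ <- .projectClosed(loop, iz)
  arc1 <- .extractArc(loop, pn$arc, pi_$arc)
  arc2 <- .extractArc(loop, pi_$arc, pn$arc)
  arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE] # also NZ -> IZ
  h1 <- max(arc1 %*% up); h2 <- max(arc2 %*% up)
  if (h1 >= h2) arc1 else arc2
}

# Coronal curve through the sagittal point sp: surface cut by the plane
# through AL, AR and sp, superior/near-sp arc, ordered AL -> AR.
.coronalCurve <- function(mesh, sp) {
  al <- landmark(mesh, "AL"); ar <- landmark(mesh, "AR")
  nrm <- .cross(ar - al, sp - al)
  if (sqrt(sum(nrm^2)) < 1e-9)
    stop("degenerate coordinate: sagittal point collinear with AL-AR")
  loop <- .planeSlice(mesh, al, nrm)
  pa <- .projectClosed(loop, al)
  pb <- .projectClosed(loop, ar)
  arc1 <- .extractArc(loop, pa$arc, pb$arc)
  arc2 <- .extractArc(loop, pb$arc, pa$arc)
  arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]
  d1 <- .projectOpen(arc1, sp)$dist
  d2 <- .projectOpen(arc2, sp)$dist
  if (d1 <= d2) arc1 else arc2
}

#' Forward CPC mapping: proportional coordinates to a scalp point
#'
#' Walks proportional arc length \code{p[1]} (p_nz) along the sagittal
#' curve, takes the coronal curve through that point (surface cut by the
#' plane through AL, AR and the sagittal point), and walks proportional arc
#' length \code{p[2]} (p_al) along it from AL.
#'
#' @param mesh a \code{ScalpMesh}.
#' @param p numeric(2): \code{c(p_nz, p_al)}, both in [0, 1]; p_nz must be
#'   in the open interval (0, 1) unless p_al = 0.5 (the poles collapse to
#'   NZ/IZ).
#' @return numeric(3), the scalp point in mm.
#' @export
cpcForward <- function(mesh, p) {
  pnz <- p[1L]; pal <- p[2L]
  if (any(p < 0 | p > 1)) stop("CPC coordinates must lie in [0, 1]")
  if (pnz <= 0 || pnz >= 1) {
    if (abs(pal - 0.5) < 1e-9)
      return(if (pnz <= 0) landmark(mesh, "NZ") else landmark(mesh, "IZ"))
    stop("degenerate coordinate: p_nz at a pole with p_al != 0.5")
  }
  sag <- sagittalCurve(mesh)
  sp <- .pointAtFraction(sag, pnz)
  cc <- .coronalCurve(mesh, sp)
  .pointAtFraction(cc, pal)
}

#' Inverse CPC mapping: scalp point to proportional coordinates
#'
#' Finds p_nz by solving for the coronal plane through AL, AR containing
#' the query point, then reads p_al as the arc-length fraction of the
#' point's projection onto that coronal curve. At the preauricular poles
#' every coronal curve meets (p_al in {0, 1}), so p_nz is undefined and
#' returned as NA there.
#'
#' @param mesh a \code{ScalpMesh}.
#' @param q numeric(3) point within \code{tol} of the surface.
#' @param tol off-surface tolerance in mm; default 2 mean edge lengths.
#' @return numeric(2): \code{c(p_nz, p_al)}.
#' @export
cpcInverse <- function(mesh, q, tol = NULL) {
  if (is.null(tol)) tol <- 2 * .meanEdgeLength(mesh)
  nz <- landmark(mesh, "NZ"); iz <- landmark(mesh, "IZ")
  al <- landmark(mesh, "AL"); ar <- landmark(mesh, "AR")
  eps <- 1e-6
  if (sqrt(sum((q - nz)^2)) < eps) return(c(0, 0.5))
  if (sqrt(sum((q - iz)^2)) < eps) return(c(1, 0.5))
  if (sqrt(sum((q - al)^2)) < eps) return(c(NA_real_, 0))
  if (sqrt(sum((q - ar)^2)) < eps) return(c(NA_real_, 1))
  sag <- sagittalCurve(mesh)
  g <- function(t) {
    sp <- .pointAtFraction(sag, t)
    n <- .unit(.cross(ar - al, sp - al))
    sum((q - al) * n)
  }
  lo <- 1e-4; hi <- 1 - 1e-4
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi)) {
    # beyond a pole: clamp to whichever end is closer in plane distance
    pnz <- if (abs(glo) < abs(ghi)) lo else hi
  } else {
    pnz <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  }
  sp <- .pointAtFraction(sag, pnz)
  cc <- .coronalCurve(mesh, sp)
  pr <- .projectOpen(cc, q)
  if (pr$dist > tol)
    stop("point is off the scalp surface beyond tolerance (",
         signif(pr$dist, 4), " mm)")
  c(pnz, pr$frac)
}

#' Coil reference frame at a scalp position
#'
#' The outward normal is the area-weighted average of the face normals in
#' the 1-ring of the containing triangle. The 0-degree direction lies in
#' the tangent plane, perpendicular to the intersection of the tangent
#' plane with the plane through the position and both preauricular points,
#' and points backward (toward the inion side). The handle direction is the
#' 0-degree direction rotated by \code{theta} about the outward normal;
#' anticlockwise rotation (viewed from outside the head) is positive,
#' clockwise negative.
#'
#' @param mesh a \code{ScalpMesh}.
#' @param p CPC coordinates \code{c(p_nz, p_al)}.
#' @param theta handle angle in degrees, in (-180, 180].
#' @return A list of class \code{CoilFrame}: \code{center}, \code{normal},
#'   \code{zeroDir}, \code{handleDir}, \code{theta}.
#' @export
coilFrame <- function(mesh, p, theta = 0) {
  .rotateFrame(.frameAt(mesh, p), theta)
}

# orientation-independent part of the frame (one mesh slice per position)
.frameAt <- function(mesh, p) {
  ctr <- cpcForward(mesh, p)
  fi <- .nearestFace(mesh, ctr)
  tri <- mesh@faces[fi, ]
  ring <- which(rowSums(matrix(mesh@faces %in% tri, ncol = 3L)) > 0)
  fn <- .faceNormals(mesh)[ring, , drop = FALSE]
  nrm <- colSums(fn)
  if (sum(nrm * (ctr - colMeans(mesh@landmarks))) < 0) nrm <- -nrm
  nrm <- .unit(nrm)
  al <- landmark(mesh, "AL"); ar <- landmark(mesh, "AR")
  planeN <- .cross(ar - al, ctr - al)
  if (sqrt(sum(planeN^2)) < 1e-9)
    stop("frame undefined: position collinear with AL-AR")
  lineDir <- .cross(nrm, .unit(planeN))
  if (sqrt(sum(lineDir^2)) < 1e-9)
    stop("frame undefined: tangent plane parallel to the AL-AR plane")
  zero <- .unit(.cross(nrm, .unit(lineDir)))
  iz <- landmark(mesh, "IZ")
  if (sum(zero * (iz - ctr)) < 0) zero <- -zero
  structure(list(center = ctr, normal = nrm, zeroDir = zero,
                 handleDir = zero, theta = 0),
            class = "CoilFrame")
}

.rotateFrame <- function(frame, theta) {
  if (theta <= -180 || theta > 180) stop("theta must lie in (-180, 180]")
  th <- theta * pi / 180
  frame$handleDir <- .unit(cos(th) * frame$zeroDir +
                           sin(th) * .cross(frame$normal, frame$zeroDir))
  frame$theta <- theta
  frame
}

#' @export
print.CoilFrame <- function(x, ...) {
  cat("CoilFrame at (", paste(signif(x$center, 4), collapse = ", "),
      ") mm, theta = ", x$theta, " deg\n", sep = "")
  invisible(x)
}

#' Restore a coil placement from a cortical target
#'
#' Returns the CPC coordinates of the scalp point whose inward normal best
#' points at the given cortical target (the usual way literature targets in
#' MNI coordinates are projected back to the scalp). Ties in alignment
#' angle are broken by smaller Euclidean distance to the target, then by
#' distance to the mean landmark position, then by vertex order.
#'
#' @param mesh a \code{ScalpMesh} (assumed convex for the containment test).
#' @param target numeric(3) cortical point in mm; must lie inside the head.
#' @param maxAngle cap in degrees on the normal-to-target angle; no scalp
#'   point below the cap raises an error.
#' @return numeric(2) CPC coordinates.
#' @export
restorePlacement <- function(mesh, target, maxAngle = 30) {
  v <- mesh@vertices; f <- mesh@faces
  fn <- .faceNormals(mesh)
  fc <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
  inside <- all(rowSums(fn * sweep(fc, 2L, target, "-")) > -1e-9)
  if (!inside) stop("target lies outside the head surface")
  vn <- .vertexNormals(mesh)
  toTarget <- -sweep(v, 2L, target, "-")
  dist <- sqrt(rowSums(toTarget^2))
  cosang <- rowSums((-vn) * toTarget) / pmax(dist, 1e-300)
  ang <- acos(.clamp(cosang, -1, 1))
  # the antipodal patch also points its inward normal at the target (through
  # the head); keep only the target's own hemisphere unless degenerate
  ctr0 <- colMeans(mesh@landmarks)
  sameSide <- rowSums(sweep(v, 2L, ctr0) *
                      matrix(target - ctr0, nrow(v), 3L, byrow = TRUE)) >= 0
  if (any(sameSide)) ang[!sameSide] <- pi
  amin <- min(ang)
  if (amin > maxAngle * pi / 180)
    stop("target not reachable: best normal alignment ",
         signif(amin * 180 / pi, 4), " deg exceeds the cap")
  # near-tie band: on a closed surface the antipodal point aligns almost as
  # well as the near-side point; the distance tie-break resolves that
  band <- 5 * pi / 180
  cand <- which(ang <= amin + band)
  if (length(cand) > 1L) {
    dmin <- min(dist[cand]); cand <- cand[dist[cand] <= dmin + 1e-9]
  }
  if (length(cand) > 1L) {
    lc <- colMeans(mesh@landmarks)
    dl <- sqrt(rowSums(sweep(v[cand, , drop = FALSE], 2L, lc)^2))
    cand <- cand[order(dl, cand)][1L]
  }
  cpcInverse(mesh, v[cand[1L], ])
}
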