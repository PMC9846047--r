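#' Pathological network as a patient-minus-control difference map
#'
#' @param iPt,iHc \code{BrainMap}s of the patient and control states on the
#'   same grid.
#' @return \code{BrainMap} with values \code{iPt - iHc}.
#' @export
differenceMap <- function(iPt, iHc) {
  if (!identical(iPt@grid@dims, iHc@grid@dims) ||
      max(abs(iPt@grid@affine - iHc@grid@affine)) > 1e-9)
    stop("maps are on different grids")
  BrainMap(iPt@grid, iPt@values - iHc@values)
}

#' Read a meta-analysis foci table
#'
#' TSV with header columns \code{x, y, z} (MNI mm), \code{direction}
#' (+1 hyperactive, -1 hypoactive) and optional positive \code{weight}
#' (default 1).
#'
#' @param path TSV path.
#' @return A validated data.frame of foci.
#' @export
readFoci <- function(path) {
  df <- read.delim(path)
  validateFoci(df)
}

#' @rdname readFoci
#' @param foci data.frame with the foci columns.
#' @export
validateFoci <- function(foci) {
  need <- c("x", "y", "z", "direction")
  if (!all(need %in% names(foci)))
    stop("foci table needs columns x, y, z, direction")
  if (nrow(foci) < 1L) stop("foci table must have at least one row")
  if (!all(is.finite(as.matrix(foci[, c("x", "y", "z")]))))
    stop("foci coordinates must be finite")
  if (!all(foci$direction %in% c(-1, 1)))
    stop("foci direction must be +1 or -1")
  if (is.null(foci$weight)) foci$weight <- 1
  if (any(!is.finite(foci$weight) | foci$weight <= 0))
    stop("foci weights must be positive")
  foci
}

#' Build a pathological-network map from foci spheres
#'
#' Each focus contributes \code{direction * weight} to every gray-matter
#' voxel whose center lies within \code{radius} mm of it; overlapping
#' spheres add (signed), so hyper- and hypoactive foci cancel where they
#' overlap. Foci outside gray matter are kept; only the in-mask portion of
#' their spheres contributes.
#'
#' @param foci foci data.frame (see \code{\link{readFoci}}).
#' @param grid the reference \code{VoxelGrid}.
#' @param radius sphere radius in mm (default 10, the midpoint of the
#'   4-16 mm stability range).
#' @return A \code{BrainMap}.
#' @export
fociToMap <- function(foci, grid, radius = 10) {
  foci <- validateFoci(foci)
  if (radius <= 0) stop("radius must be positive")
  coords <- grid@coords
  vals <- numeric(nrow(coords))
  hit <- FALSE
  r2 <- radius^2
  for (i in seq_len(nrow(foci))) {
    d2 <- (coords[, 1] - foci$x[i])^2 + (coords[, 2] - foci$y[i])^2 +
          (coords[, 3] - foci$z[i])^2
    inside <- d2 <= r2
    if (any(inside)) {
      hit <- TRUE
      vals[inside] <- vals[inside] + foci$direction[i] * foci$weight[i]
    }
  }
  if (!hit)
    stop("empty pathology: no focus sphere covers any gray-matter voxel")
  BrainMap(grid, vals)
}

#' Sensitivity of a pathology-derived score to the foci radius
#'
#' Rebuilds the pathological map at each radius, applies \code{score} to
#' it, and reports the pairwise Pearson correlations between the maps.
#'
#' @param foci foci data.frame.
#' @param grid the reference \code{VoxelGrid}.
#' @param radii numeric vector of at least two radii in mm.
#' @param score function \code{BrainMap -> numeric(1)}.
#' @return A list with \code{table} (data.frame radius, score) and
#'   \code{correlations} (|radii| x |radii| matrix).
#' @export
radiusSensitivity <- function(foci, grid, radii, score) {
  if (length(radii) < 2L) stop("need at least two radii")
  maps <- lapply(radii, function(r) fociToMap(foci, grid, r))
  scores <- vapply(maps, score, numeric(1L))
  k <- length(radii)
  cc <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    cc[i, j] <- cc[j, i] <- mapCorrelation(maps[[i]], maps[[j]])
  }
  dimnames(cc) <- list(radii, radii)
  list(table = data.frame(radius = radii, score = scores),
       correlations = cc, maps = maps)
}
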