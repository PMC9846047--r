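#' @import methods
#' @importFrom stats cor quantile rnorm runif pf pt sd uniroot
#' @importFrom utils read.delim write.table
NULL

#' Reference voxel grid with a gray-matter mask
#'
#' A \code{VoxelGrid} fixes the discrete spatial frame every map-valued object
#' in the package lives on: the array dimensions, the 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm (MNI-style, RAS), and a
#' logical gray-matter mask. All model vectors (brain maps, connectome
#' columns, local-effect vectors) are defined only over the \code{N} masked
#' voxels; world coordinates of the masked voxel centers are precomputed and
#' stored.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @slot mask logical array of dimension \code{dims}.
#' @slot coords N x 3 numeric matrix of world-mm centers of masked voxels.
#' @slot maskIdx integer(N), linear indices of masked voxels in the array.
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", affine = "matrix", mask = "array",
                 coords = "matrix", maskIdx = "integer"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("dims must be three positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be 4x4")
    if (abs(det(object@affine)) < 1e-12)
      return("affine must be invertible")
    if (!identical(dim(object@mask), object@dims))
      return("mask dimensions must equal grid dimensions")
    n <- sum(object@mask)
    if (n < 1L) return("mask must contain at least one voxel")
    if (nrow(object@coords) != n || length(object@maskIdx) != n)
      return("coords/maskIdx inconsistent with mask")
    TRUE
  })

#' Signed brain map over the gray-matter voxels of a grid
#'
#' Holds one real value per masked voxel of its \code{\linkS4class{VoxelGrid}}.
#' Used for E-field magnitudes, stimulation networks, pathological-network
#' maps, and patient/control state vectors.
#'
#' @slot grid a \code{VoxelGrid}.
#' @slot values numeric(N), finite.
#' @export
setClass("BrainMap",
  representation(grid = "VoxelGrid", values = "numeric"),
  validity = function(object) {
    if (length(object@values) != nrow(object@grid@coords))
      return("values length must equal the number of masked voxels")
    if (!all(is.finite(object@values)))
      return("map values must all be finite")
    TRUE
  })

#' Triangulated scalp surface with fiducial landmarks
#'
#' @slot vertices M x 3 numeric matrix, mm.
#' @slot faces F x 3 integer matrix of 1-based vertex indices.
#' @slot landmarks 4 x 3 numeric matrix with rownames NZ, IZ, AL, AR
#'   (nasion, inion, left/right preauricular), points on the surface.
#' @export
setClass("ScalpMesh",
  representation(vertices = "matrix", faces = "matrix", landmarks = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be M x 3")
    if (ncol(object@faces) != 3L) return("faces must be F x 3")
    if (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices))
      return("face indices out of range")
    lm <- object@landmarks
    if (!identical(rownames(lm), c("NZ", "IZ", "AL", "AR")) ||
        ncol(lm) != 3L)
      return("landmarks must be a 4x3 matrix with rows NZ, IZ, AL, AR")
    d <- as.matrix(stats::dist(lm))
    if (any(d[upper.tri(d)] < 1e-9))
      return("landmarks must be pairwise distinct")
    TRUE
  })

#' Stimulation protocol: pulse frequency and its polarity class
#'
#' High-frequency trains (> 5 Hz) are modeled as excitatory, low-frequency
#' trains (<= 1 Hz) as inhibitory. Frequencies in (1, 5] Hz have no accepted
#' polarity under this convention and are rejected.
#'
#' @slot frequencyHz positive numeric.
#' @slot polarity +1 (excitatory) or -1 (inhibitory).
#' @export
setClass("StimProtocol",
  representation(frequencyHz = "numeric", polarity = "numeric"),
  validity = function(object) {
    f <- object@frequencyHz
    if (length(f) != 1L || !is.finite(f) || f <= 0)
      return("frequencyHz must be a positive number")
    ok <- (f > 5 && object@polarity == 1) || (f <= 1 && object@polarity == -1)
    if (!ok) return("frequency does not match polarity convention")
    TRUE
  })

#' Signed local-effect vector of a TMS pulse
#'
#' Sparse representation of the direct cortical effect: the suprathreshold
#' E-field voxels (support) carry signed weights, +w for excitatory and -w
#' for inhibitory stimulation; all other voxels are implicitly zero.
#'
#' @slot grid the reference \code{VoxelGrid}.
#' @slot support integer indices into the masked-voxel vector.
#' @slot weights signed numeric weights, one per support voxel, all of one
#'   sign and nonzero.
#' @export
setClass("LocalEffect",
  representation(grid = "VoxelGrid", support = "integer", weights = "numeric"),
  validity = function(object) {
    if (length(object@support) < 1L) return("support must be nonempty")
    if (length(object@weights) != length(object@support))
      return("weights and support lengths differ")
    if (any(object@weights == 0) || !all(is.finite(object@weights)))
      return("weights must be finite and nonzero")
    s <- sign(object@weights)
    if (length(unique(s)) != 1L) return("weights must share one sign")
    n <- nrow(object@grid@coords)
    if (min(object@support) < 1L || max(object@support) > n)
      return("support outside the gray-matter vector")
    TRUE
  })

#' Voxel-wise signed functional connectome
#'
#' Represents the N x N signed resting-state functional-connectivity operator
#' C, either materialized (\code{dense}: symmetric with unit diagonal) or
#' backed by a column-standardized time-series table (\code{timeseries}:
#' T x N with zero column means and unit column standard deviations), in
#' which case products C v are computed on demand as X'(X v)/(T-1).
#'
#' @slot grid the reference \code{VoxelGrid}.
#' @slot backend "dense" or "timeseries".
#' @slot data the N x N matrix or the standardized T x N matrix.
#' @export
setClass("Connectome",
  representation(grid = "VoxelGrid", backend = "character", data = "matrix"),
  validity = function(object) {
    n <- nrow(object@grid@coords)
    if (object@backend == "dense") {
      if (!all(dim(object@data) == c(n, n)))
        return("dense backend must be N x N")
      if (max(abs(object@data - t(object@data))) > 1e-9)
        return("dense connectome must be symmetric within 1e-9")
      if (max(abs(diag(object@data) - 1)) > 1e-9)
        return("dense connectome must have unit diagonal")
    } else if (object@backend == "timeseries") {
      if (ncol(object@data) != n)
        return("timeseries backend must be T x N")
      if (nrow(object@data) < 3L) return("need at least T = 3 timepoints")
      if (max(abs(colMeans(object@data))) > 1e-9)
        return("timeseries columns must have zero mean")
      sds <- sqrt(colSums(object@data^2) / (nrow(object@data) - 1L))
      if (max(abs(sds - 1)) > 1e-9)
        return("timeseries columns must have unit standard deviation")
    } else return("backend must be 'dense' or 'timeseries'")
    TRUE
  })

#' Coil placement search space
#'
#' The product of a list of scalp positions (CPC pairs) and a list of coil
#' orientations, in fixed position-major order.
#'
#' @slot positions P x 2 numeric matrix, columns \code{p_nz}, \code{p_al},
#'   both in [0, 1].
#' @slot orientations numeric vector of handle angles in degrees,
#'   within (-180, 180].
#' @export
setClass("SearchSpace",
  representation(positions = "matrix", orientations = "numeric"),
  validity = function(object) {
    p <- object@positions
    if (ncol(p) != 2L || nrow(p) < 1L) return("positions must be P x 2")
    if (any(p < 0 | p > 1)) return("positions must lie in [0,1]^2")
    o <- object@orientations
    if (length(o) < 1L || any(o <= -180 | o > 180))
      return("orientations must lie in (-180, 180]")
    if (anyDuplicated(p)) return("duplicate positions")
    if (anyDuplicated(o)) return("duplicate orientations")
    TRUE
  })

#' Per-subject NTA values over a search space
#'
#' @slot subject character id.
#' @slot space the \code{SearchSpace} evaluated.
#' @slot values |positions| x |orientations| matrix of NTA values; cells
#'   where the placement failed (e.g. empty E-field support) are NA.
#' @export
setClass("NTAGrid",
  representation(subject = "character", space = "SearchSpace",
                 values = "matrix"),
  validity = function(object) {
    sp <- object@space
    if (!all(dim(object@values) ==
             c(nrow(sp@positions), length(sp@orientations))))
      return("values must be |positions| x |orientations|")
    if (all(is.na(object@values))) return("all placements failed")
    v <- object@values[!is.na(object@values)]
    if (!all(is.finite(v))) return("values must be finite or NA")
    TRUE
  })

#' Subject bundle for NTA evaluation
#'
#' Ties together everything needed to score a coil placement for one
#' subject: scalp mesh, voxel grid, connectome, pathological-network map,
#' stimulation protocol, E-field parameters and threshold percent.
#'
#' @slot mesh \code{ScalpMesh}.
#' @slot grid \code{VoxelGrid} (shared by connectome and pathology).
#' @slot connectome \code{Connectome}.
#' @slot pathology \code{BrainMap} (the pathological network P).
#' @slot protocol \code{StimProtocol}.
#' @slot efield named list of stand-in E-field parameters
#'   (\code{peak}, \code{sigma}, \code{depthDecay}, \code{anisotropy}), or a
#'   function \code{(frame, grid) -> BrainMap} stored in \code{efieldFun}.
#' @slot efieldFun function or NULL.
#' @slot percent E-field threshold percent in [0, 100).
#' @export
setClass("NTASubject",
  representation(mesh = "ScalpMesh", grid = "VoxelGrid",
                 connectome = "Connectome", pathology = "BrainMap",
                 protocol = "StimProtocol", efield = "list",
                 efieldFun = "ANY", percent = "numeric"),
  validity = function(object) {
    if (!identical(object@grid@dims, object@connectome@grid@dims))
      return("connectome grid mismatch")
    if (!identical(object@grid@dims, object@pathology@grid@dims))
      return("pathology grid mismatch")
    if (object@percent < 0 || object@percent >= 100)
      return("percent must be in [0, 100)")
    TRUE
  })

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      "voxels,", nrow(object@coords), "in gray-matter mask\n")
  cat("  voxel size (mm):",
      paste(signif(sqrt(colSums(object@affine[1:3, 1:3]^2)), 4),
            collapse = " x "), "\n")
})

setMethod("show", "BrainMap", function(object) {
  v <- object@values
  cat("BrainMap over", length(v), "gray-matter voxels; range [",
      signif(min(v), 4), ",", signif(max(v), 4), "], mean",
      signif(mean(v), 4), "\n")
})

setMethod("show", "ScalpMesh", function(object) {
  cat("ScalpMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces; landmarks NZ/IZ/AL/AR\n")
})

setMethod("show", "Connectome", function(object) {
  cat("Connectome (", object@backend, " backend) over ",
      nrow(object@grid@coords), " voxels\n", sep = "")
})

setMethod("show", "NTAGrid", function(object) {
  am <- gridArgmax(object)
  cat("NTAGrid for subject", object@subject, ":",
      nrow(object@space@positions), "positions x",
      length(object@space@orientations), "orientations; max NTA",
      signif(max(object@values, na.rm = TRUE), 4), "at position",
      am[1L], ", orientation", am[2L], "\n")
})
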