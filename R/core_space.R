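#' Construct a reference voxel grid
#'
#' @param dims integer(3), voxels per axis.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm
#'   (MNI-style RAS). Defaults to isotropic \code{voxelSize} mm centered on
#'   the origin.
#' @param mask logical array of dimension \code{dims}; default all TRUE.
#' @param voxelSize isotropic voxel size in mm used when \code{affine} is
#'   missing.
#' @return A \code{\linkS4class{VoxelGrid}}.
#' @export
VoxelGrid <- function(dims, affine = NULL, mask = NULL, voxelSize = 2) {
  dims <- as.integer(dims)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelSize, 3L), 1))
    affine[1:3, 4L] <- -voxelSize * (dims - 1L) / 2
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dims)
  idx <- which(mask)
  if (length(idx) < 1L) stop("mask must contain at least one voxel")
  ijk <- arrayInd(idx, dims) - 1L
  coords <- cbind(ijk, 1) %*% t(affine)
  coords <- coords[, 1:3, drop = FALSE]
  dimnames(coords) <- NULL
  new("VoxelGrid", dims = dims, affine = affine, mask = mask,
      coords = coords, maskIdx = as.integer(idx))
}

#' Construct a brain map on a grid
#' @param grid a \code{VoxelGrid}.
#' @param values numeric vector, one finite value per masked voxel.
#' @return A \code{\linkS4class{BrainMap}}.
#' @export
BrainMap <- function(grid, values) {
  new("BrainMap", grid = grid, values = as.numeric(values))
}

#' @describeIn BrainMap number of gray-matter voxels of a grid.
#' @export
nVoxels <- function(grid) nrow(grid@coords)

#' Accessors for grids and maps
#'
#' \code{mapValues} returns the length-N value vector of a map;
#' \code{mapGrid} its grid; \code{voxelCoordinates} the N x 3 world-mm
#' centers of the masked voxels; \code{gridAffine} the index-to-world
#' affine; \code{gmMask} the logical mask array.
#'
#' @param x a \code{BrainMap} or \code{VoxelGrid}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
mapValues <- function(x) x@values

#' @rdname accessors
#' @export
mapGrid <- function(x) x@grid

#' @rdname accessors
#' @export
voxelCoordinates <- function(x) x@coords

#' @rdname accessors
#' @export
gridAffine <- function(x) x@affine

#' @rdname accessors
#' @export
gmMask <- function(x) x@mask

#' Read a 3D volume into a brain map
#'
#' Reads a NIfTI volume, optionally validating it against a reference grid,
#' and restricts it to the gray-matter mask. Values inside the mask must be
#' finite.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param grid optional reference \code{VoxelGrid}; when given, the volume's
#'   dimensions must match and its affine must agree within \code{tol} mm.
#' @param tol affine agreement tolerance in mm.
#' @return A \code{\linkS4class{BrainMap}}.
#' @export
readVolume <- function(path, grid = NULL, tol = 1e-3) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (is.null(grid)) {
    grid <- VoxelGrid(dim(arr), affine = aff)
  } else {
    if (!identical(as.integer(dim(arr)), grid@dims))
      stop("incompatible grid: volume dimensions ",
           paste(dim(arr), collapse = "x"), " vs grid ",
           paste(grid@dims, collapse = "x"))
    if (max(abs(aff - grid@affine)) > tol)
      stop("incompatible grid: affine mismatch beyond tolerance")
  }
  vals <- arr[grid@maskIdx]
  if (!all(is.finite(vals)))
    stop("volume contains non-finite values inside the gray-matter mask")
  BrainMap(grid, vals)
}

#' Write a brain map as a 3D volume
#'
#' Voxels outside the gray-matter mask are written as zero.
#'
#' @param map a \code{BrainMap}.
#' @param path output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(map, path) {
  grid <- map@grid
  arr <- array(0, grid@dims)
  arr[grid@maskIdx] <- map@values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(grid@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a gray-matter mask volume
#'
#' @param grid a \code{VoxelGrid}.
#' @param path NIfTI path.
#' @return \code{writeMask}: the path; \code{gridFromMask}: a
#'   \code{VoxelGrid} whose mask is the volume's nonzero set.
#' @export
writeMask <- function(grid, path) {
  arr <- array(0, grid@dims)
  arr[grid@maskIdx] <- 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(grid@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
gridFromMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  VoxelGrid(dim(arr), affine = aff, mask = arr != 0)
}

#' Pearson correlation between two brain maps
#'
#' Computed over the gray-matter voxels of the shared grid. Both maps must
#' be non-constant; degenerate (zero-variance) maps are an error rather
#' than silently dropped.
#'
#' @param a,b \code{BrainMap}s on the same grid.
#' @return Correlation in [-1, 1].
#' @export
mapCorrelation <- function(a, b) {
  if (!identical(a@grid@dims, b@grid@dims) ||
      max(abs(a@grid@affine - b@grid@affine)) > 1e-9 ||
      !identical(a@grid@maskIdx, b@grid@maskIdx))
    stop("maps are on different grids")
  if (sd(a@values) < 1e-300 || sd(b@values) < 1e-300)
    stop("degenerate map: zero variance over the gray-matter mask")
  cor(a@values, b@values)
}
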