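#' Build a voxel-wise connectome from a time-series table
#'
#' Columns are voxel time series. \code{mode = "dense"} materializes the
#' N x N Pearson correlation matrix; \code{mode = "lazy"} stores the
#' column-standardized table and computes connectome products on demand as
#' X'(X v)/(T-1). Both backends represent the same operator.
#'
#' @param x T x N numeric matrix, T >= 3, no constant columns.
#' @param grid the reference \code{VoxelGrid} (N masked voxels).
#' @param mode "dense" or "lazy".
#' @return A \code{\linkS4class{Connectome}}.
#' @export
connectomeFromTimeseries <- function(x, grid, mode = c("lazy", "dense")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least T = 3 timepoints")
  if (ncol(x) != nVoxels(grid))
    stop("time series has ", ncol(x), " columns but the grid has ",
         nVoxels(grid), " gray-matter voxels")
  sds <- apply(x, 2L, sd)
  if (any(sds < 1e-12)) stop("constant time-series column(s): ",
                             paste(utils::head(which(sds < 1e-12)), collapse = ", "))
  xs <- scale(x)
  attr(xs, "scaled:center") <- NULL
  attr(xs, "scaled:scale") <- NULL
  if (mode == "dense") {
    cc <- crossprod(xs) / (nrow(xs) - 1L)
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    new("Connectome", grid = grid, backend = "dense", data = cc)
  } else {
    new("Connectome", grid = grid, backend = "timeseries", data = xs)
  }
}

#' Construct a connectome from a dense matrix
#'
#' @param c N x N signed symmetric matrix with unit diagonal.
#' @param grid the reference \code{VoxelGrid}.
#' @return A \code{\linkS4class{Connectome}}.
#' @export
denseConnectome <- function(c, grid) {
  new("Connectome", grid = grid, backend = "dense", data = as.matrix(c))
}

# Connectome product with a sparse weight matrix W (N x K), columns already
# normalized by the caller. Returns N x K.
.connectomeProduct <- function(conn, w) {
  if (conn@backend == "dense") {
    as.matrix(conn@data %*% w)
  } else {
    xs <- conn@data
    crossprod(xs, as.matrix(xs %*% w)) / (nrow(xs) - 1L)
  }
}

#' Stimulation network of a local-effect vector
#'
#' The connectome-weighted whole-brain profile of the directly stimulated
#' region: \code{E_n = C E_l / ||E_l||_1}, the signed combination of the
#' seed columns of C with weights normalized by the sum of their absolute
#' values. Positive (excitatory) weights give a convex combination of seed
#' maps; flipping the protocol sign exactly negates the network.
#'
#' @param conn a \code{Connectome}.
#' @param el a \code{LocalEffect} on the same grid.
#' @return A \code{BrainMap}.
#' @export
stimulationNetwork <- function(conn, el) {
  if (!identical(conn@grid@dims, el@grid@dims))
    stop("connectome and local effect are on different grids")
  n <- nVoxels(conn@grid)
  l1 <- sum(abs(el@weights))
  w <- Matrix::sparseMatrix(i = el@support, j = rep(1L, length(el@support)),
                            x = el@weights / l1, dims = c(n, 1L))
  BrainMap(conn@grid, as.numeric(.connectomeProduct(conn, w)))
}

#' Seed connectivity map of a single voxel
#'
#' @param conn a \code{Connectome}.
#' @param voxel index into the masked-voxel vector.
#' @return A \code{BrainMap}; the self-connection value is 1.
#' @export
seedMap <- function(conn, voxel) {
  n <- nVoxels(conn@grid)
  if (voxel < 1L || voxel > n) stop("voxel outside the gray-matter mask")
  if (conn@backend == "dense") {
    BrainMap(conn@grid, conn@data[, voxel])
  } else {
    xs <- conn@data
    v <- as.numeric(crossprod(xs, xs[, voxel])) / (nrow(xs) - 1L)
    v[voxel] <- 1
    BrainMap(conn@grid, v)
  }
}
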