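# Analytic head surfaces, shell grids, modular connectomes and planted
# cohorts: every input the pipeline needs, generated deterministically.

# Row-normalized squared-exponential smoothing kernel over the grid's
# gray-matter voxels. Deterministic given the grid and scale, so every
# connectome realization shares one spatial-covariance structure; cached
# because grid-search studies rebuild connectomes per subject.
.kernelEnv <- new.env(parent = emptyenv())

.localKernel <- function(grid, localScale) {
  key <- paste(nVoxels(grid), localScale,
               format(sum(grid@coords) + sum(grid@dims), digits = 15))
  hit <- .kernelEnv[[key]]
  if (!is.null(hit)) return(hit)
  xyz <- grid@coords
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  kw <- exp(-pmax(d2, 0) / (2 * localScale^2))
  kw <- sweep(kw, 2L, sqrt(colSums(kw^2)), "/") # unit-variance smoothed noise
  .kernelEnv[[key]] <- kw
  kw
}

# unit icosphere: subdivided icosahedron, vertices normalized to radius 1
.icosphere <- function(subdiv = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lvl in seq_len(subdiv)) {
    env <- new.env(hash = TRUE, size = 4L * nrow(f))
    nv <- nrow(v)
    verts <- vector("list", 3L * nrow(f))
    vcount <- 0L
    mid <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      hit <- env[[key]]
      if (!is.null(hit)) return(hit)
      vcount <<- vcount + 1L
      verts[[vcount]] <<- .unit(v[i, ] + v[j, ])
      idx <- nv + vcount
      env[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      nf[4L * k - 3L, ] <- c(a, ab, ca)
      nf[4L * k - 2L, ] <- c(b, bc, ab)
      nf[4L * k - 1L, ] <- c(cc, ca, bc)
      nf[4L * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, verts[seq_len(vcount)]))
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Generate an analytic head surface with fiducial landmarks
#'
#' A subdivided icosphere scaled to an ellipsoid, with the four fiducials
#' at their analytic positions: nasion and inion on the anterior/posterior
#' midline, the preauricular points lateral, all on the z = 0 plane.
#' Deterministic given its arguments.
#'
#' @param radius nominal head radius in mm.
#' @param axes length-3 positive axis ratios (x right, y anterior,
#'   z superior); the ellipsoid semi-axes are \code{radius * axes}.
#' @param subdiv icosphere subdivision level (level k has
#'   \code{20 * 4^k} faces).
#' @return A \code{\linkS4class{ScalpMesh}}.
#' @export
makeHead <- function(radius = 90, axes = c(0.85, 1, 0.95), subdiv = 4L) {
  if (length(axes) != 3L || any(!is.finite(axes)) || any(axes <= 0))
    stop("invalid axis ratios")
  if (radius <= 0) stop("radius must be positive")
  ico <- .icosphere(subdiv)
  semi <- radius * axes
  v <- sweep(ico$vertices, 2L, semi, "*")
  lm <- rbind(NZ = c(0, semi[2L], 0), IZ = c(0, -semi[2L], 0),
              AL = c(-semi[1L], 0, 0), AR = c(semi[1L], 0, 0))
  ScalpMesh(v, ico$faces, lm)
}

#' Gray-matter shell grid under a head surface
#'
#' Builds a voxel grid covering the head and masks the voxels emulating a
#' cortical shell: centers whose ellipsoidal radius lies in
#' \code{[R - thickness, R - gap]}, where R is the mean semi-axis of the
#' head (scalp), \code{gap} the scalp-to-cortex clearance and
#' \code{thickness - gap} the shell depth.
#'
#' @param head a \code{ScalpMesh} from \code{\link{makeHead}} (semi-axes
#'   are recovered from its landmarks and vertex extent).
#' @param voxelSize isotropic voxel size in mm.
#' @param thickness inner offset from the scalp in mm (> gap).
#' @param gap outer offset from the scalp in mm.
#' @return A \code{\linkS4class{VoxelGrid}}.
#' @export
makeShellGrid <- function(head, voxelSize = 6, thickness = 24, gap = 12) {
  if (thickness <= 0 || gap < 0 || thickness <= gap)
    stop("need thickness > gap >= 0 and thickness > 0")
  a <- abs(landmark(head, "AR")[1L])
  b <- abs(landmark(head, "NZ")[2L])
  cc <- max(head@vertices[, 3L])
  semi <- c(a, b, cc)
  r <- mean(semi)
  if (thickness >= r) stop("shell thicker than the head radius")
  dims <- as.integer(ceiling((2 * semi + 2 * voxelSize) / voxelSize))
  affine <- diag(c(rep(voxelSize, 3L), 1))
  affine[1:3, 4L] <- -voxelSize * (dims - 1L) / 2
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  xyz <- cbind(idx, 1) %*% t(affine)
  rho <- r * sqrt((xyz[, 1L] / semi[1L])^2 + (xyz[, 2L] / semi[2L])^2 +
                  (xyz[, 3L] / semi[3L])^2)
  mask <- array(rho >= r - thickness & rho <= r - gap, dims)
  if (!any(mask)) stop("empty shell: no voxel center falls in the band")
  VoxelGrid(dims, affine = affine, mask = mask)
}

#' Modular voxel-wise connectome with anti-correlated networks
#'
#' Partitions the gray-matter voxels into K spatially contiguous networks
#' (angular sectors around the vertical axis) and simulates T timepoints
#' from a block-correlated factor model: voxel i in network k follows
#' \code{sqrt(rhoWithin) f_k + sqrt(1 - rhoWithin) e_i (+ noiseSd eta_i)}
#' with network factors f correlated as \code{between / rhoWithin}. The
#' empirical within/between-block correlations converge to
#' \code{rhoWithin} / \code{between} as T grows (for noiseSd = 0).
#'
#' @param grid a \code{VoxelGrid}.
#' @param k number of networks.
#' @param rhoWithin within-network correlation in (0, 1).
#' @param between between-network correlation, scalar or K x K matrix
#'   (negative entries give anti-correlated networks); the implied K x K
#'   factor correlation matrix must be positive semi-definite.
#' @param timepoints number of timepoints T.
#' @param noiseSd additional measurement-noise standard deviation.
#' @param localCorr variance share in [0, 1 - rhoWithin) of a spatially
#'   local signal component (squared-exponential kernel, scale
#'   \code{localScale} mm). Real rsFC has
#'   local spatial autocorrelation on top of its network structure; with
#'   \code{localCorr > 0} seed maps peak near their seed, which makes coil
#'   position identifiable within a network. The default 0 gives the pure
#'   block model.
#' @param localScale smoothing-kernel scale in mm of the local component;
#'   the kernel structure is deterministic given the grid, so all
#'   realizations share one spatial covariance.
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return list with \code{connectome} (time-series backend) and
#'   \code{labels} (integer network label per voxel).
#' @export
makeConnectome <- function(grid, k = 2L, rhoWithin = 0.8, between = -0.4,
                           timepoints = 200L, noiseSd = 0, localCorr = 0,
                           localScale = 20, seed = 1L) {
  if (rhoWithin <= 0 || rhoWithin >= 1) stop("rhoWithin must be in (0, 1)")
  if (localCorr < 0 || rhoWithin + localCorr >= 1)
    stop("need rhoWithin + localCorr < 1")
  if (timepoints < 3L) stop("need at least 3 timepoints")
  if (is.matrix(between)) {
    if (!all(dim(between) == c(k, k))) stop("between must be K x K")
    sig <- between / rhoWithin
    diag(sig) <- 1
  } else {
    sig <- matrix(between / rhoWithin, k, k)
    diag(sig) <- 1
  }
  ch <- tryCatch(chol(sig), error = function(e)
    stop("the implied factor correlation matrix is not positive definite"))
  xyz <- grid@coords
  ang <- atan2(xyz[, 1L], xyz[, 2L]) # 0 = anterior, +/-pi = posterior
  shifted <- (ang + pi / k) %% (2 * pi) # sector 1 centered on anterior
  labels <- as.integer(.clamp(floor(shifted / (2 * pi / k)) + 1L, 1L, k))
  n <- nVoxels(grid)
  x <- .withSeed(seed, {
    f <- matrix(rnorm(timepoints * k), timepoints, k) %*% ch
    e <- matrix(rnorm(timepoints * n), timepoints, n)
    out <- sqrt(rhoWithin) * f[, labels, drop = FALSE] +
      sqrt(1 - rhoWithin - localCorr) * e
    if (localCorr > 0) {
      kw <- .localKernel(grid, localScale)
      eps2 <- matrix(rnorm(timepoints * n), timepoints, n)
      out <- out + sqrt(localCorr) * eps2 %*% kw
    }
    if (noiseSd > 0)
      out <- out + noiseSd * matrix(rnorm(timepoints * n), timepoints, n)
    out
  })
  list(connectome = connectomeFromTimeseries(x, grid, mode = "lazy"),
       labels = labels)
}

#' Plant a pathological network and simulate a treatment cohort
#'
#' Emulates a retrospective validation study end to end. The pathology is
#' planted on one network: hypoactive (-1) foci inside the target network
#' and hyperactive (+1) foci inside its most anti-correlated partner, so
#' that excitatory stimulation of the target network is the beneficial
#' placement under the NTA sign convention. Each subject gets their own
#' connectome realization, a coil placement jittered around (and away
#' from) the scalp projection of the target, and an outcome
#' \code{beta * NTA + noise}.
#'
#' @param head a \code{ScalpMesh}.
#' @param grid a \code{VoxelGrid}.
#' @param labels network labels from \code{\link{makeConnectome}}.
#' @param nSubjects cohort size.
#' @param targetNetwork index of the planted network.
#' @param nFoci foci per network.
#' @param radius foci sphere radius in mm.
#' @param beta coupling of outcome to true NTA.
#' @param sigmaE outcome noise sd; if NULL it is set from \code{targetR}.
#' @param targetR population NTA-outcome correlation used to derive
#'   \code{sigmaE} when it is NULL (set \code{beta = 0} for null cohorts,
#'   in which case outcomes are pure noise with sd 1).
#' @param jitter half-width of the uniform CPC jitter around the projected
#'   target position.
#' @param rhoWithin,between,timepoints,noiseSd,localCorr,localScale
#'   connectome parameters, see \code{\link{makeConnectome}}. The cohort
#'   defaults make the local spatial-autocorrelation component the dominant
#'   spatially varying term (as it is in real rsFC), so that coil position
#'   within a network is identifiable from the stimulation network.
#' @param k number of networks.
#' @param anisotropy E-field across/along-handle ratio (< 1 makes NTA
#'   orientation sensitive).
#' @param percent E-field threshold percent.
#' @param protocol a \code{StimProtocol}.
#' @param seed master seed; per-subject connectomes, placements and
#'   outcomes are derived from it deterministically.
#' @return list: \code{subjects} (list of \code{NTASubject}),
#'   \code{placements}, \code{cohort} (data.frame subject, p_nz, p_al,
#'   theta, nta, outcome, sex, age), \code{foci}, \code{pathology},
#'   \code{truth} (target network, its scalp projection and CPC).
#' @export
makePlantedCohort <- function(head, grid, labels, nSubjects = 15L,
                              targetNetwork = 1L, nFoci = 4L, radius = 10,
                              beta = 1, sigmaE = NULL, targetR = 0.9,
                              jitter = 0.18, rhoWithin = 0.35, between = -0.15,
                              timepoints = 200L, noiseSd = 0, localCorr = 0.45,
                              localScale = 14, k = 2L,
                              anisotropy = 0.6, percent = 75,
                              protocol = stimProtocol(10), seed = 1L) {
  tv <- which(labels == targetNetwork)
  if (length(tv) == 0L) stop("target network has no voxels")
  other <- which(labels != targetNetwork)
  coords <- grid@coords
  # Plant a compact cluster of hypoactive foci on the coil-reachable upper
  # part of the target network (meta-analysis foci of a disorder cluster
  # regionally), and a hyperactive cluster on the anti-correlated network.
  # The pool is the superior cap (polar angle < 50 deg), where the scalp
  # projection is well inside the CPC domain away from the preauricular
  # poles, restricted to the angular core of each sector: foci of a
  # disorder sit within a network, and a planted target hugging a network
  # boundary makes the recovery question ill-posed.
  polar <- acos(coords[, 3L] / pmax(sqrt(rowSums(coords^2)), 1e-300))
  sectorW <- 2 * pi / k
  inSector <- ((atan2(coords[, 1L], coords[, 2L]) + pi / k) %% (2 * pi)) %%
    sectorW / sectorW
  upper <- function(idx) {
    u <- idx[polar[idx] < 50 * pi / 180 &
             inSector[idx] > 0.25 & inSector[idx] < 0.75]
    if (length(u)) u else idx[coords[idx, 3L] > 0]
  }
  pickCluster <- function(cands, m, clusterRadius = 15) {
    c0 <- cands[sample.int(length(cands), 1L)]
    d2 <- rowSums(sweep(coords[cands, , drop = FALSE], 2L, coords[c0, ])^2)
    pool <- cands[d2 <= clusterRadius^2]
    pool[sample.int(length(pool), min(m, length(pool)))]
  }
  clusters <- .withSeed(.subSeed(seed, 1L), {
    list(neg = pickCluster(upper(tv), nFoci),
         pos = if (length(other)) pickCluster(upper(other), nFoci)
               else integer(0))
  })
  fociIdx <- c(clusters$neg, clusters$pos)
  dirs <- rep(c(-1, 1), c(length(clusters$neg), length(clusters$pos)))
  foci <- data.frame(x = coords[fociIdx, 1L], y = coords[fociIdx, 2L],
                     z = coords[fociIdx, 3L], direction = dirs, weight = 1)
  pathology <- fociToMap(foci, grid, radius)
  # scalp projection of the planted (hypoactive) focus cluster
  targetCentroid <- colMeans(coords[fociIdx[dirs == -1], , drop = FALSE])
  projCpc <- restorePlacement(head, targetCentroid, maxAngle = 89)
  efield <- list(peak = 100, sigma = 12, depthDecay = 18,
                 anisotropy = anisotropy)
  orientations <- seq(0, -165, by = -15)
  subjects <- vector("list", nSubjects)
  placements <- data.frame(p_nz = numeric(nSubjects),
                           p_al = numeric(nSubjects),
                           theta = numeric(nSubjects))
  ntaTrue <- numeric(nSubjects)
  for (s in seq_len(nSubjects)) {
    conn <- makeConnectome(grid, k = k, rhoWithin = rhoWithin,
                           between = between, timepoints = timepoints,
                           noiseSd = noiseSd, localCorr = localCorr,
                           localScale = localScale,
                           seed = .subSeed(seed, 100L + s))$connectome
    subjects[[s]] <- ntaSubject(head, grid, conn, pathology,
                                protocol = protocol, efield = efield,
                                percent = percent)
    pl <- .withSeed(.subSeed(seed, 200L + s), {
      c(.clamp(projCpc[1L] + runif(1L, -jitter, jitter), 0.05, 0.95),
        .clamp(projCpc[2L] + runif(1L, -jitter, jitter), 0.05, 0.95),
        sample(orientations, 1L))
    })
    placements[s, ] <- pl
    ntaTrue[s] <- ntaForPlacement(subjects[[s]], pl)
  }
  if (is.null(sigmaE)) {
    sigmaE <- if (beta == 0 || nSubjects < 2L) 1
    else abs(beta) * sd(ntaTrue) * sqrt(1 / targetR^2 - 1)
  }
  demo <- .withSeed(.subSeed(seed, 300L), {
    list(eps = rnorm(nSubjects, 0, sigmaE),
         sex = sample(0:1, nSubjects, replace = TRUE),
         age = round(rnorm(nSubjects, 42, 11)))
  })
  outcome <- beta * ntaTrue + demo$eps
  cohort <- data.frame(subject = sprintf("S%02d", seq_len(nSubjects)),
                       p_nz = placements$p_nz, p_al = placements$p_al,
                       theta = placements$theta, nta = ntaTrue,
                       outcome = outcome, sex = demo$sex, age = demo$age)
  list(subjects = subjects, placements = placements, cohort = cohort,
       foci = foci, pathology = pathology,
       truth = list(targetNetwork = targetNetwork,
                    targetCentroid = targetCentroid,
                    projectionCpc = projCpc, sigmaE = sigmaE, beta = beta))
}
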