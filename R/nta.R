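#' Bundle a subject for NTA evaluation
#'
#' @param mesh \code{ScalpMesh}.
#' @param grid \code{VoxelGrid}.
#' @param connectome \code{Connectome} on \code{grid}.
#' @param pathology \code{BrainMap} P on \code{grid}.
#' @param protocol \code{StimProtocol}.
#' @param efield named list of stand-in parameters passed to
#'   \code{\link{syntheticEField}} (\code{peak}, \code{sigma},
#'   \code{depthDecay}, \code{anisotropy}).
#' @param efieldFun optional function \code{(frame, grid) -> BrainMap}
#'   supplying a precomputed/loaded E-field instead of the stand-in.
#' @param percent E-field threshold percent.
#' @return An \code{\linkS4class{NTASubject}}.
#' @export
ntaSubject <- function(mesh, grid, connectome, pathology,
                       protocol = stimProtocol(10), efield = list(),
                       efieldFun = NULL, percent = 90) {
  defaults <- list(peak = 100, sigma = 12, depthDecay = 18, anisotropy = 1)
  efield <- utils::modifyList(defaults, efield)
  new("NTASubject", mesh = mesh, grid = grid, connectome = connectome,
      pathology = pathology, protocol = protocol, efield = efield,
      efieldFun = efieldFun, percent = percent)
}

#' Network targeting accuracy
#'
#' The spatial anti-correlation between a stimulation network and the
#' pathological network: \code{NTA = -corr(E_n, P)} over gray matter.
#' Ranges over [-1, 1]; +1 means the stimulation network is a perfect
#' mirror of the pathology.
#'
#' @param en stimulation network \code{BrainMap}.
#' @param p pathological network \code{BrainMap} on the same grid.
#' @return numeric(1) in [-1, 1].
#' @export
nta <- function(en, p) -mapCorrelation(en, p)

.subjectEField <- function(subject, frame) {
  if (is.function(subject@efieldFun)) {
    subject@efieldFun(frame, subject@grid)
  } else {
    ef <- subject@efield
    syntheticEField(frame, subject@grid, peak = ef$peak, sigma = ef$sigma,
                    depthDecay = ef$depthDecay, anisotropy = ef$anisotropy)
  }
}

#' NTA of one coil placement for one subject
#'
#' Runs the full model chain: coil frame at the CPC position, induced
#' E-field, thresholded signed local-effect vector, connectome-derived
#' stimulation network, and the anti-correlation with the pathological
#' network. Deterministic for fixed inputs.
#'
#' @param subject an \code{NTASubject}.
#' @param placement list or numeric: \code{p_nz}, \code{p_al},
#'   \code{theta} (degrees).
#' @return numeric(1) NTA value.
#' @export
ntaForPlacement <- function(subject, placement) {
  pl <- as.numeric(unlist(placement))[1:3]
  frame <- coilFrame(subject@mesh, pl[1:2], pl[3L])
  ef <- .subjectEField(subject, frame)
  el <- localEffectVector(ef, subject@percent, subject@protocol)
  en <- stimulationNetwork(subject@connectome, el)
  nta(en, subject@pathology)
}

#' Construct a coil-placement search space
#'
#' @param positions P x 2 matrix or data.frame of CPC pairs (p_nz, p_al).
#' @param orientations numeric vector of handle angles in degrees; the
#'   default is the 12-orientation set 0, -15, ..., -165.
#' @return A \code{\linkS4class{SearchSpace}}.
#' @export
searchSpace <- function(positions, orientations = seq(0, -165, by = -15)) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  new("SearchSpace", positions = positions,
      orientations = as.numeric(orientations))
}

#' Regular CPC lattice search space
#'
#' @param pnz,pal numeric vectors of p_nz / p_al lattice values.
#' @param orientations handle angles in degrees.
#' @return A \code{SearchSpace}; positions are in position-major order,
#'   p_al varying fastest.
#' @export
latticeSpace <- function(pnz, pal, orientations = seq(0, -165, by = -15)) {
  grid <- expand.grid(p_al = pal, p_nz = pnz)
  searchSpace(cbind(grid$p_nz, grid$p_al), orientations)
}

#' Exhaustive NTA grid search over a search space
#'
#' Evaluates every (position, orientation) combination with no early
#' stopping. Placements that fail (e.g. empty E-field support) are
#' recorded as NA and excluded from the argmax; an all-failed grid is an
#' error. The argmax tie-break is lexicographic: lowest position index,
#' then lowest orientation index.
#'
#' @param subject an \code{NTASubject}.
#' @param space a \code{SearchSpace}.
#' @param subjectId id stored in the result.
#' @return An \code{\linkS4class{NTAGrid}}.
#' @export
gridSearch <- function(subject, space, subjectId = "subject") {
  pos <- space@positions
  ors <- space@orientations
  np <- nrow(pos); no <- length(ors)
  n <- nVoxels(subject@grid)
  axisymmetric <- !is.function(subject@efieldFun) &&
    subject@efield$anisotropy == 1
  supports <- vector("list", np * no)
  weights <- vector("list", np * no)
  for (ip in seq_len(np)) {
    frame0 <- tryCatch(.frameAt(subject@mesh, pos[ip, ]),
                       error = function(e) NULL)
    elCache <- NULL
    for (io in seq_len(no)) {
      cell <- (ip - 1L) * no + io
      if (axisymmetric && !is.null(elCache)) {
        supports[[cell]] <- elCache$support
        weights[[cell]] <- elCache$weights
        next
      }
      el <- if (is.null(frame0)) NULL else tryCatch({
        frame <- .rotateFrame(frame0, ors[io])
        ef <- .subjectEField(subject, frame)
        localEffectVector(ef, subject@percent, subject@protocol)
      }, error = function(e) NULL)
      if (is.null(el)) {
        supports[[cell]] <- integer(0)
        weights[[cell]] <- numeric(0)
      } else {
        supports[[cell]] <- el@support
        weights[[cell]] <- el@weights
        if (axisymmetric) elCache <- list(support = el@support,
                                          weights = el@weights)
      }
    }
  }
  lens <- lengths(supports)
  ok <- lens > 0L
  if (!any(ok)) stop("all placements failed")
  l1 <- vapply(weights[ok], function(w) sum(abs(w)), numeric(1L))
  w <- Matrix::sparseMatrix(
    i = unlist(supports[ok]),
    j = rep(seq_len(sum(ok)), lens[ok]),
    x = unlist(weights[ok]) / rep(l1, lens[ok]),
    dims = c(n, sum(ok)))
  en <- .connectomeProduct(subject@connectome, w)
  ntas <- rep(NA_real_, np * no)
  ntas[ok] <- -.colCors(en, subject@pathology@values)
  vals <- matrix(ntas, nrow = np, ncol = no, byrow = TRUE)
  new("NTAGrid", subject = subjectId, space = space, values = vals)
}

#' Argmax placement of an NTA grid
#'
#' @param grid an \code{NTAGrid}.
#' @return integer(2): (position index, orientation index) of the maximum,
#'   ties broken lexicographically.
#' @export
gridArgmax <- function(grid) {
  v <- grid@values
  mx <- max(v, na.rm = TRUE)
  hits <- which(!is.na(v) & v >= mx - 0, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(position = unname(hits[1L, 1L]), orientation = unname(hits[1L, 2L]))
}

#' Optimal placement of an NTA grid as CPC + orientation
#' @param grid an \code{NTAGrid}.
#' @return data.frame(subject, p_nz, p_al, theta, nta).
#' @export
optimalPlacement <- function(grid) {
  am <- gridArgmax(grid)
  data.frame(subject = grid@subject,
             p_nz = grid@space@positions[am[1L], 1L],
             p_al = grid@space@positions[am[1L], 2L],
             theta = grid@space@orientations[am[2L]],
             nta = grid@values[am[1L], am[2L]])
}

#' Two-way position x orientation ANOVA across subjects
#'
#' Fixed-effects two-way ANOVA of NTA on the crossed position and
#' orientation factors, with subjects as replicates, using the standard
#' balanced sums-of-squares decomposition. Grids with failed (NA) cells
#' are rejected rather than imputed.
#'
#' @param grids list of \code{NTAGrid}s on one shared \code{SearchSpace},
#'   at least two subjects.
#' @return data.frame with rows position, orientation, interaction:
#'   sum of squares, df, F and p (F-distribution, balanced dfs), plus the
#'   residual row.
#' @export
gridAnova <- function(grids) {
  if (length(grids) < 2L) stop("need at least two subjects")
  sp <- grids[[1L]]@space
  for (g in grids) {
    if (!isTRUE(all.equal(g@space@positions, sp@positions)) ||
        !isTRUE(all.equal(g@space@orientations, sp@orientations)))
      stop("all grids must share one search space")
    if (anyNA(g@values)) stop("incomplete grid (missing cells): subject ",
                              g@subject)
  }
  np <- nrow(sp@positions); no <- length(sp@orientations)
  ns <- length(grids)
  y <- array(0, c(np, no, ns))
  for (s in seq_len(ns)) y[, , s] <- grids[[s]]@values
  gm <- mean(y)
  mP <- apply(y, 1L, mean)
  mO <- apply(y, 2L, mean)
  mPO <- apply(y, c(1L, 2L), mean)
  ssP <- ns * no * sum((mP - gm)^2)
  ssO <- ns * np * sum((mO - gm)^2)
  ssI <- ns * sum((sweep(sweep(mPO, 1L, mP), 2L, mO) + gm)^2)
  ssE <- sum((y - array(mPO, c(np, no, ns)))^2)
  dfP <- np - 1L; dfO <- no - 1L; dfI <- dfP * dfO
  dfE <- np * no * (ns - 1L)
  if (ssE / dfE < 1e-24)
    stop("degenerate ANOVA: zero error variance across subjects")
  msE <- ssE / dfE
  f <- c(ssP / dfP, ssO / dfO, ssI / dfI) / msE
  p <- pf(f, c(dfP, dfO, dfI), dfE, lower.tail = FALSE)
  data.frame(term = c("position", "orientation", "interaction", "residual"),
             ss = c(ssP, ssO, ssI, ssE),
             df = c(dfP, dfO, dfI, dfE),
             F = c(f, NA), p = c(p, NA))
}

#' Sensitivity of NTA to the E-field threshold
#'
#' Recomputes NTA at each threshold percent for a fixed set of placements
#' and reports the pairwise correlations of the per-placement NTA vectors
#' between thresholds.
#'
#' @param subject an \code{NTASubject}.
#' @param placements data.frame with columns p_nz, p_al, theta.
#' @param percents numeric vector of at least two threshold percents.
#' @param method correlation method for the pairwise comparison
#'   ("pearson" or "spearman").
#' @return list: \code{nta} (|placements| x |percents| matrix),
#'   \code{table} (long data.frame), \code{correlations}.
#' @export
thresholdSensitivity <- function(subject, placements, percents,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(percents) < 2L) stop("need at least two threshold percents")
  npl <- nrow(placements)
  efields <- vector("list", npl)
  for (i in seq_len(npl)) {
    frame <- coilFrame(subject@mesh,
                       c(placements$p_nz[i], placements$p_al[i]),
                       placements$theta[i])
    efields[[i]] <- .subjectEField(subject, frame)
  }
  vals <- matrix(NA_real_, npl, length(percents))
  for (j in seq_along(percents)) {
    for (i in seq_len(npl)) {
      el <- localEffectVector(efields[[i]], percents[j], subject@protocol)
      en <- stimulationNetwork(subject@connectome, el)
      vals[i, j] <- nta(en, subject@pathology)
    }
  }
  colnames(vals) <- percents
  cc <- cor(vals, method = method)
  tab <- data.frame(placement = rep(seq_len(npl), length(percents)),
                    percent = rep(percents, each = npl),
                    nta = as.numeric(vals))
  list(nta = vals, table = tab, correlations = cc)
}
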