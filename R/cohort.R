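#' Validate a cohort table
#'
#' @param cohort data.frame with at least \code{nta} and \code{outcome}
#'   columns; optional \code{sex} (binary) and \code{age}.
#' @param n minimum number of rows.
#' @return The cohort, invisibly checked.
#' @export
validateCohort <- function(cohort, n = 3L) {
  if (!all(c("nta", "outcome") %in% names(cohort)))
    stop("cohort table needs columns nta and outcome")
  if (anyNA(cohort$nta) || anyNA(cohort$outcome))
    stop("missing nta/outcome values in analyzed rows")
  if (nrow(cohort) < n) stop("need at least ", n, " subjects")
  cohort
}

.oneTailedP <- function(r, df) {
  # one-tailed p for the alternative r > 0 via the t transform
  if (r >= 1) return(0)
  if (r <= -1) return(1)
  t <- r * sqrt(df / (1 - r^2))
  pt(t, df, lower.tail = FALSE)
}

#' Correlation between NTA and clinical improvement
#'
#' Pearson correlation with a one-tailed p-value for the model's
#' directional hypothesis that higher NTA predicts larger improvement
#' (t transform, n - 2 df).
#'
#' @param cohort cohort data.frame (columns nta, outcome).
#' @return list(r, p_one_tailed, n).
#' @export
efficacyCorrelation <- function(cohort) {
  cohort <- validateCohort(cohort)
  n <- nrow(cohort)
  if (sd(cohort$nta) < 1e-300 || sd(cohort$outcome) < 1e-300)
    stop("zero variance in nta or outcome")
  r <- cor(cohort$nta, cohort$outcome)
  list(r = r, p_one_tailed = .oneTailedP(r, n - 2L), n = n)
}

#' Permutation test with randomly reassigned outcomes
#'
#' Builds the null by permuting the outcome column, recomputing the
#' NTA-outcome correlation each time;
#' \code{p = (1 + #(r* >= r_obs)) / (1 + n_perm)}.
#'
#' @param cohort cohort data.frame.
#' @param nPerm number of permutations (default 1e5).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return list(p, r_obs, n_perm, seed, r_null).
#' @export
permuteOutcomes <- function(cohort, nPerm = 1e5, seed = 1L) {
  cohort <- validateCohort(cohort)
  if (nPerm < 1) stop("nPerm must be >= 1")
  x <- cohort$nta; y <- cohort$outcome
  rObs <- cor(x, y)
  rNull <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) cor(x, sample(y)), numeric(1L))
  })
  list(p = (1 + sum(rNull >= rObs)) / (1 + nPerm), r_obs = rObs,
       n_perm = nPerm, seed = seed, r_null = rNull)
}

#' Permutation test with randomly relocated pathological networks
#'
#' Builds the null by relocating every pathological focus to a uniformly
#' sampled gray-matter voxel (preserving focus count, directions and
#' weights), rebuilding the pathological map, recomputing each subject's
#' NTA at their fixed placement, and recomputing the cohort correlation;
#' \code{p = (1 + #(r* >= r_obs)) / (1 + n_perm)}. Only the pathological
#' map is randomized; the connectome is left intact.
#'
#' @param subjects list of \code{NTASubject}s (their \code{pathology} slot
#'   is ignored; the map is rebuilt from \code{foci}).
#' @param placements data.frame with columns p_nz, p_al, theta, one row
#'   per subject.
#' @param outcomes numeric vector of clinical improvements.
#' @param foci foci data.frame (see \code{\link{readFoci}}).
#' @param radius foci sphere radius in mm.
#' @param nPerm number of null networks (default 1e5).
#' @param seed RNG seed.
#' @param relocateFun relocation hook \code{function(foci, coords)} used to
#'   draw one null foci table; the default samples gray-matter voxel
#'   centers uniformly. Supplying \code{identity}-like hooks is intended
#'   for testing.
#' @param enMat optional precomputed N x n_subjects matrix of stimulation
#'   networks (columns in subject order); avoids re-running the model
#'   chain when the test is repeated over many outcome draws.
#' @return list(p, r_obs, n_perm, seed, r_null, nta_obs, en_mat).
#' @export
permuteNetworks <- function(subjects, placements, outcomes, foci,
                            radius = 10, nPerm = 1e5, seed = 1L,
                            relocateFun = NULL, enMat = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  ns <- length(subjects)
  stopifnot(nrow(placements) == ns, length(outcomes) == ns)
  grid <- subjects[[1L]]@grid
  n <- nVoxels(grid)
  if (n < nrow(foci)) stop("degenerate null: mask smaller than foci count")
  # fixed per-subject stimulation networks
  if (is.null(enMat)) {
    enMat <- matrix(0, n, ns)
    for (s in seq_len(ns)) {
      subj <- subjects[[s]]
      frame <- coilFrame(subj@mesh,
                         c(placements$p_nz[s], placements$p_al[s]),
                         placements$theta[s])
      ef <- .subjectEField(subj, frame)
      el <- localEffectVector(ef, subj@percent, subj@protocol)
      enMat[, s] <- stimulationNetwork(subj@connectome, el)@values
    }
  }
  pObs <- fociToMap(foci, grid, radius)
  ntaObs <- -.colCors(enMat, pObs@values)
  rObs <- cor(ntaObs, outcomes)
  coords <- grid@coords
  if (is.null(relocateFun)) {
    relocateFun <- function(foci, coords) {
      idx <- sample.int(nrow(coords), nrow(foci), replace = TRUE)
      foci$x <- coords[idx, 1L]
      foci$y <- coords[idx, 2L]
      foci$z <- coords[idx, 3L]
      foci
    }
  }
  rNull <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      fstar <- relocateFun(foci, coords)
      pstar <- tryCatch(fociToMap(fstar, grid, radius), error = function(e) NULL)
      if (is.null(pstar)) return(NA_real_)
      ntaStar <- -.colCors(enMat, pstar@values)
      cor(ntaStar, outcomes)
    }, numeric(1L))
  })
  if (all(is.na(rNull)))
    stop("degenerate null: no relocation produced a nonempty pathology")
  rNull <- rNull[!is.na(rNull)]
  list(p = (1 + sum(rNull >= rObs)) / (1 + length(rNull)), r_obs = rObs,
       n_perm = length(rNull), seed = seed, r_null = rNull,
       nta_obs = ntaObs, en_mat = enMat)
}

#' Partial correlation controlling for a demographic covariate
#'
#' Pearson correlation of the residuals of nta and outcome after each is
#' regressed (with intercept) on the covariate; one-tailed p with n - 3
#' df.
#'
#' @param cohort cohort data.frame including the covariate column.
#' @param covariate "sex" or "age" (any numeric column name is accepted;
#'   sex is expected to be coded as a binary indicator).
#' @return list(r_partial, p_one_tailed, n).
#' @export
partialCorrelation <- function(cohort, covariate = c("sex", "age")) {
  covariate <- if (is.character(covariate)) covariate[1L] else covariate
  cohort <- validateCohort(cohort, n = 4L)
  if (!covariate %in% names(cohort)) stop("covariate column not found")
  z <- as.numeric(cohort[[covariate]])
  if (anyNA(z)) stop("missing covariate values")
  if (sd(z) < 1e-300) stop("constant covariate")
  rx <- stats::residuals(stats::lm(cohort$nta ~ z))
  ry <- stats::residuals(stats::lm(cohort$outcome ~ z))
  scale0 <- sd(cohort$outcome) + sd(cohort$nta)
  if (sd(rx) < 1e-10 * scale0 || sd(ry) < 1e-10 * scale0)
    stop("degenerate partial correlation: a residual is constant")
  r <- cor(rx, ry)
  list(r_partial = r, p_one_tailed = .oneTailedP(r, nrow(cohort) - 3L),
       n = nrow(cohort))
}
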