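test_that("NTA is the negated spatial correlation", {
  g <- VoxelGrid(c(6, 1, 1), voxelSize = 1)
  v <- withr::with_seed(9, list(en = rnorm(6), p = rnorm(6)))
  en <- BrainMap(g, v$en); p <- BrainMap(g, v$p)
  # hand Pearson oracle
  ex <- v$en - mean(v$en); px <- v$p - mean(v$p)
  oracle <- -sum(ex * px) / sqrt(sum(ex^2) * sum(px^2))
  expect_equal(nta(en, p), oracle, tolerance = 1e-12)
  expect_equal(nta(BrainMap(g, -v$p), p), 1.0)
  expect_equal(nta(p, p), -1.0)
  expect_true(abs(nta(en, p)) <= 1)
})

test_that("the placement chain matches the manual seed-map composition", {
  st <- testStudy()
  subj <- st$subjects[[1]]
  pl <- c(0.35, 0.55, -45)
  # manual chain: frame -> E-field -> local effect -> network -> NTA
  frame <- coilFrame(subj@mesh, pl[1:2], pl[3])
  ef <- syntheticEField(frame, subj@grid, peak = subj@efield$peak,
                        sigma = subj@efield$sigma,
                        depthDecay = subj@efield$depthDecay,
                        anisotropy = subj@efield$anisotropy)
  el <- localEffectVector(ef, subj@percent, subj@protocol)
  en <- stimulationNetwork(subj@connectome, el)
  expect_equal(ntaForPlacement(subj, pl), nta(en, subj@pathology),
               tolerance = 1e-12)
})

test_that("a singleton-support E-field reduces NTA to the seed column", {
  st <- testStudy()
  subj <- st$subjects[[1]]
  voxel <- 25L
  # E-field hook that stimulates exactly one voxel
  single <- function(frame, grid) {
    v <- numeric(nVoxels(grid)); v[voxel] <- 1
    BrainMap(grid, v)
  }
  s2 <- ntaSubject(subj@mesh, subj@grid, subj@connectome, subj@pathology,
                   protocol = subj@protocol, efieldFun = single,
                   percent = 90)
  expect_equal(ntaForPlacement(s2, c(0.4, 0.5, 0)),
               nta(seedMap(subj@connectome, voxel), subj@pathology),
               tolerance = 1e-12)
})

test_that("excitatory and inhibitory protocols give exactly negated NTA", {
  st <- testStudy()
  hf <- st$subjects[[1]]
  lf <- ntaSubject(hf@mesh, hf@grid, hf@connectome, hf@pathology,
                   protocol = stimProtocol(1), efield = hf@efield,
                   percent = hf@percent)
  for (pl in list(c(0.3, 0.4, 0), c(0.5, 0.6, -90))) {
    expect_equal(ntaForPlacement(lf, pl), -ntaForPlacement(hf, pl),
                 tolerance = 1e-12)
  }
})

test_that("grid search evaluates the full space and finds the argmax", {
  st <- testStudy()
  subj <- st$subjects[[1]]
  one <- searchSpace(matrix(c(0.4, 0.5), 1), orientations = -30)
  g1 <- gridSearch(subj, one)
  expect_equal(dim(g1@values), c(1L, 1L))
  expect_equal(gridArgmax(g1), c(position = 1L, orientation = 1L))
  expect_equal(g1@values[1, 1], ntaForPlacement(subj, c(0.4, 0.5, -30)),
               tolerance = 1e-12)
  sp <- latticeSpace(seq(0.2, 0.5, length.out = 4),
                     seq(0.4, 0.7, length.out = 3),
                     orientations = c(0, -90))
  gr <- gridSearch(subj, sp)
  expect_equal(dim(gr@values), c(12L, 2L))
  expect_true(all(is.finite(gr@values)))
  am <- gridArgmax(gr)
  expect_equal(gr@values[am[1], am[2]], max(gr@values))
  # argmax invariant to positive affine rescaling of the pathology
  p2 <- BrainMap(subj@grid, 3.2 * mapValues(subj@pathology) + 0.7)
  s2 <- ntaSubject(subj@mesh, subj@grid, subj@connectome, p2,
                   protocol = subj@protocol, efield = subj@efield,
                   percent = subj@percent)
  expect_equal(gridArgmax(gridSearch(s2, sp)), am)
})

test_that("the default orientation set spans 0 to -165 in 15-degree steps", {
  sp <- latticeSpace(c(0.3, 0.4), c(0.5))
  expect_equal(sp@orientations, seq(0, -165, by = -15))
  expect_length(sp@orientations, 12L)
  expect_equal(parseOrientations("0:-165:15"), seq(0, -165, by = -15))
})

test_that("the grid ANOVA matches the brute-force decomposition and aov", {
  np <- 5L; no <- 4L; ns <- 6L
  sp <- latticeSpace(seq(0.2, 0.6, length.out = np), 0.5,
                     orientations = seq(0, -45, length.out = no))
  vals <- withr::with_seed(21, {
    a <- rnorm(np); b <- rnorm(no)
    lapply(seq_len(ns), function(s)
      outer(a, b, "+") + matrix(rnorm(np * no, sd = 0.3), np, no))
  })
  grids <- lapply(seq_len(ns), function(s)
    new("NTAGrid", subject = paste0("S", s), space = sp, values = vals[[s]]))
  res <- gridAnova(grids)
  # brute-force sums of squares from first principles
  y <- array(unlist(vals), c(np, no, ns))
  gm <- mean(y)
  ssP <- ssO <- ssI <- ssE <- 0
  for (i in seq_len(np)) for (j in seq_len(no)) {
    mij <- mean(y[i, j, ])
    mi <- mean(y[i, , ]); mj <- mean(y[, j, ])
    ssI <- ssI + ns * (mij - mi - mj + gm)^2
    ssE <- ssE + sum((y[i, j, ] - mij)^2)
  }
  for (i in seq_len(np)) ssP <- ssP + ns * no * (mean(y[i, , ]) - gm)^2
  for (j in seq_len(no)) ssO <- ssO + ns * np * (mean(y[, j, ]) - gm)^2
  msE <- ssE / (np * no * (ns - 1))
  expect_equal(res$ss[1:4], c(ssP, ssO, ssI, ssE), tolerance = 1e-8)
  expect_equal(res$F[3], (ssI / ((np - 1) * (no - 1))) / msE,
               tolerance = 1e-8)
  # independent cross-check against base aov on the long layout
  long <- data.frame(
    y = as.numeric(y),
    p = factor(rep(rep(seq_len(np), no), ns)),
    o = factor(rep(rep(seq_len(no), each = np), ns)))
  tab <- summary(stats::aov(y ~ p * o, data = long))[[1]]
  expect_equal(res$F[1:3], tab[1:3, "F value"], tolerance = 1e-8)
  expect_equal(res$p[1:3], tab[1:3, "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$df, c(np - 1, no - 1, (np - 1) * (no - 1),
                         np * no * (ns - 1)))
})

test_that("degenerate and malformed ANOVA inputs are rejected", {
  sp <- latticeSpace(c(0.3, 0.5), 0.5, orientations = c(0, -90))
  const <- new("NTAGrid", subject = "a", space = sp,
               values = matrix(0.2, 2, 2))
  expect_error(gridAnova(list(const)), "two subjects")
  expect_error(gridAnova(list(const, const)), "degenerate")
  holey <- new("NTAGrid", subject = "b", space = sp,
               values = matrix(c(NA, 1, 2, 3), 2, 2))
  ok <- new("NTAGrid", subject = "c", space = sp,
            values = matrix(rnorm(4), 2, 2))
  expect_error(gridAnova(list(holey, ok)), "missing cells")
})

test_that("the threshold sweep reports stable NTA vectors", {
  st <- testStudy()
  subj <- st$subjects[[1]]
  placements <- expand.grid(p_nz = c(0.25, 0.4, 0.55),
                            p_al = c(0.4, 0.6), theta = c(0, -90))
  out <- thresholdSensitivity(subj, placements, c(75, 90, 99))
  expect_equal(dim(out$nta), c(nrow(placements), 3L))
  expect_true(all(is.finite(out$nta)))
  # duplicated percents give identical columns
  dup <- thresholdSensitivity(subj, placements[1:4, ], c(80, 80))
  expect_identical(dup$nta[, 1], dup$nta[, 2])
  expect_equal(dup$correlations[1, 2], 1.0)
  expect_error(thresholdSensitivity(subj, placements, 90), "two")
})
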