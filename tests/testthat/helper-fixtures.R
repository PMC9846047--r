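# Fixtures are generated in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# analytic unit sphere head at a given subdivision level
sphereHead <- function(subdiv = 3L, radius = 1) {
  fixture(paste0("sphere_", subdiv, "_", radius),
          function() makeHead(radius = radius, axes = c(1, 1, 1),
                              subdiv = subdiv))
}

# default (slightly ellipsoidal) head + shell grid used by pipeline tests
testHead <- function() fixture("head3", function() makeHead(subdiv = 3L))

testGrid <- function() fixture("shell7", function()
  makeShellGrid(testHead(), voxelSize = 7))

# small planted study shared by pipeline-level tests
testStudy <- function() fixture("study", function() {
  h <- testHead()
  g <- testGrid()
  labels <- makeConnectome(g, timepoints = 3L, seed = 1L)$labels
  makePlantedCohort(h, g, labels, nSubjects = 4L, timepoints = 120L,
                    seed = 7L)
})

# tiny fully-masked grid for algebraic tests
tinyGrid <- function(n = 4L, voxelSize = 2) {
  VoxelGrid(rep(n, 3L), voxelSize = voxelSize)
}

# random dense correlation-valued connectome on a grid with N voxels
randomConnectomePair <- function(grid, timepoints = 30L, seed = 1L) {
  x <- withr::with_seed(seed, matrix(rnorm(timepoints * nVoxels(grid)),
                                     timepoints))
  list(dense = connectomeFromTimeseries(x, grid, mode = "dense"),
       lazy = connectomeFromTimeseries(x, grid, mode = "lazy"),
       x = x)
}

# analytic CPC forward map on a radius-R sphere with the standard landmarks
sphereCpcOracle <- function(p, radius = 1) {
  phi <- pi * p[1L]
  psi <- pi * p[2L]
  radius * c(-cos(psi), sin(psi) * cos(phi), sin(psi) * sin(phi))
}
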