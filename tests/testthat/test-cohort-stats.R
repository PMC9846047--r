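test_that("the efficacy correlation matches the closed-form t oracle", {
  co <- withr::with_seed(31, data.frame(nta = rnorm(12), outcome = rnorm(12)))
  res <- efficacyCorrelation(co)
  r <- cor(co$nta, co$outcome)
  t <- r * sqrt((12 - 2) / (1 - r^2))
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$p_one_tailed, pt(t, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$n, 12L)
  # cross-check against cor.test's one-sided p
  ct <- cor.test(co$nta, co$outcome, alternative = "greater")
  expect_equal(res$p_one_tailed, unname(ct$p.value), tolerance = 1e-10)
})

test_that("perfect and reversed rankings hit the p-value boundaries", {
  up <- data.frame(nta = 1:8, outcome = (1:8) * 2 + 3)
  res <- efficacyCorrelation(up)
  expect_equal(res$r, 1.0)
  expect_lt(res$p_one_tailed, 1e-10)
  down <- data.frame(nta = c(1, 2, 3), outcome = c(3, 2, 1))
  rd <- efficacyCorrelation(down)
  expect_equal(rd$r, -1.0)
  expect_gt(rd$p_one_tailed, 0.999) # one-tailed test in the wrong direction
  expect_error(efficacyCorrelation(data.frame(nta = c(1, 1, 1),
                                              outcome = 1:3)),
               "zero variance")
  expect_error(efficacyCorrelation(data.frame(nta = 1:2, outcome = 2:1)),
               "at least 3")
})

test_that("outcome permutation p is exact for a perfect ranking", {
  co <- data.frame(nta = 1:8, outcome = 1:8)
  res <- permuteOutcomes(co, nPerm = 999, seed = 4)
  # no permutation beats r = 1; only ties at the identity can inflate p
  expect_lte(res$p, (1 + sum(res$r_null >= 1 - 1e-12)) / 1000)
  expect_equal(res$p, 1 / 1000, tolerance = 0.05)
  # reproducible under a fixed seed, in (0, 1]
  res2 <- permuteOutcomes(co, nPerm = 999, seed = 4)
  expect_identical(res$p, res2$p)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("Monte-Carlo permutation agrees with exhaustive enumeration", {
  co <- withr::with_seed(17, data.frame(nta = rnorm(5), outcome = rnorm(5)))
  # exhaustive null over all 120 orderings of the outcome column
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  rAll <- apply(perms, 1, function(ix) cor(co$nta, co$outcome[ix]))
  rObs <- cor(co$nta, co$outcome)
  piExact <- mean(rAll >= rObs)
  nPerm <- 20000
  res <- permuteOutcomes(co, nPerm = nPerm, seed = 8)
  se <- sqrt(piExact * (1 - piExact) / nPerm)
  expect_lt(abs(res$p - piExact), 3 * se + 2 / nPerm)
})

test_that("the network null with an identity relocation returns p = 1", {
  st <- testStudy()
  keep <- function(foci, coords) foci
  res <- permuteNetworks(st$subjects, st$cohort, st$cohort$outcome,
                         st$foci, radius = 10, nPerm = 5, seed = 1,
                         relocateFun = keep)
  expect_equal(res$p, 1.0)
  expect_true(all(abs(res$r_null - res$r_obs) < 1e-12))
  # observed per-subject NTA matches the placement chain
  direct <- vapply(seq_along(st$subjects), function(s)
    ntaForPlacement(st$subjects[[s]],
                    c(st$cohort$p_nz[s], st$cohort$p_al[s],
                      st$cohort$theta[s])), numeric(1))
  expect_equal(res$nta_obs, direct, tolerance = 1e-10)
})

test_that("the network null is seeded, valid and reusable via enMat", {
  st <- testStudy()
  a <- permuteNetworks(st$subjects, st$cohort, st$cohort$outcome, st$foci,
                       radius = 10, nPerm = 50, seed = 42)
  b <- permuteNetworks(st$subjects, st$cohort, st$cohort$outcome, st$foci,
                       radius = 10, nPerm = 50, seed = 42, enMat = a$en_mat)
  expect_identical(a$p, b$p)
  expect_true(a$p > 0 && a$p <= 1)
  c_ <- permuteNetworks(st$subjects, st$cohort, st$cohort$outcome, st$foci,
                        radius = 10, nPerm = 50, seed = 43, enMat = a$en_mat)
  expect_false(identical(a$r_null, c_$r_null))
})

test_that("partial correlation matches the recursion-formula oracle", {
  df <- data.frame(nta = c(0.2, 0.5, 0.1, 0.9, 0.4, 0.7),
                   outcome = c(1.1, 2.3, 0.4, 3.1, 1.0, 2.8),
                   age = c(31, 45, 28, 60, 39, 51))
  res <- partialCorrelation(df, "age")
  rxy <- cor(df$nta, df$outcome)
  rxz <- cor(df$nta, df$age)
  ryz <- cor(df$outcome, df$age)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$r_partial, oracle, tolerance = 1e-12)
  t <- oracle * sqrt((6 - 3) / (1 - oracle^2))
  expect_equal(res$p_one_tailed, pt(t, 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("orthogonal covariates leave the correlation unchanged", {
  n <- 8L
  base <- withr::with_seed(5, list(x = rnorm(n), y = rnorm(n)))
  # covariate orthogonal to both variables by construction (residualized)
  zraw <- withr::with_seed(6, rnorm(n))
  z <- residuals(lm(zraw ~ base$x + base$y))
  df <- data.frame(nta = base$x, outcome = base$y, sex = z)
  res <- partialCorrelation(df, "sex")
  expect_equal(res$r_partial, cor(base$x, base$y), tolerance = 1e-10)
  # covariate equal to the outcome leaves a constant residual
  bad <- data.frame(nta = base$x, outcome = base$y, age = base$y)
  expect_error(partialCorrelation(bad, "age"), "degenerate")
  expect_error(partialCorrelation(data.frame(nta = base$x,
                                             outcome = base$y,
                                             sex = rep(1, n)), "sex"),
               "constant")
})
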