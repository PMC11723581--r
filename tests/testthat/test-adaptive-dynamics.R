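test_that("the singular point is the mean of the pathogen optima", {
  expect_equal(singular_point(simplex_optima(3)), c(0, 0), tolerance = 1e-12)
  expect_equal(singular_point(matrix(c(-0.5, 0.5), 2, 1)), 0)
  expect_equal(singular_point(rbind(c(0, 0), c(1, 0), c(0, 1))),
               c(1 / 3, 1 / 3))
  expect_error(singular_point(matrix(1, 1, 2)), "at least two")
})

test_that("pathogen covariance uses the population normalisation", {
  expect_equal(as.numeric(pathogen_covariance(matrix(c(-0.5, 0.5), 2, 1))),
               0.25)
  for (m in c(2, 4, 7)) {
    ev <- eigen(pathogen_covariance(simplex_optima(m)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_equal(ev, rep(1 / (2 * m), m - 1), tolerance = 1e-12)
  }
  expect_equal(pathogen_covariance(matrix(1, 3, 2)), matrix(0, 2, 2))
})

test_that("the general branching condition follows the matrix sign", {
  # exact boundary: largest eigenvalue zero, no branching
  Sp <- diag(c(0.2, 0.1))
  v0 <- branching_condition_general(Sp, Sp / 2)
  expect_equal(max(v0$eigenvalues), 0)
  expect_false(v0$branching)
  # isotropic m = 3, v = 7: 1/6 - 2/49 > 0
  v1 <- branching_condition_general(diag(1 / 6, 2), diag(1 / 49, 2))
  expect_true(v1$branching)
  expect_true(v1$positive_definite)
  expect_equal(v1$eigenvalues, rep(1 / 6 - 2 / 49, 2))
  # v = 2: 1/6 - 2/4 < 0
  v2 <- branching_condition_general(diag(1 / 6, 2), diag(1 / 4, 2))
  expect_false(v2$branching)
  # disruptive in one direction only
  v3 <- branching_condition_general(diag(c(0.5, 0.01)), diag(0.05, 2))
  expect_true(v3$branching)
  expect_false(v3$positive_definite)
  expect_error(branching_condition_general(matrix(c(1, 2, 0, 1), 2), diag(2)),
               "symmetric")
  expect_error(branching_condition_general(diag(2), diag(c(1, -1))),
               "positive definite")
})

test_that("the symmetric threshold is v_c = 2 sqrt(m), increasing in m", {
  expect_equal(branching_threshold_symmetric(3), 2 * sqrt(3))
  expect_equal(branching_threshold_symmetric(4), 4)
  m <- 2:30
  expect_true(all(diff(sapply(m, branching_threshold_symmetric)) > 0))
})

test_that("symmetric threshold agrees with the general condition", {
  set.seed(20)
  for (i in 1:100) {
    m <- sample(2:40, 1)
    vc <- branching_threshold_symmetric(m)
    Sp <- pathogen_covariance(simplex_optima(m))
    eps <- 1e-6
    above <- branching_condition_general(Sp, diag((vc + eps)^-2, m - 1))
    below <- branching_condition_general(Sp, diag((vc - eps)^-2, m - 1))
    expect_true(above$branching)
    expect_false(below$branching)
  }
})

test_that("predict_branching combines singular point, verdict and threshold", {
  cfg <- small_gaussian_config()
  v <- predict_branching(cfg)
  expect_equal(v$singular_point, c(0, 0), tolerance = 1e-12)
  expect_true(v$branching) # v = 7 > 2 sqrt(3)
  expect_equal(v$v_critical, 2 * sqrt(3))
  # non-simplex optima: no closed-form critical virulence
  v2 <- predict_branching(list(optima = rbind(c(0, 0), c(2, 0), c(0, 1)),
                               v = 7))
  expect_true(is.na(v2$v_critical))
})

test_that("the singular point attracts an off-centre population", {
  cfg <- small_gaussian_config(N = 2000L, mu = 5e-4, generations = 4000L,
                               K = 10, init = c(0.25, 0.25), thin = 200L,
                               seed = 2L)
  sim <- wf_simulate(cfg)
  mean_trait <- t(sapply(sim$snapshots, function(sn) {
    colSums(as.matrix(sn$repr) * sn$count) / sum(sn$count)
  }))
  d <- sqrt(rowSums(mean_trait^2))
  # distance to x* shrinks substantially from its starting value
  expect_lt(mean(tail(d, 3)), 0.4 * d[1])
})
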