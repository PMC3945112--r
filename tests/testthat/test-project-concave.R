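test_that("projection handles the canonical small cases exactly", {
  expect_equal(as.numeric(projectConcave(c(0, -2, 0))[1:3]),
               rep(-2 / 3, 3), tolerance = 1e-10)
  # linear sequences are concave: fixed points
  v <- 1.5 + 0.3 * (0:9)
  expect_equal(as.numeric(projectConcave(v))[1:10], v, tolerance = 1e-12)
  expect_equal(as.numeric(projectConcave(c(0, 2, 0)))[1:3], c(0, 2, 0),
               tolerance = 1e-12)
})

test_that("projection agrees with a generic QP solver, also under weights", {
  skip_if_not_installed("pracma")
  set.seed(8)
  for (i in 1:60) {
    n <- sample(3:15, 1)
    v <- rnorm(n, sd = 3)
    w <- if (i %% 2 == 0) runif(n, 0.2, 3) else rep(1, n)
    u <- projectConcave(v, weights = w)
    expect_lt(max(abs(u - qpConcaveProject(v, w))), 1e-6)
  }
})

test_that("projection output is feasible and idempotent", {
  set.seed(9)
  v <- cumsum(rnorm(500))
  u <- suppressWarnings(projectConcave(v))
  expect_lte(max(diff(as.numeric(u), differences = 2)), 1e-8)
  u2 <- projectConcave(as.numeric(u))
  expect_equal(as.numeric(u2), as.numeric(u), tolerance = 1e-9)
  expect_error(projectConcave(c(1, NA, 2)), "finite")
})
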