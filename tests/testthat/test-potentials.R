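# term-by-term re-evaluation, independent of potential_energy()
direct_energy <- function(p, x, y) {
  u <- p$confinement_weight * (x^p$confinement_degree + y^p$confinement_degree)
  for (i in seq_len(nrow(p$gaussians))) {
    gi <- p$gaussians[i, ]
    u <- u + gi$sign * exp(-(x - gi$center_x)^2 / (2 * gi$width^2)) *
      exp(-(y - gi$center_y)^2 / (2 * gi$width^2))
  }
  u
}

test_that("energy matches independent term-by-term evaluation", {
  # a Gaussian term evaluated at its own center contributes exactly exp(0)
  p1 <- model_potential(1e-4, 4, tibble::tibble(center_x = 1.5, center_y = -2,
                                                sign = -1, width = 0.8))
  expect_equal(potential_energy(p1, 1.5, -2),
               1e-4 * (1.5^4 + 2^4) - 1, tolerance = 1e-12)

  # hand evaluation of the five Gaussian terms of the 4-state landscape at
  # the origin (confinement vanishes there): 1 - 2 e^{-5/1.28} - 2 e^{-4.25/1.28}
  p4 <- builtin_potential("four_state")
  expect_equal(potential_energy(p4, 0, 0),
               1 - 2 * exp(-5 / 1.28) - 2 * exp(-4.25 / 1.28),
               tolerance = 1e-12)
  expect_equal(potential_energy(p4, 0, 0), 0.887, tolerance = 1e-3)

  set.seed(42)
  for (nm in c("linear3", "triangular3", "four_state")) {
    p <- builtin_potential(nm)
    xs <- runif(20, -3, 3); ys <- runif(20, -3, 3)
    expect_equal(potential_energy(p, xs, ys), direct_energy(p, xs, ys),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradient agrees with finite differences", {
  p4 <- builtin_potential("four_state")
  g0 <- potential_gradient(p4, 0, 0)
  expect_equal(unlist(g0), c(dU_dx = 0, dU_dy = 0), tolerance = 1e-12)

  # pure confinement: dU/dx = d W x^(d-1)
  pc <- model_potential(1e-4, 4)
  expect_equal(potential_gradient(pc, 1, 0)$dU_dx, 4e-4, tolerance = 1e-12)
  expect_equal(potential_gradient(pc, 1, 0)$dU_dy, 0)

  set.seed(7)
  h <- 1e-6
  for (nm in c("linear3", "triangular3", "four_state")) {
    p <- builtin_potential(nm)
    xs <- runif(100, -3, 3); ys <- runif(100, -3, 3)
    g <- potential_gradient(p, xs, ys)
    fd_x <- (potential_energy(p, xs + h, ys) -
               potential_energy(p, xs - h, ys)) / (2 * h)
    fd_y <- (potential_energy(p, xs, ys + h) -
               potential_energy(p, xs, ys - h)) / (2 * h)
    expect_equal(g$dU_dx, fd_x, tolerance = 1e-5)
    expect_equal(g$dU_dy, fd_y, tolerance = 1e-5)
  }
})

test_that("built-in potentials have the stated geometry", {
  p4 <- builtin_potential("four_state")
  expect_identical(p4$confinement_degree, 4L)
  expect_equal(sum(p4$gaussians$sign == 1), 1)
  expect_equal(sum(p4$gaussians$sign == -1), 4)
  # wells antisymmetric about the origin -> inversion symmetry of U
  set.seed(3)
  xs <- runif(25, -3, 3); ys <- runif(25, -3, 3)
  expect_equal(potential_energy(p4, xs, ys), potential_energy(p4, -xs, -ys),
               tolerance = 1e-12)

  p3 <- builtin_potential("linear3")
  expect_identical(p3$confinement_degree, 6L)
  expect_equal(nrow(p3$gaussians), 3)
  expect_true(all(p3$gaussians$sign == -1))
  expect_equal(stats::var(p3$gaussians$center_y), 0)  # collinear

  expect_error(builtin_potential("bogus"), "Unknown potential")
})

test_that("confinement dominates far from the wells", {
  # the quartic confinement with W = 1e-4 needs a larger radius than the
  # sextic one to clear the wells by 10 units; 20 covers both
  for (nm in c("linear3", "triangular3", "four_state")) {
    p <- builtin_potential(nm)
    g <- p$gaussians
    e_centers <- potential_energy(p, g$center_x, g$center_y)
    expect_true(all(potential_energy(p, 20, 20) > e_centers + 10))
    expect_true(all(potential_energy(p, -20, 0) > e_centers + 10))
  }
})

test_that("potentials round-trip through the JSON config format", {
  p <- builtin_potential("triangular3")
  path <- withr::local_tempfile(fileext = ".json")
  write_potential(p, path)
  q <- read_potential(path)
  expect_equal(q$confinement_weight, p$confinement_weight)
  expect_equal(q$confinement_degree, p$confinement_degree)
  expect_equal(as.data.frame(q$gaussians), as.data.frame(p$gaussians))
  set.seed(1)
  xs <- runif(10, -3, 3); ys <- runif(10, -3, 3)
  expect_equal(potential_energy(q, xs, ys), potential_energy(p, xs, ys))
})

test_that("constructor rejects invalid configurations", {
  expect_error(model_potential(-1, 4), "positive")
  expect_error(model_potential(1e-4, 3), "even")
  expect_error(model_potential(1e-4, 4,
    tibble::tibble(center_x = 0, center_y = 0, sign = 2, width = 0.8)),
    "sign")
  expect_error(model_potential(1e-4, 4,
    tibble::tibble(center_x = 0, center_y = 0, sign = 1, width = -1)),
    "width")
})
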