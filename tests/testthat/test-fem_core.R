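test_that("beam element stiffness matches the canonical Euler-Bernoulli matrix", {
  b <- beam_element(1, 1, 1, 1:4)
  K <- beam_element_stiffness(b)
  expect_equal(K, matrix(c(12, 6, -12, 6,
                           6, 4, -6, 2,
                           -12, -6, 12, -6,
                           6, 2, -6, 4), 4, 4, byrow = TRUE))
  expect_equal(K, t(K))
  expect_equal(qr(K)$rank, 2L)  # two rigid-body modes
})

test_that("beam stiffness has rigid-body null modes and is linear in EI", {
  b <- beam_element(2.1e9, 3.2e-17, 4.3e-4, 1:4)
  K <- beam_element_stiffness(b)
  # pure translation
  expect_lt(max(abs(K %*% c(1, 0, 1, 0))), 1e-10 * max(abs(K)))
  # rigid rotation: u(x) = x with slope 1 at both ends
  L <- b$length
  expect_lt(max(abs(K %*% c(0, 1, L, 1))), 1e-10 * max(abs(K)))
  K2 <- beam_element_stiffness(beam_element(2 * 2.1e9, 3.2e-17, 4.3e-4, 1:4))
  expect_equal(K2, 2 * K)
})

test_that("invalid element specifications are rejected", {
  expect_error(beam_element(1, 1, -1, 1:4), "length")
  expect_error(beam_element(-1, 1, 1, 1:4), "modulus")
  expect_error(beam_element(1, 1, 1, c(1, 1, 2, 3)), "distinct")
  expect_error(spring_element(-5, c(1, 2)), "stiffness")
  expect_error(spring_element(1, c(3, 3)), "distinct")
})

test_that("spring element stiffness is [[k,-k],[-k,k]] with zero row sums", {
  expect_equal(spring_element_stiffness(spring_element(5, c(1, 2))),
               matrix(c(5, -5, -5, 5), 2, 2))
  expect_equal(spring_element_stiffness(spring_element(0, c(1, 2))),
               matrix(0, 2, 2))
  for (k in c(0.5, 3, 1e6)) {
    K <- spring_element_stiffness(spring_element(k, c(1, 2)))
    expect_equal(rowSums(K), c(0, 0))
  }
})

test_that("global assembly sums shared entries and is order-invariant", {
  sys <- assemble_global(list(), two_spring_chain(), n_dofs = 3)
  expect_equal(sys$K, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  sys_rev <- assemble_global(list(), rev(two_spring_chain()), n_dofs = 3)
  expect_identical(sys$K, sys_rev$K)
  expect_error(assemble_global(list(), list(spring_element(1, c(1, 4))), 3),
               "out of range")
})

test_that("the 13-element follicle layout assembles to a symmetric 20x20 matrix", {
  m <- build_model(follicle_params())
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  expect_equal(dim(sys$K), c(20L, 20L))
  expect_lt(max(abs(sys$K - t(sys$K))), 1e-12 * max(abs(sys$K)))
  # the RS spring (element 10) joins DOFs 5 and 15
  k3 <- follicle_params()$k3
  expect_equal(sys$K[5, 15], -k3)
  expect_equal(sys$K[15, 5], -k3)
  # no other coupling between vibrissa node 3 and wall node 3
  expect_equal(sys$K[6, 15], 0)
})

test_that("with ground springs removed, uniform translation is a rigid-body mode", {
  p <- tweak_params(follicle_params(), k5 = 0, k6 = 0)
  m <- build_model(p)
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  v <- numeric(20)
  v[c(1, 3, 5, 7, 9, 11, 13, 15, 17)] <- 1  # all beam translations
  expect_lt(max(abs(sys$K %*% v)), 1e-10 * max(abs(sys$K)))
})

test_that("penalty boundary conditions modify only constrained entries", {
  m <- build_model(follicle_params())
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  sys_bc <- apply_boundary_conditions(sys, m$constraints)
  # load vector nonzero only at DOF 8 (prescribed values at 19, 20 are zero)
  expect_true(sys_bc$f[8] != 0)
  expect_equal(sys_bc$f[-8], numeric(19))
  # penalties on the three constrained diagonals only
  delta <- sys_bc$K - sys$K
  expect_equal(which(delta != 0, arr.ind = TRUE)[, 1],
               c(8L, 19L, 20L), ignore_attr = TRUE)
  expect_true(all(diag(sys_bc$K)[c(8, 19, 20)] >= sys_bc$beta))
  # empty constraint set leaves the system unchanged
  expect_identical(apply_boundary_conditions(sys, data.frame(
    dof = integer(0), value = numeric(0)))$K, sys$K)
  expect_error(apply_boundary_conditions(sys, data.frame(
    dof = c(8L, 8L), value = c(0, 1))), "duplicate")
})

test_that("solver honours prescribed values within the penalty error bound", {
  p <- follicle_params()
  m <- build_model(p)
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  sys_bc <- apply_boundary_conditions(sys, m$constraints)
  d <- solve_displacements(sys_bc)
  bound <- 10 * max(abs(d)) / (sys_bc$beta / mean(diag(sys$K)))
  expect_lt(abs(d[19]), bound)
  expect_lt(abs(d[20]), bound)
  expect_equal(d[8], p$deflection_angle, tolerance = 1e-6)
})

test_that("zero prescribed deflection yields the zero solution, and the solve is linear", {
  base <- follicle_params()
  d0 <- solve_follicle(tweak_params(base, deflection_angle = 0))
  expect_equal(d0, numeric(20))
  d <- solve_follicle(base)
  d_neg <- solve_follicle(tweak_params(base,
                                       deflection_angle = -base$deflection_angle))
  expect_rel_equal(d_neg, -d, 1e-10)
  for (c_mult in c(-1, 0.5, 2)) {
    dc <- solve_follicle(tweak_params(base,
      deflection_angle = c_mult * base$deflection_angle))
    expect_rel_equal(dc, c_mult * d, 1e-10)
  }
})

test_that("penalty solution matches the elimination oracle and converges with beta", {
  for (mode in c("diag", "modulus")) {
    p <- follicle_params(beta_mode = mode)
    m <- build_model(p)
    d_pen <- solve_follicle(p)
    d_ora <- oracle_constrained_solve(m$beams, m$springs, m$constraints,
                                      m$n_dofs)
    expect_rel_equal(d_pen, d_ora, 1e-5)
  }
  # error shrinks at least 100x from beta = 1e5*mean(diag) to 1e9*mean(diag)
  p <- follicle_params()
  m <- build_model(p)
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  d_ora <- oracle_constrained_solve(m$beams, m$springs, m$constraints, 20)
  err <- vapply(c(1e5, 1e9), function(mult) {
    s2 <- apply_boundary_conditions(sys, m$constraints,
                                    beta = mult * mean(diag(sys$K)))
    max(abs(solve_displacements(s2) - d_ora)) / max(abs(d_ora))
  }, numeric(1))
  expect_gt(err[1] / err[2], 100)
})

test_that("oracle reproduces Hooke's law for a single grounded spring", {
  k <- 250
  spr <- list(spring_element(k, c(1, 2)))
  delta <- 3e-3
  d <- oracle_constrained_solve(list(), spr,
                                data.frame(dof = c(1L, 2L),
                                           value = c(delta, 0)),
                                n_dofs = 2)
  expect_equal(d, c(delta, 0))
  # reaction force at the grounded end is -k * delta
  K <- assemble_global(list(), spr, 2)$K
  expect_equal(as.numeric(K %*% d), c(k * delta, -k * delta))
  # zero prescribed values give the zero solution
  d0 <- oracle_constrained_solve(list(), spr,
                                 data.frame(dof = c(1L, 2L), value = c(0, 0)),
                                 n_dofs = 2)
  expect_equal(d0, c(0, 0))
})
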