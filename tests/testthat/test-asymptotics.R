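test_that("early-time system freezes the orientation and relaxes the shape", {
  d <- early_time_rhs(0.7, 0.2, 0.1, nu = 1.5, Gamma = 1, r_bar = 2)
  expect_identical(d[["dA"]], 0)
  # no overlap, no propulsion forcing: only the shape relaxation acts
  d <- early_time_rhs(0, -1, 0.3, nu = 1.5, Gamma = 1, r_bar = 2)
  expect_identical(d[["dB"]], 0)
  expect_lt(d[["dC"]], 0)
  # the overlap indicator responds through D's own evolution equation,
  # recovered here by the chain rule on (A, B, C)
  rb <- 2; nu <- 1.5; G <- 1
  for (state in list(c(1, 0.2, 0.1), c(1, -0.5, 0.4), c(0.5, 0.05, -0.2))) {
    d <- early_time_rhs(state[1], state[2], state[3], nu, G, rb)
    dD_chain <- 2 * (rb^2 - 1) * state[1] * d[["dA"]] +
      2 * sqrt(rb) * d[["dB"]] - d[["dC"]] / rb
    D <- (rb^2 - 1) * state[1]^2 + 2 * sqrt(rb) * state[2] - state[3] / rb
    ind <- as.numeric(D > 0)
    dD_direct <- 2 * sqrt(rb) * nu * state[1] +
      (16 * (1 + rb^4) / (G * rb^2 * (1 + rb^2))) * state[3] -
      4 * rb * (5 + rb^2) / (1 + rb^2) * sqrt(max(D, 0)) * ind
    expect_equal(dD_chain, dD_direct, tolerance = 1e-12)
  }
})

test_that("early-time solutions converge to the far-field constants", {
  # long-time limit of the ODE against the closed-form constants
  et <- solve_early_time(a = 1, nu = 1.5, Gamma = 1, r_bar = 2, tau_max = 1000)
  expect_lt(et$far_field_residual, 1e-6)
  ff <- far_field_limits(1, 1.5, 1, 2)
  expect_equal(ff$A_inf, 1)
  # rigid sublimit: no shape perturbation survives
  ff0 <- far_field_limits(1, 1.5, 0, 2)
  expect_identical(ff0$C_inf, 0)
  expect_equal(ff0$B_inf, 1.5^2 / (8 * 2^1.5) - 3 / (2 * sqrt(2)),
               tolerance = 1e-14)
  # no propulsion: overlap pushes the cells strictly apart
  ffn <- far_field_limits(1, 0, 1, 2)
  expect_equal(ffn$B_inf, -(2^2 - 1) / (2 * sqrt(2)), tolerance = 1e-14)
  expect_identical(ffn$C_inf, 0)
  expect_true(isTRUE(far_field_limits(-1, 1.5, 1, 2)$unstable))
})

test_that("late-time solution matches, decays and has the printed pole", {
  a <- 1; nu <- 2; G <- 1; rb <- 2
  # matching at T -> 0+ equals the far field, exactly
  lt0 <- late_time_solution(0, a, nu, G, rb)
  ff <- far_field_limits(a, nu, G, rb)
  expect_identical(lt0$A, ff$A_inf)
  expect_identical(lt0$B, ff$B_inf)
  expect_identical(lt0$C, ff$C_inf)
  # T * A -> (rb^2+1)/(4 nu sqrt(rb) (rb^2-1)) algebraically
  Tbig <- 1e8
  expect_equal(Tbig * late_time_solution(Tbig, a, nu, G, rb)$A,
               (rb^2 + 1) / (4 * nu * sqrt(rb) * (rb^2 - 1)),
               tolerance = 1e-6)
  # separable ODE: dA/dT = -4 nu sqrt(rb) (rb^2-1)/(rb^2+1) A^2
  h <- 1e-6
  for (Tq in c(0.5, 2, 10)) {
    fd <- (late_time_solution(Tq + h, a, nu, G, rb)$A -
             late_time_solution(Tq - h, a, nu, G, rb)$A) / (2 * h)
    A <- late_time_solution(Tq, a, nu, G, rb)$A
    expect_equal(fd, -4 * nu * sqrt(rb) * (rb^2 - 1) / (rb^2 + 1) * A^2,
                 tolerance = 1e-6)
  }
  # wide cells blow up in finite time
  ltw <- late_time_solution(0.01, a, nu, G, 0.5)
  expect_true(is.finite(ltw$pole_time) && ltw$pole_time > 0)
  expect_error(late_time_solution(ltw$pole_time * 1.01, a, nu, G, 0.5), "pole")
  expect_identical(late_time_solution(1, a, nu, G, 2)$pole_time, Inf)
})

test_that("composite solution starts at the scaled perturbation and is shape-independent", {
  p <- model_params(nu = 2, gamma = 0.1, r_bar = 2)
  spec <- perturbation_spec(eps = 0.1, a = 1, b = 1, c = 1, Gamma = 1)
  comp <- composite_solution(c(0, 1, 10), spec, p)
  expect_equal(comp$alpha[1], 0.1 * 1, tolerance = 1e-14)
  # the orientation composite carries no shape-parameter dependence
  tgrid <- seq(0, 50, length.out = 101)
  alphas <- lapply(c(0.1, 1, 10), function(G) {
    sp <- perturbation_spec(0.1, 1, 1, 1, Gamma = G)
    composite_solution(tgrid, sp, model_params(nu = 2, gamma = 0.1 * G,
                                               r_bar = 2))$alpha
  })
  expect_identical(alphas[[1]], alphas[[2]])
  expect_identical(alphas[[1]], alphas[[3]])
})

test_that("the rigid sublimit agrees with the shape-free limit of the full forms", {
  rs <- rigid_sublimit_solutions(a = 1, nu = 2, r_bar = 2)
  expect_equal(rs$A_late(0), 1, tolerance = 1e-14)
  for (Tq in c(0, 0.5, 3, 40)) {
    lt <- late_time_solution(Tq, 1, 2, 0, 2)
    expect_equal(rs$A_late(Tq), lt$A, tolerance = 1e-14)
    expect_equal(rs$B_late(Tq), lt$B, tolerance = 1e-14)
  }
  # algebraic decay to zero for long cells
  expect_lt(abs(rs$A_late(1e7)), 1e-6)
  expect_lt(abs(rs$B_late(1e7)), 1e-12)
  # early-time derivative closed form
  expect_equal(rs$dB_early(0.2),
               2 * 1 - 2 * sqrt(2) * sqrt(3 + 2 * sqrt(2) * 0.2),
               tolerance = 1e-14)
})

test_that("slow-manifold flow fixes the endpoints and preserves the constraint", {
  r <- 2
  Y <- function(s) -sqrt((r^2 - 1) * s^2 + 1) / sqrt(r)
  expect_equal(unname(slow_manifold_rhs(0, Y(0), r)), c(0, 0))
  expect_equal(unname(slow_manifold_rhs(1, Y(1), r)), c(0, 0))
  # the constrained derivative identity (r^2-1) s0 ds0 = r Y0 dY0
  for (s in seq(0.05, 0.95, by = 0.1)) {
    d <- slow_manifold_rhs(s, Y(s), r)
    expect_equal((r^2 - 1) * s * d[["ds0"]], r * Y(s) * d[["dY0"]],
                 tolerance = 1e-12)
  }
  # single-ODE reduction agrees after substituting the constraint
  sgrid <- seq(0.05, 0.95, by = 0.05)
  for (s in sgrid)
    expect_equal(slow_manifold_single_ode(s, r),
                 slow_manifold_rhs(s, Y(s), r)[["ds0"]], tolerance = 1e-12)
  expect_true(all(slow_manifold_single_ode(sgrid, r) < 0))
  expect_error(slow_manifold_rhs(1.2, -1, r), "s0")
})

test_that("slow-manifold time integrates the reduced ODE and diverges at alignment", {
  r <- 2
  expect_identical(slow_manifold_time(0.5, 0.5, r), 0)
  # quadrature vs the reduced-ODE solver crossing times
  red <- solve_slow_manifold(0.8, r, tau_end = 6, n_save = 4000)
  for (s_to in c(0.6, 0.4, 0.3)) {
    tau_ode <- stats::approx(rev(red$s0), rev(red$tau), xout = s_to)$y
    expect_equal(slow_manifold_time(0.8, s_to, r), tau_ode, tolerance = 1e-5)
  }
  # leading divergence s_to * tau -> (r^2+1)/(4 sqrt(r)(r^2-1))
  lead <- vapply(c(1e-3, 1e-4, 1e-5), function(s_to)
    s_to * slow_manifold_time(0.5, s_to, r), 0)
  expect_equal(lead[3], (r^2 + 1) / (4 * sqrt(r) * (r^2 - 1)),
               tolerance = 0.01)
  expect_true(all(diff(abs(lead - (r^2 + 1) / (4 * sqrt(r) * (r^2 - 1)))) < 0))
  expect_error(slow_manifold_time(0.5, 0, r), "infinite time")
})
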