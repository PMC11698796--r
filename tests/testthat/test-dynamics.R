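test_that("right-hand side matches the printed branch behaviour", {
  p <- model_params(nu = 1, gamma = 1, r_bar = 2)
  # region A with r at its preferred value: pure self-propulsion
  d <- rhs_full(cell_state(y = -2, alpha = 0.3, r = 2), p)
  expect_equal(unname(d), c(cos(0.3), sin(0.3), 0, 0), tolerance = 1e-14)
  # steady state: only the decoupled horizontal drift remains
  d <- rhs_full(cell_state(y = -1 / sqrt(2), alpha = 0, r = 2), p)
  expect_equal(unname(d), c(p$nu, 0, 0, 0), tolerance = 1e-12)
  # rotational symmetry (alpha, y) -> (-alpha, -y)
  st <- sample_states(50, seed = 5)
  for (i in seq_len(20)) {
    d1 <- rhs_full(cell_state(y = st$y[i], alpha = st$alpha[i], r = st$r[i]), p)
    d2 <- rhs_full(cell_state(y = -st$y[i], alpha = -st$alpha[i], r = st$r[i]), p)
    expect_equal(unname(d2), unname(d1) * c(1, -1, -1, 1), tolerance = 1e-12)
  }
  expect_error(rhs_full(cell_state(y = -0.5, alpha = 0.2, r = 2),
                        model_params(nu = 1, gamma = 0, r_bar = 2)),
               "rhs_rigid")
})

test_that("rigid and nu0 right-hand sides are consistent reductions", {
  p <- rigid_params(2, 2)
  # region A
  expect_equal(unname(rhs_rigid(0.4, -1.6, p)), c(2 * sin(0.4), 0),
               tolerance = 1e-14)
  # steady point
  expect_equal(unname(rhs_rigid(0, -1 / sqrt(2), p)), c(0, 0), tolerance = 1e-13)
  # overlap avoidance rotates clockwise for long cells in region B
  expect_lt(rhs_rigid(0.3, -0.5, p)[["dalpha"]], 0)
  # nu0 is rigid at nu = 0
  p0 <- rigid_params(0, 2)
  st <- sample_states(50, seed = 6)
  for (i in seq_len(20)) {
    expect_equal(rhs_nu0(st$alpha[i], st$y[i], 2),
                 rhs_rigid(st$alpha[i], st$y[i],
                           model_params(nu = 0, gamma = 0, r_bar = 2)),
                 tolerance = 1e-14)
  }
  # nu0 vanishes identically in region A and on its boundary
  expect_equal(unname(rhs_nu0(0.4, -1.6, 2)), c(0, 0))
  b <- boundary_curves(0.4, 2)
  expect_equal(unname(rhs_nu0(0.4, -b$Gamma_AB, 2)), c(0, 0))
  # region-C push-apart rate is bounded away from zero
  d <- rhs_nu0(0.6, -0.2, 2)
  expect_lte(d[["dy"]], -4 * 0.2 / (2^2 - 1))
  expect_error(rhs_rigid(0.1, -0.5, model_params(r_bar = 1)), "r = 1")
})

test_that("the vector field is continuous across both region boundaries", {
  p <- model_params(nu = 1.3, gamma = 0.7, r_bar = 2)
  ab <- boundary_states(200, "AB", seed = 8)
  jump_ab <- vapply(seq_len(nrow(ab)), function(i) {
    dA <- rhs_branch(ab$alpha[i], ab$y[i], ab$r[i], p, "A", "full")
    dB <- rhs_branch(ab$alpha[i], ab$y[i], ab$r[i], p, "B", "full")
    max(abs(dA - dB))
  }, 0)
  expect_lt(max(jump_ab), 1e-8)
  bc <- boundary_states(200, "BC", seed = 9)
  jump_bc <- vapply(seq_len(nrow(bc)), function(i) {
    dB <- rhs_branch(bc$alpha[i], bc$y[i], bc$r[i], p, "B", "full")
    dC <- rhs_branch(bc$alpha[i], bc$y[i], bc$r[i], p, "C", "full")
    # dy agrees exactly in closed form: 2 sign(y) / (gamma2 gamma1^2)
    g <- gamma_factors(bc$alpha[i], bc$r[i])
    closed <- -2 / (sqrt(g$g2sq) * g$g1sq)
    expect_equal(dB[["dy"]] - p$nu * sin(bc$alpha[i]), closed, tolerance = 1e-10)
    max(abs(dB - dC))
  }, 0)
  expect_lt(max(jump_bc), 1e-8)
})

test_that("trajectories stay region-consistent and respect symmetry", {
  p <- rigid_params(2, 2)
  tr <- integrate_trajectory(cell_state(y = -0.35, alpha = 0.9, r = 2), p,
                             t_end = 50, mode = "rigid")
  expect_true(all(diff(tr$states$t) > 0))
  expect_identical(tr$regions,
                   cellign:::.classify(tr$states$alpha, tr$states$y, 2))
  expect_true(all(tr$states$r == 2))  # rigid invariant, exact
  # mirrored start gives the mirrored trajectory
  tr2 <- integrate_trajectory(cell_state(y = 0.35, alpha = -0.9, r = 2), p,
                              t_end = 50, mode = "rigid")
  tq <- seq(0, min(max(tr$states$t), max(tr2$states$t)), length.out = 30)
  for (v in c("alpha", "y")) {
    a1 <- stats::approx(tr$states$t, tr$states[[v]], tq)$y
    a2 <- stats::approx(tr2$states$t, tr2$states[[v]], tq)$y
    expect_equal(a1, -a2, tolerance = 1e-6)
  }
})

test_that("zero-propulsion trajectories follow the three-way behaviour", {
  p0 <- rigid_params(0, 2)
  # (i) region-A start: stationary (terminates immediately under policy)
  tr <- integrate_trajectory(cell_state(y = -1.5, alpha = 0.4, r = 2), p0,
                             t_end = 10, mode = "nu0")
  expect_identical(tr$events$kind, "terminated-stationary")
  expect_equal(tr$states$y[nrow(tr$states)], -1.5)
  # without the policy the state is constant in time
  tr <- integrate_trajectory(cell_state(y = -1.5, alpha = 0.4, r = 2), p0,
                             t_end = 10, mode = "nu0", terminate = FALSE)
  expect_lt(max(abs(tr$states$y + 1.5), abs(tr$states$alpha - 0.4)), 1e-12)
  # (ii) region-C start crosses into B exactly once and never re-enters
  tr <- integrate_trajectory(cell_state(y = -0.3, alpha = pi / 4, r = 2), p0,
                             t_end = 100, mode = "nu0")
  expect_identical(sum(tr$events$kind == "BC-crossing"), 1L)
  expect_identical(tr$events$kind[nrow(tr$events)], "terminated-stationary")
  # (iii) region-B start converges to the A-B boundary in finite time
  tr <- integrate_trajectory(cell_state(y = -0.8, alpha = pi / 4, r = 2), p0,
                             t_end = 100, mode = "nu0")
  last <- tr$states[nrow(tr$states), ]
  expect_identical(tr$events$kind[nrow(tr$events)], "terminated-stationary")
  expect_lt(last$t, 5)
  expect_equal(last$y^2, gamma_factors(last$alpha, 2)$g1sq, tolerance = 1e-10)
})

test_that("first integral of the region-B arcs is conserved at nu = 0", {
  r <- 2
  K <- (r^2 + 1) / (r^2 - 1)
  first_integral <- function(alpha, y)
    y^2 - (1 / (2 * r)) * K * (r^2 * log(cos(alpha)) - log(sin(alpha)))
  ics <- sample_region_B(10, r, seed = 12)
  for (i in seq_len(nrow(ics))) {
    tr <- integrate_trajectory(cell_state(y = ics$y0[i], alpha = ics$alpha0[i],
                                          r = r), rigid_params(0, r),
                               t_end = 50, mode = "nu0",
                               rtol = 1e-11, atol = 1e-13)
    s <- tr$states
    inB <- tr$regions == "B" & s$alpha > 1e-3
    F <- first_integral(s$alpha[inB], s$y[inB])
    expect_lt(max(abs(F - F[1])), 1e-8)
  }
})

test_that("trajectory CSV + sidecar round trip preserves the run", {
  p <- rigid_params(2, 2)
  tr <- integrate_trajectory(cell_state(y = -0.6, alpha = 0.5, r = 2), p,
                             t_end = 5, mode = "rigid", terminate = FALSE,
                             n_save = 20L)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path, seed = 42L)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$states, tr$states, tolerance = 1e-15)
  expect_identical(tr2$regions, tr$regions)
  expect_equal(tr2$events$time, tr$events$time, tolerance = 1e-15)
  expect_identical(tr2$events$kind, tr$events$kind)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(meta$seed, 42L)
  unlink(c(path, paste0(path, ".json")))
})
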