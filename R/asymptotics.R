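# Perturbation machinery around the perfect-alignment steady state
# (0, -1/sqrt(r_bar), r_bar), its rigid sublimit, and the small-nu
# slow-manifold reduction.
#
# Perturbation scalings: alpha = eps*A, y = -1/sqrt(r_bar) + eps^2*B,
# r = r_bar + eps^2*C, with the shape parameter in the distinguished limit
# gamma = eps*Gamma.  Two timescales: an early time t = O(eps) over which
# the cells are pushed apart (A unchanged), and a late time t = O(1/eps)
# over which the orientation decays algebraically.

#' Specification of a perturbation experiment
#'
#' @param eps Small parameter `eps > 0` setting the perturbation scale.
#' @param a,b,c Order-one initial amplitudes of the `alpha`, `y`, `r`
#'   perturbations.
#' @param Gamma Rescaled shape parameter `Gamma = gamma / eps >= 0`
#'   (`Gamma = 0` is the rigid sublimit).
#' @return An object of class `cellign_perturbation`.
#' @export
perturbation_spec <- function(eps, a, b = 0, c = 0, Gamma = 1) {
  stopifnot(is.numeric(eps), eps > 0, is.numeric(Gamma), Gamma >= 0)
  structure(list(eps = eps, a = a, b = b, c = c, Gamma = Gamma),
            class = "cellign_perturbation")
}

#' Perturbed initial state implied by a perturbation specification
#'
#' Applies the scalings `alpha = eps a`, `y = -1/sqrt(r_bar) + eps^2 b`,
#' `r = r_bar + eps^2 c` exactly.
#'
#' @param spec A [perturbation_spec()].
#' @param r_bar Preferred aspect ratio.
#' @return A [cell_state()].
#' @export
perturbed_state <- function(spec, r_bar) {
  stopifnot(inherits(spec, "cellign_perturbation"))
  cell_state(x = 0, y = -1 / sqrt(r_bar) + spec$eps^2 * spec$b,
             alpha = spec$eps * spec$a, r = r_bar + spec$eps^2 * spec$c)
}

# overlap indicator argument D = (r_bar^2 - 1) A^2 + 2 sqrt(r_bar) B - C/r_bar
.Dhat <- function(A, B, C, r_bar) (r_bar^2 - 1) * A^2 + 2 * sqrt(r_bar) * B - C / r_bar

#' Early-time leading-order perturbation equations
#'
#' Derivatives with respect to the early time `tau = t / eps`:
#' `dA/dtau = 0` (the orientation is frozen over this timescale),
#' `dB/dtau = nu A - 2 sqrt(r_bar) sqrt(D) 1_{D>0}` and
#' `dC/dtau = -(16 (1 + r_bar^4) / (Gamma r_bar (1 + r_bar^2))) C
#'  + (16 r_bar^2 / (1 + r_bar^2)) sqrt(D) 1_{D>0}`, with
#' `D = (r_bar^2 - 1) A^2 + 2 sqrt(r_bar) B - C / r_bar` deciding whether
#' the cells overlap.  With `Gamma = 0` (rigid sublimit) the restoration is
#' instantaneous and `C` is held identically zero.
#'
#' @param Ahat,Bhat,Chat Perturbation values.
#' @param nu Self-propulsion strength.
#' @param Gamma Rescaled shape parameter (`gamma / eps`).
#' @param r_bar Preferred aspect ratio.
#' @return Named vector `(dA, dB, dC)` of tau-derivatives.
#' @export
early_time_rhs <- function(Ahat, Bhat, Chat, nu, Gamma, r_bar) {
  D <- .Dhat(Ahat, Bhat, Chat, r_bar)
  sq <- if (D > 0) sqrt(D) else 0
  dB <- nu * Ahat - 2 * sqrt(r_bar) * sq
  dC <- if (Gamma > 0) {
    -(16 * (1 + r_bar^4) / (Gamma * r_bar * (1 + r_bar^2))) * Chat +
      (16 * r_bar^2 / (1 + r_bar^2)) * sq
  } else 0
  c(dA = 0, dB = dB, dC = dC)
}

#' Solve the early-time perturbation system
#'
#' Numerical integration of [early_time_rhs()] from `(a, b, c)` up to
#' `tau_max` (there is no closed form for `Bhat`, `Chat`).  For `a > 0`
#' the solution converges to the far-field constants of
#' [far_field_limits()]; the attained residual is reported.
#'
#' @param a,b,c Initial amplitudes.
#' @inheritParams early_time_rhs
#' @param tau_max Integration horizon in early time.
#' @param n_save Saved points (log-spaced tail resolution is not needed;
#'   uniform grid).
#' @param rtol,atol Integrator tolerances.
#' @return List with `sol` (data.frame `tau, A, B, C`), interpolating
#'   functions `B_fun`, `C_fun`, and `far_field_residual`.
#' @export
solve_early_time <- function(a, b = 0, c = 0, nu, Gamma, r_bar,
                             tau_max = 1e3, n_save = 2000L,
                             rtol = 1e-10, atol = 1e-12) {
  func <- function(t, s, p)
    list(unname(early_time_rhs(s[1], s[2], s[3], nu, Gamma, r_bar)))
  times <- seq(0, tau_max, length.out = n_save + 1L)
  out <- deSolve::lsoda(c(A = a, B = b, C = c), times, func, NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  sol <- data.frame(tau = out[, "time"], A = out[, "A"], B = out[, "B"],
                    C = out[, "C"])
  ff <- if (a > 0) far_field_limits(a, nu, Gamma, r_bar) else NULL
  res <- if (!is.null(ff) && !isTRUE(ff$unstable)) {
    max(abs(sol$B[nrow(sol)] - ff$B_inf), abs(sol$C[nrow(sol)] - ff$C_inf))
  } else NA_real_
  list(sol = sol,
       B_fun = stats::approxfun(sol$tau, sol$B, rule = 2),
       C_fun = stats::approxfun(sol$tau, sol$C, rule = 2),
       far_field_residual = res)
}

#' Early-time far-field limits
#'
#' The `tau -> infinity` constants of the early-time system for `a > 0`:
#' `A -> a`,
#' `B -> nu^2 a^2 / (8 r_bar^(3/2)) - (r_bar^2 - 1) a^2 / (2 sqrt(r_bar))
#'  + Gamma nu a r_bar / (4 (1 + r_bar^4))`,
#' `C -> Gamma nu a r_bar^(5/2) / (2 (1 + r_bar^4))`.
#' These are the matching conditions for the late-time solution.  For
#' `a < 0` the early-time dynamics end in escape (no far field); an
#' `unstable` marker is returned.
#'
#' @param a Orientation perturbation amplitude.
#' @inheritParams early_time_rhs
#' @return List with `A_inf`, `B_inf`, `C_inf` (and `unstable = TRUE`
#'   instead when `a < 0`).
#' @export
far_field_limits <- function(a, nu, Gamma, r_bar) {
  if (a < 0)
    return(list(unstable = TRUE,
                note = "a < 0: overlap ceases and the perturbation escapes"))
  list(A_inf = a,
       B_inf = nu^2 * a^2 / (8 * r_bar^(3 / 2)) -
         (r_bar^2 - 1) * a^2 / (2 * sqrt(r_bar)) +
         Gamma * nu * a * r_bar / (4 * (1 + r_bar^4)),
       C_inf = Gamma * nu * a * r_bar^(5 / 2) / (2 * (1 + r_bar^4)))
}

#' Late-time perturbation solution
#'
#' Closed-form solution over the late time `T = eps t`:
#' `A(T) = a / (4 a nu sqrt(r_bar) ((r_bar^2 - 1)/(r_bar^2 + 1)) T + 1)`,
#' `B(T) = ((nu^2 + 4 r_bar (1 - r_bar^2)) / (8 r_bar^(3/2))) A^2
#'  + (Gamma nu r_bar / (4 (r_bar^4 + 1))) A`,
#' `C(T) = (Gamma nu r_bar^(5/2) / (2 (r_bar^4 + 1))) A`.
#' For long cells (`r_bar > 1`, `a > 0`) all three decay to zero
#' algebraically; for wide cells (`r_bar < 1`) the denominator vanishes at
#' a finite positive time and the perturbation blows up -- evaluation at or
#' beyond the pole is an error reporting its location (see `pole_time`).
#'
#' @param T_slow Late time value(s) `>= 0`; vectorised.
#' @param a Orientation amplitude (`> 0`).
#' @inheritParams early_time_rhs
#' @return List of vectors `A`, `B`, `C` plus `pole_time` (`Inf` for
#'   `r_bar >= 1`).
#' @export
late_time_solution <- function(T_slow, a, nu, Gamma, r_bar) {
  stopifnot(a > 0)
  .check_r_not_one(r_bar, "late_time_solution")
  k <- 4 * a * nu * sqrt(r_bar) * (r_bar^2 - 1) / (r_bar^2 + 1)
  pole <- if (k < 0) -1 / k else Inf
  if (any(T_slow >= pole))
    stop("late-time solution has a finite-time pole at T = ", signif(pole, 8),
         " for r_bar < 1; cannot evaluate at or beyond it", call. = FALSE)
  A <- a / (k * T_slow + 1)
  list(A = A,
       B = (nu^2 + 4 * r_bar * (1 - r_bar^2)) / (8 * r_bar^(3 / 2)) * A^2 +
         Gamma * nu * r_bar / (4 * (r_bar^4 + 1)) * A,
       C = Gamma * nu * r_bar^(5 / 2) / (2 * (r_bar^4 + 1)) * A,
       pole_time = pole)
}

#' Uniformly valid composite perturbation solution
#'
#' Additive composite of the early- and late-time solutions minus their
#' common matching part:
#' `alpha(t) ~ eps * A_late(eps t)` (independent of the shape parameter),
#' `y(t) + 1/sqrt(r_bar) ~ eps^2 Bhat(t/eps) + eps^2 B_late(eps t)
#'  - eps^2 ((nu^2 + 4 r_bar - 4 r_bar^3)/(8 r_bar^(3/2))) a^2
#'  - eps gamma nu r_bar a / (4 (r_bar^4 + 1))`, and analogously for
#' `r(t) - r_bar` (with `gamma = eps Gamma`).  The early-time functions
#' `Bhat`, `Chat` are obtained numerically via [solve_early_time()].
#'
#' @param t Time value(s) `>= 0`; vectorised.
#' @param spec A [perturbation_spec()] with `a > 0`.
#' @param params A [model_params()] providing `nu` and `r_bar > 1`
#'   (`params$gamma` is ignored in favour of `eps * Gamma`).
#' @param early Optional precomputed result of [solve_early_time()] (reused
#'   across calls; must match `spec`).
#' @return A data.frame with columns `t, alpha, y, r`.
#' @export
composite_solution <- function(t, spec, params, early = NULL) {
  stopifnot(inherits(spec, "cellign_perturbation"),
            inherits(params, "cellign_params"))
  if (spec$a <= 0) stop("composite solution requires a > 0", call. = FALSE)
  if (params$r_bar <= 1) stop("composite solution requires r_bar > 1", call. = FALSE)
  eps <- spec$eps; a <- spec$a; Gamma <- spec$Gamma
  nu <- params$nu; rb <- params$r_bar
  gamma <- eps * Gamma
  if (is.null(early))
    early <- solve_early_time(a, spec$b, spec$c, nu, Gamma, rb,
                              tau_max = max(t) / eps + 1)
  lt <- late_time_solution(eps * t, a, nu, Gamma, rb)
  common_B <- (nu^2 + 4 * rb - 4 * rb^3) / (8 * rb^(3 / 2)) * a^2
  y <- -1 / sqrt(rb) + eps^2 * early$B_fun(t / eps) + eps^2 * lt$B -
    eps^2 * common_B - eps * gamma * nu * rb * a / (4 * (rb^4 + 1))
  r <- rb + eps^2 * early$C_fun(t / eps) + eps^2 * lt$C -
    eps * gamma * nu * rb^(5 / 2) * a / (2 * (rb^4 + 1))
  data.frame(t = t, alpha = eps * lt$A, y = y, r = r)
}

#' Rigid sublimit of the perturbation analysis
#'
#' The `Gamma -> 0` limit: `Chat == 0`, the early-time system reduces to
#' `dBhat/dtau = nu a - 2 sqrt(r) sqrt((r^2 - 1) a^2 + 2 sqrt(r) Bhat)`,
#' and the late-time closed forms become
#' `A_late(T) = a (r^2 + 1) / (4 a nu sqrt(r) (r^2 - 1) T + r^2 + 1)` and
#' `B_late(T) = ((nu^2 + 4 r - 4 r^3) / (8 r^(3/2))) A_late(T)^2`.
#'
#' @param a Orientation amplitude (`> 0` for the decaying branch).
#' @param nu Self-propulsion strength.
#' @param r_bar Preferred (= fixed) aspect ratio `> 1`.
#' @return List with `A_early` (constant `a`), `dB_early(Bhat)` (the
#'   early-time derivative function), and closed-form functions
#'   `A_late(T)`, `B_late(T)`.
#' @export
rigid_sublimit_solutions <- function(a, nu, r_bar) {
  if (r_bar <= 1) stop("rigid sublimit requires r_bar > 1", call. = FALSE)
  r <- r_bar
  A_late <- function(T)
    a * (r^2 + 1) / (4 * a * nu * sqrt(r) * (r^2 - 1) * T + r^2 + 1)
  list(A_early = a,
       dB_early = function(Bhat) {
         D <- (r^2 - 1) * a^2 + 2 * sqrt(r) * Bhat
         nu * a - 2 * sqrt(r) * (if (D > 0) sqrt(D) else 0)
       },
       A_late = A_late,
       B_late = function(T)
         (nu^2 + 4 * r - 4 * r^3) / (8 * r^(3 / 2)) * A_late(T)^2)
}

# ---------------------------------------------------------------------------
# Small-nu slow manifold: for 0 < nu << 1 the dynamics after the fast
# (nu = 0) arrival are confined to the A-B boundary gamma_1^2(alpha) = y^2
# and evolve over the slow time tau = nu (t - T).

#' Slow-manifold vector field on the A-B boundary
#'
#' Leading-order slow-time derivatives of `s0 = sin(alpha)` and `Y0 = y`
#' constrained to `gamma_1^2(alpha) = y^2`:
#' `ds0/dtau = 4 r (r^2-1) Y0 s0^2 (1 - s0^2) / (4 (r^2-1)^2 s0^2 (1 -
#' s0^2) + r (r^2+1) Y0^2)` and the analogous `dY0/dtau` with numerator
#' `4 (r^2-1)^2 s0^3 (1 - s0^2)`.  The denominator cannot vanish for
#' `Y0 != 0`; the flow preserves the constraint.
#'
#' @param s0 `sin` of the leading-order orientation, in `[0, 1]`.
#' @param Y0 Leading-order `y < 0`.
#' @param r Aspect ratio `> 1`.
#' @return Named vector `(ds0, dY0)`.
#' @export
slow_manifold_rhs <- function(s0, Y0, r) {
  .check_nu0_args(r)
  if (s0 < 0 || s0 > 1) stop("s0 must lie in [0, 1]", call. = FALSE)
  den <- 4 * (r^2 - 1)^2 * s0^2 * (1 - s0^2) + r * (r^2 + 1) * Y0^2
  c(ds0 = 4 * r * (r^2 - 1) * Y0 * s0^2 * (1 - s0^2) / den,
    dY0 = 4 * (r^2 - 1)^2 * s0^3 * (1 - s0^2) / den)
}

#' Reduced single slow-manifold ODE
#'
#' [slow_manifold_rhs()] with the constraint solved as
#' `Y0 = -sqrt((r^2 - 1) s0^2 + 1) / sqrt(r)`:
#' `ds0/dtau = -4 sqrt(r) (r^2-1) sqrt((r^2-1) s0^2 + 1) s0^2 (1 - s0^2) /
#' (4 (r^2-1)^2 s0^2 (1-s0^2) + (r^2+1)(r^2-1) s0^2 + r^2 + 1)`,
#' strictly negative on `(0, 1)`: the slow drift always moves toward
#' perfect alignment.
#'
#' @param s0 `sin` of the orientation, in `(0, 1)`; vectorised.
#' @param r Aspect ratio `> 1`.
#' @return `ds0/dtau` (negative).
#' @export
slow_manifold_single_ode <- function(s0, r) {
  .check_nu0_args(r)
  if (any(s0 < 0) || any(s0 > 1)) stop("s0 must lie in [0, 1]", call. = FALSE)
  -4 * sqrt(r) * (r^2 - 1) * sqrt((r^2 - 1) * s0^2 + 1) * s0^2 * (1 - s0^2) /
    (4 * (r^2 - 1)^2 * s0^2 * (1 - s0^2) + (r^2 + 1) * (r^2 - 1) * s0^2 +
       r^2 + 1)
}

#' Slow time to drift between two orientations on the slow manifold
#'
#' Separating variables in the reduced ODE gives
#' `tau = I / (4 sqrt(r) (r^2 - 1))` with
#' `I = int_{s_to}^{s_from} (4 (r^2-1)^2 s^2 (1-s^2) + (r^2+1)(r^2-1) s^2 +
#' r^2 + 1) / (s^2 (1 - s^2) sqrt((r^2-1) s^2 + 1)) ds`.
#' As `s_to -> 0` the integrand behaves like `(r^2 + 1)/s^2`, so
#' `tau ~ (r^2 + 1) / (4 sqrt(r) (r^2 - 1) s_to)` diverges: perfect
#' alignment is only reached in infinite (slow) time, which is why
#' `s_to = 0` is rejected.
#'
#' @param s_from,s_to Orientation range `0 < s_to <= s_from < 1`.
#' @param r Aspect ratio `> 1`.
#' @param rel.tol Quadrature relative tolerance.
#' @return Slow time `tau >= 0`.
#' @export
slow_manifold_time <- function(s_from, s_to, r, rel.tol = 1e-10) {
  .check_nu0_args(r)
  if (s_to <= 0)
    stop("s_to = 0: the slow drift reaches perfect alignment only in ",
         "infinite time (tau ~ (r^2+1)/(4 sqrt(r) (r^2-1) s_to))",
         call. = FALSE)
  stopifnot(s_to <= s_from, s_from < 1)
  if (s_to == s_from) return(0)
  integrand <- function(s) {
    (4 * (r^2 - 1)^2 * s^2 * (1 - s^2) + (r^2 + 1) * (r^2 - 1) * s^2 +
       r^2 + 1) / (s^2 * (1 - s^2) * sqrt((r^2 - 1) * s^2 + 1))
  }
  I <- stats::integrate(integrand, s_to, s_from, rel.tol = rel.tol,
                        abs.tol = 0, subdivisions = 400L)$value
  I / (4 * sqrt(r) * (r^2 - 1))
}

#' Solve the reduced slow-manifold ODE
#'
#' Integrates [slow_manifold_single_ode()] from `s_init` over the slow time
#' `tau` in `[0, tau_end]`.
#'
#' @param s_init Initial `s0` in `(0, 1)`.
#' @param r Aspect ratio `> 1`.
#' @param tau_end Slow-time horizon.
#' @param n_save Number of saved points.
#' @return A data.frame with columns `tau, s0, Y0`.
#' @export
solve_slow_manifold <- function(s_init, r, tau_end, n_save = 400L) {
  func <- function(t, s, p) list(slow_manifold_single_ode(min(max(s[1], 0), 1), r))
  times <- seq(0, tau_end, length.out = n_save + 1L)
  out <- deSolve::lsoda(c(s0 = s_init), times, func, NULL,
                        rtol = 1e-10, atol = 1e-12)
  s0 <- pmin(pmax(out[, "s0"], 0), 1)
  data.frame(tau = out[, "time"], s0 = s0,
             Y0 = -sqrt((r^2 - 1) * s0^2 + 1) / sqrt(r))
}
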