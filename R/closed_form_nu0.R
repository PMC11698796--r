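# Closed-form results for the rigid zero-propulsion system (nu = 0, r > 1
# fixed).  Without self-propulsion, overlap avoidance is the only driver:
# region A is a continuum of stationary points, region-C starts cross into
# region B in finite time and never return, and region-B arcs follow an
# explicit curve y(alpha) until they stop on the A-B boundary in finite
# time.

.check_nu0_args <- function(r) {
  .check_r_not_one(r, "the nu = 0 closed forms")
  if (r < 1)
    stop("the nu = 0 closed forms require r > 1 (long cells)", call. = FALSE)
  invisible(r)
}

#' Closed-form region-B trajectory curve for nu = 0
#'
#' Along region-B arcs of the zero-propulsion rigid system the orbit is the
#' explicit curve (negative branch)
#' `y(alpha) = -sqrt(y0^2 + (1/(2r)) ((r^2+1)/(r^2-1))
#'   log( cos(alpha)^(r^2) sin(alpha0) / (sin(alpha) cos(alpha0)^(r^2)) ))`.
#'
#' @param alpha Query orientation(s) in `(0, pi/2)`; vectorised.
#' @param alpha0,y0 Initial condition with `y0 < 0`, `alpha0` in `(0, pi/2)`.
#' @param r Fixed aspect ratio `> 1`.
#' @return `y(alpha)` (negative).  Errors if `alpha` lies outside the curve
#'   (negative radicand) or at the log singularities `0, pi/2`.
#' @export
trajectory_curve_nu0 <- function(alpha, alpha0, y0, r) {
  .check_nu0_args(r)
  stopifnot(y0 < 0)
  if (any(alpha <= 0) || any(alpha >= pi / 2) || alpha0 <= 0 || alpha0 >= pi / 2)
    stop("alpha and alpha0 must lie strictly inside (0, pi/2) (log singularity)",
         call. = FALSE)
  rad <- y0^2 + (1 / (2 * r)) * (r^2 + 1) / (r^2 - 1) *
    (r^2 * log(cos(alpha)) - log(sin(alpha)) +
       log(sin(alpha0)) - r^2 * log(cos(alpha0)))
  if (any(rad < -1e-12))
    stop("alpha outside the trajectory curve (negative radicand)", call. = FALSE)
  -sqrt(pmax(rad, 0))
}

# log of the A-B arrival function h(s) = s (1-s^2)^(-r^2/2)
#   * exp(2 (r^2-1)^2/(r^2+1) s^2); strictly increasing on [0, 1).
.log_h_AB <- function(s, r) {
  log(s) - (r^2 / 2) * log1p(-s^2) + 2 * (r^2 - 1)^2 / (r^2 + 1) * s^2
}

# log of the B-C boundary function f(s) = s (1-s^2)^(-r^2/2)
#   * exp(2 (r^2-1)^3 s^2 (1-s^2) / ((r^2+1)(s^2 + r^2 (1-s^2)))).
.log_f_BC <- function(s, r) {
  log(s) - (r^2 / 2) * log1p(-s^2) +
    2 * (r^2 - 1)^3 * s^2 * (1 - s^2) /
      ((r^2 + 1) * (s^2 + r^2 * (1 - s^2)))
}

# Bracketed monotone root solve of logfun(s) = target on (0, 1).
.mono_root <- function(logfun, target, r, tol = 1e-14) {
  lo <- 1e-300; hi <- 1 - 1e-12
  flo <- logfun(lo, r) - target
  fhi <- logfun(hi, r) - target
  if (flo > 0 || fhi < 0)
    stop("internal error: failed to bracket the monotone root ",
         "(contradicts strict monotonicity)", call. = FALSE)
  stats::uniroot(function(s) logfun(s, r) - target, c(lo, hi),
                 f.lower = flo, f.upper = fhi, tol = tol)$root
}

#' Final orientation of a zero-propulsion interaction
#'
#' A region-B (or region-C) start of the nu = 0 rigid system stops on the
#' A-B boundary at orientation `alpha_T = arcsin(s_T)`, where `s_T` is the
#' unique root in `[0, 1)` of the strictly increasing function
#' `h(s) = s (1-s^2)^(-r^2/2) exp(2 (r^2-1)^2 s^2 / (r^2+1))` equated to
#' `(sin(alpha0)/cos(alpha0)^(r^2)) exp(2 ((r^2-1)/(r^2+1)) (r y0^2 - 1))`.
#' (The factor `r y0^2` follows from substituting `y^2 = gamma_1^2` into the
#' trajectory curve.)  Starts already on the A-B boundary return `alpha0`.
#'
#' @inheritParams trajectory_curve_nu0
#' @return The terminal orientation `alpha_T` in `[0, alpha0]`.
#' @examples
#' final_angle_nu0(pi / 4, -0.3, 2)
#' @export
final_angle_nu0 <- function(alpha0, y0, r) {
  .check_nu0_args(r)
  stopifnot(y0 < 0, alpha0 > 0, alpha0 < pi / 2)
  st <- .nu0_b_start(alpha0, y0, r)
  target <- log(sin(st$alpha0)) - r^2 * log(cos(st$alpha0)) +
    2 * (r^2 - 1) / (r^2 + 1) * (r * st$y0^2 - 1)
  asin(.mono_root(.log_h_AB, target, r))
}

# The closed-form curve holds on region-B arcs.  A region-C start first
# follows the region-C dynamics; advance it numerically to the B-C
# crossing and continue from there (region B is forward-invariant, so the
# crossing point is the start of the closed-form arc).
.nu0_b_start <- function(alpha0, y0, r) {
  g <- gamma_factors(alpha0, r)
  gbc2 <- g$g1sq - 1 / g$g2sq
  # strictly inside region C only; B-C boundary points start the B arc
  if (y0^2 >= gbc2 - 1e-10)
    return(list(alpha0 = alpha0, y0 = y0, t_entry = 0))
  tr <- integrate_trajectory(cell_state(x = 0, y = y0, alpha = alpha0, r = r),
                             model_params(nu = 0, gamma = 0, r_bar = r),
                             t_end = 1e3, mode = "nu0",
                             rtol = 1e-11, atol = 1e-13, n_save = 10L)
  ev <- tr$events
  icross <- which(ev$kind == "BC-crossing")[1]
  if (is.na(icross))
    stop("internal error: region-C start did not produce a B-C crossing",
         call. = FALSE)
  tcross <- ev$time[icross]
  i <- which.min(abs(tr$states$t - tcross))
  list(alpha0 = tr$states$alpha[i], y0 = tr$states$y[i], t_entry = tcross)
}

#' Region-B invariance root (no re-entry into region C)
#'
#' A trajectory launched on the B-C boundary satisfies `f(s) = f(sin
#' alpha0)` with the strictly increasing function `f`; the unique root is
#' the initial condition itself, which is the closed-form statement that
#' region B is forward-invariant for nu = 0 (a trajectory that leaves
#' region C can never re-enter it).
#'
#' @param alpha0 Initial orientation in `(0, pi/2)` on the B-C boundary.
#' @param r Fixed aspect ratio `> 1`.
#' @return The root `s_sol` (numerically equal to `sin(alpha0)`).
#' @export
bc_no_reentry_root <- function(alpha0, r) {
  .check_nu0_args(r)
  stopifnot(alpha0 > 0, alpha0 < pi / 2)
  .mono_root(.log_f_BC, .log_f_BC(sin(alpha0), r), r)
}

#' Finite interaction time of a zero-propulsion region-B start
#'
#' The arrival time at the A-B boundary follows from separating variables
#' in the orientation equation along the closed-form curve:
#' `T = ((r^2+1) / (8 (r^2-1))) * J` with
#' `J = int_{alpha_T}^{alpha_0} gamma_1^4 /
#'   (|y| sin(alpha) cos(alpha) sqrt(gamma_1^2 - y^2)) d alpha`.
#' The integrand has an integrable inverse-square-root singularity at
#' `alpha_T`, removed by the substitution `alpha = alpha_T + u^2` before
#' adaptive quadrature.
#'
#' @inheritParams trajectory_curve_nu0
#' @param rel.tol Quadrature relative tolerance.
#' @return Arrival time `T >= 0`.
#' @examples
#' interaction_time_nu0(pi / 4, -0.3, 2)
#' @export
interaction_time_nu0 <- function(alpha0, y0, r, rel.tol = 1e-10) {
  .check_nu0_args(r)
  stopifnot(y0 < 0, alpha0 > 0, alpha0 < pi / 2)
  st <- .nu0_b_start(alpha0, y0, r)
  alpha0 <- st$alpha0; y0 <- st$y0
  aT <- final_angle_nu0(alpha0, y0, r)
  if (aT >= alpha0 - 1e-14) return(st$t_entry)
  integrand <- function(u) {
    a <- aT + u^2
    y <- trajectory_curve_nu0(a, alpha0, y0, r)
    g1sq <- gamma_factors(a, r)$g1sq
    rad <- pmax(g1sq - y^2, 0)
    # g = -gamma_1^4 / (y sc sqrt(rad)) > 0 since y < 0; times dalpha = 2u du
    -g1sq^2 / (y * sin(a) * cos(a) * sqrt(rad)) * 2 * u
  }
  J <- tryCatch(
    stats::integrate(integrand, 0, sqrt(alpha0 - aT),
                     rel.tol = rel.tol, abs.tol = 0,
                     subdivisions = 400L)$value,
    error = function(e)
      stop("quadrature failed between alpha_T = ", signif(aT, 8),
           " and alpha0 = ", signif(alpha0, 8), ": ", conditionMessage(e),
           call. = FALSE))
  st$t_entry + (r^2 + 1) / (8 * (r^2 - 1)) * J
}
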