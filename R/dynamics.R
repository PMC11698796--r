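# Piecewise-smooth governing equations of the symmetric two-cell system and
# event-aware trajectory integration.
#
# The right-hand side switches between three branches according to the
# overlap region (A: none, B: two intersection points, C: four).  The
# branches join continuously across both boundaries: the region-B overlap
# terms vanish as y^2 -> Gamma_AB^2, and at y^2 = Gamma_BC^2 the B and C
# branches agree via the identity gamma_1^2 - Gamma_BC^2 = 1/gamma_2^2.

# sign(.) with the convention sign(0) = +1 (y = 0 is only reachable while
# crossing between half-planes inside region C).
.sign1 <- function(v) ifelse(v >= 0, 1, -1)

# Branch-explicit right-hand side.  Returns c(dx, dy, dalpha, dr).
# `region` forces a branch (used by continuity checks); `mode` selects the
# full deformable system, the rigid limit (dr = 0) or the rigid nu = 0 case.
.rhs_core <- function(alpha, y, r, nu, gamma, r_bar, region, mode) {
  s <- sin(alpha); cc <- cos(alpha); sc <- s * cc
  g1sq <- r * s^2 + cc^2 / r
  dx <- nu * cc
  dy_ov <- 0; da <- 0; dr_ov <- 0
  if (region != "A") {
    if (r == 1)
      stop("degenerate geometry: r = 1 in overlap region ", region,
           " (division by r^2 - 1)", call. = FALSE)
    if (region == "B") {
      u <- g1sq - y^2
      if (u < -1e-12)
        stop("internal-consistency error: negative region-B radicand ",
             u, call. = FALSE)
      # float noise within the boundary tie band evaluates to exactly 0
      rt <- if (u < 1e-12) 0 else sqrt(u)
      dy_ov <- 2 * rt * .sign1(y) / g1sq
      da <- -8 * (r^2 - 1) / (r^2 + 1) * sc * rt * abs(y) / g1sq^2
      dr_ov <- 16 * r / (r^2 + 1) * (cc^2 - r^2 * s^2) * rt * abs(y) / g1sq^2
    } else {  # region C
      g2sq <- s^2 / r + r * cc^2
      dy_ov <- 2 * r * y / (g1sq * abs((r^2 - 1) * sc))
      da <- 4 * r * .sign1((r - 1) * sc) / (r^2 + 1) *
        (y^2 * (((r^2 - 1) / r)^2 * sc^2 / g1sq^2 -
                  (r / (r^2 - 1))^2 * (g2sq^2 - 1) / sc^2 -
                  1 / g1sq^2) +
           (g2sq - g1sq) / (g1sq * g2sq))
      # dr assembled from dalpha and the overlap part of dy (= ydot - nu sin a);
      # the (cos^2 - sin^2) factor is fixed by continuity with the region-B
      # branch at the B-C boundary, where the inner intersection pair merges
      dr_ov <- 4 * r * sc * da +
        8 * r^2 * y * dy_ov / (1 + r^2) * (cc^2 - s^2)
    }
  }
  dr <- if (mode == "full") {
    -(16 / gamma) * (1 + r_bar * r^3) / (r_bar * (r^2 + 1)) * (r - r_bar) + dr_ov
  } else 0
  c(dx = dx, dy = nu * s + dy_ov, dalpha = da, dr = dr)
}

#' Evaluate one branch of the governing equations
#'
#' Low-level access to the piecewise right-hand side with the region branch
#' forced, independent of where the state actually lies.  Intended for
#' checking continuity of the vector field across the region boundaries;
#' normal integration classifies the region automatically.
#'
#' @param alpha,y,r State components.
#' @param params A [model_params()].
#' @param region Branch to evaluate: `"A"`, `"B"` or `"C"`.
#' @param mode `"full"` (deformable), `"rigid"` or `"nu0"`.
#' @return Named vector `(dx, dy, dalpha, dr)`.
#' @export
rhs_branch <- function(alpha, y, r, params, region = c("A", "B", "C"),
                       mode = c("full", "rigid", "nu0")) {
  stopifnot(inherits(params, "cellign_params"))
  region <- match.arg(region)
  mode <- match.arg(mode)
  nu <- if (mode == "nu0") 0 else params$nu
  .rhs_core(alpha, y, r, nu, params$gamma, params$r_bar, region, mode)
}

#' Full deformable right-hand side
#'
#' Time derivatives `(dx, dy, dalpha, dr)` of the three-variable (plus
#' decoupled `x`) deformable two-cell system, with the branch chosen by
#' [classify_region()].  The aspect-ratio equation always contains the
#' restoration term `-(16/gamma) (1 + r_bar r^3) / (r_bar (r^2+1)) (r -
#' r_bar)`; in region C `dr` is assembled from the already-computed `dalpha`
#' and the overlap part of `dy`.
#'
#' @param state A [cell_state()].
#' @param params A [model_params()] with `gamma > 0`.
#' @return Named numeric vector `(dx, dy, dalpha, dr)`.
#' @examples
#' p <- model_params(nu = 1, gamma = 1, r_bar = 2)
#' rhs_full(cell_state(y = -2, alpha = 0.3, r = 2), p)  # region A: no overlap
#' @export
rhs_full <- function(state, params) {
  stopifnot(inherits(state, "cellign_state"), inherits(params, "cellign_params"))
  if (params$gamma == 0)
    stop("gamma = 0 means rigid cells: the restoration term is replaced by ",
         "the constraint r == r_bar; use rhs_rigid()", call. = FALSE)
  reg <- .classify(state$alpha, state$y, state$r)
  .rhs_core(state$alpha, state$y, state$r, params$nu, params$gamma,
            params$r_bar, reg, "full")
}

#' Rigid-cell right-hand side
#'
#' The `gamma -> 0` limit: cells restore their preferred aspect ratio
#' instantly, so `r == r_bar` and the system reduces to two variables
#' `(alpha, y)` (plus decoupled `x`).  Identical to the `dy`, `dalpha`
#' branches of [rhs_full()] with `r = r_bar` and `dr` suppressed.
#'
#' @param alpha,y State components of cell 1.
#' @param params A [model_params()]; `r_bar > 1` expected ("long" cells) --
#'   `r_bar < 1` is accepted with a warning, `r_bar = 1` is a degeneracy
#'   error.
#' @return Named numeric vector `(dy, dalpha)`.
#' @export
rhs_rigid <- function(alpha, y, params) {
  stopifnot(inherits(params, "cellign_params"))
  .check_r_not_one(params$r_bar, "rhs_rigid")
  if (params$r_bar < 1)
    warning("rhs_rigid: r_bar < 1 (wide cells); the rigid analysis assumes long cells",
            call. = FALSE)
  reg <- .classify(alpha, y, params$r_bar)
  d <- .rhs_core(alpha, y, params$r_bar, params$nu, 0, params$r_bar, reg, "rigid")
  d[c("dy", "dalpha")]
}

#' Zero-propulsion rigid right-hand side
#'
#' [rhs_rigid()] with `nu = 0`: overlap avoidance is the only driver, so the
#' derivatives vanish identically throughout region A and on the A-B
#' boundary (a line of stationary points).
#'
#' @param alpha,y State components of cell 1.
#' @param r Fixed aspect ratio, `> 1`.
#' @return Named numeric vector `(dy, dalpha)`.
#' @export
rhs_nu0 <- function(alpha, y, r) {
  .check_r_not_one(r, "rhs_nu0")
  if (r < 1)
    warning("rhs_nu0: r < 1 (wide cells); the zero-propulsion analysis assumes r > 1",
            call. = FALSE)
  reg <- .classify(alpha, y, r)
  d <- .rhs_core(alpha, y, r, 0, 0, r, reg, "nu0")
  d[c("dy", "dalpha")]
}

# ---------------------------------------------------------------------------
# Event-aware integration

.GBC2 <- function(alpha, r) {
  g <- gamma_factors(alpha, r)
  g$g1sq - 1 / g$g2sq
}

#' Integrate a two-cell trajectory with region-boundary event handling
#'
#' Adaptive (stiff-capable, [deSolve::lsodar()]) integration of the
#' piecewise governing equations.  Root functions on `y^2 - Gamma_AB^2` and
#' `y^2 - Gamma_BC^2` resolve every region-boundary crossing; integration is
#' restarted at each resolved root so branch switches never happen mid-step.
#'
#' Termination policy (`terminate = TRUE`, forward runs):
#' * `mode = "nu0"` (or `nu = 0`): stop when the state reaches the A-B
#'   boundary, where the right-hand side vanishes (event
#'   `"terminated-stationary"`).  The boundary is approached tangentially,
#'   so the stop is root-resolved on `gamma_1^2 - y^2 = delta` with
#'   `delta = 1e-12` and the remaining arrival time (O(sqrt(delta)))
#'   added analytically.
#' * `nu > 0`: stop when the state is in region A with
#'   `sign(y) * sin(alpha) > 0` -- cell 1 beyond its partner and heading
#'   away, so by straight-line region-A motion it can never re-enter overlap
#'   (`"terminated-separating"`); or when the orientation has converged to
#'   the half-stable alignment point, `|alpha| < tol_align` while still
#'   interacting (`"terminated-stationary"`; the exact state is only reached
#'   in infinite time).
#'
#' @param state0 Initial [cell_state()].
#' @param params A [model_params()].
#' @param t_end Time horizon (duration for backward runs), `> 0`.
#' @param mode `"full"` (deformable; needs `gamma > 0`), `"rigid"` or
#'   `"nu0"`.  Rigid modes hold `r` fixed.
#' @param direction `"forward"` or `"backward"` (backward integration is
#'   used for separatrix computation; no termination policy is applied).
#' @param rtol,atol Integrator tolerances.
#' @param tol_align Orientation tolerance declaring convergence to the
#'   aligned state.
#' @param terminate Apply the termination policy? Set `FALSE` to record the
#'   full time span regardless.
#' @param n_save Approximate number of saved states on `[0, t_end]`
#'   (crossing times are always saved).
#' @param max_events Safety cap on boundary events.
#' @return An object of class `cellign_trajectory`: list with `states`
#'   (data.frame `t, x, y, alpha, r`), `regions` (per saved state),
#'   `events` (data.frame `time, kind` with kind in `AB-crossing`,
#'   `BC-crossing`, `terminated-stationary`, `terminated-separating`,
#'   `t_end`), and the run metadata.
#' @examples
#' p <- model_params(nu = 2, gamma = 0, r_bar = 2)
#' tr <- integrate_trajectory(cell_state(y = -0.6, alpha = 0.5, r = 2), p,
#'                            t_end = 50, mode = "rigid")
#' tail(tr$states)
#' @export
integrate_trajectory <- function(state0, params, t_end,
                                 mode = c("full", "rigid", "nu0"),
                                 direction = c("forward", "backward"),
                                 rtol = 1e-9, atol = 1e-11,
                                 tol_align = 1e-4,
                                 terminate = TRUE,
                                 n_save = 200L, max_events = 1000L) {
  stopifnot(inherits(state0, "cellign_state"), inherits(params, "cellign_params"),
            is.numeric(t_end), t_end > 0)
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "full" && params$gamma == 0)
    stop("mode = 'full' requires gamma > 0; use mode = 'rigid'", call. = FALSE)
  r_fix <- switch(mode, full = NA_real_, rigid = params$r_bar, nu0 = state0$r)
  if (mode == "rigid" && abs(state0$r - params$r_bar) > 1e-12)
    warning("mode = 'rigid' holds r = r_bar; initial r ignored", call. = FALSE)
  if (mode != "full") .check_r_not_one(r_fix, paste0("mode '", mode, "'"))
  nu_eff <- if (mode == "nu0") 0 else params$nu
  dirsgn <- if (direction == "forward") 1 else -1
  if (direction == "backward") terminate <- FALSE

  y0 <- c(x = state0$x, y = state0$y, alpha = state0$alpha,
          r = if (mode == "full") state0$r else r_fix)

  func <- function(t, s, p) {
    d <- .rhs_core(s[["alpha"]], s[["y"]], s[["r"]], nu_eff, params$gamma,
                   params$r_bar, .classify(s[["alpha"]], s[["y"]], s[["r"]]),
                   mode)
    if (mode != "full") d[["dr"]] <- 0
    list(dirsgn * d)
  }
  rootfun <- function(t, s, p) {
    g <- gamma_factors(s[["alpha"]], s[["r"]])
    # small deadband on the A-B event: trajectories sliding along the
    # boundary graze it at the integration-noise level, which would fire
    # the root at every step; a genuine exit into region A crosses the
    # offset immediately (the branch switch itself is classification-based
    # and unaffected)
    g1 <- s[["y"]]^2 - g$g1sq - 1e-8
    g2 <- s[["y"]]^2 - (g$g1sq - 1 / g$g2sq)
    g3 <- if (nu_eff == 0) (g$g1sq - s[["y"]]^2) - 1e-12
          else abs(s[["alpha"]]) - tol_align
    c(g1, g2, g3)
  }

  grid <- seq(0, t_end, length.out = max(n_save, 2L) + 1L)
  rows <- list(); ev_t <- numeric(0); ev_k <- character(0)
  push_rows <- function(m) rows[[length(rows) + 1L]] <<- m
  t0 <- 0; s0 <- y0; done <- FALSE; final_kind <- NULL; final_time <- NA_real_
  last_root <- -Inf; stuck <- 0L

  check_immediate <- function(t0, s0) {
    # returns terminal kind or NULL
    if (!terminate) return(NULL)
    al <- s0[["alpha"]]; yy <- s0[["y"]]; rr <- s0[["r"]]
    reg <- .classify(al, yy, rr)
    if (nu_eff == 0) {
      g <- gamma_factors(al, rr)
      if (reg == "A" || g$g1sq - yy^2 <= 1e-11) return("terminated-stationary")
    } else {
      g1sq <- gamma_factors(al, rr)$g1sq
      # in A, or on the A-B boundary moving outward, with cell 1 past its
      # partner and heading away: straight-line motion, never re-enters
      if ((reg == "A" || yy^2 >= g1sq - 1e-11) &&
          .sign1(yy) * sin(al) > 0 && sin(al) != 0)
        return("terminated-separating")
      if (abs(al) < tol_align && yy^2 <= gamma_factors(al, rr)$g1sq + 1e-12 &&
          .sign1(yy) * sin(al) <= 0)
        return("terminated-stationary")
    }
    NULL
  }

  repeat {
    k <- check_immediate(t0, s0)
    if (!is.null(k)) {
      final_kind <- k; final_time <- t0
      push_rows(matrix(c(t0, s0), nrow = 1,
                       dimnames = list(NULL, c("time", names(s0)))))
      done <- TRUE
    }
    if (done) break
    # region-A motion of the rigid system is exactly linear (alpha frozen,
    # y drifting at nu sin alpha): advance it in closed form -- the
    # adaptive integrator would otherwise grow its steps so large that the
    # brief re-entry window of the boundary root can be stepped over
    if (mode != "full") {
      al <- s0[["alpha"]]; yy <- s0[["y"]]; rr <- s0[["r"]]
      g1s <- gamma_factors(al, rr)$g1sq
      if (yy^2 > g1s + 1e-12) {
        vy <- dirsgn * nu_eff * sin(al)
        y_hit <- .sign1(yy) * sqrt(g1s)
        dt_hit <- if (vy != 0) (y_hit - yy) / vy else Inf
        lin_rows <- function(t_stop, y_stop) {
          tg <- c(grid[grid > t0 + 1e-12 & grid < t_stop], t_stop)
          m <- cbind(time = tg, x = s0[["x"]] +
                       dirsgn * nu_eff * cos(al) * (tg - t0),
                     y = yy + vy * (tg - t0), alpha = al, r = rr)
          m[nrow(m), "y"] <- y_stop
          m
        }
        if (!is.finite(dt_hit) || dt_hit <= 0 || t0 + dt_hit >= t_end) {
          # drifting parallel or away: straight-line motion to the horizon
          t_lin <- t_end
          push_rows(lin_rows(t_lin, yy + vy * (t_lin - t0)))
          final_kind <- "t_end"; final_time <- t_end
          done <- TRUE
          break
        }
        push_rows(lin_rows(t0 + dt_hit, y_hit))
        s0[["x"]] <- s0[["x"]] + dirsgn * nu_eff * cos(al) * dt_hit
        s0[["y"]] <- y_hit
        t0 <- t0 + dt_hit
        ev_t <- c(ev_t, t0); ev_k <- c(ev_k, "AB-crossing")
        next
      }
    }
    times <- c(t0, grid[grid > t0 + 1e-12 * max(1, t_end)])
    if (length(times) < 2L) times <- c(t0, t_end)
    if (times[length(times)] < t_end) times <- c(times, t_end)
    out <- NULL
    for (attempt in 1:5) {
      out <- tryCatch(suppressWarnings(
        deSolve::lsodar(y = s0, times = times, func = func, parms = NULL,
                        rootfunc = rootfun, rtol = rtol, atol = atol,
                        maxsteps = 100000)),
        error = function(e) e)
      if (!inherits(out, "error")) break
      # restart landed on (or within resolution of) a root: nudge forward
      # with one explicit Euler step and try again
      h <- 1e-7 * max(1, abs(t0)) * attempt
      s0 <- s0 + h * func(t0, s0, NULL)[[1]]
      t0 <- t0 + h
      times <- c(t0, times[times > t0])
      if (length(times) < 2L) times <- c(t0, t_end)
    }
    if (inherits(out, "error"))
      stop("integrator failure near t = ", signif(t0, 8), ", state (alpha = ",
           signif(s0[["alpha"]], 6), ", y = ", signif(s0[["y"]], 6), "): ",
           conditionMessage(out), call. = FALSE)
    push_rows(unclass(out))
    troot <- attr(out, "troot")
    iroot <- attr(out, "iroot")
    istate <- attr(out, "istate")[1]
    if (is.null(troot) || length(troot) == 0 || is.na(troot[1]) ||
        is.null(iroot) || !any(iroot != 0)) {
      t_last <- out[nrow(out), "time"]
      if (istate < 0 && t_last < t_end - 1e-10 * max(1, t_end)) {
        # integrator returned early (work limit); results are valid as far
        # as they go -- continue from the last state
        if (t_last <= t0 + 1e-12 * max(1, t_end))
          stop("step-size collapse: no progress past t = ", t_last,
               ", state (alpha = ", signif(out[nrow(out), "alpha"], 6),
               ", y = ", signif(out[nrow(out), "y"], 6), ")", call. = FALSE)
        s0 <- out[nrow(out), c("x", "y", "alpha", "r")]
        names(s0) <- c("x", "y", "alpha", "r")
        t0 <- t_last
        next
      }
      final_kind <- "t_end"; final_time <- t_end
      done <- TRUE
      break
    }
    ind <- which(iroot != 0)
    tr <- troot[1]
    s0 <- out[nrow(out), c("x", "y", "alpha", "r")]
    names(s0) <- c("x", "y", "alpha", "r")
    if (3L %in% ind && terminate) {
      if (nu_eff == 0) {
        # tangential arrival at the A-B boundary: add the analytic remainder
        al <- s0[["alpha"]]; yy <- s0[["y"]]; rr <- s0[["r"]]
        g <- gamma_factors(al, rr)
        u <- max(g$g1sq - yy^2, 0)
        # near the boundary u' = c sqrt(u); the remaining arrival time is
        # 2 sqrt(u)/|c| (the radicand decays linearly in sqrt(u))
        dg1sq <- (rr - 1 / rr) * sin(2 * al)
        cc <- dg1sq * (-8 * (rr^2 - 1) / (rr^2 + 1) * sin(al) * cos(al) *
                         abs(yy) / g$g1sq^2) - 4 * abs(yy) / g$g1sq
        t_arr <- if (cc < 0) tr + 2 * sqrt(u) / abs(cc) else tr
        s0[["y"]] <- .sign1(yy) * sqrt(g$g1sq)
        final_kind <- "terminated-stationary"; final_time <- t_arr
        push_rows(matrix(c(t_arr, s0), nrow = 1,
                         dimnames = list(NULL, c("time", names(s0)))))
        done <- TRUE
      } else {
        al <- s0[["alpha"]]; yy <- s0[["y"]]
        # convergence to the half-stable point: the orientation has dropped
        # to tol_align on the approaching side and outside the deep-overlap
        # sliver (region C near y = 0, from which cells still crawl over)
        gbc2 <- .GBC2(al, s0[["r"]])
        if (yy^2 > gbc2 + 1e-12 && .sign1(yy) * sin(al) <= 0) {
          final_kind <- "terminated-stationary"; final_time <- tr
          done <- TRUE
        }
        # else: grazing of |alpha| = tol_align without convergence; continue
      }
      if (done) break
    }
    for (ii in intersect(ind, c(1L, 2L))) {
      ev_t <- c(ev_t, tr)
      ev_k <- c(ev_k, if (ii == 1L) "AB-crossing" else "BC-crossing")
    }
    if (length(ev_t) > max_events)
      stop("more than ", max_events, " boundary events; step-size collapse ",
           "suspected near the ",
           if (1L %in% ind) "A-B" else "B-C", " boundary at t = ", tr,
           ", state (alpha = ", signif(s0[["alpha"]], 6),
           ", y = ", signif(s0[["y"]], 6), ", r = ", signif(s0[["r"]], 6), ")",
           call. = FALSE)
    if (tr - last_root < 1e-11 * max(1, tr)) {
      stuck <- stuck + 1L
      if (stuck > 50L)
        stop("step-size collapse near a region boundary at t = ", tr,
             ", state (alpha = ", signif(s0[["alpha"]], 6),
             ", y = ", signif(s0[["y"]], 6), ")", call. = FALSE)
      # nudge across the boundary with one tiny Euler step
      h <- 1e-9 * max(1, abs(tr))
      d <- func(tr, s0, NULL)[[1]]
      s0 <- s0 + h * d
      t0 <- tr + h
    } else {
      stuck <- 0L
      t0 <- tr
    }
    last_root <- tr
    if (t0 >= t_end) { final_kind <- "t_end"; final_time <- t_end; done <- TRUE; break }
  }

  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[, "time"]) | c(TRUE, diff(tab[, "time"]) > 0), , drop = FALSE]
  tab <- tab[order(tab[, "time"]), , drop = FALSE]
  tab <- tab[!duplicated(tab[, "time"]), , drop = FALSE]
  states <- data.frame(t = tab[, "time"], x = tab[, "x"], y = tab[, "y"],
                       alpha = tab[, "alpha"], r = tab[, "r"])
  regions <- .classify(states$alpha, states$y, states$r)
  events <- data.frame(time = c(ev_t, final_time),
                       kind = c(ev_k, final_kind),
                       stringsAsFactors = FALSE)
  structure(list(states = states, regions = regions, events = events,
                 mode = mode, direction = direction, params = params,
                 tol_align = tol_align, t_end = t_end),
            class = "cellign_trajectory")
}

#' @export
print.cellign_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Two-cell trajectory (%s, %s): %d states, t in [%g, %g]\n",
              x$mode, x$direction, n, x$states$t[1], x$states$t[n]))
  cat("events:\n"); print(x$events)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Trajectory round trip (CSV + JSON sidecar)

#' Write a trajectory to CSV with a JSON event sidecar
#'
#' The CSV has header `t,x,y,alpha,r,region` at full float precision; events
#' and run metadata (mode, direction, parameters, and optionally a seed and
#' config hash) go to `<path>.json`.
#'
#' @param traj A `cellign_trajectory`.
#' @param path CSV output path.
#' @param seed Optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  stopifnot(inherits(traj, "cellign_trajectory"))
  df <- cbind(traj$states, region = traj$regions)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(mode = traj$mode, direction = traj$direction,
               params = unclass(traj$params), tol_align = traj$tol_align,
               t_end = traj$t_end,
               events = traj$events)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the `.json` sidecar is read alongside).
#' @return A `cellign_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- do.call(model_params, as.list(meta$params))
  ev <- as.data.frame(meta$events)
  structure(list(states = df[, c("t", "x", "y", "alpha", "r")],
                 regions = df$region, events = ev,
                 mode = meta$mode, direction = meta$direction, params = p,
                 tol_align = meta$tol_align, t_end = meta$t_end),
            class = "cellign_trajectory")
}
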