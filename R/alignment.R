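# Steady states, numerical stability probing, separatrix computation,
# final-angle maps and the alignment-strength statistic S_align.

#' Perfect-alignment steady states
#'
#' The side-by-side configurations `(alpha, y, r) = (0, +/- 1/sqrt(r_bar),
#' r_bar)`: both cells at their preferred aspect ratio, parallel, with
#' boundaries just touching.  Each returned state is verified to have
#' `|(dy, dalpha, dr)| < 1e-12` under the governing equations (`dx = nu` is
#' the common drift).
#'
#' @param params A [model_params()].
#' @return A list of two [cell_state()] objects (lower and upper).
#' @examples
#' steady_states(model_params(nu = 1, gamma = 1, r_bar = 2))
#' @export
steady_states <- function(params) {
  stopifnot(inherits(params, "cellign_params"))
  rb <- params$r_bar
  out <- lapply(c(-1, 1), function(sg)
    cell_state(x = 0, y = sg / sqrt(rb), alpha = 0, r = rb))
  for (st in out) {
    d <- if (params$gamma > 0) rhs_full(st, params)
         else c(rhs_rigid(st$alpha, st$y, params), dr = 0)
    if (max(abs(d[c("dy", "dalpha", "dr")])) >= 1e-12)
      stop("internal error: steady-state residual exceeds 1e-12", call. = FALSE)
  }
  out
}

#' Numerically probe the stability of the alignment state
#'
#' Perturbs the steady state `(0, -1/sqrt(r_bar), r_bar)` by `alpha = eps *
#' a` (with `b = c = 0`), integrates the full deformable system and
#' classifies the outcome:
#' * `"decays"`: the orientation decays toward 0 with an algebraic (not
#'   exponential) rate -- the hallmark of the half-stable state for long
#'   cells perturbed with `a > 0`;
#' * `"escapes"`: the state enters region A and the cells separate
#'   (long cells, `a < 0`);
#' * `"turns"`: the orientation grows toward `pi/2` (wide cells,
#'   `r_bar < 1`, head-to-head route);
#' * `"undetermined"`: none of the above within `t_end` (diagnostics
#'   attached).
#'
#' @param params A [model_params()] with `gamma > 0`.
#' @param a Signed orientation perturbation amplitude.
#' @param eps Perturbation scale (default 0.05).
#' @param t_end Integration horizon.
#' @param turn_threshold Orientation declaring the "turns" route.
#' @return List with `classification`, the fitted algebraic constant
#'   `talpha_limit` (tail mean of `t * alpha(t)`, decays only), the
#'   residual ratio `exp_over_alg` of exponential vs algebraic tail fits,
#'   and the `trajectory`.
#' @export
stability_probe <- function(params, a, eps = 0.05, t_end = 2000,
                            turn_threshold = 1) {
  stopifnot(inherits(params, "cellign_params"))
  if (params$gamma <= 0)
    stop("stability_probe uses the full deformable system; gamma > 0 required",
         call. = FALSE)
  st0 <- perturbed_state(perturbation_spec(eps, a, 0, 0,
                                           Gamma = params$gamma / eps),
                         params$r_bar)
  tr <- integrate_trajectory(st0, params, t_end = t_end, mode = "full",
                             rtol = 1e-9, atol = 1e-11, n_save = 400L)
  kinds <- tr$events$kind
  s <- tr$states
  if ("terminated-separating" %in% kinds)
    return(list(classification = "escapes", trajectory = tr))
  if (max(s$alpha) >= turn_threshold)
    return(list(classification = "turns", trajectory = tr))
  tail_idx <- s$t >= max(s$t) / 10 & s$alpha > 0
  if ("terminated-stationary" %in% kinds ||
      (sum(tail_idx) >= 10 && s$alpha[nrow(s)] < eps * abs(a))) {
    tt <- s$t[tail_idx]; aa <- s$alpha[tail_idx]
    # algebraic decay alpha ~ K/t (slope fixed at -1 on log-log) vs
    # exponential decay alpha ~ A exp(-lambda t)
    rss_alg <- sum(stats::lm(log(aa) ~ offset(-log(tt)))$residuals^2)
    rss_exp <- sum(stats::lm(log(aa) ~ tt)$residuals^2)
    n_tail <- max(5L, round(sum(tail_idx) / 10))
    talpha <- mean(utils::tail(tt * aa, n_tail))
    return(list(classification = "decays",
                talpha_limit = talpha,
                exp_over_alg = rss_exp / rss_alg,
                trajectory = tr))
  }
  list(classification = "undetermined", trajectory = tr,
       note = "no decay, escape or turn detected within t_end")
}

#' Post-interaction orientation of a single initial condition
#'
#' Integrates the rigid system forward from `(alpha0, y0)` under the
#' termination policy of [integrate_trajectory()] and reports the final
#' orientation: the angle at the finite-time end of the interaction, or 0
#' when the trajectory has converged to the half-stable alignment point
#' (which is only reached in infinite time, so convergence is declared at
#' `|alpha| < tol_align`).
#'
#' @param alpha0 Initial orientation in `(0, pi/2)`.
#' @param y0 Initial vertical offset in `(-sqrt(r), 0)`.
#' @param params A [model_params()]; `r_bar` is the fixed aspect ratio.
#' @param t_end Horizon; reaching it without classification flags the node
#'   as `"capped"`.
#' @param tol_align Alignment convergence tolerance (reported as 0).
#' @param align_cutoff Orientation below which, on the region-B side, the
#'   trajectory is inside the attracting cone of the half-stable point and
#'   classified aligned without riding the slow slide to `tol_align`; set
#'   to `tol_align` to disable the shortcut.
#' @param rtol,atol Integrator tolerances.
#' @return List with `alpha_final` (in `[0, pi/2]`) and `outcome`
#'   (`"aligned"`, `"separated"` or `"capped"`).
#' @examples
#' p <- model_params(nu = 2, gamma = 0, r_bar = 2)
#' final_angle(0.5, -0.6, p)
#' @export
final_angle <- function(alpha0, y0, params, t_end = 1e4, tol_align = 1e-4,
                        align_cutoff = 0.02, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "cellign_params"))
  mode <- if (params$nu == 0) "nu0" else "rigid"
  # once the orientation has dropped below align_cutoff on the region-B
  # side, the state lies inside the attracting cone of the half-stable
  # point (overlap avoidance dominates propulsion throughout region B at
  # such small angles), so the infinite-time limit alpha -> 0 is already
  # decided; stopping there skips the asymptotic tail of the slide
  cut <- max(align_cutoff, tol_align)
  st0 <- cell_state(x = 0, y = y0, alpha = alpha0, r = params$r_bar)
  tr <- integrate_trajectory(st0, params, t_end = t_end, mode = mode,
                             rtol = rtol, atol = atol, tol_align = cut,
                             n_save = 25L)
  last <- tr$states[nrow(tr$states), ]
  kind <- tr$events$kind[nrow(tr$events)]
  af <- abs(last$alpha)
  if (kind == "t_end") {
    outcome <- "capped"
  } else if (af <= cut * (1 + 1e-9) && kind == "terminated-stationary" &&
             params$nu > 0) {
    # converged to the half-stable point (exact alignment takes infinite time)
    af <- 0
    outcome <- "aligned"
  } else {
    outcome <- "separated"
  }
  list(alpha_final = min(max(af, 0), pi / 2), outcome = outcome,
       t_final = last$t, kind = kind)
}

#' Alignment-strength statistic S_align
#'
#' Normalised double integral of the post-interaction orientation over the
#' initial-condition rectangle `alpha0 in (0, pi/2)`, `y0 in (-sqrt(r), 0)`
#' (cell 1 underneath its partner and moving toward it):
#' `S_align = (1 / ((pi/2) sqrt(r))) * integral integral
#'   ((pi/2 - alpha_final(alpha0, y0)) / (pi/2)) dalpha0 dy0`,
#' discretised by the midpoint rule on a uniform `grid_n x grid_n` grid.
#' `S_align = 1` means every initial condition ends perfectly aligned;
#' `S_align = 0` would mean every interaction ends head-to-head.
#' Never-interacting nodes (region A with the cells already separating)
#' keep `alpha_final = alpha0` and are included, following the literal
#' integration domain.
#'
#' @param params A [model_params()]; the sweep statistic uses the rigid
#'   system with aspect ratio `r_bar`.
#' @param grid_n Grid resolution per axis (`>= 8`).
#' @param t_end,tol_align,rtol,atol Passed to [final_angle()].
#' @param include_noninteracting Include region-A nodes whose cells never
#'   meet (default `TRUE`, the literal domain); `FALSE` restricts the
#'   average to nodes that interact.
#' @return List with `S_align` in `[0, 1]`, `coverage` (fraction of nodes
#'   not capped; a warning is issued if any were), and the per-node `grid`
#'   data.frame (`alpha0, y0, alpha_final, outcome`).
#' @export
alignment_strength <- function(params, grid_n = 20L, t_end = 1e4,
                               tol_align = 1e-4, rtol = 1e-8, atol = 1e-10,
                               include_noninteracting = TRUE) {
  stopifnot(inherits(params, "cellign_params"), grid_n >= 8L)
  r <- params$r_bar
  a_mid <- (seq_len(grid_n) - 0.5) * (pi / 2) / grid_n
  y_mid <- -sqrt(r) + (seq_len(grid_n) - 0.5) * sqrt(r) / grid_n
  grid <- expand.grid(alpha0 = a_mid, y0 = y_mid)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    fa <- final_angle(grid$alpha0[i], grid$y0[i], params, t_end = t_end,
                      tol_align = tol_align, rtol = rtol, atol = atol)
    c(fa$alpha_final, fa$outcome == "capped",
      fa$kind == "terminated-separating" && fa$t_final == 0)
  }, numeric(3))
  grid$alpha_final <- res[1, ]
  grid$capped <- as.logical(res[2, ])
  grid$never_interacted <- as.logical(res[3, ])
  keep <- if (include_noninteracting) rep(TRUE, nrow(grid)) else !grid$never_interacted
  S <- mean((pi / 2 - grid$alpha_final[keep]) / (pi / 2))
  coverage <- 1 - mean(grid$capped)
  if (coverage < 1)
    warning(sprintf("%d of %d grid nodes hit the t_end cap; S_align computed over all nodes",
                    sum(grid$capped), nrow(grid)), call. = FALSE)
  list(S_align = S, coverage = coverage, grid = grid, grid_n = grid_n)
}

# Outcome of one forward run, for separatrix bisection: TRUE if aligned.
.aligned_outcome <- function(alpha0, y0, params, t_end, rtol, atol) {
  fa <- final_angle(alpha0, y0, params, t_end = t_end, tol_align = 1e-4,
                    rtol = rtol, atol = atol)
  fa$outcome == "aligned"
}

#' Separatrix between alignment and crawl-over
#'
#' The rigid system (`r_bar > 1`, `nu > 0`) has two outcomes for initial
#' conditions with `alpha0 in (0, pi/2)`, `y0 < 0`: convergence to the
#' half-stable alignment point, or crawling over the partner cell and
#' separating with `y > 0`.  At each of `n_slices` orientation slices the
#' dividing `y` is bracketed over the whole strip and refined by bisection
#' on the forward-run outcome: the aligned side lies below (more negative
#' `y`), the separated side above.  Slices where the curve has left the
#' strip are trimmed.  A reference trace obtained by backward integration
#' from just off a refined point -- the separatrix is transversally
#' attracting in reverse time -- is attached as `$backward`.
#'
#' @param params A [model_params()] with `nu > 0`, `r_bar > 1`.
#' @param n_slices Number of refined orientation slices (default 10).
#' @param alpha_min,alpha_max Orientation range of the slices.
#' @param bisect_tol Absolute tolerance on the refined `y` values.
#' @param t_end Forward-run horizon used in outcome classification.
#' @param rtol,atol Integrator tolerances for the outcome runs.
#' @param trace_backward Also record the backward-integration trace?
#' @return An object of class `cellign_separatrix`: data.frame `points`
#'   with columns `alpha, y`, ordered by `alpha`.
#' @export
separatrix <- function(params, n_slices = 10L, alpha_min = 0.05,
                       alpha_max = pi / 2 - 0.05, bisect_tol = 1e-6,
                       t_end = 3000, rtol = 1e-8, atol = 1e-10,
                       trace_backward = TRUE) {
  stopifnot(inherits(params, "cellign_params"))
  if (params$nu <= 0 || params$r_bar <= 1)
    stop("separatrix requires nu > 0 and r_bar > 1 (rigid long cells)",
         call. = FALSE)
  r <- params$r_bar
  y_floor <- -sqrt(r) + 1e-6
  y_ceil <- -1e-6
  bisect_y <- function(alpha) {
    y_lo <- y_floor; y_hi <- y_ceil
    a_lo <- .aligned_outcome(alpha, y_lo, params, t_end, rtol, atol)
    a_hi <- .aligned_outcome(alpha, y_hi, params, t_end, rtol, atol)
    if (a_hi)  # whole slice aligned: separatrix above the strip (not seen)
      return(NA_real_)
    if (!a_lo) # whole slice separated: separatrix has left the strip
      return(NA_real_)
    while (y_hi - y_lo > bisect_tol) {
      ym <- (y_lo + y_hi) / 2
      if (.aligned_outcome(alpha, ym, params, t_end, rtol, atol)) y_lo <- ym
      else y_hi <- ym
    }
    (y_lo + y_hi) / 2
  }
  slices <- seq(alpha_min, alpha_max, length.out = n_slices)
  pts <- vapply(slices, bisect_y, numeric(1))
  ok <- !is.na(pts)
  if (sum(ok) < 2L)
    stop("separatrix bisection failed to separate outcomes at the slices ",
         "alpha in [", signif(alpha_min, 4), ", ", signif(alpha_max, 4),
         "]; no dividing curve inside the strip", call. = FALSE)
  poly <- data.frame(alpha = slices[ok], y = pts[ok])
  # reference trace of the dividing trajectory: the separatrix is
  # transversally attracting in reverse time, so backward integration from
  # just off a refined point follows it (the computational route of the
  # underlying analysis); kept as a diagnostic alongside the refined points
  bs <- NULL
  if (trace_backward) {
    i0 <- which(ok)[ceiling(sum(ok) / 2)]
    st_seed <- cell_state(x = 0, y = pts[i0] - 1e-4, alpha = slices[i0], r = r)
    # the trace typically stalls once the reverse-time flow steepens; the
    # partial arc is all that is kept (solver chatter swallowed)
    invisible(utils::capture.output(
      back <- try(suppressWarnings(
        integrate_trajectory(st_seed, params, t_end = 10, mode = "rigid",
                             direction = "backward", rtol = 1e-8, atol = 1e-10,
                             n_save = 200L)), silent = TRUE),
      type = "output"))
    if (!inherits(back, "try-error")) {
      bs <- back$states
      keep <- bs$alpha > 0 & bs$alpha < pi / 2 & bs$y < 0 & bs$y > -sqrt(r)
      bs <- bs[keep, c("alpha", "y")]
    }
  }
  structure(list(points = poly, params = params, backward = bs,
                 bisect_tol = bisect_tol),
            class = "cellign_separatrix")
}

#' @export
print.cellign_separatrix <- function(x, ...) {
  cat(sprintf("Separatrix polyline (%d refined slices), alpha in [%g, %g]\n",
              nrow(x$points), min(x$points$alpha), max(x$points$alpha)))
  print(x$points)
  invisible(x)
}
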