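# Exact geometry of the mirror-symmetric two-ellipse configuration.
#
# Cell 1 has centre (x, y), orientation alpha and aspect ratio r; cell 2 is
# its mirror image at (x, -y) with orientation -alpha and the same r.  All
# quantities are non-dimensional (lengths scaled by sqrt(A/pi), so each
# ellipse has unit area times pi).

#' Model parameters of the two-cell system
#'
#' Bundles the three non-dimensional parameters that govern the symmetric
#' two-cell dynamics: the self-propulsion strength `nu` (ratio of propulsion
#' speed to overlap-avoidance strength in the presence of substrate
#' friction), the shape-change parameter `gamma` (ratio of overlap-avoidance
#' strength to the strength of relaxation toward the preferred aspect
#' ratio; `gamma = 0` means perfectly rigid cells), and the preferred aspect
#' ratio `r_bar` (`r_bar > 1` for "long" cells that move along their long
#' axis, `r_bar < 1` for "wide" cells).
#'
#' `r_bar = 1` (circular cells) is accepted here but rejected by operations
#' that divide by `r^2 - 1`: circular cells exert no torque in this
#' framework and the region geometry degenerates.
#'
#' @param nu Self-propulsion strength, `>= 0`.
#' @param gamma Shape-change parameter, `>= 0`.
#' @param r_bar Preferred aspect ratio, `> 0`.
#' @return An object of class `cellign_params`.
#' @examples
#' model_params(nu = 2, gamma = 1, r_bar = 2)
#' @export
model_params <- function(nu = 1, gamma = 1, r_bar = 2) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(r_bar), length(r_bar) == 1L, is.finite(r_bar))
  if (nu < 0) stop("`nu` must be >= 0", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (r_bar <= 0) stop("`r_bar` must be > 0", call. = FALSE)
  structure(list(nu = nu, gamma = gamma, r_bar = r_bar),
            class = "cellign_params")
}

#' @export
print.cellign_params <- function(x, ...) {
  cat(sprintf("Two-cell model parameters: nu = %g, gamma = %g, r_bar = %g\n",
              x$nu, x$gamma, x$r_bar))
  invisible(x)
}

#' State of the symmetric two-cell system
#'
#' Stores the state of cell 1 only; cell 2 is fully determined by the mirror
#' construction (centre `(x, -y)`, orientation `-alpha`, same aspect ratio).
#' `alpha` is stored unwrapped -- all geometry uses `sin(alpha)` and
#' `cos(alpha)` directly, so no canonical interval is enforced.
#'
#' @param x Horizontal centre coordinate of both cells.
#' @param y Vertical centre coordinate of cell 1 (cell 2 sits at `-y`).
#' @param alpha Orientation of cell 1 in radians (cell 2 at `-alpha`).
#' @param r Current aspect ratio, `> 0`.
#' @return An object of class `cellign_state`.
#' @examples
#' cell_state(y = -0.5, alpha = 0.3, r = 2)
#' @export
cell_state <- function(x = 0, y, alpha, r) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            is.numeric(y), length(y) == 1L, is.finite(y),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(r), length(r) == 1L, is.finite(r))
  if (r <= 0) stop("aspect ratio `r` must be > 0", call. = FALSE)
  structure(list(x = x, y = y, alpha = alpha, r = r),
            class = "cellign_state")
}

#' @export
print.cellign_state <- function(x, ...) {
  cat(sprintf("Cell state: x = %g, y = %g, alpha = %g, r = %g (cell 2 mirrored at -y, -alpha)\n",
              x$x, x$y, x$alpha, x$r))
  invisible(x)
}

.check_r <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("aspect ratio `r` must be positive and finite", call. = FALSE)
  invisible(r)
}

.check_r_not_one <- function(r, what = "this operation") {
  .check_r(r)
  if (any(r == 1))
    stop("degenerate geometry: r = 1 (circular cells) is not admitted by ",
         what, " (division by r^2 - 1; circular cells exert no torque)",
         call. = FALSE)
  invisible(r)
}

#' Point on (or inside) a cell boundary
#'
#' Parametrises material points of either cell as `X + s R(+/-alpha) k(r,
#' theta)` with the rotation matrix `R` and shape vector
#' `k(r, theta) = (sqrt(r) cos(theta), sin(theta)/sqrt(r))`.  With `s = 1`
#' (the default) this traces the elliptic boundary.  For cell 2 the signs of
#' `alpha` and `y` are mirrored.
#'
#' @param state A [cell_state()].
#' @param cell Which cell, `1` or `2`.
#' @param theta Boundary parameter angle(s) in radians; vectorised.
#' @param s Radial material coordinate in `[0, 1]`; `s = 1` is the boundary.
#' @return A numeric matrix with one `(x, y)` row per `theta`.
#' @examples
#' boundary_point(cell_state(y = -0.5, alpha = 0, r = 2), 1, theta = 0)
#' @export
boundary_point <- function(state, cell = 1, theta, s = 1) {
  stopifnot(inherits(state, "cellign_state"), cell %in% c(1, 2))
  .check_r(state$r)
  a <- if (cell == 1) state$alpha else -state$alpha
  yc <- if (cell == 1) state$y else -state$y
  kx <- sqrt(state$r) * cos(theta)
  ky <- sin(theta) / sqrt(state$r)
  px <- state$x + s * (cos(a) * kx - sin(a) * ky)
  py <- yc + s * (sin(a) * kx + cos(a) * ky)
  cbind(x = px, y = py)
}

#' Orientation-shape factors gamma_1^2 and gamma_2^2
#'
#' The two quadratic forms `gamma_1^2 = r sin^2(alpha) + cos^2(alpha)/r` and
#' `gamma_2^2 = sin^2(alpha)/r + r cos^2(alpha)` that control where the two
#' mirror-symmetric ellipse boundaries intersect.  Both are strictly
#' positive; they satisfy `gamma_1^2 * gamma_2^2 - ((r^2-1) sin(alpha)
#' cos(alpha) / r)^2 = 1`.
#'
#' @param alpha Orientation(s) in radians; vectorised.
#' @param r Aspect ratio(s), `> 0`.
#' @return A list with components `g1sq` and `g2sq`.
#' @examples
#' gamma_factors(pi / 4, 3)  # both equal 5/3
#' @export
gamma_factors <- function(alpha, r) {
  .check_r(r)
  s2 <- sin(alpha)^2
  c2 <- cos(alpha)^2
  list(g1sq = r * s2 + c2 / r, g2sq = s2 / r + r * c2)
}

#' Region boundary curves in the (alpha, y) plane
#'
#' The configuration space splits into regions with 0, 2 or 4 boundary
#' intersection points.  The outer boundary (0 vs 2 intersections) is
#' `Gamma_AB(alpha) = gamma_1(alpha)`; the inner boundary (2 vs 4) is
#' `Gamma_BC(alpha) = (r^2 - 1) sin(alpha) cos(alpha) / (r gamma_2(alpha))`,
#' whose sign follows `sin(alpha) cos(alpha)` and `(r^2 - 1)`.
#'
#' @inheritParams gamma_factors
#' @return A list with components `Gamma_AB` (`= gamma_1 > 0`) and
#'   `Gamma_BC` (signed).
#' @export
boundary_curves <- function(alpha, r) {
  g <- gamma_factors(alpha, r)
  list(Gamma_AB = sqrt(g$g1sq),
       Gamma_BC = (r^2 - 1) * sin(alpha) * cos(alpha) / (r * sqrt(g$g2sq)))
}

# Vectorised internal classifier.  Ties within `tol` of a boundary are
# assigned to the region with more intersections, so that the vanishing
# square roots there evaluate to 0 rather than NaN; the right-hand side is
# continuous across both boundaries, so the choice cannot alter trajectories.
.classify <- function(alpha, y, r, tol = 1e-12) {
  g <- gamma_factors(alpha, r)
  gbc2 <- g$g1sq - 1 / g$g2sq     # Gamma_BC^2 via the closed-form identity
  y2 <- y^2
  ifelse(y2 <= gbc2 + tol, "C", ifelse(y2 <= g$g1sq + tol, "B", "A"))
}

#' Classify the overlap region of a configuration
#'
#' Region `A`: the two cells do not overlap (0 boundary intersections).
#' Region `B`: shallow overlap with 2 intersection points.  Region `C`: deep
#' overlap with 4 intersection points.  Formally `A` is `y^2 > Gamma_AB^2`,
#' `C` is `y^2 < Gamma_BC^2` and `B` lies between.  Exact ties (within an
#' absolute band of `1e-12`) are classified as the region with more
#' intersection points.
#'
#' @param state A [cell_state()].
#' @return An object of class `cellign_region`: a list with `label`
#'   (`"A"`, `"B"` or `"C"`) and `n_intersections` (0, 2 or 4).
#' @examples
#' classify_region(cell_state(y = -2, alpha = 0, r = 2))    # A
#' classify_region(cell_state(y = -0.5, alpha = 0, r = 2))  # B
#' @export
classify_region <- function(state) {
  stopifnot(inherits(state, "cellign_state"))
  lab <- .classify(state$alpha, state$y, state$r)
  structure(list(label = lab,
                 n_intersections = c(A = 0L, B = 2L, C = 4L)[[lab]]),
            class = "cellign_region")
}

#' @export
print.cellign_region <- function(x, ...) {
  cat(sprintf("Region %s (%d boundary intersection points)\n",
              x$label, x$n_intersections))
  invisible(x)
}

# Clamp a square-root radicand: float noise within -tol is flattened to 0,
# anything more negative signals a classification/geometry mismatch.
.safe_sqrt <- function(v, tol = 1e-12, context = "radicand") {
  if (v < -tol)
    stop("internal-consistency error: negative ", context, " (", v,
         ") beyond tolerance while classified as overlapping", call. = FALSE)
  sqrt(max(v, 0))
}

#' Analytic intersection points of the two cell boundaries
#'
#' Returns the explicit intersection points of the mirror-symmetric ellipse
#' pair, in Cartesian coordinates relative to the cells' shared x-position.
#' In region `B` these are the two points `P_B+-` on the x-axis
#' (`second coordinate 0`); in region `C` the additional pair `P_C+-` is
#' mirror-symmetric about the x-axis.  In region `A` the set is empty.
#'
#' @param state A [cell_state()].
#' @return An object of class `cellign_intersections`: list with `points`
#'   (n x 2 matrix) and `kind` (`"B+"`, `"B-"`, `"C+"`, `"C-"`).
#' @examples
#' intersection_points(cell_state(y = -0.5, alpha = 0, r = 2))  # (+-1, 0)
#' @export
intersection_points <- function(state) {
  stopifnot(inherits(state, "cellign_state"))
  reg <- .classify(state$alpha, state$y, state$r)
  if (reg == "A") {
    return(structure(list(points = matrix(numeric(0), ncol = 2,
                                          dimnames = list(NULL, c("x", "y"))),
                          kind = character(0)),
                     class = "cellign_intersections"))
  }
  .check_r_not_one(state$r, "intersection_points")
  r <- state$r; y <- state$y; a <- state$alpha
  sc <- sin(a) * cos(a)
  g <- gamma_factors(a, r)
  rootB <- .safe_sqrt(g$g1sq - y^2, context = "P_B radicand")
  xB0 <- -y * (r^2 - 1) * sc / r
  pts <- rbind(c((xB0 + rootB) / g$g1sq, 0),
               c((xB0 - rootB) / g$g1sq, 0))
  kind <- c("B+", "B-")
  if (reg == "C") {
    # P_C exists only off the symmetry axes, where sin(alpha)cos(alpha) != 0
    gbc2 <- g$g1sq - 1 / g$g2sq
    rootC <- .safe_sqrt(gbc2 - y^2, context = "P_C radicand")
    pref <- r / ((r^2 - 1) * sc)
    pts <- rbind(pts,
                 pref * c(-y * g$g2sq, rootC),
                 pref * c(-y * g$g2sq, -rootC))
    # the +/- label follows the sign of the second coordinate
    kc <- if (pref >= 0) c("C+", "C-") else c("C-", "C+")
    kind <- c(kind, kc)
  }
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, kind = kind),
            class = "cellign_intersections")
}

#' @export
print.cellign_intersections <- function(x, ...) {
  cat(sprintf("%d boundary intersection point(s)\n", nrow(x$points)))
  if (nrow(x$points)) print(cbind(as.data.frame(x$points), kind = x$kind))
  invisible(x)
}

#' Implicit ellipse equation residual
#'
#' Evaluates `((R(+-alpha)^T (p - X))_1^2 / r + r (R(+-alpha)^T (p - X))_2^2)
#' - 1` for a point `p`, i.e. the implicit equation of the chosen cell's
#' boundary.  Zero iff the point lies on the boundary; negative inside,
#' positive outside.  Serves as an independent oracle for the analytic
#' intersection points.
#'
#' @param state A [cell_state()].
#' @param cell Which cell, `1` or `2`.
#' @param point A length-2 vector or an n x 2 matrix of points.
#' @return Numeric residual(s).
#' @examples
#' st <- cell_state(y = 0, alpha = 0, r = 1)
#' implicit_residual(st, 1, c(2, 0))  # 3
#' @export
implicit_residual <- function(state, cell = 1, point) {
  stopifnot(inherits(state, "cellign_state"), cell %in% c(1, 2))
  .check_r(state$r)
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  a <- if (cell == 1) state$alpha else -state$alpha
  yc <- if (cell == 1) state$y else -state$y
  dx <- point[, 1] - state$x
  dy <- point[, 2] - yc
  # local coordinates: R(a)^T (p - X)
  lx <- cos(a) * dx + sin(a) * dy
  ly <- -sin(a) * dx + cos(a) * dy
  lx^2 / state$r + state$r * ly^2 - 1
}

#' Brute-force intersection count via boundary scan
#'
#' Independent oracle for [classify_region()] and [intersection_points()]:
#' scans cell 1's boundary parameter `theta` on a fine grid, locates sign
#' changes of cell 2's implicit residual and polishes each bracketed root
#' with [stats::uniroot()].  Returns the number of distinct intersection
#' points found.  Purely numerical; makes no use of the analytic formulas.
#'
#' @param state A [cell_state()].
#' @param n_scan Number of grid points on `[0, 2*pi)`.
#' @return Integer intersection count (0, 2 or 4 away from region borders).
#' @export
count_intersections_scan <- function(state, n_scan = 2048) {
  stopifnot(inherits(state, "cellign_state"))
  theta <- seq(0, 2 * pi, length.out = n_scan + 1L)
  p <- boundary_point(state, 1, theta)
  res <- implicit_residual(state, 2, p)
  f <- function(th) implicit_residual(state, 2, boundary_point(state, 1, th))
  n <- 0L
  for (i in seq_len(n_scan)) {
    r1 <- res[i]; r2 <- res[i + 1L]
    if (r1 == 0) n <- n + 1L
    else if (r1 * r2 < 0) {
      stats::uniroot(f, c(theta[i], theta[i + 1L]), tol = 1e-12)
      n <- n + 1L
    }
  }
  n
}
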