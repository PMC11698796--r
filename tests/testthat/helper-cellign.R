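# Shared helpers: deterministic samplers for property-style tests.

# Random states across the overlap regions: alpha in (0, pi/2),
# y in (-sqrt(r), 0), r in (1.1, 5).
sample_states <- function(n, seed = 1) {
  set.seed(seed)
  r <- runif(n, 1.1, 5)
  data.frame(alpha = runif(n, 1e-3, pi / 2 - 1e-3),
             y = -runif(n, 1e-3, 1) * sqrt(r),
             r = r)
}

# Points exactly on the A-B (or B-C) boundary for a sampled (alpha, r).
boundary_states <- function(n, which = c("AB", "BC"), seed = 1) {
  which <- match.arg(which)
  set.seed(seed)
  r <- runif(n, 1.1, 5)
  alpha <- runif(n, 0.05, pi / 2 - 0.05)
  b <- boundary_curves(alpha, r)
  y <- if (which == "AB") -b$Gamma_AB else -abs(b$Gamma_BC)
  data.frame(alpha = alpha, y = y, r = r)
}

# Region-B initial conditions at fixed r (interior of the strip
# Gamma_BC < |y| < Gamma_AB).
sample_region_B <- function(n, r, seed = 1, margin = 0.05) {
  set.seed(seed)
  alpha <- runif(n, 0.1, pi / 2 - 0.1)
  b <- boundary_curves(alpha, r)
  u <- runif(n, margin, 1 - margin)
  data.frame(alpha0 = alpha,
             y0 = -(abs(b$Gamma_BC) + u * (b$Gamma_AB - abs(b$Gamma_BC))))
}

rigid_params <- function(nu, r) model_params(nu = nu, gamma = 0, r_bar = r)
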