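# Independent numerical oracles used to validate the closed forms.
# These deliberately avoid the package's own code paths.

# Gaussian-source concentration, written out independently
oracle_conc <- function(r, t, d, sigma, c0 = 1) {
  c0 * (sigma^2 / (sigma^2 + 2 * d * t))^1.5 *
    exp(-r^2 / (2 * (sigma^2 + 2 * d * t)))
}

# hemisphere moles by adaptive shell quadrature of the concentration profile
oracle_hemisphere_moles <- function(t, d, sigma, R, c0 = 1) {
  2 * pi * integrate(function(r) r^2 * oracle_conc(r, t, d, sigma, c0),
                     0, R, rel.tol = 1e-10)$value
}

# total moles (R -> Inf) by quadrature
oracle_total_moles <- function(t, d, sigma, c0 = 1) {
  2 * pi * integrate(function(r) r^2 * oracle_conc(r, t, d, sigma, c0),
                     0, Inf, rel.tol = 1e-10)$value
}

# Monte-Carlo integration of the flow-advected hemisphere-moles model
# (uniform sampling of the radial integrand)
oracle_mc_flow_moles <- function(t, d, sigma, R, v, c0 = 1, n = 1e7,
                                 seed = 42) {
  set.seed(seed)
  b <- 4 * d * t + 2 * sigma^2
  r <- runif(n, 0, R)
  pref <- 2 * pi * c0 * (1 + 2 * d * t / sigma^2)^(-1.5) *
    exp(-v^2 * t^2 / b)
  pref * R * mean(r^2 * exp(-(r^2 + 2 * r * v * t) / b))
}

# Crank-Nicolson finite-difference solution of slab efflux:
# reflecting boundary at x = 0, absorbing at x = L, uniform IC c0.
# Returns C(x_eval, t) for each t in `times` (dimensionless-friendly).
oracle_cn_slab <- function(d, L, x_eval, times, c0 = 1, nx = 401,
                           dt = NULL) {
  dx <- L / (nx - 1)
  if (is.null(dt)) dt <- 0.25 * dx^2 / d * 4 # CN is unconditionally stable
  lam <- d * dt / (2 * dx^2)
  # interior nodes 1..nx-1 unknown (node nx fixed at 0); Neumann at node 1
  n <- nx - 1
  main_a <- rep(1 + 2 * lam, n)
  lower_a <- rep(-lam, n - 1)
  upper_a <- rep(-lam, n - 1)
  upper_a[1] <- -2 * lam # ghost-node reflection at x = 0
  A <- diag(main_a)
  A[cbind(2:n, 1:(n - 1))] <- lower_a
  A[cbind(1:(n - 1), 2:n)] <- upper_a
  B <- diag(rep(1 - 2 * lam, n))
  B[cbind(2:n, 1:(n - 1))] <- lam
  B[cbind(1:(n - 1), 2:n)] <- -upper_a # = lam, doubled in row 1
  Ainv <- solve(A)
  M <- Ainv %*% B
  u <- rep(c0, n)
  grid <- seq(0, L, length.out = nx)
  times_o <- sort(times)
  out <- numeric(length(times_o))
  t_now <- 0
  for (i in seq_along(times_o)) {
    steps <- round((times_o[i] - t_now) / dt)
    for (s in seq_len(steps)) u <- M %*% u
    t_now <- t_now + steps * dt
    out[i] <- stats::approx(grid[1:n], as.numeric(u), xout = x_eval)$y
  }
  out[match(times, times_o)]
}

# closed-form OLS slope/intercept and slope SE
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se_slope <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, se_slope = se_slope)
}

# dense-grid maximiser of the arrival curve at fixed r
oracle_grid_peak_time <- function(r, d, sigma, t_max, n = 2e5) {
  tt <- seq(0, t_max, length.out = n)
  cc <- oracle_conc(r, tt, d, sigma)
  tt[which.max(cc)]
}
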