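# Independent 1-D Crank-Nicolson reference solver (dense base-R linear
# algebra, uniform grid) for a single homogeneous layer with a depth-only
# exponential source, Robin surface exchange and a fixed bottom
# temperature. Used to verify the axisymmetric finite-volume solver in the
# radially uniform limit.

oracle_1d_cn <- function(depth, rho, cp, k, q0, mu, h, ambient, core,
                         duration, dz = 5e-6, dt = 5e-4) {
  n <- round(depth / dz) + 1L
  z <- seq(0, depth, length.out = n)
  alpha <- k / (rho * cp)
  # interior: dT/dt = alpha T'' + q/(rho cp); node 1 Robin, node n Dirichlet
  A <- matrix(0, n, n)   # spatial operator L such that dT/dt = L T + s
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- alpha / dz^2
    A[i, i] <- -2 * alpha / dz^2
    A[i, i + 1] <- alpha / dz^2
  }
  # surface node: ghost from -k (T2 - T0)/(2dz) = h (T1 - Tamb)
  # T0 = T2 + 2 dz h / k (Tamb - T1)
  A[1, 1] <- -2 * alpha / dz^2 * (1 + dz * h / k)
  A[1, 2] <- 2 * alpha / dz^2
  s <- q0 * exp(-mu * z) / (rho * cp)
  s[1] <- s[1] + 2 * alpha / dz^2 * dz * h / k * ambient
  s[n] <- 0
  A[n, ] <- 0                      # Dirichlet: dT/dt = 0, T stays at core
  # steady initial condition: solve L T + s0 = 0 (without laser)
  s0 <- rep(0, n); s0[1] <- 2 * alpha / dz^2 * dz * h / k * ambient
  Ared <- A[1:(n - 1), 1:(n - 1)]
  rhs <- -(s0[1:(n - 1)] + A[1:(n - 1), n] * core)
  t_init <- c(solve(Ared, rhs), core)
  # Crank-Nicolson stepping
  nsteps <- round(duration / dt)
  eye <- diag(n)
  lhs <- eye - dt / 2 * A
  rhsm <- eye + dt / 2 * A
  lhs_inv <- solve(lhs)
  tt <- t_init
  for (step in seq_len(nsteps)) {
    tt <- lhs_inv %*% (rhsm %*% tt + dt * s)
    tt[n] <- core
  }
  list(z = z, t_final = as.numeric(tt), t_init = t_init)
}
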