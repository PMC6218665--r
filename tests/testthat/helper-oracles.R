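# Independent oracles used across the test files.

# Consistent-mass matrix of a trilinear brick with edge lengths hx,hy,hz:
# tensor product of 1-D linear-element mass matrices [[h/3, h/6],[h/6, h/3]],
# evaluated entry-wise through the corner sign pattern (same-corner factor
# h/3, opposite h/6 per axis).
q1_mass_oracle <- function(hx, hy, hz) {
  s <- matrix(c(-1, -1, -1, +1, -1, -1, +1, +1, -1, -1, +1, -1,
                -1, -1, +1, +1, -1, +1, +1, +1, +1, -1, +1, +1),
              ncol = 3, byrow = TRUE)
  h <- c(hx, hy, hz)
  M <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    f <- 1
    for (d in 1:3) f <- f * (if (s[a, d] == s[b, d]) h[d] / 3 else h[d] / 6)
    M[a, b] <- f
  }
  M
}

# Central finite difference of a basis evaluation function at xi.
fd_gradient <- function(f, xi, eps = 1e-6) {
  g <- sapply(1:3, function(d) {
    e <- numeric(3); e[d] <- eps
    (f(xi + e)$values - f(xi - e)$values) / (2 * eps)
  })
  matrix(g, ncol = 3)
}

# Closed-form integral of xi1^a xi2^b xi3^c over [-1,1]^3.
monomial_integral <- function(a, b, c) {
  one <- function(p) if (p %% 2 == 1) 0 else 2 / (p + 1)
  one(a) * one(b) * one(c)
}

# Apply a quadrature rule to a function of the reference coordinates.
quad_apply <- function(rule, f) {
  sum(rule$weights * apply(rule$points, 1, f))
}

# Plain 0-D forward-Euler integration of the kinetics in model time.
cell_trajectory <- function(phi0, r0, dt_model, n_steps,
                            params = aliev_panfilov_params()) {
  phi <- numeric(n_steps + 1); r <- numeric(n_steps + 1)
  phi[1] <- phi0; r[1] <- r0
  for (i in seq_len(n_steps)) {
    phi[i + 1] <- phi[i] + dt_model * ionic_current(phi[i], r[i], params)
    r[i + 1] <- r[i] + dt_model * gating_rate(phi[i], r[i], params)
  }
  list(phi = phi, r = r)
}

# A smooth, localized nodal field for exercising the steppers away from
# rest: gaussian bump along x centred at x0.
bump_state <- function(system, x0 = NULL, width = 2, height = 0.3) {
  st <- new_state(system)
  x <- system$mesh$nodes[, 1]
  if (is.null(x0)) x0 <- mean(range(x))
  st$u <- height * exp(-((x - x0) / width)^2)
  st
}

# One semi-implicit step computed through the monolithic (uncondensed)
# system that keeps all incompatible-mode coefficients as unknowns:
# [[K_u, L^T], [L, K_alpha]] z_{n+1} = M z_n / dt + \int Phi f(phi_n, r_n).
monolithic_si_step <- function(state, system) {
  full <- monofem:::build_full_system(system)
  z_n <- c(state$u, if (full$nc > 0) as.vector(t(state$alpha)) else NULL)
  phi_q <- monofem:::full_phi_q(full, z_n, system)
  p <- system$params
  f <- ionic_current(phi_q, state$r, p) / p$tau
  pe <- (f * full$wdet_e) %*% t(full$Phi)
  rhs <- as.numeric(full$M %*% z_n) / system$dt +
    as.numeric(full$Sfull %*% as.vector(pe))
  z <- as.numeric(Matrix::solve(full$A0, rhs))
  list(u = z[seq_len(system$ndof)],
       alpha = if (full$nc > 0)
         matrix(z[-seq_len(system$ndof)], system$nel, 3, byrow = TRUE)
       else NULL)
}
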