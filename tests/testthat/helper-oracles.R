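# Independent numerical oracles used by the tests.

# Finite-difference solve of the cue diffusion equation dc/dt = Dc c_xx on
# [0, l] with c(0) = c0 (Dirichlet) and zero flux at x = l, from a zero
# initial condition, via deSolve's stiff method-of-lines integrator.
# Independent of the package's eigenfunction series.
fd_concentration <- function(l, Dc, c0, times_s, n_grid = 2001) {
  dx <- l / (n_grid - 1)
  rhs <- function(t, y, parms) {
    dy <- numeric(n_grid)
    dy[1] <- 0  # boundary held at c0
    dy[2:(n_grid - 1)] <- Dc *
      (y[1:(n_grid - 2)] - 2 * y[2:(n_grid - 1)] + y[3:n_grid]) / dx^2
    dy[n_grid] <- Dc * 2 * (y[n_grid - 1] - y[n_grid]) / dx^2
    list(dy)
  }
  y0 <- c(c0, rep(0, n_grid - 1))
  out <- deSolve::ode.1D(y0, times = c(0, times_s), func = rhs,
                         parms = NULL, nspec = 1, dimens = n_grid,
                         method = "lsoda", rtol = 1e-8, atol = 1e-10)
  list(x = seq(0, l, length.out = n_grid),
       c = out[-1, -1, drop = FALSE])  # one row per requested time
}

# Fully explicit fine-grid reference solve of the growth-cone equation:
# forward-Euler diffusion plus first-order upwind advection on a grid of
# n_grid nodes, with the drift velocity built from face-averaged series
# concentrations and face-difference gradients (a discretisation
# independent of the solver under test, which uses Crank-Nicolson
# diffusion and analytic series gradients).
reference_ks_solve <- function(l, Dc, c0, k, m, n_grid = 2001,
                               sigma = 25, x0 = l / 2, Dg = 7e-3,
                               t_end = 172800) {
  dx <- l / (n_grid - 1)
  x <- seq(0, l, length.out = n_grid)
  xf <- x[-n_grid] + dx / 2
  dom <- gel_domain(l, Dc_um2_s = Dc, n_grid = n_grid)

  # stability: diffusion and an advective CFL estimated at a late time
  vguess <- if (c0 > 0 && k > 0) {
    cn <- exact_concentration(dom, c0, x, t_end)
    max(abs((k / (1 + m * (cn[-n_grid] + cn[-1]) / 2)^2) * diff(cn) / dx))
  } else 0
  dt <- min(0.4 * dx^2 / Dg,
            if (vguess > 0) 0.4 * dx / vguess else Inf,
            t_end / 200)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps

  g <- exp(-(x - x0)^2 / (2 * sigma^2))
  w <- c(dx / 2, rep(dx, n_grid - 2), dx / 2)
  g <- g / sum(w * g)
  x0g <- ref_peak(g, x)

  # precompute series factors at the nodes for fast per-step evaluation
  use_chemo <- c0 > 0 && k > 0
  if (use_chemo) {
    Nser <- neuritaxis:::.series_n_terms(dt / 2, l, Dc)
    mu <- (2 * seq_len(Nser) - 1) * pi / (2 * l)
    bcoef <- 4 / ((2 * seq_len(Nser) - 1) * pi)
    Sn <- sin(outer(x, mu))
  }
  for (s in seq_len(nsteps)) {
    tm <- (s - 1) * dt + dt / 2
    if (use_chemo) {
      cn <- pmax(c0 * (1 - drop(Sn %*% (bcoef * exp(-mu^2 * Dc * tm)))), 0)
      cf <- (cn[-n_grid] + cn[-1]) / 2
      v <- (k / (1 + m * cf)^2) * diff(cn) / dx
    } else {
      v <- numeric(n_grid - 1)
    }
    Fadv <- ifelse(v > 0, v * g[-n_grid], v * g[-1])
    Fdif <- -Dg * diff(g) / dx
    Ftot <- Fadv + Fdif
    g <- g - dt * c(Ftot[1] / (dx / 2), diff(Ftot) / dx,
                    -Ftot[n_grid - 1] / (dx / 2))
  }
  list(d = abs(ref_peak(g, x) - x0g), g = g, x = x, nsteps = nsteps)
}

# quadratic-interpolated peak (local reimplementation for the oracle)
ref_peak <- function(g, x) {
  j <- which.max(g)
  if (j == 1 || j == length(g)) return(x[j])
  den <- g[j - 1] - 2 * g[j] + g[j + 1]
  if (den >= 0) return(x[j])
  x[j] + 0.5 * (g[j - 1] - g[j + 1]) / den * (x[2] - x[1])
}
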