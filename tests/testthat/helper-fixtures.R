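# Shared fixtures and independent oracles, built in code at test time.

co_fixture <- function() {
  list(model = build_co_model(1e6, 100),
       theta = c(k_open = 1e6, k_close = 100))
}

# Strongly cooperative two-binding-step ground truth (first site weak,
# second strong; EC50 ~ 5 uM with 990/10 gating).
coop_fixture <- function() {
  list(model = build_sequential_model(2, cooperative = TRUE,
                                      e_plus = 990, e_minus = 10),
       theta = c(k1 = 2e6, km1 = 1000, k2 = 2e7, km2 = 100))
}

# Strong-first/weak-second cooperative truth used for the model
# discrimination study: in this regime tied-rate (independent) expansions
# misfit as badly as a one-step model, while the free second binding step
# is decisive.
discrimination_fixture <- function() {
  list(model = build_sequential_model(2, cooperative = TRUE,
                                      e_plus = 990, e_minus = 10),
       theta = c(k1 = 2e7, km1 = 100, k2 = 2e6, km2 = 1000))
}

# Rectangular concentration trace from explicit levels/durations.
rect_trace <- function(levels_M, durations_s, dt = 5e-4) {
  correct_protocol(protocol(levels_M, durations_s), tau_ligand = 0, dt = dt)
}

# C-O step-response closed form: Po(t) for a step to constant conc applied
# at t = 0 starting from Po0.
co_step_po <- function(theta, conc, t, po0) {
  a <- theta[[1]] * conc; b <- theta[[2]]
  po_inf <- if (a + b == 0) po0 else a / (a + b)
  po_inf + (po0 - po_inf) * exp(-(a + b) * t)
}

# Detailed-balance stationary open probability of the sequential
# cooperative chain: product of equilibrium constants.
coop_stationary_po <- function(theta, e_plus, e_minus, conc, m) {
  K <- unname(theta[seq(1, 2 * m, 2)] / theta[seq(2, 2 * m, 2)])
  w <- cumprod(c(1, K * conc))          # C0..Cm
  wO <- w[m + 1] * e_plus / e_minus
  wO / (sum(w) + wO)
}

# Independent-oracle propagation: integrate dp/dt = p Q(c_i) interval by
# interval with lsoda at tight tolerance, chaining the state.
ode_po_oracle <- function(model, theta, conc_trace, p0 = NULL) {
  dt <- conc_trace$time_s[2] - conc_trace$time_s[1]
  if (is.null(p0))
    p0 <- stationary_distribution(model, theta, conc_trace$conc_M[1])
  p <- as.numeric(p0)
  po <- numeric(nrow(conc_trace))
  for (i in seq_len(nrow(conc_trace))) {
    po[i] <- sum(p[model$open_states])
    Q <- q_matrix(model, theta, conc_trace$conc_M[i])
    sol <- deSolve::lsoda(p, c(0, dt),
                          function(t, y, parms) list(as.numeric(y %*% Q)),
                          rtol = 1e-11, atol = 1e-13)
    p <- as.numeric(sol[2, -1])
  }
  po
}

# Brute-force microstate oracle for independent binding: m identical sites
# as 2^m occupancy patterns plus one open state reachable from the fully
# occupied pattern. Returns Po over a rectangular conc trace.
microstate_po_oracle <- function(m, kon, koff, e_plus, e_minus, conc_trace) {
  n_closed <- 2^m
  s <- n_closed + 1L
  occ <- as.matrix(expand.grid(rep(list(0:1), m)))
  build_q <- function(conc) {
    Q <- matrix(0, s, s)
    for (i in seq_len(n_closed)) {
      for (site in seq_len(m)) {
        j <- i + (if (occ[i, site] == 0) 1L else -1L) * 2L^(site - 1L)
        if (occ[i, site] == 0) Q[i, j] <- Q[i, j] + kon * conc
        else Q[i, j] <- Q[i, j] + koff
      }
    }
    full <- which(rowSums(occ) == m)
    Q[full, s] <- e_plus
    Q[s, full] <- e_minus
    diag(Q) <- diag(Q) - rowSums(Q)
    Q
  }
  p <- c(1, rep(0, s - 1))  # all sites empty
  dt <- conc_trace$time_s[2] - conc_trace$time_s[1]
  po <- numeric(nrow(conc_trace))
  cache <- list()
  for (i in seq_len(nrow(conc_trace))) {
    po[i] <- p[s]
    key <- format(conc_trace$conc_M[i], digits = 15)
    if (is.null(cache[[key]]))
      cache[[key]] <- as.matrix(Matrix::expm(build_q(conc_trace$conc_M[i]) * dt))
    p <- as.numeric(p %*% cache[[key]])
  }
  po
}
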