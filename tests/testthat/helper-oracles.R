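# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's closed-form/Laplace code paths.

# RK4 integration of the depot -> central linear system:
#   dA1/dt = -kf A1  (+ bolus D into depot at dose times)
#   dA2/dt =  kf A1 - ke A2,  C = A2 / V
ode_conc_oracle <- function(times, dose_t, dose_a, cl, v, kf, h = 0.01) {
  ke <- cl / v
  events <- sort(unique(c(dose_t, times)))
  a1 <- a2 <- 0
  t <- 0
  out <- setNames(numeric(length(times)), format(times, digits = 12))
  if (any(times == 0)) out[format(0, digits = 12)] <- 0
  for (i in seq_along(dose_t)) if (dose_t[i] == 0) a1 <- a1 + dose_a[i]
  deriv <- function(a) c(-kf * a[1], kf * a[1] - ke * a[2])
  grid_to <- max(times)
  while (t < grid_to - 1e-12) {
    nxt <- min(c(events[events > t + 1e-12], grid_to))
    span <- nxt - t
    nstep <- max(1L, ceiling(span / h))
    hh <- span / nstep
    a <- c(a1, a2)
    for (s in seq_len(nstep)) {
      k1 <- deriv(a)
      k2 <- deriv(a + hh / 2 * k1)
      k3 <- deriv(a + hh / 2 * k2)
      k4 <- deriv(a + hh * k3)
      a <- a + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    a1 <- a[1]; a2 <- a[2]; t <- nxt
    for (i in seq_along(dose_t))
      if (abs(dose_t[i] - t) < 1e-12) a1 <- a1 + dose_a[i]
    hit <- which(abs(times - t) < 1e-12)
    if (length(hit)) out[hit] <- a2 / v
  }
  unname(out)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of e^{-x^2} f(x) dx = sum w_i f(x_i))
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (e$vectors[1, idx]^2) * sqrt(pi))
}

# Adaptive Gauss-Hermite -2 log marginal likelihood for a single subject
# with ONE random effect: integrand exp(-g(eta)), g = -log p(y|eta) -
# log dnorm(eta, 0, sqrt(om2)).  Centered/scaled at the mode.
agq_neg2ll_oracle <- function(g, om2, n_nodes = 64) {
  opt <- optimize(g, c(-8, 8))
  m <- opt$minimum
  h <- 1e-4
  curv <- (g(m + h) - 2 * g(m) + g(m - h)) / h^2
  s <- 1 / sqrt(max(curv, 1e-10))
  gh <- gauss_hermite(n_nodes)
  z <- m + sqrt(2) * s * gh$nodes
  lt <- log(gh$weights) + gh$nodes^2 +
    vapply(z, function(e) -g(e), 0) + log(sqrt(2) * s)
  M <- max(lt)
  -2 * (M + log(sum(exp(lt - M))))
}

# Superposition-to-convergence oracle for the steady-state trough: keep
# adding doses until the pre-dose trough changes by < tol.
css_min_oracle <- function(cl, v, kf, dose, tau, tol = 1e-9) {
  ke <- cl / v
  single <- function(t) dose / v * kf / (kf - ke) * (exp(-ke * t) - exp(-kf * t))
  trough <- 0
  for (m in 1:100000) {
    add <- single(m * tau)
    trough <- trough + add
    if (add < tol) break
  }
  trough
}

# Shared small synthetic fixtures ---------------------------------------

make_rich_dataset <- function(n = 12, seed = 101, parameters = NULL) {
  cfg <- simulation_config(
    n_subjects = n, seed = seed,
    parameters = if (is.null(parameters)) default_parameters() else parameters)
  simulate_trial(cfg)
}

table2_truth <- function() default_parameters()
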