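# Independent oracles, deliberately coded against different formulations
# than the package implementations they check.

# Single-ligand mass balance by damped fixed-point iteration on the free
# species concentrations (P_free, L_free); bound = P_free * L_free / Kd.
oracle_direct_bound <- function(x, Kd, FL, tol = 1e-13, max_iter = 100000) {
  if (x == 0) return(0)
  Pf <- x; Lf <- FL
  for (i in seq_len(max_iter)) {
    Pf <- 0.5 * Pf + 0.5 * x / (1 + Lf / Kd)
    Lf <- 0.5 * Lf + 0.5 * FL / (1 + Pf / Kd)
    res <- max(abs(Pf * (1 + Lf / Kd) - x) / x,
               abs(Lf * (1 + Pf / Kd) - FL) / FL)
    if (res < tol) return(Pf * Lf / Kd)
  }
  stop("oracle_direct_bound did not converge")
}

# Exact closed-form free protein for two competing ligands (trigonometric
# solution of the competitive-binding cubic), then bound species by mass
# action. Completely independent of the package's fixed-point solver.
oracle_ternary_cubic <- function(P0, L0, C0, KL, KC) {
  a <- KL + KC + L0 + C0 - P0
  b <- KC * (L0 - P0) + KL * (C0 - P0) + KL * KC
  c <- -KL * KC * P0
  q <- (a^2 - 3 * b)
  theta <- acos(pmin(pmax((-2 * a^3 + 9 * a * b - 27 * c) /
                            (2 * sqrt(q^3)), -1), 1))
  Pf <- -a / 3 + (2 / 3) * sqrt(q) * cos(theta / 3)
  # the trigonometric form loses precision when the root is tiny relative
  # to the coefficients; polish on the cubic to machine precision
  for (i in 1:3) {
    Pf <- Pf - (((Pf + a) * Pf + b) * Pf + c) /
      ((3 * Pf + 2 * a) * Pf + b)
  }
  boundL <- L0 * Pf / (KL + Pf)
  boundC <- C0 * Pf / (KC + Pf)
  c(bound_tracer = boundL, bound_comp = boundC, free_protein = Pf)
}

# Brute-force ITC integrator: replays the injection sequence, solving each
# post-injection equilibrium by 1-D root finding on the free protein-site
# concentration rather than the quadratic.
oracle_itc_heats <- function(protocol, Kd_M, dH, N = 1) {
  kd <- Kd_M * 1e6
  V0 <- protocol$cell_volume
  P <- protocol$cell_conc
  X <- 0
  B_prev <- 0
  heats <- numeric(length(protocol$injection_volumes))
  for (i in seq_along(protocol$injection_volumes)) {
    f <- protocol$injection_volumes[i] / V0
    P <- P * (1 - f)
    X <- X * (1 - f) + protocol$syringe_conc * f
    sites <- N * P
    froot <- function(free_sites) {
      bound <- free_sites * X / (kd + free_sites)
      free_sites + bound - sites
    }
    free_sites <- stats::uniroot(froot, c(0, sites), tol = 1e-14)$root
    B <- free_sites * X / (kd + free_sites)
    heats[i] <- dH * (B - B_prev * (1 - f)) * V0 * 1e-3
    B_prev <- B
  }
  heats
}
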