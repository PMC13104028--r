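test_that("intensity and anisotropy follow the channel algebra", {
  cases <- list(
    # P, S, G, I, r
    list(0, 1, 1, 1, 1),          # fully polarized limit
    list(1, 1, 1, 3, 0),          # S = P*G -> unpolarized
    list(100, 250, 1.1, 470, (250 - 110) / 470)
  )
  for (cs in cases) {
    ch <- channel_reading(P = cs[[1]], S = cs[[2]], G = cs[[3]])
    expect_equal(intensity_from_channels(ch), cs[[4]])
    ap <- anisotropy_from_channels(ch)
    expect_equal(ap$I, cs[[4]])
    expect_equal(ap$r, cs[[5]], tolerance = 1e-12)
  }
  expect_error(channel_reading(-1, 1), class = "dl_invalid_input")
  expect_error(channel_reading(1, NaN), class = "dl_invalid_input")
  expect_error(anisotropy_from_channels(channel_reading(0, 0)),
               class = "dl_degenerate")
})

test_that("channel synthesis round-trips anisotropy exactly", {
  set.seed(42)
  for (i in 1:50) {
    r <- runif(1, -0.45, 0.9)   # physical range: S, P >= 0 needs r > -0.5
    I <- runif(1, 10, 1e4)
    G <- runif(1, 0.5, 2)
    ap <- anisotropy_from_channels(channels_from_anisotropy(r, I, G))
    expect_equal(ap$r, r, tolerance = 1e-12)
    expect_equal(ap$I, I, tolerance = 1e-12)
  }
})

test_that("fraction_bound interpolates between plateaus and clamps noise", {
  expect_equal(fraction_bound(0.05, 0.05, 0.25), 0)
  expect_equal(fraction_bound(0.25, 0.05, 0.25), 1)
  expect_equal(fraction_bound(0.15, 0.05, 0.25), 0.5)
  # lam != 1 de-linearizes the map
  expect_equal(fraction_bound(0.15, 0.05, 0.25, lam = 2),
               0.1 / (2 * 0.1 + 0.1))
  # overshoot within 3*r_sd is clamped with a warning
  expect_warning(
    lb <- fraction_bound(0.253, 0.05, 0.25, r_sd = 0.002),
    class = "dl_clamped")
  expect_equal(lb, 1)
  # far outside is a hard error
  expect_error(fraction_bound(0.4, 0.05, 0.25, r_sd = 0.002),
               class = "dl_invalid_input")
  expect_error(fraction_bound(0.1, 0.3, 0.2), class = "dl_invalid_input")
})

test_that("direct_bound_concentration matches limits and the oracle", {
  expect_equal(direct_bound_concentration(0, 1, 0.05), 0)
  # stoichiometric limit: tight binding, excess protein -> all tracer bound
  expect_equal(direct_bound_concentration(1, 1e-9, 0.05), 0.05,
               tolerance = 1e-6)
  # frozen from the mass-balance oracle (prints as 0.0246875)
  expect_equal(direct_bound_concentration(1, 1, 0.05), 0.024687548813,
               tolerance = 1e-9)
  expect_error(direct_bound_concentration(-1, 1, 0.05),
               class = "dl_invalid_input")
  # mass-balance oracle agreement at 1e-10
  set.seed(11)
  for (i in 1:50) {
    x <- 10^runif(1, -3, 3); Kd <- 10^runif(1, -2, 2)
    FL <- 10^runif(1, -3, 0)
    expect_equal(direct_bound_concentration(x, Kd, FL),
                 oracle_direct_bound(x, Kd, FL),
                 tolerance = 1e-10)
  }
})

test_that("direct_bound_concentration is monotone and bounded", {
  set.seed(12)
  for (i in 1:30) {
    Kd <- 10^runif(1, -2, 2); FL <- 10^runif(1, -3, 0)
    x <- sort(10^runif(20, -3, 4))
    y <- direct_bound_concentration(x, Kd, FL)
    expect_true(all(diff(y) >= -1e-12))           # nondecreasing in x
    expect_true(all(y <= pmin(x, FL) + 1e-12))    # never exceeds min(x, FL)
    y2 <- direct_bound_concentration(x, Kd * 2, FL)
    expect_true(all(y2 <= y + 1e-12))             # nonincreasing in Kd
    # saturation: x -> Inf recovers FL
    expect_equal(direct_bound_concentration(1e9, Kd, FL), FL,
                 tolerance = 1e-6)
  }
})

test_that("logistic_value obeys its identities", {
  prm <- logistic_params(r_max = 0.2, r_min = 0.05, x0 = 10, p = 1)
  expect_equal(logistic_value(10, prm), (0.2 + 0.05) / 2)
  expect_equal(logistic_value(30, prm), 0.1625)
  expect_equal(logistic_value(0, prm), 0.05)
  expect_error(logistic_value(-1, prm), class = "dl_invalid_input")
  expect_error(logistic_params(0.2, 0.05, x0 = -1, p = 1),
               class = "dl_invalid_input")
  expect_error(logistic_params(0.2, 0.05, x0 = 1, p = 0),
               class = "dl_invalid_input")
  # midpoint equals the plateau mean for arbitrary parameter draws
  set.seed(13)
  for (i in 1:25) {
    prm <- logistic_params(r_max = runif(1), r_min = runif(1),
                           x0 = 10^runif(1, -2, 3),
                           p = sample(c(-1, 1), 1) * runif(1, 0.3, 4))
    expect_equal(logistic_value(prm$x0, prm), (prm$r_max + prm$r_min) / 2)
  }
})

test_that("logistic parameterization is symmetric under plateau/slope flip", {
  x <- 10^seq(-2, 3, length.out = 40)
  prm <- logistic_params(r_max = 0.2, r_min = 0.05, x0 = 13.4, p = 1.3)
  flipped <- logistic_params(r_max = prm$r_min, r_min = prm$r_max,
                             x0 = prm$x0, p = -prm$p)
  expect_equal(logistic_value(x, prm), logistic_value(x, flipped),
               tolerance = 1e-12)
})

test_that("ternary_equilibrium reduces, symmetrizes and conserves mass", {
  sys <- competition_system(P_tot = 1, FL = 0.0167, Kd_tracer = 0.81,
                            Kd_comp = 10)
  # no competitor -> the direct quadratic
  eq0 <- ternary_equilibrium(sys, 0)
  expect_equal(eq0$bound_tracer,
               direct_bound_concentration(1, 0.81, 0.0167),
               tolerance = 1e-9)
  expect_equal(eq0$bound_comp, 0)
  # equal Kd and equal totals -> symmetric occupancy
  sys_sym <- competition_system(1, 0.0167, 0.81, 0.81)
  eqs <- ternary_equilibrium(sys_sym, 0.0167)
  expect_equal(eqs$bound_tracer, eqs$bound_comp, tolerance = 1e-9)
  # mass balance and mass action to 1e-10 relative on random systems
  set.seed(14)
  for (i in 1:30) {
    s <- competition_system(10^runif(1, -1, 1), 10^runif(1, -3, -1),
                            10^runif(1, -1, 1), 10^runif(1, -1, 2))
    Ct <- 10^runif(1, -2, 3)
    eq <- ternary_equilibrium(s, Ct)
    Lf <- s$FL - eq$bound_tracer
    Cf <- Ct - eq$bound_comp
    Pf <- eq$free_protein
    expect_equal(Pf + eq$bound_tracer + eq$bound_comp, s$P_tot,
                 tolerance = 1e-10)
    expect_equal(Pf * Lf / eq$bound_tracer, s$Kd_tracer, tolerance = 1e-8)
    expect_equal(Pf * Cf / eq$bound_comp, s$Kd_comp, tolerance = 1e-8)
  }
})

test_that("ternary_equilibrium agrees with the closed-form cubic", {
  set.seed(15)
  for (i in 1:40) {
    s <- competition_system(10^runif(1, -1, 1), 10^runif(1, -3, -1),
                            10^runif(1, -1, 1), 10^runif(1, -1, 2))
    Ct <- 10^runif(1, -2, 3)
    eq <- ternary_equilibrium(s, Ct)
    orc <- oracle_ternary_cubic(s$P_tot, s$FL, Ct, s$Kd_tracer, s$Kd_comp)
    expect_equal(eq$bound_tracer, unname(orc["bound_tracer"]),
                 tolerance = 1e-8)
    expect_equal(eq$free_protein, unname(orc["free_protein"]),
                 tolerance = 1e-8)
  }
})
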