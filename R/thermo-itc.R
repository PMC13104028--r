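# Gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

#' Gibbs energy from a dissociation constant
#'
#' `dG = R * T * ln(Kd)` with `Kd` in molar (standard state 1 M), reported
#' in kJ/mol; negative for any sub-molar affinity.
#'
#' @param Kd dissociation constant (M, > 0; vectorized).
#' @param T_K temperature (K, > 0). Default 298.15 (25 C).
#' @return Gibbs energy in kJ/mol.
#' @examples
#' delta_g_from_kd(0.81e-6)  # about -34.77 kJ/mol
#' @export
delta_g_from_kd <- function(Kd, T_K = 298.15) {
  stopifnot_finite(Kd, "Kd", positive = TRUE)
  stopifnot_finite(T_K, "T_K", positive = TRUE)
  .R_GAS * T_K * log(Kd) / 1000
}

#' Dissociation constant from a Gibbs energy
#'
#' Inverse of [delta_g_from_kd()].
#'
#' @param dG Gibbs energy (kJ/mol).
#' @inheritParams delta_g_from_kd
#' @return Kd in M.
#' @export
kd_from_delta_g <- function(dG, T_K = 298.15) {
  stopifnot_finite(dG, "dG")
  stopifnot_finite(T_K, "T_K", positive = TRUE)
  exp(dG * 1000 / (.R_GAS * T_K))
}

#' Thermodynamic record for one binding measurement
#'
#' Bundles the calorimetric triple (`dH`, `minus_TdS`, `dG`, all kJ/mol)
#' with optional `Kd` (M) and stoichiometry `N`, and enforces the identity
#' `dG = dH + (-T dS)` to within printed-rounding tolerance when all three
#' terms are present.
#'
#' @param T_K temperature (K). Default 298.15.
#' @param Kd dissociation constant (M) or `NA`.
#' @param dG,dH,minus_TdS energies in kJ/mol (`NA` allowed for `dG`).
#' @param N binding stoichiometry or `NA`.
#' @param tol consistency tolerance in kJ/mol (default 0.15, generous enough
#'   for values printed to one decimal).
#' @return A `thermo_record` list.
#' @export
thermo_record <- function(dH, minus_TdS, dG = NA_real_, Kd = NA_real_,
                          N = NA_real_, T_K = 298.15, tol = 0.15) {
  stopifnot_finite(dH, "dH")
  stopifnot_finite(minus_TdS, "minus_TdS")
  if (!is.na(dG) && abs(dG - (dH + minus_TdS)) > tol) {
    dl_abort(sprintf(
      "inconsistent triple: dH + (-TdS) = %.3f but dG = %.3f (tol %.2f)",
      dH + minus_TdS, dG, tol), "dl_invalid_input")
  }
  structure(list(T_K = T_K, Kd = Kd, dG = dG, dH = dH,
                 minus_TdS = minus_TdS, N = N),
            class = "thermo_record")
}

#' Check the dG = dH + (-TdS) identity for a record
#'
#' @param rec a [thermo_record()], or any list with `dH` and `minus_TdS`
#'   (and optionally a stated `dG`).
#' @return List with `dG_computed` and `discrepancy` (computed minus stated;
#'   `NA` when no dG was stated).
#' @export
thermo_consistency <- function(rec) {
  if (is.null(rec$dH) || is.null(rec$minus_TdS) ||
      is.na(rec$dH) || is.na(rec$minus_TdS)) {
    dl_abort("need both dH and minus_TdS to compute dG", "dl_invalid_input")
  }
  dG_computed <- rec$dH + rec$minus_TdS
  stated <- if (is.null(rec$dG)) NA_real_ else rec$dG
  list(dG_computed = dG_computed,
       discrepancy = if (is.na(stated)) NA_real_ else dG_computed - stated)
}

#' ITC injection protocol
#'
#' @param cell_conc protein concentration in the cell (uM).
#' @param syringe_conc titrant concentration in the syringe (uM).
#' @param cell_volume active cell volume (uL).
#' @param injection_volumes per-injection volumes (uL); e.g. an initial
#'   0.2 uL purge followed by 19 x 3 uL.
#' @param T_K temperature (K).
#' @return An `itc_protocol` list.
#' @export
itc_protocol <- function(cell_conc = 25, syringe_conc = 500,
                         cell_volume = 275,
                         injection_volumes = c(0.2, rep(3, 19)),
                         T_K = 298.15) {
  stopifnot_finite(cell_conc, "cell_conc", positive = TRUE)
  stopifnot_finite(syringe_conc, "syringe_conc", positive = TRUE)
  stopifnot_finite(cell_volume, "cell_volume", positive = TRUE)
  stopifnot_finite(injection_volumes, "injection_volumes", positive = TRUE)
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes, T_K = T_K),
            class = "itc_protocol")
}

# Cell concentrations after each injection under the proportional
# displacement (perfusion) model: each injection of dv displaces a fraction
# dv/V0 of the instantaneously mixed cell contents.
itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  n <- length(protocol$injection_volumes)
  P <- numeric(n); X <- numeric(n)
  p_prev <- protocol$cell_conc; x_prev <- 0
  for (i in seq_len(n)) {
    f <- protocol$injection_volumes[i] / V0
    P[i] <- p_prev * (1 - f)
    X[i] <- x_prev * (1 - f) + protocol$syringe_conc * f
    p_prev <- P[i]; x_prev <- X[i]
  }
  list(P = P, X = X, dil = 1 - protocol$injection_volumes / V0)
}

#' Simulate single-site ITC injection heats
#'
#' One-site ligand-depletion isotherm with proportional-displacement
#' bookkeeping: after each injection the complex concentration in the cell
#' is the quadratic root for totals (`N * P`, `X`), and the injection heat
#' is the enthalpy released by the change in cell complex content
#' (correcting for complex expelled by the injection itself).
#'
#' @param protocol an [itc_protocol()].
#' @param Kd dissociation constant (M, > 0).
#' @param dH binding enthalpy (kJ/mol).
#' @param N binding stoichiometry (> 0). Default 1.
#' @return Numeric vector of per-injection heats in uJ (same sign as `dH`).
#' @export
simulate_itc <- function(protocol, Kd, dH, N = 1) {
  stopifnot(inherits(protocol, "itc_protocol"))
  stopifnot_finite(Kd, "Kd", positive = TRUE)
  stopifnot_finite(dH, "dH")
  stopifnot_finite(N, "N", positive = TRUE)
  kd_uM <- Kd * 1e6
  cc <- itc_concentrations(protocol)
  B <- direct_bound_concentration(cc$X, Kd = kd_uM, FL = N * cc$P)
  B_prev <- c(0, utils::head(B, -1))
  dB <- B - B_prev * cc$dil
  # uM * uL = 1e-12 mol; kJ/mol * 1e-12 mol = 1e-9 J = 1e-3 uJ
  dH * dB * protocol$cell_volume * 1e-3
}

#' Fit single-site ITC heats for Kd, dH and stoichiometry
#'
#' Nonlinear least squares of [simulate_itc()] against observed injection
#' heats (dilution heats assumed pre-subtracted; set `offset = TRUE` to
#' co-fit a constant per-injection nuisance heat). Warns when the titration
#' does not reach saturation, in which case the Kd uncertainty is large.
#'
#' @param heats observed per-injection heats (uJ), one per protocol
#'   injection.
#' @param protocol an [itc_protocol()].
#' @param offset co-fit a constant offset heat per injection.
#' @param drop_first ignore the customary small first injection in the fit
#'   (its heat is corrupted by diffusion across the syringe tip). Default
#'   TRUE when the first injection volume is < half the median volume.
#' @return An `itc_fit`: list with `Kd` (M), `dH` (kJ/mol), `N`, standard
#'   errors, `saturation` (final fraction of sites filled), `fit`.
#' @export
fit_itc <- function(heats, protocol, offset = FALSE, drop_first = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"))
  stopifnot_finite(heats, "heats")
  nv <- length(protocol$injection_volumes)
  if (length(heats) != nv) {
    dl_abort("length(heats) must match the protocol injection count",
             "dl_invalid_input")
  }
  if (nv < 10) {
    dl_abort("need >= 10 injections for an informative fit",
             "dl_invalid_input")
  }
  if (diff(range(heats)) <= 1e-12 * max(abs(heats), 1)) {
    dl_abort("flat heat series: nothing to fit", "dl_fit_error")
  }
  if (is.null(drop_first)) {
    drop_first <- protocol$injection_volumes[1] <
      0.5 * stats::median(protocol$injection_volumes)
  }
  use <- seq_len(nv)
  if (drop_first) use <- use[-1]
  model <- function(logKd, dH, N, q0) {
    simulate_itc(protocol, Kd = exp(logKd), dH = dH, N = N)[use] + q0
  }
  total_inj <- sum(simulate_itc(protocol, Kd = 1e-12, dH = 1, N = 1)[use])
  dH0 <- sum(heats[use]) / max(total_inj, 1e-12)
  dat <- data.frame(q = heats[use])
  starts <- list(logKd = log(protocol$cell_conc * 1e-6 / 5), dH = dH0, N = 1)
  lower <- c(logKd = log(1e-15), dH = -1e5, N = 0.05)
  upper <- c(logKd = log(1), dH = 1e5, N = 20)
  if (offset) {
    form <- q ~ model(logKd, dH, N, q0)
    starts$q0 <- 0
    lower <- c(lower, q0 = -Inf); upper <- c(upper, q0 = Inf)
  } else {
    form <- q ~ model(logKd, dH, N, 0)
  }
  fit <- tryCatch(
    stats::nls(form, data = dat, start = starts, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 1000, tol = 1e-12,
                                            warnOnly = TRUE)),
    error = function(e) {
      dl_abort(paste0("ITC fit failed: ", conditionMessage(e)),
               "dl_fit_error")
    }
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  Kd_hat <- exp(cf[["logKd"]])
  cc <- itc_concentrations(protocol)
  B_end <- direct_bound_concentration(utils::tail(cc$X, 1), Kd_hat * 1e6,
                                      cf[["N"]] * utils::tail(cc$P, 1))
  saturation <- B_end / (cf[["N"]] * utils::tail(cc$P, 1))
  if (is.finite(saturation) && saturation < 0.9) {
    dl_warn(sprintf("saturation not reached (%.0f%% of sites at endpoint); Kd poorly constrained",
                    100 * saturation), "dl_unsaturated")
  }
  structure(list(Kd = Kd_hat, Kd_se = Kd_hat * unname(se[["logKd"]]),
                 dH = cf[["dH"]], dH_se = unname(se[["dH"]]),
                 N = cf[["N"]], N_se = unname(se[["N"]]),
                 saturation = saturation,
                 offset = if (offset) cf[["q0"]] else 0,
                 fit = fit),
            class = "itc_fit")
}
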