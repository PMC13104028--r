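#' Polarized plate-reader channel readings
#'
#' Bundles the raw perpendicular (`P`) and parallel (`S`) channel intensities
#' of one or more wells together with the instrument gain factor `G`. All
#' downstream anisotropy algebra starts from this object.
#'
#' @param P perpendicular channel intensity (arbitrary units, >= 0);
#'   vectorized over wells.
#' @param S parallel channel intensity (arbitrary units, >= 0); same length
#'   as `P`.
#' @param G instrument gain factor (dimensionless, > 0); scalar or one value
#'   per well. Defaults to 1, the value used when the instrument is
#'   G-calibrated upstream.
#' @return A `channel_reading`: a data frame with columns `P`, `S`, `G`.
#' @examples
#' channel_reading(P = 100, S = 250, G = 1.1)
#' @export
channel_reading <- function(P, S, G = 1) {
  stopifnot_finite(P, "P", non_negative = TRUE)
  stopifnot_finite(S, "S", non_negative = TRUE)
  stopifnot_finite(G, "G", positive = TRUE)
  if (length(S) != length(P)) {
    dl_abort("`P` and `S` must have the same length", "dl_invalid_input")
  }
  out <- data.frame(P = P, S = S, G = rep_len(G, length(P)))
  class(out) <- c("channel_reading", "data.frame")
  out
}

#' Total fluorescence intensity from polarized channels
#'
#' Computes the G-corrected total intensity `I = 2*P*G + S`.
#'
#' @param channels a [channel_reading()].
#' @return Numeric vector of total intensities.
#' @export
intensity_from_channels <- function(channels) {
  if (!inherits(channels, "channel_reading")) {
    channels <- channel_reading(channels$P, channels$S, channels$G)
  }
  2 * channels$P * channels$G + channels$S
}

#' Anisotropy and total intensity from polarized channels
#'
#' Computes `r = (S - P*G) / I` with `I = 2*P*G + S`. Wells with
#' non-positive total intensity carry no polarization information and raise
#' a degenerate-well error.
#'
#' @inheritParams intensity_from_channels
#' @return A data frame with columns `I` (total intensity) and `r`
#'   (anisotropy), one row per well.
#' @examples
#' anisotropy_from_channels(channel_reading(P = 100, S = 250, G = 1.1))
#' @export
anisotropy_from_channels <- function(channels) {
  if (!inherits(channels, "channel_reading")) {
    channels <- channel_reading(channels$P, channels$S, channels$G)
  }
  I <- intensity_from_channels(channels)
  if (any(I <= 0)) {
    dl_abort("degenerate well: total intensity I <= 0", "dl_degenerate")
  }
  data.frame(I = I, r = (channels$S - channels$P * channels$G) / I)
}

#' Invert anisotropy and total intensity back to polarized channels
#'
#' Exact inverse of [anisotropy_from_channels()]: given a target anisotropy
#' `r` (|r| < 1) and total intensity `I`, returns the unique `(P, S)` pair
#' with `S = I*(1 + 2r)/3` and `P = I*(1 - r)/(3G)`. Used by the synthetic
#' plate generators to synthesize raw channel data from a binding model.
#'
#' @param r anisotropy, in (-0.5, 1) (vectorized); outside this range one of
#'   the channel intensities would have to be negative.
#' @param I total intensity, > 0.
#' @param G gain factor, > 0.
#' @return A [channel_reading()].
#' @export
channels_from_anisotropy <- function(r, I, G = 1) {
  stopifnot_finite(r, "r")
  stopifnot_finite(I, "I", positive = TRUE)
  if (any(r <= -0.5) || any(r >= 1)) {
    dl_abort("`r` must lie in (-0.5, 1) to invert to non-negative channels",
             "dl_invalid_input")
  }
  S <- I * (1 + 2 * r) / 3
  P <- I * (1 - r) / (3 * G)
  channel_reading(P = P, S = S, G = G)
}

#' Fraction of fluorescent ligand bound from an anisotropy value
#'
#' Converts an anisotropy `r` between the free-tracer plateau `r_min` and the
#' bound-tracer plateau `r_max` into the bound fraction
#' `L_b = (r - r_min) / (lam*(r_max - r) + (r - r_min))`, where
#' `lam = I_bound / I_unbound` corrects for any intensity change on binding.
#' For the tracer used here the intensity does not change (`lam = 1`) and the
#' expression reduces to linear interpolation between the plateaus.
#'
#' Noise routinely pushes measured anisotropies slightly beyond the fitted
#' plateaus; values within `3 * r_sd` (plus a small absolute tolerance) of a
#' plateau are clamped into \[0, 1\] with a warning, values further out raise
#' an error.
#'
#' @param r measured anisotropy (vectorized).
#' @param r_min anisotropy of the free tracer (lower plateau).
#' @param r_max anisotropy of the fully bound tracer (upper plateau);
#'   must exceed `r_min`.
#' @param lam intensity ratio bound/unbound, > 0. Default 1.
#' @param r_sd measurement noise scale used for the clamping tolerance.
#' @return Bound fraction(s) in \[0, 1\].
#' @export
fraction_bound <- function(r, r_min, r_max, lam = 1, r_sd = 0) {
  stopifnot_finite(r, "r")
  stopifnot_finite(lam, "lam", positive = TRUE)
  stopifnot_finite(r_sd, "r_sd", non_negative = TRUE)
  if (!is.finite(r_min) || !is.finite(r_max) || r_max <= r_min) {
    dl_abort("plateaus must satisfy r_max > r_min", "dl_invalid_input")
  }
  tol <- 3 * max(r_sd) + 1e-9 * (r_max - r_min)
  low <- r < r_min
  high <- r > r_max
  if (any(r < r_min - tol) || any(r > r_max + tol)) {
    dl_abort("anisotropy outside [r_min, r_max] beyond 3*r_sd tolerance",
             "dl_invalid_input")
  }
  if (any(low | high)) {
    dl_warn("anisotropy overshoots a plateau within tolerance; clamped",
            "dl_clamped")
    r <- pmin(pmax(r, r_min), r_max)
  }
  (r - r_min) / (lam * (r_max - r) + (r - r_min))
}

#' Bound tracer concentration under ligand depletion
#'
#' The single-site binding isotherm without the free-ligand approximation:
#' for total titrant (protein) `x`, tracer total `FL` and dissociation
#' constant `Kd`, the complex concentration is the physical root of the
#' mass-balance quadratic,
#' `y = ((Kd + x + FL) - sqrt((Kd + x + FL)^2 - 4*x*FL)) / 2`.
#'
#' @param x total titrant concentration (uM, >= 0; vectorized).
#' @param Kd dissociation constant (uM, > 0).
#' @param FL total fluorescent-ligand (tracer) concentration (uM, > 0).
#' @return Bound tracer concentration(s), in `[0, min(x, FL)]`.
#' @examples
#' direct_bound_concentration(x = 1, Kd = 1, FL = 0.05)  # 0.0246875
#' @export
direct_bound_concentration <- function(x, Kd, FL) {
  stopifnot_finite(x, "x", non_negative = TRUE)
  stopifnot_finite(Kd, "Kd", positive = TRUE)
  stopifnot_finite(FL, "FL", positive = TRUE)
  s <- Kd + x + FL
  disc <- s * s - 4 * x * FL
  # disc >= Kd^2 > 0 analytically; the rationalized form of the smaller
  # root avoids catastrophic cancellation when s >> FL
  y <- 2 * x * FL / (s + sqrt(pmax(disc, 0)))
  pmin(pmax(y, 0), pmin(x, FL))
}

#' Four-parameter sigmoidal logistic parameters
#'
#' @param r_max plateau approached as x -> Inf (for p > 0).
#' @param r_min plateau approached as x -> 0 (for p > 0). Plateaus are
#'   deliberately unordered: descending competition curves are fitted with
#'   `r_min > r_max` or, equivalently, with the sign of `p` flipped.
#' @param x0 curve midpoint (uM, > 0); the IC50 of a competition curve.
#' @param p Hill-type slope (dimensionless, nonzero).
#' @return A `logistic_params` list.
#' @export
logistic_params <- function(r_max, r_min, x0, p) {
  stopifnot_finite(r_max, "r_max")
  stopifnot_finite(r_min, "r_min")
  stopifnot_finite(x0, "x0", positive = TRUE)
  stopifnot_finite(p, "p")
  if (p == 0) dl_abort("slope `p` must be nonzero", "dl_invalid_input")
  structure(list(r_max = r_max, r_min = r_min, x0 = x0, p = p),
            class = "logistic_params")
}

#' Evaluate the sigmoidal logistic model
#'
#' `y = r_max + (r_min - r_max) / (1 + (x/x0)^p)`. At `x = x0` this is the
#' plateau mean regardless of `p`; for `p > 0` the curve runs from `r_min`
#' at `x -> 0` to `r_max` at `x -> Inf`.
#'
#' @param x titrant concentration (uM, >= 0; vectorized).
#' @param params a [logistic_params()].
#' @return Model anisotropy value(s).
#' @export
logistic_value <- function(x, params) {
  stopifnot_finite(x, "x", non_negative = TRUE)
  stopifnot(inherits(params, "logistic_params"))
  with(params, {
    ratio <- (x / x0)^p
    # x = 0 with p < 0 gives ratio = Inf -> y = r_max; make that explicit
    y <- r_max + (r_min - r_max) / (1 + ratio)
    y[is.infinite(ratio)] <- r_max
    y
  })
}

#' Titration series with replicate statistics
#'
#' Ordered (concentration, anisotropy) points for a direct or competition
#' titration. Concentrations must be unique and strictly positive except for
#' an optional single zero point; points are stored sorted ascending.
#'
#' @param x titrant concentrations (uM).
#' @param r_mean mean anisotropy per point.
#' @param r_sd standard deviation per point (0 allowed).
#' @param n_rep replicates per point (integer >= 1).
#' @return A `titration_series` data frame.
#' @export
titration_series <- function(x, r_mean, r_sd = 0, n_rep = 1L) {
  stopifnot_finite(x, "x", non_negative = TRUE)
  stopifnot_finite(r_mean, "r_mean")
  stopifnot_finite(r_sd, "r_sd", non_negative = TRUE)
  n <- length(x)
  if (length(r_mean) != n) {
    dl_abort("`x` and `r_mean` lengths differ", "dl_invalid_input")
  }
  if (anyDuplicated(x)) {
    dl_abort("concentrations must be unique", "dl_invalid_input")
  }
  if (sum(x == 0) > 1) {
    dl_abort("at most one zero-concentration point allowed", "dl_invalid_input")
  }
  out <- data.frame(x = x, r_mean = r_mean,
                    r_sd = rep_len(r_sd, n),
                    n_rep = as.integer(rep_len(n_rep, n)))
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("titration_series", "data.frame")
  out
}

# Shared logistic least-squares fit. Weighted by 1/r_sd^2 when the series
# carries replicate SDs (n_rep > 1 and all sds positive). Returns the nls
# object plus extracted parameters/standard errors.
fit_logistic <- function(series, weighted = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  dat <- series[series$x > 0, , drop = FALSE]
  if (nrow(dat) < 6) {
    dl_abort("need >= 6 positive-concentration points for a logistic fit",
             "dl_invalid_input")
  }
  rng <- range(dat$r_mean)
  if (diff(rng) <= 1e-10) {
    dl_abort("flat series: no transition to fit", "dl_fit_error")
  }
  # analytic initialization: plateaus from the low-/high-x ends, x0 from the
  # concentration nearest the half-range crossing, slope +1 (sign free).
  r_lo_end <- mean(utils::head(dat$r_mean, 2))
  r_hi_end <- mean(utils::tail(dat$r_mean, 2))
  half <- (r_lo_end + r_hi_end) / 2
  x0_start <- dat$x[which.min(abs(dat$r_mean - half))]
  if (x0_start <= 0) x0_start <- stats::median(dat$x)
  w <- NULL
  if (weighted && all(dat$n_rep > 1) && all(dat$r_sd > 0)) {
    w <- 1 / dat$r_sd^2
  }
  fit <- tryCatch(
    stats::nls(
      r_mean ~ r_max + (r_min - r_max) / (1 + exp(p * (log(x) - log(x0)))),
      data = dat,
      start = list(r_min = r_lo_end, r_max = r_hi_end,
                   x0 = x0_start, p = 1),
      weights = w,
      algorithm = "port",
      lower = c(r_min = -1, r_max = -1, x0 = min(dat$x) / 1e3, p = -20),
      upper = c(r_min = 1, r_max = 1, x0 = max(dat$x) * 1e3, p = 20),
      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                   warnOnly = TRUE)
    ),
    error = function(e) {
      dl_abort(paste0("logistic fit failed: ", conditionMessage(e)),
               "dl_fit_error")
    }
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  list(fit = fit,
       params = logistic_params(r_max = cf[["r_max"]], r_min = cf[["r_min"]],
                                x0 = cf[["x0"]], p = cf[["p"]]),
       se = se)
}

#' Fit a competition titration with the sigmoidal logistic model
#'
#' Weighted nonlinear least squares of the four-parameter logistic; the
#' midpoint `x0` is reported as the IC50. Plateaus are left unordered so the
#' same call fits ascending (direct) and descending (competition) curves.
#'
#' @param series a [titration_series()] with at least 6 positive points.
#' @param weighted use `1/r_sd^2` weights when replicate SDs are available.
#'   Off by default: with the protocol's triplicates, per-point SDs are
#'   2-degree-of-freedom estimates whose inverse-variance weights correlate
#'   with the residuals and measurably bias the fitted midpoint; unweighted
#'   least squares is the safer estimator at this replicate depth.
#' @return An object of class `ic50_fit`: list with `ic50`, `ic50_se`,
#'   `params` ([logistic_params()]), `se` (all four standard errors),
#'   `fit` (the underlying `nls` object).
#' @export
fit_ic50 <- function(series, weighted = FALSE) {
  lf <- fit_logistic(series, weighted = weighted)
  structure(list(ic50 = lf$params$x0,
                 ic50_se = unname(lf$se[["x0"]]),
                 params = lf$params, se = lf$se, fit = lf$fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g +/- %.2g uM (logistic midpoint, slope p = %.3g)\n",
              x$ic50, x$ic50_se, x$params$p))
  invisible(x)
}

#' Fit a direct titration for the tracer dissociation constant
#'
#' Two-stage procedure mirroring the direct-titration analysis: (1) fit the
#' four-parameter logistic to estimate the free- and bound-tracer plateaus
#' `r_min`/`r_max`; (2) convert anisotropies to bound fractions via
#' [fraction_bound()] (with intensity ratio `lam`); (3) least-squares fit of
#' the ligand-depletion quadratic [direct_bound_concentration()] for `Kd`.
#'
#' @param series a [titration_series()] of protein concentration vs tracer
#'   anisotropy; >= 6 points spanning the transition.
#' @param FL final tracer concentration in the well (uM).
#' @param lam intensity ratio bound/unbound (default 1).
#' @param weighted weight the plateau pre-fit by replicate SDs.
#' @return An object of class `kd_fit`: list with `Kd`, `Kd_se`, `r_min`,
#'   `r_max`, `lam`, `FL`, `logistic` (stage-1 result), `fit` (stage-3 `nls`).
#' @export
fit_direct_kd <- function(series, FL, lam = 1, weighted = FALSE) {
  stopifnot_finite(FL, "FL", positive = TRUE)
  lf <- fit_logistic(series, weighted = weighted)
  pl <- sort(c(lf$params$r_min, lf$params$r_max))
  r_min <- pl[1]; r_max <- pl[2]
  dat <- series[series$x > 0, , drop = FALSE]
  # plateau clamping tolerance: replicate noise plus the stage-1 model's own
  # residual scale (the logistic only approximates the depletion quadratic)
  sig <- max(max(dat$r_sd), stats::sd(stats::resid(lf$fit)))
  Lb <- suppressWarnings(
    fraction_bound(dat$r_mean, r_min, r_max, lam = lam, r_sd = sig)
  )
  dd <- data.frame(x = dat$x, Lb = Lb, r = dat$r_mean)
  kd_start <- max(lf$params$x0 - FL / 2, min(dat$x))
  fit0 <- tryCatch(
    stats::nls(Lb ~ direct_bound_concentration(x, Kd, FL) / FL,
               data = dd, start = list(Kd = kd_start),
               algorithm = "port",
               lower = c(Kd = 1e-9), upper = c(Kd = 1e9),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) {
      dl_abort(paste0("Kd fit failed: ", conditionMessage(e)), "dl_fit_error")
    }
  )
  # joint refinement on the anisotropy scale: freezing the logistic plateau
  # estimates biases Kd (the logistic only approximates the depletion
  # quadratic), so re-fit (Kd, r_min, r_max) against the exact model with
  # the staged estimates as starting values.
  span <- r_max - r_min
  fit <- tryCatch(
    stats::nls(
      r ~ r_lo + (r_hi - r_lo) * direct_bound_concentration(x, Kd, FL) / FL,
      data = dd,
      start = list(Kd = stats::coef(fit0)[["Kd"]], r_lo = r_min,
                   r_hi = r_max),
      algorithm = "port",
      lower = c(Kd = 1e-9, r_lo = r_min - span, r_hi = r_min),
      upper = c(Kd = 1e9, r_lo = r_max, r_hi = r_max + span),
      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) fit0
  )
  cf <- stats::coef(fit)
  Kd <- cf[["Kd"]]
  Kd_se <- tryCatch(summary(fit)$coefficients["Kd", "Std. Error"],
                    error = function(e) NA_real_)
  if ("r_lo" %in% names(cf)) {
    r_min <- cf[["r_lo"]]; r_max <- cf[["r_hi"]]
  }
  structure(list(Kd = Kd, Kd_se = Kd_se, r_min = r_min, r_max = r_max,
                 lam = lam, FL = FL, logistic = lf, fit = fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g +/- %.2g uM (plateaus r_min = %.4g, r_max = %.4g)\n",
              x$Kd, x$Kd_se, x$r_min, x$r_max))
  invisible(x)
}

#' Competitive ternary binding system
#'
#' Generative description of a competition fluorescence-anisotropy well:
#' one protein, a fluorescent tracer and an unlabeled competitor, each
#' binding the same site with independent dissociation constants.
#'
#' @param P_tot total protein concentration (uM).
#' @param FL total tracer concentration (uM).
#' @param Kd_tracer tracer dissociation constant (uM).
#' @param Kd_comp competitor dissociation constant (uM).
#' @return A `competition_system` list.
#' @export
competition_system <- function(P_tot, FL, Kd_tracer, Kd_comp) {
  for (nm in c("P_tot", "FL", "Kd_tracer", "Kd_comp")) {
    stopifnot_finite(get(nm), nm, positive = TRUE)
  }
  structure(list(P_tot = P_tot, FL = FL,
                 Kd_tracer = Kd_tracer, Kd_comp = Kd_comp),
            class = "competition_system")
}

#' Exact ternary competition equilibrium
#'
#' Solves the coupled mass-balance/mass-action system for protein P, tracer
#' L and competitor C sharing one site, by damped fixed-point iteration on
#' the three free concentrations:
#' \deqn{P_f = P_{tot} / (1 + L_f/K_L + C_f/K_C),\quad
#'       L_f = L_{tot} / (1 + P_f/K_L),\quad
#'       C_f = C_{tot} / (1 + P_f/K_C).}
#' With no competitor this reduces to [direct_bound_concentration()].
#'
#' @param sys a [competition_system()].
#' @param C_tot total competitor concentration (uM, >= 0; vectorized).
#' @param damping fixed-point damping factor in (0, 1].
#' @param tol relative convergence tolerance on all free species.
#' @param max_iter iteration cap; exceeding it raises a numerical error.
#' @return A data frame with one row per `C_tot`: `bound_tracer`,
#'   `bound_comp`, `free_protein`, `iterations`.
#' @export
ternary_equilibrium <- function(sys, C_tot, damping = 0.5, tol = 1e-12,
                                max_iter = 10000L) {
  stopifnot(inherits(sys, "competition_system"))
  stopifnot_finite(C_tot, "C_tot", non_negative = TRUE)
  one <- function(Ct) {
    P_tot <- sys$P_tot; FL <- sys$FL
    KL <- sys$Kd_tracer; KC <- sys$Kd_comp
    Pf <- P_tot; Lf <- FL; Cf <- Ct
    for (it in seq_len(max_iter)) {
      Pf_new <- P_tot / (1 + Lf / KL + Cf / KC)
      Pf2 <- (1 - damping) * Pf + damping * Pf_new
      Lf_new <- FL / (1 + Pf2 / KL)
      Lf2 <- (1 - damping) * Lf + damping * Lf_new
      Cf_new <- if (Ct > 0) Ct / (1 + Pf2 / KC) else 0
      Cf2 <- (1 - damping) * Cf + damping * Cf_new
      Pf <- Pf2; Lf <- Lf2; Cf <- Cf2
      # converge on the true mass-balance residuals, not the (damped) step
      # size, which understates the error when contraction is slow
      res <- max(
        abs(Pf * (1 + Lf / KL + Cf / KC) - P_tot) / P_tot,
        abs(Lf * (1 + Pf / KL) - FL) / FL,
        if (Ct > 0) abs(Cf * (1 + Pf / KC) - Ct) / Ct else 0)
      if (res < tol) {
        return(c(bound_tracer = FL - Lf, bound_comp = Ct - Cf,
                 free_protein = Pf, iterations = it))
      }
    }
    dl_abort("ternary equilibrium fixed-point iteration did not converge",
             "dl_numeric_error")
  }
  res <- t(vapply(C_tot, one, numeric(4)))
  out <- as.data.frame(res)
  out$iterations <- as.integer(out$iterations)
  out
}
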