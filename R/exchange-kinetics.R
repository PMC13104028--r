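#' Extracted-ion-chromatogram time-course records
#'
#' One row per sampling time of a hydrazone-exchange reaction, holding the
#' integrated EIC peak areas of the starting (reactant) and exchanged
#' (product) hydrazones. Extra `area_*` columns for side species are kept
#' and included in the normalization.
#'
#' @param time_h sampling times (hours, >= 0).
#' @param area_reactant peak area of the starting hydrazone (>= 0).
#' @param area_product peak area of the exchanged hydrazone (>= 0).
#' @param ... additional named `area_*` numeric columns (side species).
#' @return An `eic_records` data frame.
#' @export
eic_records <- function(time_h, area_reactant, area_product, ...) {
  stopifnot_finite(time_h, "time_h", non_negative = TRUE)
  stopifnot_finite(area_reactant, "area_reactant", non_negative = TRUE)
  stopifnot_finite(area_product, "area_product", non_negative = TRUE)
  extra <- list(...)
  if (length(extra) && (is.null(names(extra)) ||
                        !all(startsWith(names(extra), "area_")))) {
    dl_abort("side-species columns must be named area_*", "dl_invalid_input")
  }
  out <- data.frame(time_h = time_h, area_reactant = area_reactant,
                    area_product = area_product)
  for (nm in names(extra)) out[[nm]] <- stopifnot_finite(extra[[nm]], nm,
                                                         non_negative = TRUE)
  if (any(rowSums(out[, -1, drop = FALSE]) <= 0)) {
    dl_abort("record with zero total peak area", "dl_degenerate")
  }
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eic_records", "data.frame")
  out
}

#' Exchange conversion from normalized peak areas
#'
#' `conversion = area_product / sum(all area columns)`. With only the two
#' named species this is product / (reactant + product); when side-species
#' columns are present the normalization spans all listed species.
#'
#' @param records an [eic_records()] table (the constructor rejects
#'   zero-total-area rows).
#' @return Conversion fraction(s) in \[0, 1\], one per record.
#' @export
conversion <- function(records) {
  if (!inherits(records, "eic_records")) {
    records <- do.call(eic_records, as.list(records))
  }
  areas <- records[, setdiff(names(records), "time_h"), drop = FALSE]
  records$area_product / rowSums(areas)
}

#' Fit a first-order approach-to-equilibrium time course
#'
#' Least-squares fit of `c(t) = c_eq * (1 - exp(-k * t))` to the observed
#' conversions — the pseudo-first-order model appropriate for exchange under
#' a fixed aldehyde excess.
#'
#' @param records an [eic_records()] table with >= 3 time points, at least
#'   one at t >= 1 h.
#' @return An `exchange_fit`: list with `c_eq`, `k` (per hour), standard
#'   errors `c_eq_se`/`k_se`, `residuals`, and the underlying `fit`.
#' @export
fit_timecourse <- function(records) {
  if (!inherits(records, "eic_records")) {
    records <- do.call(eic_records, as.list(records))
  }
  conv <- conversion(records)
  dat <- data.frame(t = records$time_h, conv = conv)
  dat <- dat[is.finite(dat$conv), , drop = FALSE]
  if (nrow(dat) < 3 || max(dat$t) < 1) {
    dl_abort("need >= 3 time points including t >= 1 h", "dl_invalid_input")
  }
  c_eq0 <- min(max(dat$conv), 0.999)
  half_idx <- which.min(abs(dat$conv - c_eq0 / 2))
  k0 <- log(2) / max(dat$t[half_idx], 1e-3)
  fit <- tryCatch(
    stats::nls(conv ~ c_eq * (1 - exp(-k * t)), data = dat,
               start = list(c_eq = max(c_eq0, 0.1), k = k0),
               algorithm = "port",
               lower = c(c_eq = 1e-6, k = 1e-9),
               upper = c(c_eq = 1, k = 1e6),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) {
      dl_abort(paste0("time-course fit failed: ", conditionMessage(e)),
               "dl_fit_error")
    }
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(c_eq = NA_real_, k = NA_real_))
  structure(list(c_eq = cf[["c_eq"]], k = cf[["k"]],
                 c_eq_se = unname(se[["c_eq"]]), k_se = unname(se[["k"]]),
                 residuals = stats::resid(fit), fit = fit),
            class = "exchange_fit")
}

#' Time to reach a given fraction of the exchange plateau
#'
#' For the single-exponential model the time at which conversion reaches
#' `fraction_of_plateau * c_eq` is `-log(1 - fraction_of_plateau) / k`.
#' Formalizes the practical-equilibration judgment (e.g. 95% of plateau).
#'
#' @param fit an [fit_timecourse()] result (or any list with `k > 0`).
#' @param fraction_of_plateau target fraction in (0, 1).
#' @return Time in hours.
#' @export
equilibration_time <- function(fit, fraction_of_plateau) {
  k <- fit$k
  stopifnot_finite(k, "k", positive = TRUE)
  stopifnot_finite(fraction_of_plateau, "fraction_of_plateau", positive = TRUE)
  if (any(fraction_of_plateau >= 1)) {
    dl_abort("fraction_of_plateau must be < 1 (plateau is asymptotic)",
             "dl_invalid_input")
  }
  -log(1 - fraction_of_plateau) / k
}

#' Hydrazine-resin loading from the piperidine-fulvene absorbance assay
#'
#' Per-assay loading `L (mmol/g) = (101 * A301) / (7.8 * weight_mg)` from
#' the absorbance at 301 nm of the Fmoc-deprotection supernatant, averaged
#' over replicate assays (the assay is run in triplicate).
#'
#' @param A301 absorbance at 301 nm (>= 0), one value per assay.
#' @param weight_mg resin mass per assay (mg, > 0).
#' @return List with `per_assay` loadings and their `mean` (mmol/g).
#' @export
resin_loading <- function(A301, weight_mg) {
  stopifnot_finite(A301, "A301", non_negative = TRUE)
  stopifnot_finite(weight_mg, "weight_mg", positive = TRUE)
  L <- 101 * A301 / (7.8 * rep_len(weight_mg, length(A301)))
  list(per_assay = L, mean = mean(L))
}
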