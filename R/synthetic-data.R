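#' Simulation configuration for the synthetic-data generators
#'
#' One object fixes everything a generator needs beyond the science
#' parameters: the random seed, the noise model and the plate protocol
#' (replicates, serial-dilution layout, sequential-addition mixing). Every
#' generator is a deterministic function of `(cfg$seed, parameters)`.
#'
#' Noise is injected either on the raw polarization channels (additive
#' Gaussian SD `noise_sd_channels` on P and S, the physical place noise
#' arises) or directly on anisotropy (`noise_sd_r`) — never both; the
#' constructor enforces mutual exclusion. The channel-noise default is
#' calibrated so that the induced anisotropy SD is about 0.002 near
#' r = 0.2 at the default intensity scale `I0 = 100`.
#'
#' @param seed integer random seed.
#' @param noise `"channels"`, `"r"` or `"none"`.
#' @param noise_sd_channels Gaussian SD on P and S (arbitrary units).
#' @param noise_sd_r Gaussian SD on anisotropy.
#' @param noise_cv_area multiplicative CV for EIC peak-area noise.
#' @param I0 total-intensity scale of synthetic wells (arbitrary units).
#' @param G instrument gain factor.
#' @param n_replicates replicate wells per titration point.
#' @param dilution_points number of serial-dilution points.
#' @param dilution_factor serial dilution factor (> 1).
#' @param mix_dilution dilution from sequential equal-volume additions
#'   (three 20 uL additions per well => 3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, noise = c("channels", "r", "none"),
                       noise_sd_channels = 0.124, noise_sd_r = 0.002,
                       noise_cv_area = 0.01, I0 = 100, G = 1,
                       n_replicates = 3L, dilution_points = 24L,
                       dilution_factor = 2, mix_dilution = 3) {
  noise <- match.arg(noise)
  stopifnot_finite(seed, "seed")
  stopifnot_finite(noise_sd_channels, "noise_sd_channels", non_negative = TRUE)
  stopifnot_finite(noise_sd_r, "noise_sd_r", non_negative = TRUE)
  stopifnot_finite(noise_cv_area, "noise_cv_area", non_negative = TRUE)
  stopifnot_finite(I0, "I0", positive = TRUE)
  stopifnot_finite(G, "G", positive = TRUE)
  stopifnot_finite(dilution_factor, "dilution_factor", positive = TRUE)
  if (dilution_factor <= 1) {
    dl_abort("dilution_factor must exceed 1", "dl_invalid_input")
  }
  stopifnot_finite(mix_dilution, "mix_dilution", positive = TRUE)
  structure(list(seed = as.integer(seed), noise = noise,
                 noise_sd_channels = noise_sd_channels,
                 noise_sd_r = noise_sd_r, noise_cv_area = noise_cv_area,
                 I0 = I0, G = G, n_replicates = as.integer(n_replicates),
                 dilution_points = as.integer(dilution_points),
                 dilution_factor = dilution_factor,
                 mix_dilution = mix_dilution),
            class = "sim_config")
}

# Final well concentrations for a serial dilution of `stock` followed by
# sequential-addition mixing: top final = stock / mix_dilution, then one
# dilution_factor step per point.
serial_dilution <- function(stock, cfg, n_points = cfg$dilution_points) {
  stock / cfg$mix_dilution / cfg$dilution_factor^(seq_len(n_points) - 1)
}

# Noise application shared by the titration generators. Takes true r per
# well, returns measured r per well, honoring the configured noise channel.
apply_r_noise <- function(r_true, cfg) {
  switch(cfg$noise,
    none = r_true,
    r = r_true + stats::rnorm(length(r_true), 0, cfg$noise_sd_r),
    channels = {
      ch <- channels_from_anisotropy(r_true, I = cfg$I0, G = cfg$G)
      P <- pmax(ch$P + stats::rnorm(length(r_true), 0, cfg$noise_sd_channels),
                0)
      S <- pmax(ch$S + stats::rnorm(length(r_true), 0, cfg$noise_sd_channels),
                0)
      anisotropy_from_channels(channel_reading(P, S, cfg$G))$r
    })
}

# Collapse per-replicate measured r into a titration_series.
collapse_replicates <- function(x, r_mat) {
  titration_series(
    x = x,
    r_mean = rowMeans(r_mat),
    r_sd = apply(r_mat, 1, function(v) if (length(v) > 1) stats::sd(v) else 0),
    n_rep = ncol(r_mat)
  )
}

#' Generate a direct-titration plate
#'
#' Simulates the direct tracer titration: protein serially diluted
#' (`dilution_points` x `dilution_factor`-fold) from `protein_stock`, tracer
#' added from `FL_stock`, both diluted `mix_dilution`-fold by the sequential
#' additions. True anisotropy comes from the ligand-depletion quadratic
#' mapped between the plateaus (intensity ratio `lam = 1`), is inverted to
#' raw channels and noised per the configuration.
#'
#' @param cfg a [sim_config()].
#' @param Kd true tracer dissociation constant (uM).
#' @param FL_stock tracer stock concentration (uM; 0.05 = 50 nM).
#' @param protein_stock protein stock concentration (uM).
#' @param r_min,r_max free-/bound-tracer anisotropy plateaus.
#' @return List with `series` (a [titration_series()] of replicate-averaged
#'   anisotropy), `plate` (per-well raw channels and derived r), and
#'   `truth` (all ground-truth parameters and the noiseless series).
#' @export
gen_direct_titration <- function(cfg, Kd = 0.81, FL_stock = 0.05,
                                 protein_stock = 200,
                                 r_min = 0.05, r_max = 0.20) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_finite(Kd, "Kd", positive = TRUE)
  stopifnot_finite(FL_stock, "FL_stock", positive = TRUE)
  stopifnot_finite(protein_stock, "protein_stock", positive = TRUE)
  set.seed(cfg$seed)
  x <- serial_dilution(protein_stock, cfg)
  FL <- FL_stock / cfg$mix_dilution
  Lb <- direct_bound_concentration(x, Kd, FL) / FL
  r_true <- r_min + (r_max - r_min) * Lb
  n <- length(x)
  r_mat <- matrix(NA_real_, n, cfg$n_replicates)
  plates <- vector("list", cfg$n_replicates)
  for (j in seq_len(cfg$n_replicates)) {
    r_meas <- apply_r_noise(r_true, cfg)
    r_mat[, j] <- r_meas
    ch <- channels_from_anisotropy(r_meas, I = cfg$I0, G = cfg$G)
    plates[[j]] <- data.frame(replicate = j, x = x, P = ch$P, S = ch$S,
                              G = cfg$G, r = r_meas)
  }
  series <- collapse_replicates(x, r_mat)
  list(series = series,
       plate = do.call(rbind, plates),
       truth = list(Kd = Kd, FL = FL, r_min = r_min, r_max = r_max,
                    x = x, r_true = r_true,
                    series_noiseless = titration_series(x, r_true)))
}

#' Generate a competition-titration series from the exact ternary model
#'
#' Simulates the competition assay: competitor serially diluted from
#' `top_stock` over `n_points`, fixed final protein and tracer, true bound
#' tracer from [ternary_equilibrium()], anisotropy mapped between the
#' plateaus and noised per the configuration.
#'
#' @param cfg a [sim_config()].
#' @param sys a [competition_system()] (final concentrations; the standard
#'   competition protocol is 1 uM protein, 16.7 nM tracer).
#' @param top_stock competitor stock for the first point (uM).
#' @param n_points number of dilution points (default 16).
#' @param r_min,r_max anisotropy plateaus of the free/bound tracer.
#' @return List with `series`, and `truth` (including the noiseless series
#'   and per-point bound fractions).
#' @export
gen_competition_titration <- function(cfg, sys, top_stock = 5000,
                                      n_points = 16L,
                                      r_min = 0.05, r_max = 0.20) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sys, "competition_system"))
  stopifnot_finite(top_stock, "top_stock", positive = TRUE)
  set.seed(cfg$seed)
  C <- serial_dilution(top_stock, cfg, n_points = n_points)
  eq <- ternary_equilibrium(sys, C)
  Lb <- eq$bound_tracer / sys$FL
  r_true <- r_min + (r_max - r_min) * Lb
  r_mat <- vapply(seq_len(cfg$n_replicates),
                  function(j) apply_r_noise(r_true, cfg),
                  numeric(length(C)))
  series <- collapse_replicates(C, r_mat)
  list(series = series,
       truth = list(sys = sys, C = C, Lb = Lb, r_true = r_true,
                    r_min = r_min, r_max = r_max,
                    series_noiseless = titration_series(C, r_true)))
}

#' Calibrate a competitor dissociation constant to a target IC50
#'
#' Root-finds the competitor `Kd` at which the *noiseless* competition curve
#' generated from the exact ternary equilibrium, fitted with the sigmoidal
#' logistic, has midpoint exactly `target_ic50`. Used to plant competitors
#' at printed potencies.
#'
#' @param target_ic50 desired fitted midpoint (uM).
#' @param cfg a [sim_config()] (noise setting ignored; the calibration curve
#'   is noiseless).
#' @param P_tot,FL,Kd_tracer fixed system constants (uM).
#' @param top_stock,n_points competitor dilution layout.
#' @param r_min,r_max anisotropy plateaus.
#' @param interval log10-Kd search interval.
#' @return Calibrated competitor Kd (uM).
#' @export
calibrate_competitor_kd <- function(target_ic50, cfg, P_tot = 1,
                                    FL = 0.05 / 3, Kd_tracer = 0.81,
                                    top_stock = 5000, n_points = 16L,
                                    r_min = 0.05, r_max = 0.20,
                                    interval = c(-4, 5)) {
  stopifnot_finite(target_ic50, "target_ic50", positive = TRUE)
  cfg0 <- cfg; cfg0$noise <- "none"; cfg0$n_replicates <- 1L
  midpoint_at <- function(log10_kd) {
    sys <- competition_system(P_tot, FL, Kd_tracer, 10^log10_kd)
    gen <- gen_competition_titration(cfg0, sys, top_stock = top_stock,
                                     n_points = n_points,
                                     r_min = r_min, r_max = r_max)
    fit_ic50(gen$series, weighted = FALSE)$ic50
  }
  root <- stats::uniroot(function(lk) midpoint_at(lk) - target_ic50,
                         interval = interval, tol = 1e-10)
  10^root$root
}

#' Generate a duplicate-well screen plate
#'
#' Simulates one dynamic-ligation screen plate: `n_fragments` sample wells
#' in duplicate, plus buffer and anchor control wells. Non-planted fragments
#' sit at the buffer mean (true relative anisotropy 1); planted binders are
#' assigned the true relative anisotropies in `planted`. The anchor control
#' sits between buffer and full displacement, reflecting the anchor
#' peptide's intermediate potency. Noise is Gaussian on anisotropy with SD
#' `cfg$noise_sd_r` (channel noise is equivalent at this readout level).
#'
#' @param cfg a [sim_config()] (`n_replicates` is ignored: the screen design
#'   is duplicate wells).
#' @param n_fragments number of library fragments on the plate.
#' @param planted named numeric vector: true r_rel for planted binders;
#'   names must be fragment ids of the form produced here (`F001`, ...) or
#'   arbitrary ids included in the plate.
#' @param r_buffer true buffer-well anisotropy.
#' @param anchor_r_rel true anchor-control relative anisotropy.
#' @param n_buffer,n_anchor control well counts.
#' @return List with `wells` (a [screen_wells()] table) and `truth`
#'   (per-fragment true r_rel sidecar).
#' @export
gen_screen_plate <- function(cfg, n_fragments = 165L,
                             planted = numeric(0), r_buffer = 0.2,
                             anchor_r_rel = 0.8, n_buffer = 24L,
                             n_anchor = 24L) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_finite(r_buffer, "r_buffer", positive = TRUE)
  stopifnot_finite(anchor_r_rel, "anchor_r_rel", positive = TRUE)
  set.seed(cfg$seed)
  frag_ids <- sprintf("F%03d", seq_len(n_fragments))
  if (length(planted)) {
    if (is.null(names(planted))) {
      names(planted) <- frag_ids[seq_along(planted)]
    }
    if (!all(names(planted) %in% frag_ids)) {
      dl_abort("planted fragment ids not on the plate", "dl_invalid_input")
    }
  }
  true_rel <- stats::setNames(rep(1, n_fragments), frag_ids)
  true_rel[names(planted)] <- planted
  sd_r <- if (cfg$noise == "none") 0 else cfg$noise_sd_r
  mk <- function(true_r, n) true_r + stats::rnorm(n, 0, sd_r)
  sample_wells <- screen_wells(
    fragment_id = rep(frag_ids, each = 2),
    replicate_index = rep(1:2, times = n_fragments),
    r = mk(rep(true_rel * r_buffer, each = 2), 2 * n_fragments),
    role = "sample")
  buffer_wells <- screen_wells(fragment_id = NA, replicate_index = 1:n_buffer,
                               r = mk(rep(r_buffer, n_buffer), n_buffer),
                               role = "buffer")
  anchor_wells <- screen_wells(fragment_id = NA, replicate_index = 1:n_anchor,
                               r = mk(rep(anchor_r_rel * r_buffer, n_anchor),
                                      n_anchor),
                               role = "anchor")
  wells <- rbind(sample_wells, buffer_wells, anchor_wells)
  class(wells) <- c("screen_wells", "data.frame")
  list(wells = wells,
       truth = data.frame(fragment_id = frag_ids,
                          true_r_rel = unname(true_rel),
                          planted = frag_ids %in% names(planted)))
}

# Small pool of valid aldehyde-like SMILES used to decorate synthetic
# fragment tables; purely synthetic stand-ins, not the screened library.
.SYNTH_SMILES <- c(
  "O=Cc1ccccc1", "O=Cc1ccccc1O", "O=Cc1ccc(O)cc1", "O=Cc1ccc(C)cc1",
  "O=Cc1ccc(OC)cc1", "O=Cc1cccc(C(=O)O)c1", "O=Cc1ccc(Cl)cc1",
  "O=Cc1ccncc1", "O=Cc1ccco1", "O=Cc1cccs1", "O=CC1CCCCC1",
  "O=Cc1ccc(N)cc1", "O=Cc1ccc(F)cc1", "O=Cc1cccc(O)c1C",
  "O=Cc1ccc(CC(C)C)cc1", "O=Cc1cc(O)ccc1O", "O=Cc1cccnc1",
  "O=Cc1ccc2ccccc2c1", "O=CCc1ccccc1", "O=Cc1cc(C)ccc1O"
)

#' Generate a fragment descriptor table with planted filter violations
#'
#' Draws descriptors that straddle the rule-of-three bounds with known
#' ground truth: in-bounds records are sampled inside every window,
#' violations are planted by pushing one randomly chosen descriptor out of
#' bounds. A synthetic SMILES from a small built-in aldehyde pool is
#' attached to each record.
#'
#' @param cfg a [sim_config()].
#' @param n number of fragments.
#' @param n_violations number of records planted out of bounds.
#' @return List with `fragments` (a [fragment_table()]) and `truth`
#'   (per-record expected verdict and violated rule).
#' @export
gen_fragment_table <- function(cfg, n = 200L, n_violations = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n < 1) dl_abort("n must be >= 1", "dl_invalid_input")
  if (n_violations > n) {
    dl_abort("n_violations cannot exceed n", "dl_invalid_input")
  }
  set.seed(cfg$seed)
  ids <- sprintf("S%03d", seq_len(n))
  df <- data.frame(
    fragment_id = ids,
    smiles = rep_len(.SYNTH_SMILES, n),
    MW = stats::runif(n, 90, 390),
    HBA = sample(0:3, n, replace = TRUE),
    HBD = sample(0:3, n, replace = TRUE),
    clogP = stats::runif(n, -2, 5),
    LogS = stats::runif(n, -6, 1),
    stringsAsFactors = FALSE)
  rule <- rep(NA_character_, n)
  if (n_violations > 0) {
    idx <- sample.int(n, n_violations)
    rules <- sample(c("MW", "HBA", "HBD", "clogP"), n_violations,
                    replace = TRUE)
    for (i in seq_along(idx)) {
      j <- idx[i]
      switch(rules[i],
        MW = { df$MW[j] <- sample(c(stats::runif(1, 10, 80),
                                    stats::runif(1, 400, 600)), 1) },
        HBA = { df$HBA[j] <- sample(4:8, 1) },
        HBD = { df$HBD[j] <- sample(4:8, 1) },
        clogP = { df$clogP[j] <- stats::runif(1, 5.01, 9) })
      rule[j] <- rules[i]
    }
  }
  list(fragments = fragment_table(df),
       truth = data.frame(fragment_id = ids,
                          retain = is.na(rule),
                          violated_rule = rule,
                          stringsAsFactors = FALSE))
}

#' Generate a first-order exchange time course
#'
#' Conversions follow `c(t) = c_eq * (1 - exp(-k t))` on the supplied
#' sampling grid (default: the 1, 2, 4, 8, 12, 24, 48 h schedule); peak
#' areas are scaled to a fixed total and perturbed with multiplicative
#' Gaussian noise of CV `cfg$noise_cv_area` (unless noise is `"none"`).
#'
#' @param cfg a [sim_config()].
#' @param c_eq equilibrium conversion fraction in (0, 1].
#' @param k observed rate constant (per hour).
#' @param times sampling times (hours).
#' @param total_area nominal summed peak area per record.
#' @return List with `records` (an [eic_records()] table) and `truth`.
#' @export
gen_timecourse <- function(cfg, c_eq = 0.9, k = 0.125,
                           times = c(1, 2, 4, 8, 12, 24, 48),
                           total_area = 1e6) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_finite(c_eq, "c_eq", positive = TRUE)
  if (c_eq > 1) dl_abort("c_eq must be <= 1", "dl_invalid_input")
  stopifnot_finite(k, "k", positive = TRUE)
  stopifnot_finite(times, "times", non_negative = TRUE)
  set.seed(cfg$seed)
  conv <- c_eq * (1 - exp(-k * times))
  prod_a <- total_area * conv
  reac_a <- total_area * (1 - conv)
  if (cfg$noise != "none" && cfg$noise_cv_area > 0) {
    prod_a <- prod_a * pmax(1 + stats::rnorm(length(times), 0,
                                             cfg$noise_cv_area), 1e-6)
    reac_a <- reac_a * pmax(1 + stats::rnorm(length(times), 0,
                                             cfg$noise_cv_area), 1e-6)
  }
  list(records = eic_records(times, reac_a, prod_a),
       truth = list(c_eq = c_eq, k = k, conversion = conv))
}
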