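make_plate <- function(sample_r, buffer_r, anchor_r, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("F%03d", seq_along(sample_r))
  rbind(
    screen_wells(ids, 1L, sample_r, "sample"),
    screen_wells(NA, seq_along(buffer_r), buffer_r, "buffer"),
    screen_wells(NA, seq_along(anchor_r), anchor_r, "anchor")
  ) -> w
  class(w) <- c("screen_wells", "data.frame")
  w
}

test_that("relative_anisotropy normalizes to the buffer mean", {
  w <- make_plate(sample_r = c(0.189, 0.21, 0.105),
                  buffer_r = c(0.20, 0.22), anchor_r = c(0.15, 0.15))
  w <- relative_anisotropy(w)
  expect_equal(w$r_rel[w$role == "sample"], c(0.9, 1.0, 0.5))
  expect_equal(mean(w$r_rel[w$role == "buffer"]), 1)
  # difference mode
  wd <- relative_anisotropy(make_plate(0.25, c(0.2, 0.2), c(0.15, 0.15)),
                            mode = "difference")
  expect_equal(wd$r_rel[wd$role == "sample"], 0.05)
  # failure modes
  one_buffer <- make_plate(0.2, 0.2, c(0.1, 0.1))
  one_buffer <- one_buffer[-(nrow(one_buffer) - 1), ]
  class(one_buffer) <- c("screen_wells", "data.frame")
  expect_error(relative_anisotropy(
    make_plate(0.2, c(0, 0), c(0.1, 0.1))), class = "dl_degenerate")
})

test_that("replicate_stats uses the n-1 SD and flags singletons", {
  st <- replicate_stats(c(0.9, 1.0, 1.1))
  expect_equal(st$mean, 1.0)
  expect_equal(st$sd, 0.1)
  expect_equal(replicate_stats(c(3, 3))$sd, 0)
  expect_warning(st1 <- replicate_stats(5), class = "dl_single_replicate")
  expect_equal(st1$sd, 0)
  expect_error(replicate_stats(numeric(0)), class = "dl_invalid_input")
})

test_that("compute_thresholds is mean minus k SD per control group", {
  thr <- compute_thresholds(c(1, 1, 1), c(0.9, 1.0, 1.1))
  expect_equal(thr$t_neg, 1.0)
  expect_equal(thr$t_pos, 1.0 - 3 * 0.1)
  expect_error(compute_thresholds(c(1, 1), 0.8), class = "dl_invalid_input")
  thr2 <- compute_thresholds(c(0.9, 1.1), c(0.9, 1.1), k = 2)
  expect_equal(thr2$t_neg, 1 - 2 * sd(c(0.9, 1.1)))
})

test_that("call_hits applies strict inequalities and nested tiers", {
  thr <- structure(list(t_neg = 0.95, t_pos = 0.7, k = 3),
                   class = "threshold_pair")
  res <- structure(
    data.frame(fragment_id = c("A", "B", "C", "D"),
               r_rel_mean = c(0.95, 0.949, 0.70, 0.65),
               r_rel_sd = 0.01, n = 2L, stringsAsFactors = FALSE),
    class = c("screen_results", "data.frame"))
  out <- call_hits(res, thr)
  got <- setNames(as.character(out$tier), out$fragment_id)
  expect_equal(got[["A"]], "none")      # tie at t_neg is not a hit
  expect_equal(got[["B"]], "hit")
  expect_equal(got[["C"]], "hit")       # tie at t_pos stays plain hit
  expect_equal(got[["D"]], "improved")
  # sorted ascending by mean
  expect_equal(out$fragment_id, c("D", "C", "B", "A"))
  # nesting: improved implies hit-threshold passage
  expect_true(all(out$r_rel_mean[out$tier == "improved"] < thr$t_neg))
})

test_that("hit calls are invariant to well order and common rescaling", {
  gp <- gen_screen_plate(sim_config(seed = 21, noise = "r",
                                    noise_sd_r = 0.002),
                         n_fragments = 40,
                         planted = c(F005 = 0.9, F017 = 0.85))
  pipeline <- function(wells) {
    w <- relative_anisotropy(wells)
    thr <- compute_thresholds(w$r_rel[w$role == "buffer"],
                              w$r_rel[w$role == "anchor"])
    call_hits(screen_results(w), thr)
  }
  base <- pipeline(gp$wells)
  # permute wells
  perm <- gp$wells[sample(nrow(gp$wells)), ]
  class(perm) <- c("screen_wells", "data.frame")
  expect_equal(pipeline(perm)$tier, base$tier)
  expect_equal(pipeline(perm)$fragment_id, base$fragment_id)
  # rescale all raw anisotropies by a positive constant
  scaled <- gp$wells
  scaled$r <- scaled$r * 7.3
  class(scaled) <- c("screen_wells", "data.frame")
  expect_equal(pipeline(scaled)$r_rel_mean, base$r_rel_mean,
               tolerance = 1e-12)
  expect_equal(pipeline(scaled)$tier, base$tier)
})

test_that("null plates produce no hits at zero noise and planted binders are found", {
  null_gp <- gen_screen_plate(sim_config(seed = 3, noise = "none"),
                              n_fragments = 30)
  w <- relative_anisotropy(null_gp$wells)
  thr <- compute_thresholds(w$r_rel[w$role == "buffer"],
                            w$r_rel[w$role == "anchor"])
  out <- call_hits(screen_results(w), thr)
  expect_equal(sum(out$tier != "none"), 0)
  # planted far below both thresholds lands in the improved tier
  gp <- gen_screen_plate(sim_config(seed = 4, noise = "r",
                                    noise_sd_r = 0.002),
                         n_fragments = 30, planted = c(F010 = 0.5))
  w <- relative_anisotropy(gp$wells)
  thr <- compute_thresholds(w$r_rel[w$role == "buffer"],
                            w$r_rel[w$role == "anchor"])
  out <- call_hits(screen_results(w), thr)
  expect_equal(as.character(out$tier[out$fragment_id == "F010"]), "improved")
  expect_equal(sum(out$tier != "none"), 1)
})

test_that("lowering noise never loses planted binders", {
  planted <- c(F002 = 0.92, F008 = 0.9, F013 = 0.88)
  recovered <- function(seed, sd) {
    gp <- gen_screen_plate(sim_config(seed = seed, noise = "r",
                                      noise_sd_r = sd),
                           n_fragments = 20, planted = planted)
    w <- relative_anisotropy(gp$wells)
    thr <- compute_thresholds(w$r_rel[w$role == "buffer"],
                              w$r_rel[w$role == "anchor"])
    out <- call_hits(screen_results(w), thr)
    out$fragment_id[out$tier != "none"]
  }
  for (seed in 31:35) {
    hi <- intersect(recovered(seed, 0.004), names(planted))
    lo <- intersect(recovered(seed, 0.001), names(planted))
    expect_true(all(hi %in% lo))
  }
})

test_that("property_correlation joins, ranks and handles degeneracy", {
  res <- structure(
    data.frame(fragment_id = c("A", "B", "C", "D"),
               r_rel_mean = c(0.1, 0.2, 0.3, 0.4),
               r_rel_sd = 0, n = 2L, stringsAsFactors = FALSE),
    class = c("screen_results", "data.frame"))
  frg <- data.frame(fragment_id = c("A", "B", "C", "D"),
                    MW = c(100, 150, 200, 250),
                    LogS = c(-1, -1, -1, -1))
  out <- property_correlation(res, frg)
  expect_equal(unname(out$rho[["MW"]]), 1)           # perfect rank agreement
  expect_true(is.na(out$rho[["LogS"]]))              # zero-variance property
  expect_equal(nrow(out$scatter), 4)
  # zero-variance outcome
  res0 <- res; res0$r_rel_mean <- rep(0.5, 4)
  expect_true(all(is.na(property_correlation(res0, frg)$rho)))
  # missing fragment is a keyed error naming the culprit
  expect_error(property_correlation(res, frg[-2, ]), regexp = "B",
               class = "dl_lookup_error")
  # uncorrelated draws stay near zero
  set.seed(99)
  n <- 165
  resr <- structure(
    data.frame(fragment_id = sprintf("F%03d", 1:n),
               r_rel_mean = rnorm(n, 1, 0.02), r_rel_sd = 0, n = 2L),
    class = c("screen_results", "data.frame"))
  frgr <- data.frame(fragment_id = sprintf("F%03d", 1:n),
                     MW = runif(n, 80, 400), LogS = runif(n, -6, 1))
  expect_lt(max(abs(property_correlation(resr, frgr)$rho)), 0.2)
})
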