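#' Screen plate well table
#'
#' One row per well of a dynamic-ligation screen plate. Sample wells carry a
#' `fragment_id`; control wells are tagged by `role` (`"buffer"` for the
#' negative control, `"anchor"` for the anchor acylhydrazone positive
#' control) and carry no fragment id.
#'
#' @param fragment_id fragment identifier, `NA` for control wells.
#' @param replicate_index integer replicate index (>= 1) within a fragment
#'   or control group.
#' @param r measured anisotropy.
#' @param role `"sample"`, `"buffer"` or `"anchor"`.
#' @return A `screen_wells` data frame.
#' @export
screen_wells <- function(fragment_id, replicate_index, r, role) {
  stopifnot_finite(r, "r")
  role <- match.arg(role, c("sample", "buffer", "anchor"),
                    several.ok = TRUE)
  role <- rep_len(role, length(r))
  fragment_id <- rep_len(as.character(fragment_id), length(r))
  if (any(role != "sample" & !is.na(fragment_id))) {
    dl_abort("control wells must not carry a fragment_id", "dl_invalid_input")
  }
  if (any(role == "sample" & is.na(fragment_id))) {
    dl_abort("sample wells must carry a fragment_id", "dl_invalid_input")
  }
  out <- data.frame(fragment_id = fragment_id,
                    replicate_index = as.integer(rep_len(replicate_index,
                                                         length(r))),
                    r = r, role = role, stringsAsFactors = FALSE)
  class(out) <- c("screen_wells", "data.frame")
  out
}

#' Buffer-relative anisotropy per well
#'
#' Expresses every well's anisotropy relative to the buffer control wells on
#' the same plate. In the default `"ratio"` mode `r_rel = r / mean(r_buffer)`
#' so buffer wells average to 1 and the scale is dimensionless and
#' plate-comparable; `"difference"` mode returns `r - mean(r_buffer)`.
#'
#' @param wells a [screen_wells()] table with >= 2 buffer wells.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return The input table with an added `r_rel` column.
#' @export
relative_anisotropy <- function(wells, mode = c("ratio", "difference")) {
  stopifnot(inherits(wells, "screen_wells"))
  mode <- match.arg(mode)
  buf <- wells$r[wells$role == "buffer"]
  if (length(buf) < 2) {
    dl_abort("need >= 2 buffer wells to normalize a plate",
             "dl_invalid_input")
  }
  m <- mean(buf)
  if (mode == "ratio" && m <= 0) {
    dl_abort("degenerate control: mean buffer anisotropy <= 0",
             "dl_degenerate")
  }
  wells$r_rel <- if (mode == "ratio") wells$r / m else wells$r - m
  wells
}

#' Replicate mean and sample standard deviation
#'
#' @param values numeric replicate measurements (>= 1 value).
#' @return List with `mean` and `sd` (the n-1 sample SD; 0 with a warning
#'   for a single replicate).
#' @export
replicate_stats <- function(values) {
  if (length(values) == 0) {
    dl_abort("empty replicate set", "dl_invalid_input")
  }
  stopifnot_finite(values, "values")
  if (length(values) == 1) {
    dl_warn("single replicate: SD reported as 0", "dl_single_replicate")
    return(list(mean = values, sd = 0))
  }
  list(mean = mean(values), sd = stats::sd(values))
}

#' Dual screen thresholds: buffer-based and anchor-based mean minus 3 SD
#'
#' Each threshold is `mean - k * SD` of the corresponding control group's
#' buffer-relative anisotropies, with SDs taken from the same plate's
#' control replicates (no cross-plate pooling).
#'
#' @param buffer_rel buffer-control relative anisotropies (>= 2 values).
#' @param anchor_rel anchor-control relative anisotropies (>= 2 values).
#' @param k threshold multiplier (default 3).
#' @return A `threshold_pair` list with `t_neg` (buffer-based) and `t_pos`
#'   (anchor-based).
#' @export
compute_thresholds <- function(buffer_rel, anchor_rel, k = 3) {
  stopifnot_finite(k, "k", positive = TRUE)
  one <- function(v, nm) {
    if (length(v) < 2) {
      dl_abort(sprintf("need >= 2 %s control replicates for a threshold", nm),
               "dl_invalid_input")
    }
    stopifnot_finite(v, nm)
    mean(v) - k * stats::sd(v)
  }
  structure(list(t_neg = one(buffer_rel, "buffer"),
                 t_pos = one(anchor_rel, "anchor"), k = k),
            class = "threshold_pair")
}

#' Aggregate screen wells into per-fragment results
#'
#' Collapses duplicate sample wells to a per-fragment mean and sample SD of
#' the relative anisotropy.
#'
#' @param wells output of [relative_anisotropy()].
#' @param min_replicates minimum wells per fragment (default 2, the screen's
#'   duplicate design; raise to require triplicates).
#' @return A `screen_results` data frame: `fragment_id`, `r_rel_mean`,
#'   `r_rel_sd`, `n`.
#' @export
screen_results <- function(wells, min_replicates = 2L) {
  stopifnot(inherits(wells, "screen_wells"), !is.null(wells$r_rel))
  sam <- wells[wells$role == "sample", , drop = FALSE]
  sp <- split(sam$r_rel, sam$fragment_id)
  if (any(lengths(sp) < min_replicates)) {
    dl_abort(sprintf("fragments with fewer than %d replicate wells present",
                     min_replicates), "dl_invalid_input")
  }
  out <- data.frame(
    fragment_id = names(sp),
    r_rel_mean = vapply(sp, mean, numeric(1)),
    r_rel_sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0,
                      numeric(1)),
    n = lengths(sp), row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("screen_results", "data.frame")
  out
}

#' Tiered hit calling against the dual thresholds
#'
#' A fragment is a `"hit"` when its mean relative anisotropy falls strictly
#' below the buffer-based threshold `t_neg`, and `"improved"` when it
#' additionally falls strictly below the anchor-based threshold `t_pos`
#' (i.e. it outperforms the anchor peptide itself). Ties at a threshold are
#' non-hits. The "improved" tier is nested inside "hit".
#'
#' @param results a [screen_results()] table.
#' @param thresholds a [compute_thresholds()] pair from the same plate.
#' @return The results table with a `tier` factor
#'   (`none < hit < improved`), sorted ascending by `r_rel_mean`.
#' @export
call_hits <- function(results, thresholds) {
  stopifnot(inherits(results, "screen_results"),
            inherits(thresholds, "threshold_pair"))
  tier <- rep("none", nrow(results))
  is_hit <- results$r_rel_mean < thresholds$t_neg
  tier[is_hit] <- "hit"
  tier[is_hit & results$r_rel_mean < thresholds$t_pos] <- "improved"
  results$tier <- factor(tier, levels = c("none", "hit", "improved"),
                         ordered = TRUE)
  results <- results[order(results$r_rel_mean), , drop = FALSE]
  rownames(results) <- NULL
  attr(results, "thresholds") <- thresholds
  results
}

#' Property-potency correlation for screen hits
#'
#' Joins screen results to a fragment descriptor table and reports the
#' Spearman rank correlation between each requested property and the mean
#' relative anisotropy, along with the joined scatter records (for plotting
#' MW or LogS against relative anisotropy).
#'
#' @param results a [screen_results()] (optionally tiered) table.
#' @param fragments a fragment descriptor data frame with a `fragment_id`
#'   column and the property columns.
#' @param properties property columns to correlate (default `MW`, `LogS`).
#' @return List with `scatter` (joined records) and `rho` (named Spearman
#'   correlations; `NA` when the outcome or property has zero variance).
#' @export
property_correlation <- function(results, fragments,
                                 properties = c("MW", "LogS")) {
  stopifnot(inherits(results, "data.frame"), inherits(fragments, "data.frame"))
  missing_ids <- setdiff(results$fragment_id, fragments$fragment_id)
  if (length(missing_ids) > 0) {
    dl_abort(sprintf("fragment(s) missing from descriptor table: %s",
                     paste(missing_ids, collapse = ", ")),
             "dl_lookup_error")
  }
  missing_cols <- setdiff(properties, names(fragments))
  if (length(missing_cols) > 0) {
    dl_abort(sprintf("descriptor column(s) absent: %s",
                     paste(missing_cols, collapse = ", ")),
             "dl_lookup_error")
  }
  scatter <- merge(as.data.frame(results),
                   fragments[, c("fragment_id", properties), drop = FALSE],
                   by = "fragment_id", sort = TRUE)
  rho <- vapply(properties, function(pr) {
    y <- scatter$r_rel_mean
    xv <- scatter[[pr]]
    if (length(unique(y)) < 2 || length(unique(xv)) < 2) return(NA_real_)
    stats::cor(xv, y, method = "spearman")
  }, numeric(1))
  list(scatter = scatter, rho = rho)
}
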