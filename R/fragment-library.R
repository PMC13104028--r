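#' Fragment descriptor table
#'
#' Validates a fragment-library table: identifier, optional SMILES, and the
#' physicochemical descriptors used by the relaxed rule-of-three filter
#' (`MW` in Da, `HBA`/`HBD` counts, `clogP`, optional `LogS`). Descriptors
#' supplied in the table are treated as authoritative; use
#' [fill_descriptors()] to compute missing values from structures.
#'
#' @param df data frame with at least `fragment_id` and any of `smiles`,
#'   `MW`, `HBA`, `HBD`, `clogP`, `LogS`.
#' @return A validated `fragment_table` data frame.
#' @export
fragment_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(df$fragment_id)) {
    dl_abort("fragment table needs a `fragment_id` column", "dl_invalid_input")
  }
  if (anyDuplicated(df$fragment_id)) {
    dl_abort("duplicate fragment_id in table", "dl_invalid_input")
  }
  for (col in c("smiles", "MW", "HBA", "HBD", "clogP", "LogS")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  df$MW <- num(df$MW); df$HBA <- num(df$HBA); df$HBD <- num(df$HBD)
  df$clogP <- num(df$clogP); df$LogS <- num(df$LogS)
  bad <- which(!is.na(df$MW) & df$MW <= 0)
  if (length(bad)) {
    dl_abort(sprintf("non-positive MW for fragment(s): %s",
                     paste(df$fragment_id[bad], collapse = ", ")),
             "dl_invalid_input")
  }
  bad <- which((!is.na(df$HBA) & (df$HBA < 0 | df$HBA != round(df$HBA))) |
                 (!is.na(df$HBD) & (df$HBD < 0 | df$HBD != round(df$HBD))))
  if (length(bad)) {
    dl_abort(sprintf("HBA/HBD must be non-negative integers (fragment %s)",
                     paste(df$fragment_id[bad], collapse = ", ")),
             "dl_invalid_input")
  }
  class(df) <- c("fragment_table", "data.frame")
  df
}

#' Fill missing descriptors from structures
#'
#' Computes MW/HBA/HBD/clogP with the cheminformatics backend for records
#' whose table value is missing; values already present are never
#' overwritten (the input table is authoritative).
#'
#' @param frags a [fragment_table()].
#' @return The table with missing descriptor values filled where a parseable
#'   SMILES is available.
#' @export
fill_descriptors <- function(frags) {
  frags <- fragment_table(frags)
  need <- which((is.na(frags$MW) | is.na(frags$HBA) | is.na(frags$HBD) |
                   is.na(frags$clogP)) & !is.na(frags$smiles))
  if (length(need) == 0) return(frags)
  d <- chem_descriptors(frags$smiles[need], ids = frags$fragment_id[need])
  for (i in seq_along(need)) {
    j <- need[i]
    if (d$ok[i] != 1) next
    if (is.na(frags$MW[j])) frags$MW[j] <- d$MW[i]
    if (is.na(frags$HBA[j])) frags$HBA[j] <- d$HBA[i]
    if (is.na(frags$HBD[j])) frags$HBD[j] <- d$HBD[i]
    if (is.na(frags$clogP[j])) frags$clogP[j] <- d$clogP[i]
  }
  frags
}

#' Relaxed rule-of-three fragment filter
#'
#' Retains a fragment iff `80 < MW < 400` (strict bounds, Da), `HBA <= 3`,
#' `HBD <= 3` and `clogP <= 5` (non-strict). The MW window is wider than the
#' classical rule of three to leave room for the formyl group every aldehyde
#' fragment must carry. Records with a missing required descriptor are
#' excluded with reason `"missing-descriptor"`.
#'
#' @param frags a [fragment_table()] (or coercible data frame).
#' @param mw_bounds strict MW window, default `c(80, 400)`.
#' @param hba_max,hbd_max,clogp_max non-strict upper bounds (3, 3, 5).
#' @return List with `retained` (fragment_table) and `rejected` (data frame
#'   with a `reason` column naming every violated rule, comma-separated).
#' @export
rule_of_three_filter <- function(frags, mw_bounds = c(80, 400),
                                 hba_max = 3, hbd_max = 3, clogp_max = 5) {
  frags <- fragment_table(frags)
  reasons <- vapply(seq_len(nrow(frags)), function(i) {
    row <- frags[i, ]
    if (any(is.na(c(row$MW, row$HBA, row$HBD, row$clogP)))) {
      return("missing-descriptor")
    }
    viol <- character(0)
    if (!(row$MW > mw_bounds[1] && row$MW < mw_bounds[2])) viol <- c(viol, "MW")
    if (row$HBA > hba_max) viol <- c(viol, "HBA")
    if (row$HBD > hbd_max) viol <- c(viol, "HBD")
    if (row$clogP > clogp_max) viol <- c(viol, "clogP")
    paste(viol, collapse = ",")
  }, character(1))
  keep <- !nzchar(reasons)
  rejected <- as.data.frame(frags)[!keep, , drop = FALSE]
  rejected$reason <- reasons[!keep]
  rownames(rejected) <- NULL
  list(retained = frags[keep, , drop = FALSE], rejected = rejected)
}

#' Greedy structural-diversity pruning
#'
#' Iterates over the table in input order and keeps a record iff its
#' path-fingerprint Tanimoto similarity to every previously kept record is
#' strictly below `similarity_threshold`; deterministic for a fixed input
#' order. Emulates the removal of structurally similar compounds during
#' library design.
#'
#' @param frags a [fragment_table()]; every record needs a SMILES.
#' @param similarity_threshold Tanimoto cutoff in (0, 1\]. Default 0.7.
#' @return The pruned `fragment_table` (attribute `"pruned_ids"` lists the
#'   removed identifiers).
#' @export
diversity_prune <- function(frags, similarity_threshold = 0.7) {
  frags <- fragment_table(frags)
  if (!is.numeric(similarity_threshold) || similarity_threshold <= 0 ||
      similarity_threshold > 1) {
    dl_abort("similarity_threshold must be in (0, 1]", "dl_invalid_input")
  }
  if (any(is.na(frags$smiles))) {
    dl_abort(sprintf("fragment(s) without structure: %s",
                     paste(frags$fragment_id[is.na(frags$smiles)],
                           collapse = ", ")), "dl_invalid_input")
  }
  fps <- chem_fingerprints(frags$smiles, ids = frags$fragment_id)
  bad <- names(fps)[vapply(fps, is.null, logical(1))]
  if (length(bad)) {
    dl_abort(sprintf("unparsable SMILES for fragment(s): %s",
                     paste(bad, collapse = ", ")), "dl_invalid_input")
  }
  kept <- integer(0)
  for (i in seq_len(nrow(frags))) {
    sims <- vapply(kept, function(j) tanimoto(fps[[i]], fps[[j]]), numeric(1))
    if (all(sims < similarity_threshold)) kept <- c(kept, i)
  }
  out <- frags[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pruned_ids") <- setdiff(frags$fragment_id,
                                     frags$fragment_id[kept])
  out
}

#' Exclude fragments bearing undesired functional groups
#'
#' Removes every record matching any of the supplied SMARTS substructure
#' patterns; the report names the first matching pattern per record. The
#' default pattern list is empty (the undesired groups are assay-specific
#' and must be supplied by the user).
#'
#' @param frags a [fragment_table()] with parseable SMILES.
#' @param patterns named character vector of SMARTS patterns (may be empty).
#'   All patterns are validated before any record is processed.
#' @return List with `retained` (fragment_table) and `excluded` (data frame
#'   with a `pattern` column naming the matching pattern).
#' @export
exclude_functional_groups <- function(frags, patterns = character(0)) {
  frags <- fragment_table(frags)
  if (length(patterns) == 0) {
    excluded <- as.data.frame(frags)[0, , drop = FALSE]
    excluded$pattern <- character(0)
    return(list(retained = frags, excluded = excluded))
  }
  if (any(is.na(frags$smiles))) {
    dl_abort(sprintf("fragment(s) without structure: %s",
                     paste(frags$fragment_id[is.na(frags$smiles)],
                           collapse = ", ")), "dl_invalid_input")
  }
  res <- chem_substructure(frags$smiles, patterns, ids = frags$fragment_id)
  if (any(!res$ok)) {
    dl_abort(sprintf("unparsable SMILES for fragment(s): %s",
                     paste(frags$fragment_id[!res$ok], collapse = ", ")),
             "dl_invalid_input")
  }
  hit_any <- rowSums(res$match) > 0
  first_pat <- apply(res$match, 1, function(v) {
    if (any(v)) colnames(res$match)[which(v)[1]] else NA_character_
  })
  excluded <- as.data.frame(frags)[hit_any, , drop = FALSE]
  excluded$pattern <- first_pat[hit_any]
  rownames(excluded) <- NULL
  retained <- frags[!hit_any, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}
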