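# Thin wrapper around the bundled RDKit helper (inst/python/chem_backend.py).
# Structure-aware operations (fingerprints, SMARTS substructure matching,
# descriptor calculation) are delegated to the python interpreter on PATH in
# one batched call per request; everything else in the package is pure R.

chem_backend_path <- function() {
  p <- system.file("python", "chem_backend.py", package = "dlscreen")
  if (!nzchar(p) || !file.exists(p)) {
    dl_abort("bundled chem_backend.py not found; is dlscreen installed?",
             "dl_config_error")
  }
  p
}

chem_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    dl_abort("no python interpreter on PATH for the cheminformatics backend",
             "dl_config_error")
  }
  py
}

chem_backend_call <- function(mode, smiles, ids = NULL, patterns = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(in_csv, out_csv)), add = TRUE)
  utils::write.csv(data.frame(id = ids, smiles = smiles,
                              stringsAsFactors = FALSE),
                   in_csv, row.names = FALSE, quote = TRUE)
  args <- c(chem_backend_path(), mode, in_csv, out_csv)
  if (!is.null(patterns)) {
    pat_csv <- tempfile(fileext = ".csv")
    on.exit(unlink(pat_csv), add = TRUE)
    utils::write.csv(data.frame(pattern_id = names(patterns),
                                smarts = unname(patterns),
                                stringsAsFactors = FALSE),
                     pat_csv, row.names = FALSE, quote = TRUE)
    args <- c(args, pat_csv)
  }
  status <- suppressWarnings(
    system2(chem_python(), shQuote(args), stdout = FALSE, stderr = TRUE)
  )
  err <- attr(status, "status")
  if (!is.null(err) && err == 3) {
    dl_abort(paste("invalid substructure pattern:",
                   paste(status, collapse = " ")), "dl_config_error")
  }
  if (!is.null(err) && err != 0) {
    dl_abort(paste("cheminformatics backend failed:",
                   paste(status, collapse = " ")), "dl_config_error")
  }
  utils::read.csv(out_csv, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(id = "character"))
}

#' Path-based hashed fingerprints for SMILES strings
#'
#' Computes 2048-bit RDKit path (Daylight-like) fingerprints through the
#' bundled python backend.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional record identifiers used in error messages.
#' @return A named list of sorted integer vectors (on-bit indices); entries
#'   for unparsable SMILES are `NULL`.
#' @export
chem_fingerprints <- function(smiles, ids = NULL) {
  res <- chem_backend_call("fingerprint", smiles, ids)
  fps <- lapply(seq_len(nrow(res)), function(i) {
    if (res$ok[i] != 1) return(NULL)
    b <- res$bits[i]
    if (is.na(b) || !nzchar(b)) integer(0) else
      as.integer(strsplit(b, " ", fixed = TRUE)[[1]])
  })
  names(fps) <- res$id
  fps
}

#' Tanimoto similarity of two bit-index fingerprints
#'
#' @param a,b integer vectors of on-bit indices.
#' @return Similarity in \[0, 1\]; 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Substructure matches against SMARTS patterns
#'
#' @param smiles character vector of SMILES.
#' @param patterns named character vector of SMARTS patterns. All patterns
#'   are validated before any record is processed; an invalid pattern raises
#'   a configuration error.
#' @param ids optional record identifiers.
#' @return List with `ok` (logical: SMILES parsed) and `match` (logical
#'   matrix, records x patterns).
#' @export
chem_substructure <- function(smiles, patterns, ids = NULL) {
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    names(patterns) <- paste0("pattern_", seq_along(patterns))
  }
  res <- chem_backend_call("match", smiles, ids, patterns = patterns)
  ok <- res$ok == 1
  mat <- as.matrix(res[, names(patterns), drop = FALSE]) == 1
  rownames(mat) <- res$id
  list(ok = ok, match = mat)
}

#' Molecular descriptors from SMILES
#'
#' Computes MW, hydrogen-bond acceptor/donor counts and Crippen clogP via
#' the bundled backend; used to fill missing descriptor-table values.
#'
#' @inheritParams chem_fingerprints
#' @return Data frame with columns `id`, `ok`, `MW`, `HBA`, `HBD`, `clogP`.
#' @export
chem_descriptors <- function(smiles, ids = NULL) {
  chem_backend_call("descriptors", smiles, ids)
}
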