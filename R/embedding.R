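# Protein representations: mean-pool residue embeddings, then normalize to
# unit length so that every protein contributes equally to the angular
# (functional) space of the proteome average.

#' Mean-pool a residue embedding matrix into one protein vector
#'
#' @param residue_matrix Numeric matrix with one row per residue (L x d).
#' @return Numeric vector of length d: the column means.
#' @export
mean_pool <- function(residue_matrix) {
  residue_matrix <- as.matrix(residue_matrix)
  if (nrow(residue_matrix) == 0L) {
    abort("empty protein: cannot mean-pool zero residues",
          class = "phagempr_input_error")
  }
  colMeans(residue_matrix)
}

#' Normalize a vector to unit Euclidean length
#'
#' @param v Numeric vector with positive norm.
#' @return `v / ||v||`, with `||result|| == 1` to within 1e-9.
#' @export
normalize_unit <- function(v) {
  v <- as.numeric(v)
  nrm <- sqrt(sum(v * v))
  if (!is.finite(nrm) || nrm <= 0) {
    abort("degenerate embedding: zero or non-finite norm",
          class = "phagempr_input_error")
  }
  v / nrm
}

#' Embed a proteome's records into unit protein representations
#'
#' Applies `backend$embed()`, [mean_pool()] and [normalize_unit()] to each
#' record. Per-protein backend failures are collected in the `failures`
#' attribute (a tibble with `protein_id` and `error`), never silently
#' dropped.
#'
#' @param records Tibble/data frame with columns `protein_id` and `sequence`
#'   (as returned by [read_proteomes()]).
#' @param backend A backend list from [get_backend()] or [mock_backend()].
#' @return Numeric matrix (n_ok x d) of unit rows, rownames = protein ids,
#'   with attribute `failures`.
#' @export
embed_proteome <- function(records, backend) {
  stopifnot(is.data.frame(records), all(c("protein_id", "sequence") %in% names(records)))
  if (!is.list(backend) || !is.function(backend$embed)) {
    abort("backend unavailable: expected a list with an embed() function",
          class = "phagempr_config_error")
  }
  rows <- vector("list", nrow(records))
  fail_id <- character(0)
  fail_msg <- character(0)
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(
      normalize_unit(mean_pool(backend$embed(records$sequence[[i]]))),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fail_id <- c(fail_id, records$protein_id[[i]])
      fail_msg <- c(fail_msg, conditionMessage(res))
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- res
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) {
    abort("all proteins failed to embed", class = "phagempr_input_error")
  }
  out <- do.call(rbind, rows[ok])
  rownames(out) <- records$protein_id[ok]
  attr(out, "failures") <- tibble(protein_id = fail_id, error = fail_msg)
  attr(out, "backend") <- backend$name
  out
}
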