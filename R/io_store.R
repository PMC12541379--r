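# Plain-text vector store: a directory holding an ordered accession list,
# a numeric matrix written at full round-trip precision, and a JSON metadata
# sidecar. Computation is always done in float64; values on disk are decimal
# strings that parse back bit-exactly.

#' Write an accession-keyed vector store
#'
#' @param path Directory to create (must not already contain a store unless
#'   `overwrite = TRUE`).
#' @param accessions Character vector of unique row keys (length n).
#' @param matrix Numeric matrix (n x d).
#' @param metadata Named list of provenance fields (backend, model,
#'   parameters). `n` and `d` are filled in automatically.
#' @param overwrite Overwrite an existing store.
#' @return `path`, invisibly.
#' @export
write_vector_store <- function(path, accessions, matrix, metadata = list(),
                               overwrite = FALSE) {
  matrix <- as.matrix(matrix)
  accessions <- as.character(accessions)
  if (length(accessions) != nrow(matrix)) {
    abort("shape mismatch: length(accessions) != nrow(matrix)",
          class = "phagempr_input_error")
  }
  if (anyDuplicated(accessions)) {
    abort("duplicate accessions in vector store", class = "phagempr_input_error")
  }
  if (dir.exists(path) && file.exists(file.path(path, "matrix.tsv")) && !overwrite) {
    abort(sprintf("store already exists at '%s'", path), class = "phagempr_input_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeLines(accessions, file.path(path, "accessions.txt"))
  lines <- apply(matrix, 1L, function(r) paste(format_roundtrip(r), collapse = "\t"))
  writeLines(lines, file.path(path, "matrix.tsv"))
  meta <- modifyList(
    list(format = "phagempr-vector-store", version = 1L,
         n = nrow(matrix), d = ncol(matrix)),
    metadata
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Shortest decimal representation that round-trips a double exactly.
format_roundtrip <- function(x) {
  s <- formatC(x, digits = 15, format = "g")
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- formatC(x[bad], digits = 17, format = "g")
  s
}

#' Read a vector store written by [write_vector_store()]
#'
#' @param path Store directory.
#' @return A `vector_store` list: `accessions` (character), `matrix`
#'   (numeric n x d with accession rownames), `d`, `metadata`.
#' @export
read_vector_store <- function(path) {
  need <- file.path(path, c("accessions.txt", "matrix.tsv", "metadata.json"))
  if (!all(file.exists(need))) {
    abort(sprintf("'%s' is not a vector store (missing files)", path),
          class = "phagempr_format_error")
  }
  accessions <- readLines(need[[1]])
  vals <- scan(need[[2]], what = numeric(), sep = "\t", quiet = TRUE)
  n <- length(accessions)
  if (n == 0L || length(vals) %% n != 0L) {
    abort("corrupt store: matrix values not a multiple of accession count",
          class = "phagempr_format_error")
  }
  mat <- matrix(vals, nrow = n, byrow = TRUE,
                dimnames = list(accessions, NULL))
  if (length(accessions) != nrow(mat)) {
    abort("corrupt store: accession count != matrix rows",
          class = "phagempr_format_error")
  }
  metadata <- jsonlite::read_json(need[[3]], simplifyVector = TRUE)
  structure(
    list(accessions = accessions, matrix = mat, d = ncol(mat), metadata = metadata),
    class = "vector_store"
  )
}

#' @export
print.vector_store <- function(x, ...) {
  cat(sprintf("<vector_store> %d accessions x %d dims\n", length(x$accessions), x$d))
  invisible(x)
}

#' Write a JSON run-metadata sidecar next to an artifact
#'
#' @param path Artifact path; the sidecar is written at `<path>.run.json`.
#' @param config Named list of parameters to record.
#' @return Sidecar path, invisibly.
#' @export
write_run_sidecar <- function(path, config) {
  sidecar <- paste0(path, ".run.json")
  payload <- list(
    package = "phagempr",
    version = as.character(utils::packageVersion("phagempr")),
    config = config
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
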