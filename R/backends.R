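# Residue-embedding backends.
#
# A backend is a list with fields `name`, `dim` and `embed(sequence)`, where
# `embed` maps one amino-acid string to an (L x dim) matrix of per-residue
# vectors. Real protein language models plug in through the same contract;
# everything in this package runs against the deterministic backends below,
# so the method's core is exercisable without a GPU.

backend_env <- new.env(parent = emptyenv())

#' Register an embedding backend constructor
#'
#' @param name Backend name used by [get_backend()] and the CLI `--backend`
#'   flag.
#' @param constructor Function returning a backend list (fields `name`,
#'   `dim`, `embed`).
#' @return Invisibly, `name`.
#' @export
register_backend <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1L, is.function(constructor))
  assign(name, constructor, envir = backend_env)
  invisible(name)
}

#' Look up and construct a registered backend
#'
#' @param name Registered backend name.
#' @param ... Passed to the backend constructor.
#' @return A backend list.
#' @export
get_backend <- function(name, ...) {
  if (!exists(name, envir = backend_env, inherits = FALSE)) {
    abort(sprintf(
      "unknown embedding backend '%s' (registered: %s)",
      name, paste(ls(backend_env), collapse = ", ")
    ), class = "phagempr_config_error")
  }
  ctor <- get(name, envir = backend_env, inherits = FALSE)
  ctor(...)
}

#' Deterministic hash-table mock backend
#'
#' Each amino-acid letter is mapped to a fixed row of a seeded random matrix,
#' so `embed()` is a pure function of the sequence. Used for all desk-scale
#' runs and tests in place of a protein language model.
#'
#' @param dim Embedding dimension.
#' @param seed Seed for the per-letter table.
#' @return A backend list with fields `name`, `dim`, `embed`.
#' @export
mock_backend <- function(dim = 16L, seed = 1L) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYBJOUXZ*", "")[[1]]
  table <- withr_seed(seed, {
    matrix(rnorm(length(alphabet) * dim), nrow = length(alphabet),
           dimnames = list(alphabet, NULL))
  })
  list(
    name = sprintf("mock-d%d-s%d", dim, seed),
    dim = as.integer(dim),
    embed = function(sequence) {
      letters <- strsplit(toupper(sequence), "")[[1]]
      if (length(letters) == 0L) abort("empty protein", class = "phagempr_input_error")
      unknown <- setdiff(letters, alphabet)
      if (length(unknown) > 0L) {
        abort(sprintf("unknown residue(s): %s", paste(unique(unknown), collapse = "")),
              class = "phagempr_input_error")
      }
      table[letters, , drop = FALSE]
    }
  )
}

#' Constant-row mock backend
#'
#' Returns the same row for every residue; useful for exact-value tests.
#'
#' @param row Numeric vector used for every residue.
#' @return A backend list.
#' @export
constant_backend <- function(row) {
  row <- as.numeric(row)
  list(
    name = "constant",
    dim = length(row),
    embed = function(sequence) {
      L <- nchar(sequence)
      if (L == 0L) abort("empty protein", class = "phagempr_input_error")
      matrix(rep(row, each = L), nrow = L)
    }
  )
}

# Local seed scope without depending on withr at run time.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.onLoad <- function(libname, pkgname) {
  register_backend("mock", mock_backend)
  register_backend("constant", constant_backend)
}
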